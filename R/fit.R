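#' Voxelwise parameter maps
#'
#' Container for fitted (or ground-truth) maps sharing one grid: `s0`, `md`
#' (um^2/ms), `fa`, `mk`, `mk_a`, `mk_i` and an integer `fit_flags` map
#' (0 = converged, 1 = a kurtosis constraint is active, 2 = non-positive
#' signal / not fitted, 3 = non-convergence).
#'
#' @param s0,md,fa,mk,mk_a,mk_i 3D arrays (or `NULL` where not estimated).
#' @param fit_flags Integer 3D array.
#' @param voxel_size Length-3 voxel size in mm.
#' @return An object of class `parameter_maps`.
#' @export
parameter_maps <- function(s0 = NULL, md = NULL, fa = NULL, mk = NULL,
                           mk_a = NULL, mk_i = NULL, fit_flags = NULL,
                           voxel_size = c(1, 1, 1)) {
  maps <- list(s0 = s0, md = md, fa = fa, mk = mk, mk_a = mk_a, mk_i = mk_i)
  dims <- unique(lapply(Filter(Negate(is.null), maps), dim))
  if (length(dims) > 1) stop("all maps must share one grid")
  structure(c(maps, list(fit_flags = fit_flags,
                         voxel_size = rep(voxel_size, length.out = 3))),
            class = "parameter_maps")
}

#' Powder (directional) average of a DWI volume
#'
#' Arithmetic mean of the signal within each shell, per voxel. With both
#' linear and spherical shells this is the directionally averaged signal
#' that the cumulant model [fit_qti()] is fitted to.
#'
#' @param vol A [dwi_volume()].
#' @return A `powder_signal` object: 4D array (x, y, z, shell) plus the
#'   per-shell table.
#' @export
powder_average <- function(vol) {
  stopifnot(inherits(vol, "dwi_volume"))
  sch <- vol$scheme
  n_sh <- nrow(sch$shells)
  if (any(sch$shells$n_in_shell == 0)) stop("empty shell in scheme")
  d <- dim(vol$data)
  mat <- matrix(vol$data, prod(d[1:3]), d[4])
  out <- matrix(0, prod(d[1:3]), n_sh)
  for (s in seq_len(n_sh)) {
    cols <- which(sch$shell_id == sch$shells$shell_id[s])
    out[, s] <- rowMeans(mat[, cols, drop = FALSE])
  }
  structure(list(data = array(out, c(d[1:3], n_sh)), shells = sch$shells,
                 voxel_size = vol$voxel_size),
            class = "powder_signal")
}

# Design matrix of the powder cumulant model in its linear parametrization
# theta = (log S0, MD, P, Q) with P = MK_I * MD^2, Q = MK_A * MD^2:
# log S = log S0 - b MD + b^2 (P + bD^2 Q) / 6
qti_design <- function(b, b_delta) {
  cbind(1, -b, b^2 / 6, b^2 * b_delta^2 / 6)
}

qti_log_model <- function(theta, b, b_delta) {
  # theta = (log S0, MD, MK_I, MK_A)
  theta[1] - b * theta[2] +
    b^2 * (theta[3] + b_delta^2 * theta[4]) * theta[2]^2 / 6
}

#' Fit the powder-averaged cumulant model (MK_A / MK_I separation)
#'
#' Fits, per voxel, `log S(b, bD) = log S0 - b MD + b^2 (MK_I + bD^2 MK_A)
#' MD^2 / 6` to the shell-averaged signal by least squares on the
#' log-signal, with box constraints `MK_I, MK_A` in \[-1, 4\] (outlier
#' guard), `MD >= 0`, `S0 > 0`. The unconstrained optimum is available in
#' closed form through the linear reparametrization
#' `(log S0, MD, MK_I MD^2, MK_A MD^2)`; voxels violating a constraint are
#' refined with box-constrained quasi-Newton (L-BFGS-B) started from the
#' clipped linear solution — the procedure is deterministic. With
#' `residual = "signal"` every voxel is instead refined by minimizing
#' signal-domain squared residuals from the same start.
#'
#' Requires at least 4 shells spanning at least 2 distinct `b_delta` and 3
#' distinct `b` values; otherwise MK_A and MK_I are not separable.
#'
#' @param powder A `powder_signal` from [powder_average()].
#' @param mask Optional logical 3D array restricting the fit.
#' @param residual `"log"` (default) or `"signal"` residual convention.
#' @return A [parameter_maps()] with `s0`, `md`, `mk_i`, `mk_a`, `fit_flags`.
#' @export
fit_qti <- function(powder, mask = NULL, residual = c("log", "signal")) {
  residual <- match.arg(residual)
  stopifnot(inherits(powder, "powder_signal"))
  sh <- powder$shells
  if (nrow(sh) < 4 || length(unique(sh$b_delta)) < 2 ||
      length(unique(round(sh$b, 9))) < 3)
    stop("scheme cannot separate MK_A and MK_I: need >= 4 shells, ",
         ">= 2 b_delta values and >= 3 b values")
  d <- dim(powder$data)
  grid <- d[1:3]
  n_vox_all <- prod(grid)
  sig <- matrix(powder$data, n_vox_all, d[4])
  vox <- if (is.null(mask)) seq_len(n_vox_all) else which(mask)

  X <- qti_design(sh$b, sh$b_delta)
  XtXinv_Xt <- solve(crossprod(X), t(X))

  s0m <- mdm <- mkim <- mkam <- array(NA_real_, grid)
  flg <- array(2L, grid)   # default: not fitted

  ok <- vox[rowSums(sig[vox, , drop = FALSE] <= 0) == 0]
  if (length(ok)) {
    L <- log(sig[ok, , drop = FALSE])
    theta <- L %*% t(XtXinv_Xt)                      # n_ok x 4
    md <- theta[, 2]
    mki <- ifelse(md > 0, theta[, 3] / md^2, NA_real_)
    mka <- ifelse(md > 0, theta[, 4] / md^2, NA_real_)
    inbox <- md >= 0 & !is.na(mki) &
      mki >= -1 & mki <= 4 & mka >= -1 & mka <= 4
    s0m[ok] <- exp(theta[, 1]); mdm[ok] <- md
    mkim[ok] <- mki; mkam[ok] <- mka
    flg[ok] <- 0L
    refine <- which(!inbox)
    if (residual == "signal") refine <- seq_along(ok)
    for (j in refine) {
      init <- c(theta[j, 1], max(md[j], 1e-4),
                min(4, max(-1, ifelse(is.na(mki[j]), 0, mki[j]))),
                min(4, max(-1, ifelse(is.na(mka[j]), 0, mka[j]))))
      yl <- L[j, ]; ys <- sig[ok[j], ]
      obj <- if (residual == "log") {
        function(p) sum((yl - qti_log_model(p, sh$b, sh$b_delta))^2)
      } else {
        function(p) sum((ys - exp(qti_log_model(p, sh$b, sh$b_delta)))^2)
      }
      fit <- stats::optim(init, obj, method = "L-BFGS-B",
                          lower = c(-Inf, 0, -1, -1),
                          upper = c(Inf, Inf, 4, 4),
                          control = list(factr = 10, maxit = 500))
      v <- ok[j]
      s0m[v] <- exp(fit$par[1]); mdm[v] <- fit$par[2]
      mkim[v] <- fit$par[3]; mkam[v] <- fit$par[4]
      clamped <- any(abs(fit$par[3:4] - c(-1, -1)) < 1e-8) ||
        any(abs(fit$par[3:4] - c(4, 4)) < 1e-8)
      flg[v] <- if (fit$convergence != 0) 3L else if (clamped) 1L else 0L
    }
  }
  parameter_maps(s0 = s0m, md = mdm, mk_i = mkim, mk_a = mkam,
                 fit_flags = flg, voxel_size = powder$voxel_size)
}

lte_subset <- function(vol, b_max = Inf, b_min = -Inf) {
  sch <- vol$scheme
  keep <- which(abs(sch$b_delta - 1) < 1e-12 & sch$b <= b_max + 1e-9 &
                  sch$b >= b_min)
  list(idx = keep, b = sch$b[keep], g = sch$directions[keep, , drop = FALSE])
}

tensor_design <- function(b, g) {
  cbind(1, -b * cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
                      2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3],
                      2 * g[, 2] * g[, 3]))
}

tensor_from_coef <- function(coef6) {
  matrix(coef6[c(1, 4, 5, 4, 2, 6, 5, 6, 3)], 3, 3)
}

fa_from_eigs <- function(ev) {
  ev <- pmax(ev, 0)
  if (all(ev == 0)) return(0)
  m <- mean(ev)
  sqrt(1.5 * sum((ev - m)^2) / sum(ev^2))
}

#' Diffusion tensor fit (LTE data, low b)
#'
#' Log-linear least-squares tensor fit on linear-encoding shells with
#' `b <= b_max` (default 1.0 ms/um^2, limiting kurtosis bias). FA uses the
#' standard normalized eigenvalue variance with negative eigenvalues
#' clipped to 0; MD is the mean clipped eigenvalue.
#'
#' @param vol A [dwi_volume()].
#' @param mask Optional logical 3D restriction.
#' @param b_max Maximum b (ms/um^2) of shells entering the fit.
#' @return A [parameter_maps()] with `s0`, `md`, `fa`, `fit_flags`.
#' @export
fit_dti <- function(vol, mask = NULL, b_max = 1.0) {
  stopifnot(inherits(vol, "dwi_volume"))
  sub <- lte_subset(vol, b_max = b_max)
  if (length(sub$idx) < 7) stop("need >= 7 LTE measurements at b <= b_max")
  X <- tensor_design(sub$b, sub$g)
  if (qr(X)$rank < 7)
    stop("rank-deficient DTI design: directions not sufficiently non-collinear")
  d <- dim(vol$data)
  grid <- d[1:3]
  sig <- matrix(vol$data, prod(grid), d[4])[, sub$idx, drop = FALSE]
  vox <- if (is.null(mask)) seq_len(prod(grid)) else which(mask)
  s0m <- mdm <- fam <- array(NA_real_, grid)
  flg <- array(2L, grid)
  ok <- vox[rowSums(sig[vox, , drop = FALSE] <= 0) == 0]
  if (length(ok)) {
    beta <- log(sig[ok, , drop = FALSE]) %*% t(solve(crossprod(X), t(X)))
    s0m[ok] <- exp(beta[, 1])
    for (j in seq_along(ok)) {
      ev <- eigen(tensor_from_coef(beta[j, 2:7]), symmetric = TRUE,
                  only.values = TRUE)$values
      mdm[ok[j]] <- mean(pmax(ev, 0))
      fam[ok[j]] <- fa_from_eigs(ev)
    }
    flg[ok] <- 0L
  }
  parameter_maps(s0 = s0m, md = mdm, fa = fam, fit_flags = flg,
                 voxel_size = vol$voxel_size)
}

# 15 unique quartic monomials of a symmetric 4th-order tensor, with
# multiplicities, evaluated at direction g. Order is fixed package-wide.
quartic_design_row <- function(g) {
  x <- g[, 1]; y <- g[, 2]; z <- g[, 3]
  cbind(x^4, y^4, z^4,
        4 * x^3 * y, 4 * x^3 * z, 4 * y^3 * x, 4 * y^3 * z,
        4 * z^3 * x, 4 * z^3 * y,
        6 * x^2 * y^2, 6 * x^2 * z^2, 6 * y^2 * z^2,
        12 * x^2 * y * z, 12 * y^2 * x * z, 12 * z^2 * x * y)
}

#' Diffusion kurtosis fit (all LTE shells)
#'
#' Weighted linear least-squares fit of the DKI expansion
#' `log S = log S0 - b D(g) + b^2/6 V(g)` over all linear-encoding data,
#' where `D(g)` is the quadratic form of the diffusion tensor and
#' `V(g) = MD^2 W(g)` the quartic form of the (scaled) kurtosis tensor.
#' Weights are the squared observed signals (the usual first-order
#' variance stabilization for log-domain fits). The mean kurtosis MK is the
#' average directional apparent kurtosis `K(g) = V(g) / D(g)^2` over a
#' fixed deterministic 60-direction set.
#'
#' @param vol A [dwi_volume()].
#' @param mask Optional logical 3D restriction.
#' @return A [parameter_maps()] with `s0`, `md`, `mk`, `fit_flags`.
#' @export
fit_dki <- function(vol, mask = NULL) {
  stopifnot(inherits(vol, "dwi_volume"))
  sub <- lte_subset(vol)
  dirs_distinct <- unique(round(sub$g, 6))
  if (nrow(dirs_distinct) < 15)
    stop("DKI needs >= 15 distinct LTE directions")
  X <- cbind(tensor_design(sub$b, sub$g),
             (sub$b^2 / 6) * quartic_design_row(sub$g))
  d <- dim(vol$data)
  grid <- d[1:3]
  sig <- matrix(vol$data, prod(grid), d[4])[, sub$idx, drop = FALSE]
  vox <- if (is.null(mask)) seq_len(prod(grid)) else which(mask)
  s0m <- mdm <- mkm <- array(NA_real_, grid)
  flg <- array(2L, grid)
  gk <- mk_direction_set()
  M2 <- cbind(gk[, 1]^2, gk[, 2]^2, gk[, 3]^2, 2 * gk[, 1] * gk[, 2],
              2 * gk[, 1] * gk[, 3], 2 * gk[, 2] * gk[, 3])
  M4 <- quartic_design_row(gk)
  ok <- vox[rowSums(sig[vox, , drop = FALSE] <= 0) == 0]
  for (v in ok) {
    y <- log(sig[v, ])
    w <- sig[v, ]^2
    beta <- tryCatch(stats::lm.wfit(X, y, w)$coefficients, error = function(e) NULL)
    if (is.null(beta) || anyNA(beta)) { flg[v] <- 3L; next }
    dcoef <- beta[2:7]; vcoef <- beta[8:22]
    md <- sum(dcoef[1:3]) / 3
    d_app <- as.numeric(M2 %*% dcoef)
    v_app <- as.numeric(M4 %*% vcoef)
    if (any(d_app <= 0)) { flg[v] <- 3L; next }
    s0m[v] <- exp(beta[1]); mdm[v] <- md
    mkm[v] <- mean(v_app / d_app^2)
    flg[v] <- 0L
  }
  parameter_maps(s0 = s0m, md = mdm, mk = mkm, fit_flags = flg,
                 voxel_size = vol$voxel_size)
}

# Banded, row-renormalized 1D Gaussian convolution matrix (n x n). Row
# renormalization keeps constants exact, including at the edges.
gauss_conv_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  r <- max(1L, ceiling(4 * sigma_vox))
  idx <- seq_len(n)
  K <- outer(idx, idx, function(i, j)
    ifelse(abs(i - j) <= r, exp(-(i - j)^2 / (2 * sigma_vox^2)), 0))
  K / rowSums(K)
}

#' Gaussian pre-smoothing of DWI data
#'
#' Separable 3D Gaussian convolution of every measurement volume, with the
#' kernel standard deviation given in mm and converted per axis to voxels
#' (`sigma_mm / voxel_size`). Kernels are truncated at 4 sigma and
#' renormalized, so constant volumes pass through unchanged. Smoothing is
#' applied to the raw DWI data before any averaging or fitting.
#'
#' @param vol A [dwi_volume()].
#' @param sigma_mm Kernel standard deviation in mm (default 1.6).
#' @return A smoothed [dwi_volume()].
#' @export
smooth_volume <- function(vol, sigma_mm = 1.6) {
  stopifnot(inherits(vol, "dwi_volume"), sigma_mm >= 0)
  if (sigma_mm == 0) return(vol)
  d <- dim(vol$data)
  sig_vox <- sigma_mm / vol$voxel_size
  K1 <- gauss_conv_matrix(d[1], sig_vox[1])
  K2 <- gauss_conv_matrix(d[2], sig_vox[2])
  K3 <- gauss_conv_matrix(d[3], sig_vox[3])
  out <- vol$data
  for (m in seq_len(d[4])) {
    a <- out[, , , m]
    a <- array(K1 %*% matrix(a, d[1]), d[1:3])
    a <- aperm(array(K2 %*% matrix(aperm(a, c(2, 1, 3)), d[2]),
                     c(d[2], d[1], d[3])), c(2, 1, 3))
    a <- aperm(array(K3 %*% matrix(aperm(a, c(3, 1, 2)), d[3]),
                     c(d[3], d[1], d[2])), c(2, 3, 1))
    out[, , , m] <- a
  }
  dwi_volume(out, vol$voxel_size, vol$scheme)
}
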