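#' Configuration of a synthetic phantom cohort
#'
#' The generator emulates the structure of a surgical meningioma cohort:
#' each phantom subject carries group labels (consistency soft/variable/firm,
#' WHO grade I/II, histological type 1-7), an ellipsoidal tumor inside an
#' ellipsoidal brain support, and voxelwise two-component Gaussian mixtures
#' whose powder-average moments (MD, MK_I, MK_A) follow stratum-specific
#' distributions. Group effects are planted as shifts of the subject-level
#' mean parameter, expressed in units of the between-subject standard
#' deviation (Cohen's d at the subject level); peritumoral-heterogeneity
#' effects are planted as a grade-dependent voxel-level MK_I jitter in the
#' rim region.
#'
#' @param strata `data.frame` with columns `consistency`
#'   (`soft|variable|firm|unknown`), `grade` (`I|II`), `type` (integer 1-7)
#'   and `n` (subjects per stratum row).
#' @param grid Length-3 integer grid shape.
#' @param voxel_size Isotropic voxel size in mm (default 2.3).
#' @param snr Signal-to-noise ratio S0/sigma for simulated data (default 30).
#' @param s0 Non-diffusion-weighted signal level.
#' @param base Named list of baseline tumor and brain parameter means
#'   (um^2/ms for `md`; dimensionless kurtoses).
#' @param between_sd Between-subject SDs of tumor `md`, `mk_a`, `mk_i`.
#' @param jitter Within-tumor voxel-level variability: SD of log-MD
#'   (log-normal diffusivity jitter) and absolute SDs of MK_A / MK_I.
#' @param effects List of planted effects, each
#'   `list(variable=, level=, parameter=, d=)` with `d` the subject-level
#'   standardized shift. Defaults reproduce the qualitative orderings the
#'   pipeline is designed to detect: firm consistency -> lower MK_A (and
#'   hence MK), variable -> lower MD, psammomatous type -> higher MK_A and
#'   MK_I medians.
#' @param rim_mki_sd Voxel-level MK_I jitter SD in the peritumoral rim for
#'   grade I and grade II subjects (the grade effect is a scale effect).
#' @param dispersion Orientation dispersion mode of tumor/brain components:
#'   `"aligned"` (one orientation per voxel), `"watson"` (six-fold cone
#'   dispersion about a per-voxel axis), `"uniform"` (twelve-fold isotropic
#'   dispersion). Decouples FA from microscopic anisotropy.
#' @param seed Master seed; all subject-level and noise substreams derive
#'   from it deterministically.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(strata = demo_strata(),
                          grid = c(24L, 24L, 24L),
                          voxel_size = 2.3,
                          snr = 30,
                          s0 = 100,
                          base = list(
                            tumor = c(md = 1.1, mk_a = 0.6, mk_i = 0.4),
                            brain = c(md = 0.8, mk_a = 0.8, mk_i = 0.2)),
                          between_sd = c(md = 0.12, mk_a = 0.20, mk_i = 0.15),
                          jitter = c(log_md = 0.10, mk_a = 0.10, mk_i = 0.08),
                          effects = default_planted_effects(),
                          rim_mki_sd = c(I = 0.08, II = 0.20),
                          dispersion = c("watson", "aligned", "uniform"),
                          seed = 1L) {
  dispersion <- match.arg(dispersion)
  stopifnot(is.data.frame(strata),
            all(c("consistency", "grade", "type", "n") %in% names(strata)))
  if (snr <= 0) stop("snr must be > 0")
  if (any(unlist(between_sd) < 0) || any(unlist(jitter) < 0) ||
      any(unlist(rim_mki_sd) < 0))
    stop("variability parameters must be >= 0")
  rownames(strata) <- NULL
  effects <- lapply(effects, as.list)
  structure(list(strata = strata, grid = as.integer(grid),
                 voxel_size = voxel_size, snr = snr, s0 = s0, base = base,
                 between_sd = between_sd, jitter = jitter, effects = effects,
                 rim_mki_sd = rim_mki_sd, dispersion = dispersion,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' @rdname cohort_config
#' @export
demo_strata <- function() {
  data.frame(
    consistency = c("firm", "firm", "variable", "variable", "soft", "soft"),
    grade       = c("II", "I", "I", "I", "I", "II"),
    type        = c(1L, 3L, 5L, 2L, 7L, 4L),
    n           = c(2L, 2L, 2L, 2L, 2L, 2L))
}

#' @rdname cohort_config
#' @export
consistency_strata <- function(n_firm = 8L, n_variable = 4L, n_soft = 4L) {
  data.frame(
    consistency = c("firm", "variable", "soft"),
    grade = "I", type = c(1L, 3L, 2L),
    n = c(n_firm, n_variable, n_soft))
}

#' @rdname cohort_config
#' @export
full_strata <- function() {
  tab <- data.frame(
    type  = c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 5L, 6L, 7L),
    grade = c("I", "II", "I", "II", "I", "II", "II", "I", "II", "I"),
    n     = c(6L, 2L, 1L, 2L, 8L, 1L, 2L, 2L, 1L, 5L))
  rows <- tab[rep(seq_len(nrow(tab)), tab$n), c("type", "grade")]
  cons <- rep("unknown", nrow(rows))
  cons[1:7] <- "firm"; cons[8:12] <- "variable"; cons[13:16] <- "soft"
  out <- data.frame(consistency = cons, grade = rows$grade, type = rows$type,
                    n = 1L)
  rownames(out) <- NULL
  out
}

# Default planted effects (subject-level standardized shifts). Directions
# follow the group orderings the pipeline should recover: firm tumors show a
# lower anisotropic-kurtosis tail, variable-consistency tumors a lower MD,
# and the psammomatous type (7) higher MK_A and MK_I medians. The grade
# effect is a rim-heterogeneity (scale) effect configured via `rim_mki_sd`.
#' @rdname cohort_config
#' @export
default_planted_effects <- function() {
  list(
    list(variable = "consistency", level = "firm",     parameter = "mk_a", d = -1.5),
    list(variable = "consistency", level = "variable", parameter = "md",   d = -1.5),
    list(variable = "type",        level = 7L,         parameter = "mk_a", d =  1.5),
    list(variable = "type",        level = 7L,         parameter = "mk_i", d =  1.2))
}

#' @rdname cohort_config
#' @export
null_effects <- function() list()

# Deterministic substream seeds below 2^31, derived from the master seed.
substream_seed <- function(master, subject, stage) {
  stage_code <- sum(utf8ToInt(stage))
  as.integer((as.double(master) * 48271 + subject * 16807 + stage_code * 69621) %%
               2147483647)
}

ellipsoid_mask <- function(grid, center, semi) {
  ix <- seq_len(grid[1]); iy <- seq_len(grid[2]); iz <- seq_len(grid[3])
  dx2 <- ((ix - center[1]) / semi[1])^2
  dy2 <- ((iy - center[2]) / semi[2])^2
  dz2 <- ((iz - center[3]) / semi[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
}

#' Generate a phantom cohort
#'
#' Deterministic given `config$seed`. Each subject gets a brain support
#' mask, an ellipsoidal tumor, per-voxel mixture parameters realizing
#' stratum-specific (MD, MK_I, MK_A) distributions, and ground-truth maps
#' computed with the same analytics as [mixture_moments()].
#'
#' @param config A [cohort_config()].
#' @return List of `phantom_subject` objects.
#' @export
sample_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  labels <- config$strata[rep(seq_len(nrow(config$strata)), config$strata$n),
                          c("consistency", "grade", "type")]
  rownames(labels) <- NULL
  lapply(seq_len(nrow(labels)), function(i)
    generate_subject(config, i, labels[i, ]))
}

generate_subject <- function(config, i, labels) {
  set.seed(substream_seed(config$seed, i, "tissue"))
  grid <- config$grid
  brain <- ellipsoid_mask(grid, (grid + 1) / 2, 0.45 * grid)
  # tumor: random center offset and semi-axes, kept inside the brain with a
  # margin that leaves room for a 2-voxel rim
  semi <- stats::runif(3, 0.11, 0.17) * min(grid)
  if (any(2 * semi + 6 > grid))
    stop("tumor larger than grid: increase grid or shrink tumor semi-axes")
  off_max <- pmax(0, 0.45 * grid - semi - 3)
  center <- (grid + 1) / 2 + stats::runif(3, -1, 1) * pmin(off_max, 0.08 * grid)
  tumor <- ellipsoid_mask(grid, center, semi) & brain
  if (!any(tumor)) stop("degenerate tumor mask")

  idx_brain <- which(brain)
  n_b <- length(idx_brain)
  in_tumor <- tumor[idx_brain]

  # subject-level stratum means with planted effects
  mu <- config$base$tumor
  for (ef in config$effects) {
    if (identical(as.character(labels[[ef$variable]]), as.character(ef$level)))
      mu[ef$parameter] <- mu[ef$parameter] +
        ef$d * config$between_sd[[ef$parameter]]
  }
  subj_tumor <- c(
    md   = max(0.3,  stats::rnorm(1, mu[["md"]],   config$between_sd[["md"]])),
    mk_a = max(0.02, stats::rnorm(1, mu[["mk_a"]], config$between_sd[["mk_a"]])),
    mk_i = max(0.02, stats::rnorm(1, mu[["mk_i"]], config$between_sd[["mk_i"]])))
  subj_brain <- c(
    md   = max(0.3,  stats::rnorm(1, config$base$brain[["md"]],   0.05)),
    mk_a = max(0.02, stats::rnorm(1, config$base$brain[["mk_a"]], 0.08)),
    mk_i = max(0.02, stats::rnorm(1, config$base$brain[["mk_i"]], 0.05)))

  # voxel-level targets: log-normal MD jitter, clipped-normal kurtosis jitter
  md_s   <- ifelse(in_tumor, subj_tumor[["md"]],   subj_brain[["md"]])
  mka_s  <- ifelse(in_tumor, subj_tumor[["mk_a"]], subj_brain[["mk_a"]])
  mki_s  <- ifelse(in_tumor, subj_tumor[["mk_i"]], subj_brain[["mk_i"]])
  md_v  <- md_s * exp(stats::rnorm(n_b, 0, config$jitter[["log_md"]]))
  mka_v <- pmax(0, mka_s + stats::rnorm(n_b, 0, config$jitter[["mk_a"]]))
  # rim voxels carry a grade-dependent MK_I heterogeneity (the planted
  # grade effect: a high-grade "MK_I ring" around the tumor)
  rim <- make_rim_roi(roi_mask(tumor, "whole_tumor"), brain, 2L)$mask
  mki_sd_v <- rep(config$jitter[["mk_i"]], n_b)
  mki_sd_v[rim[idx_brain]] <- config$rim_mki_sd[[as.character(labels$grade)]]
  mki_v <- pmax(0, mki_s + stats::rnorm(n_b, 0, mki_sd_v))

  # realize targets as 2 equal-fraction components: isotropic diffusivities
  # md (1 +/- delta_iso); anisotropy Delta_k = c * d_iso_k proportional to
  # each component's isotropic diffusivity, with c clipped below 3 to keep
  # d_perp >= 0 (a clipped-normal effective anisotropy)
  delta_iso <- pmin(sqrt(mki_v / 3), 0.95)
  d1 <- md_v * (1 + delta_iso)
  d2 <- md_v * (1 - delta_iso)
  c_an <- pmin(sqrt(15 * mka_v / (4 * (1 + delta_iso^2))), 2.997)
  ax <- stats::rnorm(n_b); ay <- stats::rnorm(n_b); az <- stats::rnorm(n_b)
  nrm <- sqrt(ax^2 + ay^2 + az^2); nrm[nrm == 0] <- 1
  vox <- data.frame(idx = idx_brain, d_iso1 = d1, d_iso2 = d2,
                    delta1 = c_an * d1, delta2 = c_an * d2,
                    ax = ax / nrm, ay = ay / nrm, az = az / nrm)

  truth <- truth_from_vox(vox, grid, config$s0)
  structure(list(id = i, labels = as.list(labels), grid = grid,
                 voxel_size = rep(config$voxel_size, 3),
                 brain_mask = roi_mask(brain, "brain"),
                 tumor_mask = roi_mask(tumor, "whole_tumor"),
                 truth = truth, vox = vox, s0 = config$s0,
                 dispersion = config$dispersion, snr = config$snr),
            class = "phantom_subject")
}

# Ground-truth maps from the per-voxel two-component parametrization; same
# analytics as mixture_moments() on the explicit component list.
truth_from_vox <- function(vox, grid, s0) {
  md <- (vox$d_iso1 + vox$d_iso2) / 2
  mk_i <- 3 * ((vox$d_iso1 - vox$d_iso2)^2 / 4) / md^2
  mk_a <- (2 / 15) * (vox$delta1^2 + vox$delta2^2) / md^2
  mk <- function(vals) {
    a <- array(NA_real_, grid); a[vox$idx] <- vals; a
  }
  list(s0 = mk(rep(s0, nrow(vox))), md = mk(md), mk_a = mk(mk_a),
       mk_i = mk(mk_i))
}

#' Explicit component table of one phantom voxel
#'
#' Expands the compact per-voxel parametrization of a phantom subject into
#' the component table used by [mixture_moments()] and
#' [synthesize_signal()], including orientation dispersion copies.
#'
#' @param subject A `phantom_subject`.
#' @param voxel Linear voxel index (must lie in the brain support).
#' @return A component `data.frame`.
#' @export
voxel_components <- function(subject, voxel) {
  row <- subject$vox[match(voxel, subject$vox$idx), ]
  if (is.na(row$idx[1])) stop("voxel ", voxel, " is outside the brain support")
  tmpl <- dispersion_template(subject$dispersion)
  axis <- c(row$ax, row$ay, row$az)
  if (axis[3] < 0) axis <- -axis   # canonical hemisphere, as in simulation
  R <- rotation_z_to(axis)
  dirs <- tmpl$dirs %*% t(R)
  out <- NULL
  for (k in 1:2) {
    d_iso <- if (k == 1) row$d_iso1 else row$d_iso2
    delta <- if (k == 1) row$delta1 else row$delta2
    d_perp <- d_iso - delta / 3
    d_par <- d_iso + 2 * delta / 3
    for (o in seq_len(nrow(dirs)))
      out <- rbind(out, tissue_component(d_par, d_perp, dirs[o, ],
                                         0.5 * tmpl$w[o]))
  }
  out
}

# Orientation dispersion templates about the z-axis (unit weights sum to 1).
dispersion_template <- function(mode) {
  switch(mode,
    aligned = list(dirs = matrix(c(0, 0, 1), 1, 3), w = 1),
    watson = {
      th <- 35 * pi / 180
      az <- 2 * pi * (0:4) / 5
      dirs <- rbind(c(0, 0, 1),
                    cbind(sin(th) * cos(az), sin(th) * sin(az),
                          rep(cos(th), 5)))
      list(dirs = dirs, w = rep(1 / 6, 6))
    },
    uniform = list(dirs = spread_directions(12), w = rep(1 / 12, 12)))
}

#' Forward-simulate DWI signals for a phantom subject
#'
#' Evaluates the multi-Gaussian forward model voxelwise under the given
#' scheme (vectorized over brain voxels) and applies Rician noise at
#' `sigma = s0 / snr`, one independent complex draw per measurement.
#' Voxels outside the brain support are zero.
#'
#' @param subject A `phantom_subject` from [sample_cohort()].
#' @param scheme An [acquisition_scheme()].
#' @param snr Signal-to-noise ratio; `Inf` for noise-free.
#' @param seed Seed of the noise substream.
#' @return A [dwi_volume()].
#' @export
simulate_signals <- function(subject, scheme, snr = subject$snr, seed = 1L) {
  stopifnot(inherits(subject, "phantom_subject"),
            inherits(scheme, "acq_scheme"))
  if (!(snr > 0)) stop("snr must be > 0 (use Inf for noise-free)")
  vox <- subject$vox
  n_v <- nrow(vox)
  n_m <- scheme$n_meas
  tmpl <- dispersion_template(subject$dispersion)
  axis <- cbind(vox$ax, vox$ay, vox$az)
  axis[axis[, 3] < 0, ] <- -axis[axis[, 3] < 0, ]   # avoid antipodal singularity
  S <- matrix(0, n_m, n_v)
  b_iso <- scheme$b * (1 - scheme$b_delta)
  b_lin <- scheme$b * scheme$b_delta
  for (o in seq_len(nrow(tmpl$dirs))) {
    t_o <- tmpl$dirs[o, ]
    # rotate template direction to each voxel axis: R(v) t with z -> v
    wx <- -axis[, 2]; wy <- axis[, 1]; cz <- axis[, 3]
    cr1 <- wy * t_o[3]; cr2 <- -wx * t_o[3]; cr3 <- wx * t_o[2] - wy * t_o[1]
    dot_wt <- wx * t_o[1] + wy * t_o[2]
    fac <- 1 / (1 + cz)
    w2 <- wx^2 + wy^2
    Vx <- t_o[1] + cr1 + fac * (wx * dot_wt - w2 * t_o[1])
    Vy <- t_o[2] + cr2 + fac * (wy * dot_wt - w2 * t_o[2])
    Vz <- t_o[3] + cr3 + fac * (-w2 * t_o[3])
    cos2 <- (scheme$directions %*% rbind(Vx, Vy, Vz))^2   # n_m x n_v
    for (k in 1:2) {
      d_iso <- if (k == 1) vox$d_iso1 else vox$d_iso2
      delta <- if (k == 1) vox$delta1 else vox$delta2
      d_perp <- d_iso - delta / 3
      expo <- outer(b_iso, d_iso) +
        b_lin * (matrix(d_perp, n_m, n_v, byrow = TRUE) +
                   cos2 * matrix(delta, n_m, n_v, byrow = TRUE))
      S <- S + (0.5 * tmpl$w[o]) * exp(-expo)
    }
  }
  S <- S * subject$s0
  if (is.finite(snr)) {
    set.seed(as.integer(seed))
    S <- add_rician_noise(S, subject$s0 / snr)
  }
  arr <- array(0, c(subject$grid, n_m))
  n_xyz <- prod(subject$grid)
  for (m in seq_len(n_m)) arr[vox$idx + (m - 1) * n_xyz] <- S[m, ]
  dwi_volume(arr, subject$voxel_size, scheme)
}

#' Parameter maps of the generator's ground truth
#'
#' Packages a subject's analytic truth maps as a [parameter_maps()] object
#' (with `mk = mk_a + mk_i` and no FA map), so ROI feature extraction can
#' run directly on ground truth without simulation or fitting.
#'
#' @param subject A `phantom_subject`.
#' @return A `parameter_maps` object.
#' @export
truth_parameter_maps <- function(subject) {
  parameter_maps(s0 = subject$truth$s0, md = subject$truth$md,
                 fa = NULL, mk = subject$truth$mk_a + subject$truth$mk_i,
                 mk_a = subject$truth$mk_a, mk_i = subject$truth$mk_i,
                 fit_flags = array(0L, subject$grid),
                 voxel_size = subject$voxel_size)
}
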