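#' Tissue components and powder-average moments
#'
#' A voxel is modelled as a mixture of axially symmetric Gaussian diffusion
#' components. Each component has axial diffusivity `d_par`, radial
#' diffusivity `d_perp` (um^2/ms, `d_par >= d_perp >= 0`), a principal
#' orientation, and a mixture fraction. Fractions within a voxel sum to 1.
#'
#' `tissue_component()` builds a one-component table; `tissue_components()`
#' stacks several. The table representation (one row per component) keeps
#' per-voxel mixtures cheap to manipulate.
#'
#' @param d_par,d_perp Axial/radial diffusivities in um^2/ms.
#' @param orientation Length-3 principal direction (normalised internally;
#'   irrelevant for isotropic components).
#' @param fraction Mixture fraction in \[0, 1\].
#' @return A `data.frame` with columns `d_par`, `d_perp`, `ox`, `oy`, `oz`,
#'   `fraction`.
#' @export
tissue_component <- function(d_par, d_perp, orientation = c(0, 0, 1),
                             fraction = 1) {
  if (d_par < d_perp || d_perp < 0)
    stop("need d_par >= d_perp >= 0")
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  o <- as.numeric(orientation)
  nrm <- sqrt(sum(o^2))
  if (nrm == 0) stop("orientation must be a nonzero vector")
  o <- o / nrm
  data.frame(d_par = d_par, d_perp = d_perp,
             ox = o[1], oy = o[2], oz = o[3], fraction = fraction)
}

#' @param ... One-component tables from [tissue_component()].
#' @rdname tissue_component
#' @export
tissue_components <- function(...) {
  comp <- do.call(rbind, list(...))
  validate_components(comp)
  comp
}

validate_components <- function(comp) {
  if (is.null(comp) || nrow(comp) == 0) stop("empty component list")
  if (abs(sum(comp$fraction) - 1) > 1e-9)
    stop("component fractions must sum to 1 (got ", sum(comp$fraction), ")")
  if (any(comp$d_par < comp$d_perp - 1e-12) || any(comp$d_perp < -1e-12))
    stop("need d_par >= d_perp >= 0 for every component")
  invisible(comp)
}

#' Powder-average moments of a Gaussian mixture
#'
#' For a mixture of Gaussian components the directionally averaged signal
#' has exact second-order cumulants: mean diffusivity
#' `MD = sum f_i D_iso_i` with `D_iso = (d_par + 2 d_perp) / 3`; isotropic
#' kurtosis `MK_I = 3 Var_f(D_iso) / MD^2` (heterogeneity of isotropic
#' diffusivities across components); and anisotropic kurtosis
#' `MK_A = 3 sum f_i (4/45) (d_par_i - d_perp_i)^2 / MD^2` (microscopic
#' anisotropy, independent of orientation dispersion). These are the ground
#' truth recovered by [fit_qti()] in the small-b limit.
#'
#' @param components Component table (see [tissue_component()]).
#' @return Named numeric vector `c(md, mk_i, mk_a)`.
#' @export
#' @examples
#' mixture_moments(tissue_component(1, 1))            # (1, 0, 0)
#' mixture_moments(tissue_components(
#'   tissue_component(0.5, 0.5, fraction = 0.5),
#'   tissue_component(1.5, 1.5, fraction = 0.5)))     # MK_I = 0.75
mixture_moments <- function(components) {
  validate_components(components)
  f <- components$fraction
  d_iso <- (components$d_par + 2 * components$d_perp) / 3
  delta <- components$d_par - components$d_perp
  md <- sum(f * d_iso)
  v_iso <- sum(f * (d_iso - md)^2)
  v_aniso <- sum(f * (4 / 45) * delta^2)
  c(md = md,
    mk_i = 3 * v_iso / md^2,
    mk_a = 3 * v_aniso / md^2)
}

#' Noise-free signal of a component mixture under an acquisition scheme
#'
#' Evaluates the multi-Gaussian forward model for one voxel. For an axially
#' symmetric b-tensor of size `b`, shape `b_delta` and symmetry axis `g`,
#' the per-component attenuation exponent is
#' `b * ((1 - b_delta)/3 * 3 D_iso + b_delta * (d_perp + (d_par - d_perp) (g.o)^2))`,
#' which reduces to the directional ADC for linear encoding (`b_delta = 1`)
#' and to `b * D_iso` for spherical encoding (`b_delta = 0`). Kurtosis in
#' the powder-averaged signal arises purely from the mixture.
#'
#' @param components Component table.
#' @param scheme An [acquisition_scheme()].
#' @param s0 Non-diffusion-weighted signal.
#' @return Numeric vector of length `scheme$n_meas`.
#' @export
synthesize_signal <- function(components, scheme, s0 = 1) {
  validate_components(components)
  stopifnot(inherits(scheme, "acq_scheme"))
  o <- as.matrix(components[, c("ox", "oy", "oz")])
  cos2 <- (scheme$directions %*% t(o))^2            # n_meas x n_comp
  d_iso <- (components$d_par + 2 * components$d_perp) / 3
  adc_lin <- matrix(components$d_perp, nrow(cos2), ncol(cos2), byrow = TRUE) +
    cos2 * matrix(components$d_par - components$d_perp,
                  nrow(cos2), ncol(cos2), byrow = TRUE)
  iso_part <- outer((1 - scheme$b_delta) * scheme$b, d_iso)
  lin_part <- (scheme$b_delta * scheme$b) * adc_lin
  s0 * as.numeric(exp(-(iso_part + lin_part)) %*% components$fraction)
}

#' Apply Rician (magnitude-reconstruction) noise
#'
#' Each measurement receives an independent complex Gaussian perturbation:
#' `sqrt((S + e1)^2 + e2^2)` with `e1, e2 ~ N(0, sigma^2)`. Draws come from
#' the current RNG state; seed management is the caller's responsibility.
#'
#' @param signal Numeric vector/array of noise-free magnitudes.
#' @param sigma Noise standard deviation (same units as `signal`).
#' @return Noisy magnitudes, same shape as `signal`.
#' @export
add_rician_noise <- function(signal, sigma) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(signal)
  n <- length(signal)
  out <- sqrt((signal + stats::rnorm(n, 0, sigma))^2 +
                stats::rnorm(n, 0, sigma)^2)
  if (!is.null(dim(signal))) dim(out) <- dim(signal)
  out
}
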