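# Shared fixtures: all built in code at test time.

# wrap a single voxel's per-measurement signal as a dwi_volume
single_voxel_volume <- function(signal, scheme, voxel_size = 2.3) {
  dwi_volume(array(signal, c(1, 1, 1, scheme$n_meas)), voxel_size, scheme)
}

# stack many voxels (rows of `signals`) along the first axis
voxel_stack_volume <- function(signals, scheme, voxel_size = 2.3) {
  n <- nrow(signals)
  arr <- array(0, c(n, 1, 1, scheme$n_meas))
  for (m in seq_len(scheme$n_meas)) arr[, 1, 1, m] <- signals[, m]
  dwi_volume(arr, voxel_size, scheme)
}

# protocol with all b-values scaled (keeps directions and shell structure)
scaled_protocol <- function(scale) {
  sch <- default_protocol()
  acquisition_scheme(sch$b * scale, sch$b_delta, sch$directions)
}

# LTE+STE scheme with direction-rich LTE shells, for tests that need the
# powder average to approximate the rotational average closely
dense_scheme <- function(scale = 1, ndir = 60) {
  bsh <- c(0.1, 0.7, 1.4, 2.0) * scale
  g <- spread_directions(ndir)
  b <- c(rep(bsh, each = ndir), rep(bsh, each = 6))
  bd <- c(rep(1, 4 * ndir), rep(0, 24))
  dirs <- rbind(g[rep(seq_len(ndir), 4), ],
                matrix(rep(c(0, 0, 1), 24), ncol = 3, byrow = TRUE))
  acquisition_scheme(b, bd, dirs)
}

# exact signals of the powder cumulant model on a scheme (per measurement)
cumulant_signal <- function(scheme, s0, md, mk_i, mk_a) {
  exp(log(s0) - scheme$b * md +
        scheme$b^2 * (mk_i + scheme$b_delta^2 * mk_a) * md^2 / 6)
}

# brute-force two-sided Mann-Whitney p by full enumeration of group splits
permutation_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- utils::combn(length(pooled), n1)
  mu <- n1 * length(y) / 2
  us <- apply(splits, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# equal-fraction isotropic pair with D_iso = md (1 +/- delta)
iso_pair <- function(md = 1, delta = 0.5) {
  tissue_components(
    tissue_component(md * (1 + delta), md * (1 + delta), fraction = 0.5),
    tissue_component(md * (1 - delta), md * (1 - delta), fraction = 0.5))
}

# orientationally isotropic anisotropic mixture: one tensor replicated over
# a well-spread direction set
powder_mixture <- function(d_par, d_perp, n_orient = 30) {
  g <- spread_directions(n_orient)
  do.call(rbind, lapply(seq_len(n_orient), function(i)
    tissue_component(d_par, d_perp, g[i, ], 1 / n_orient)))
}

demographics_path <- function() {
  system.file("extdata", "synthetic_cohort_labels.csv", package = "tvdmri")
}
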