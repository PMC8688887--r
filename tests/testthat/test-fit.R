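test_that("powder average equals an explicit per-shell loop", {
  sch <- acquisition_scheme(c(1, 1, 1), c(1, 1, 1), spread_directions(3))
  vol <- single_voxel_volume(c(1, 2, 3), sch)
  expect_equal(as.vector(powder_average(vol)$data), 2)

  sch2 <- default_protocol()
  set.seed(5)
  sig <- runif(80, 0.1, 1)
  pw <- powder_average(single_voxel_volume(sig, sch2))
  oracle <- vapply(seq_len(nrow(sch2$shells)), function(s)
    mean(sig[sch2$shell_id == sch2$shells$shell_id[s]]), numeric(1))
  expect_equal(as.vector(pw$data), oracle, tolerance = 1e-14)

  v <- 0.37  # constant across the 16 STE repeats
  sig[sch2$shell_id == 7] <- v
  pw2 <- powder_average(single_voxel_volume(sig, sch2))
  expect_equal(pw2$data[1, 1, 1, 7], v)
})

test_that("cumulant fit is exact on exactly realizable signals", {
  sch <- default_protocol()
  # mono-exponential
  pm <- fit_qti(powder_average(single_voxel_volume(
    cumulant_signal(sch, 100, 1, 0, 0), sch)))
  expect_equal(c(pm$s0[1], pm$md[1], pm$mk_i[1], pm$mk_a[1]),
               c(100, 1, 0, 0), tolerance = 1e-5)
  expect_equal(pm$fit_flags[1], 0L)
  # generic interior point
  pm2 <- fit_qti(powder_average(single_voxel_volume(
    cumulant_signal(sch, 1, 0.8, 0.5, 1.0), sch)))
  expect_equal(c(pm2$s0[1], pm2$md[1], pm2$mk_i[1], pm2$mk_a[1]),
               c(1, 0.8, 0.5, 1.0), tolerance = 1e-5)
})

test_that("kurtosis constraints clamp at 4 and flag the voxel", {
  sch <- default_protocol()
  pm <- fit_qti(powder_average(single_voxel_volume(
    cumulant_signal(sch, 1, 0.8, 4.5, 0.5), sch)))
  expect_equal(pm$mk_i[1], 4, tolerance = 1e-6)
  expect_equal(pm$fit_flags[1], 1L)
})

test_that("non-positive signals flag the voxel as missing", {
  sch <- default_protocol()
  sig <- cumulant_signal(sch, 1, 1, 0, 0)
  sig[sch$shell_id == 3] <- 0   # a whole shell lost -> powder mean 0
  pm <- fit_qti(powder_average(single_voxel_volume(sig, sch)))
  expect_equal(pm$fit_flags[1], 2L)
  expect_true(is.na(pm$md[1]))
})

test_that("cumulant fit is invariant to measurement order and scales with S0", {
  sch <- default_protocol()
  set.seed(7)
  sig <- cumulant_signal(sch, 1, 1.1, 0.4, 0.9) * exp(rnorm(80, 0, 0.01))
  pm <- fit_qti(powder_average(single_voxel_volume(sig, sch)))
  perm <- sample(80)
  sch_p <- acquisition_scheme(sch$b[perm], sch$b_delta[perm],
                              sch$directions[perm, ])
  pm_p <- fit_qti(powder_average(single_voxel_volume(sig[perm], sch_p)))
  expect_equal(pm_p$md[1], pm$md[1], tolerance = 1e-12)
  expect_equal(pm_p$mk_i[1], pm$mk_i[1], tolerance = 1e-12)
  expect_equal(pm_p$mk_a[1], pm$mk_a[1], tolerance = 1e-12)

  pm_s <- fit_qti(powder_average(single_voxel_volume(sig * 50, sch)))
  expect_equal(pm_s$s0[1], 50 * pm$s0[1], tolerance = 1e-10)
  expect_equal(pm_s$md[1], pm$md[1], tolerance = 1e-12)
  expect_equal(pm_s$mk_a[1], pm$mk_a[1], tolerance = 1e-12)
})

test_that("fitted MK_I is monotone in the generating MK_I", {
  sch <- default_protocol()
  fitted <- vapply(seq(0, 2, length.out = 9), function(k) {
    pm <- fit_qti(powder_average(single_voxel_volume(
      cumulant_signal(sch, 1, 0.9, k, 0.7), sch)))
    pm$mk_i[1]
  }, numeric(1))
  expect_true(all(diff(fitted) >= -1e-9))
})

test_that("scheme requirements for kurtosis separation are enforced", {
  g <- spread_directions(6)
  lte_only <- acquisition_scheme(rep(c(0.1, 1, 2), each = 6), rep(1, 18),
                                 g[rep(1:6, 3), ])
  vol <- single_voxel_volume(cumulant_signal(lte_only, 1, 1, 0, 0), lte_only)
  expect_error(fit_qti(powder_average(vol)), "separate")
})

test_that("DTI recovers FA from eigenvalues and is 0 for isotropic voxels", {
  sch <- default_protocol()
  vol <- single_voxel_volume(
    synthesize_signal(tissue_component(2.0, 0.2, c(1, 2, -0.5)), sch, 50), sch)
  dti <- fit_dti(vol)
  ev <- c(2, 0.2, 0.2)
  fa_true <- sqrt(1.5 * sum((ev - mean(ev))^2) / sum(ev^2))  # 0.8911
  expect_equal(dti$fa[1], fa_true, tolerance = 1e-3)
  expect_equal(dti$md[1], 0.8, tolerance = 1e-3)

  dti_iso <- fit_dti(single_voxel_volume(
    synthesize_signal(tissue_component(1, 1), sch), sch))
  expect_lt(dti_iso$fa[1], 1e-6)
})

test_that("orientation dispersion lowers FA; value matches a nonlinear refit", {
  sch <- default_protocol()
  comp <- tissue_components(
    tissue_component(2.0, 0.2, c(1, 0, 0), 0.5),
    tissue_component(2.0, 0.2, c(0, 1, 0), 0.5))
  sig <- synthesize_signal(comp, sch, 1)
  vol <- single_voxel_volume(sig, sch)
  dti <- fit_dti(vol)
  expect_lt(dti$fa[1], 0.89)

  # independent oracle: nonlinear signal-domain tensor refit on the same
  # low-b LTE measurements
  keep <- abs(sch$b_delta - 1) < 1e-9 & sch$b <= 1.0
  b <- sch$b[keep]; g <- sch$directions[keep, ]; y <- sig[keep]
  obj <- function(p) {
    D <- matrix(p[c(2, 5, 6, 5, 3, 7, 6, 7, 4)], 3, 3)
    adc <- rowSums((g %*% D) * g)
    sum((y - exp(p[1] - b * adc))^2)
  }
  fit <- stats::optim(c(0, 1, 1, 1, 0, 0, 0), obj,
                      control = list(maxit = 5000, reltol = 1e-14))
  ev <- pmax(eigen(matrix(fit$par[c(2, 5, 6, 5, 3, 7, 6, 7, 4)], 3, 3),
                   symmetric = TRUE, only.values = TRUE)$values, 0)
  fa_oracle <- sqrt(1.5 * sum((ev - mean(ev))^2) / sum(ev^2))
  expect_equal(dti$fa[1], fa_oracle, tolerance = 1e-3)
})

test_that("DKI mean kurtosis is 0 for Gaussian voxels and exact for
           isotropic-kurtosis signals", {
  sch <- default_protocol()
  vol <- single_voxel_volume(
    synthesize_signal(tissue_component(2.0, 0.2, c(1, 2, -0.5)), sch, 50), sch)
  expect_lt(abs(fit_dki(vol)$mk[1]), 1e-3)

  md <- 1.0
  sig <- exp(-sch$b * md + sch$b^2 * md^2 * 1.2 / 6)  # K = 1.2 in all dirs
  expect_equal(fit_dki(single_voxel_volume(sig, sch))$mk[1], 1.2,
               tolerance = 1e-3)
})

test_that("DKI mean kurtosis agrees with the cumulant fit's MK_A + MK_I on
           isotropic mixtures", {
  sch <- default_protocol()
  sig <- synthesize_signal(iso_pair(1, 0.5), sch)
  vol <- single_voxel_volume(sig, sch)
  mk <- fit_dki(vol)$mk[1]
  qti <- fit_qti(powder_average(vol))
  expect_lt(abs(mk - (qti$mk_i[1] + qti$mk_a[1])), 0.05)
})

test_that("smoothing preserves constants, converts sigma to voxels, and
           matches a discrete Gaussian kernel oracle", {
  sch <- acquisition_scheme(0, 0, matrix(c(0, 0, 1), 1))
  const <- dwi_volume(array(3.7, c(9, 9, 9, 1)), 2.3, sch)
  sm <- smooth_volume(const, 1.6)
  expect_lt(max(abs(sm$data - 3.7)), 1e-6)

  # unit impulse in the interior: kernel = separable normalized Gaussian
  # with per-axis sigma 1.6 / 2.3 voxels
  imp <- array(0, c(15, 15, 15, 1)); imp[8, 8, 8, 1] <- 1
  sm2 <- smooth_volume(dwi_volume(imp, 2.3, sch), 1.6)
  sv <- 1.6 / 2.3
  expect_equal(sv, 0.6957, tolerance = 1e-4)
  r <- ceiling(4 * sv)
  k1 <- exp(-((-r):r)^2 / (2 * sv^2)); k1 <- k1 / sum(k1)
  oracle <- outer(outer(k1, k1), k1)
  got <- sm2$data[(8 - r):(8 + r), (8 - r):(8 + r), (8 - r):(8 + r), 1]
  expect_equal(got, oracle, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(sum(sm2$data), 1, tolerance = 1e-10)

  expect_identical(smooth_volume(const, 0), const)
})
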