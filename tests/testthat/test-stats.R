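test_that("Cohen's d matches hand computation and a direct transcription", {
  d <- cohens_d(c(1, 2, 3), c(2, 3, 4))
  expect_equal(as.numeric(d), -1)
  expect_equal(attr(d, "s"), 1)

  set.seed(2)
  for (i in 1:200) {
    x <- rnorm(sample(2:9, 1)); y <- rnorm(sample(2:9, 1), 0.5)
    n1 <- length(x); n2 <- length(y)
    s_direct <- sqrt(((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2))
    expect_equal(as.numeric(cohens_d(x, y)),
                 (mean(x) - mean(y)) / s_direct, tolerance = 1e-12)
    expect_equal(as.numeric(cohens_d(x, y)), -as.numeric(cohens_d(y, x)))
  }
  expect_warning(dz <- cohens_d(c(1, 1), c(1, 1)), "zero pooled variance")
  expect_true(is.na(dz))
})

test_that("U test: hand case, degenerate ties, and permutation agreement", {
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw$u, 0)
  expect_equal(mw$p, 1 / 3, tolerance = 1e-12)
  expect_equal(mann_whitney(c(2, 2, 2), c(2, 2))$p, 1)

  set.seed(4)
  for (i in 1:60) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- rnorm(n1); y <- rnorm(n2, 0.8)
    expect_equal(mann_whitney(x, y)$p, permutation_p(x, y),
                 tolerance = 1e-12)
  }
  # tied data: normal approximation with tie correction, same as wilcox.test
  x <- c(1, 2, 2, 3, 5, 5, 6); y <- c(2, 3, 3, 4, 5, 7)
  expect_equal(mann_whitney(x, y)$p,
               suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                                   correct = TRUE)$p.value))
})

test_that("AUC follows the tie-adjusted U identity and honors direction", {
  expect_equal(roc_auc(c(1, 2, 10, 11), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(3, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  set.seed(9)
  for (i in 1:50) {
    n1 <- sample(3:10, 1); n2 <- sample(3:10, 1)
    sc <- c(rnorm(n1, 1), rnorm(n2))
    if (i %% 3 == 0) sc <- round(sc)   # force ties
    lab <- rep(c(TRUE, FALSE), c(n1, n2))
    u <- mann_whitney(sc[lab], sc[!lab])$u
    expect_equal(roc_auc(sc, lab), u / (n1 * n2), tolerance = 1e-12)
    # pairwise-count oracle with half-weight ties
    pairs <- outer(sc[lab], sc[!lab], function(a, b)
      (a > b) + 0.5 * (a == b))
    expect_equal(roc_auc(sc, lab), mean(pairs), tolerance = 1e-12)
    expect_equal(roc_auc(sc, lab, "less"), 1 - roc_auc(sc, lab, "greater"),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  sc <- c(rnorm(12, 0.8), rnorm(15))
  lab <- rep(c(1, 0), c(12, 15))
  ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, direction = "<",
                                        quiet = TRUE)))
  expect_equal(roc_auc(sc, lab), ref, tolerance = 1e-12)
})

test_that("bootstrap CI is ordered, seed-deterministic, and covers the null", {
  set.seed(21)
  sc <- c(rnorm(8, 1), rnorm(8)); lab <- rep(c(TRUE, FALSE), each = 8)
  ci1 <- bootstrap_auc_ci(sc, lab, n_boot = 400, seed = 99)
  ci2 <- bootstrap_auc_ci(sc, lab, n_boot = 400, seed = 99)
  expect_identical(ci1, ci2)
  expect_lte(ci1[1], ci1[2])

  # null coverage: equal distributions, n = 10/10; the 95% CI should
  # contain AUC = 0.5 in at least ~90% of datasets
  set.seed(31)
  covered <- vapply(1:200, function(i) {
    sc <- rnorm(20); lab <- rep(c(TRUE, FALSE), each = 10)
    ci <- bootstrap_auc_ci(sc, lab, n_boot = 500, seed = i)
    ci[1] <= 0.5 && 0.5 <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.90)
})

test_that("Youden cut-point equals an exhaustive threshold scan", {
  cp <- optimal_cutpoint(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(cp$cutpoint, 2.5)
  expect_equal(cp$sensitivity, 1)
  expect_equal(cp$specificity, 1)

  set.seed(17)
  for (i in 1:40) {
    sc <- round(rnorm(14), 1)
    lab <- sample(c(TRUE, FALSE), 14, replace = TRUE)
    if (!any(lab) || all(lab)) next
    cp <- optimal_cutpoint(sc, lab)
    j_all <- vapply(seq(min(sc) - 1, max(sc) + 1, by = 0.005), function(t) {
      pred <- sc > t
      mean(pred[lab]) + mean(!pred[!lab]) - 1
    }, numeric(1))
    expect_equal(cp$sensitivity + cp$specificity - 1, max(j_all),
                 tolerance = 1e-9)
  }
})

test_that("ties in Youden's J break toward the lower threshold", {
  # thresholds 1.5 and 2.5 both give J = 0.5; the lower must win
  cp <- optimal_cutpoint(c(1, 2, 3, 4), c(0, 1, 0, 1))
  expect_equal(cp$cutpoint, 1.5)
})

test_that("characteristic ranking finds a planted shift and breaks ties
           deterministically", {
  set.seed(8)
  n <- 20
  labs <- data.frame(subject = 1:n,
                     consistency = rep(c("firm", "soft"), each = n / 2),
                     grade = "I", type = 1L)
  ft <- labs
  for (p in c("s0", "md", "fa", "mk", "mk_a", "mk_i"))
    for (ch in c("p10", "p25", "p50", "p75", "p90", "std"))
      ft[[paste(p, ch, "whole_tumor", sep = "__")]] <- rnorm(n)
  # plant a strong shift in every parameter's p75 only
  for (p in c("s0", "md", "fa", "mk", "mk_a", "mk_i"))
    ft[[paste(p, "p75", "whole_tumor", sep = "__")]] <-
      rnorm(n) + 3 * (labs$consistency == "firm")
  cts <- list(contrast("firm", "consistency", "firm"))
  rk <- rank_characteristics(ft, cts)
  expect_equal(rk$characteristic[1], "p75")

  # brute-force double-loop oracle for the scores
  for (k in seq_len(nrow(rk))) {
    ds <- vapply(c("s0", "md", "fa", "mk", "mk_a", "mk_i"), function(p) {
      col <- paste(p, rk$characteristic[k], "whole_tumor", sep = "__")
      abs(as.numeric(cohens_d(ft[[col]][labs$consistency == "firm"],
                              ft[[col]][labs$consistency != "firm"])))
    }, numeric(1))
    expect_equal(rk$score[k], mean(ds), tolerance = 1e-12)
  }

  # all-identical scores: ranking is still total, in declared order
  ft0 <- ft
  for (col in grep("__", names(ft0), value = TRUE)) ft0[[col]] <- seq_len(n)
  rk0 <- suppressWarnings(rank_characteristics(ft0, cts))
  expect_equal(nrow(rk0), 6L)
  expect_equal(rk0$characteristic,
               c("p10", "p25", "p50", "p75", "p90", "std"))
})

test_that("cohort summary reproduces the reference case-mix percentages", {
  labs <- utils::read.csv(demographics_path())
  cs <- cohort_summary(labs[, c("sex", "consistency", "grade", "type")])
  grade <- cs$grade
  expect_equal(grade$percent[grade$level == "I"], 73L)
  expect_equal(grade$percent[grade$level == "II"], 27L)
  sex <- cs$sex
  expect_equal(sex$percent[sex$level == "female"], 57L)
  cons <- cs$consistency
  expect_equal(cons$percent[cons$level == "firm"], 23L)
  expect_equal(cons$percent[cons$level == "variable"], 17L)
  expect_equal(cons$percent[cons$level == "soft"], 13L)

  one <- cohort_summary(data.frame(grade = "II"))
  expect_equal(one$grade$percent, 100L)
})

test_that("the comparison grid enumerates 396 cells per ROI for 11 contrasts", {
  set.seed(12)
  labs <- utils::read.csv(demographics_path())
  ft <- labs[, c("subject", "consistency", "grade", "type")]
  for (p in c("s0", "md", "fa", "mk", "mk_a", "mk_i"))
    for (ch in c("p10", "p25", "p50", "p75", "p90", "std"))
      for (roi in c("whole_tumor", "rim"))
        ft[[paste(p, ch, roi, sep = "__")]] <- rnorm(nrow(labs))
  res <- run_all_tests(ft, default_contrasts())
  expect_equal(length(default_contrasts()), 11L)
  expect_equal(sum(res$roi == "whole_tumor"), 396L)
  expect_equal(sum(res$roi == "rim"), 396L)
  expect_equal(nrow(res), 792L)
  expect_true(all(res$p > 0 & res$p <= 1, na.rm = TRUE))
  # optional correction flag
  res_bh <- run_all_tests(ft, default_contrasts(), p_adjust = "BH")
  expect_true(all(res_bh$p_adj >= res_bh$p, na.rm = TRUE))
})

test_that("a planted group difference is detected by the grid", {
  set.seed(14)
  n <- 16
  ft <- data.frame(subject = 1:n,
                   consistency = rep(c("firm", "soft"), each = 8),
                   grade = "I", type = 1L)
  for (p in c("md", "mk_a")) for (ch in c("p10", "p50"))
    ft[[paste(p, ch, "whole_tumor", sep = "__")]] <- rnorm(n)
  ft$mk_a__p10__whole_tumor <- rnorm(n) - 2.5 * (ft$consistency == "firm")
  res <- run_all_tests(ft, list(contrast("firm", "consistency", "firm")),
                       parameters = c("md", "mk_a"), rois = "whole_tumor")
  cell <- res[res$parameter == "mk_a" & res$characteristic == "p10", ]
  expect_true(cell$significant)
  expect_lt(cell$d, 0)
})

test_that("compare_groups bundles AUC, CI, cut-point and U test coherently", {
  set.seed(6)
  ft <- data.frame(subject = 1:12,
                   consistency = rep(c("firm", "soft"), each = 6),
                   grade = "I", type = 1L,
                   mk_a__p10__whole_tumor = c(rnorm(6, -1), rnorm(6, 1)))
  res <- compare_groups(ft, contrast("firm", "consistency", "firm"),
                        "mk_a__p10__whole_tumor", direction = "less",
                        n_boot = 300, seed = 2)
  expect_gte(res$auc, 0.8)
  expect_true(res$ci[1] <= res$auc + 1e-9)
  expect_true(res$sensitivity >= 0 && res$sensitivity <= 1)
  expect_true(res$specificity >= 0 && res$specificity <= 1)
  expect_equal(res$n1, 6L)
})
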