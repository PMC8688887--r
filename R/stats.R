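#' Cohen's d with pooled standard deviation
#'
#' `d = (mean(x) - mean(y)) / s` with the pooled standard deviation
#' `s = sqrt(((n1 - 1) s1^2 + (n2 - 1) s2^2) / (n1 + n2 - 2))` using
#' n - 1 sample variances.
#'
#' @param x,y Numeric vectors (each of length >= 2).
#' @return The effect size `d` (with attribute `s`, the pooled SD);
#'   `NA` with a warning if the pooled variance is zero.
#' @export
#' @examples
#' cohens_d(c(1, 2, 3), c(2, 3, 4))  # -1
cohens_d <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("need at least 2 observations per group")
  s <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
              (n1 + n2 - 2))
  if (s == 0) {
    warning("zero pooled variance: Cohen's d undefined")
    return(structure(NA_real_, s = 0))
  }
  structure((mean(x) - mean(y)) / s, s = s)
}

#' Two-sided Mann-Whitney U test
#'
#' U is computed from midranks. The two-sided p-value is exact (full
#' enumeration of rank assignments) when `n1 + n2 <= 12` and the data are
#' tie-free; otherwise the normal approximation with tie and continuity
#' correction is used. Degenerate data in which every value is equal give
#' p = 1.
#'
#' @param x,y Numeric vectors (length >= 1).
#' @return List with `u` (U statistic of `x`) and `p`.
#' @export
mann_whitney <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both groups must be nonempty")
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (length(unique(c(x, y))) == 1L) return(list(u = u, p = 1))
  use_exact <- (n1 + n2 <= 12) && !ties
  p <- tryCatch(
    suppressWarnings(stats::wilcox.test(x, y, exact = use_exact,
                                        correct = TRUE)$p.value),
    error = function(e) NA_real_)
  if (is.na(p) || is.nan(p)) p <- 1
  list(u = u, p = min(1, p))
}

#' Rank distribution characteristics by mean absolute effect size
#'
#' For each distribution characteristic (p10 ... p90, std), averages the
#' effect size over every dMRI parameter and every supplied contrast, and
#' sorts characteristics by that score. By default the magnitude |d| is
#' averaged (the ranking should not depend on arbitrary group orientation);
#' `signed = TRUE` averages signed d. Undefined effect sizes are dropped
#' from the mean. Ties in the score break by the fixed characteristic
#' order p10 < p25 < p50 < p75 < p90 < std.
#'
#' @param features Feature table from [build_feature_table()].
#' @param contrasts List of contrasts from [contrast()].
#' @param parameters Parameters entering the average.
#' @param roi ROI whose features are ranked.
#' @param signed Average signed d instead of |d|.
#' @return `data.frame` with `characteristic` and `score`, sorted
#'   descending.
#' @export
rank_characteristics <- function(features, contrasts,
                                 parameters = c("s0", "md", "fa", "mk",
                                                "mk_a", "mk_i"),
                                 roi = "whole_tumor", signed = FALSE) {
  scores <- vapply(characteristics_order, function(ch) {
    ds <- unlist(lapply(contrasts, function(ct) {
      sel <- contrast_split(features, ct)
      vapply(parameters, function(p) {
        col <- paste(p, ch, roi, sep = "__")
        if (!col %in% names(features)) return(NA_real_)
        suppressWarnings(tryCatch(
          as.numeric(cohens_d(features[[col]][sel$pos],
                              features[[col]][sel$neg])),
          error = function(e) NA_real_))
      }, numeric(1))
    }))
    ds <- ds[!is.na(ds)]
    if (length(ds) == 0) return(NA_real_)
    if (signed) mean(ds) else mean(abs(ds))
  }, numeric(1))
  if (all(is.na(scores))) stop("all effect sizes undefined")
  ord <- order(-scores)   # stable: ties keep p10 < ... < std order
  data.frame(characteristic = characteristics_order[ord],
             score = unname(scores[ord]))
}

#' Group contrast: one level against the pooled remainder
#'
#' @param name Display name.
#' @param variable Label column (`"consistency"`, `"grade"`, `"type"`).
#' @param positive Level forming the positive group; all other labelled
#'   subjects form the pooled negative group.
#' @param exclude Levels dropped entirely (e.g. `"unknown"` consistency).
#' @return A `contrast` object.
#' @export
contrast <- function(name, variable, positive, exclude = "unknown") {
  structure(list(name = name, variable = variable, positive = positive,
                 exclude = exclude), class = "contrast")
}

contrast_split <- function(features, ct) {
  lab <- as.character(features[[ct$variable]])
  keep <- !(lab %in% ct$exclude) & !is.na(lab)
  pos <- keep & lab == as.character(ct$positive)
  neg <- keep & lab != as.character(ct$positive)
  if (!any(pos) || !any(neg))
    stop("contrast '", ct$name, "': a group is empty")
  list(pos = which(pos), neg = which(neg))
}

#' The standard 11 contrasts
#'
#' Three consistency contrasts (each consistency against the pooled other
#' two), grade II against grade I, and each of the seven histological
#' types against all other pooled types.
#'
#' @return List of [contrast()] objects.
#' @export
default_contrasts <- function() {
  c(lapply(c("soft", "variable", "firm"), function(l)
      contrast(paste0("consistency_", l), "consistency", l)),
    list(contrast("grade_II", "grade", "II")),
    lapply(1:7, function(t) contrast(paste0("type_", t), "type", t)))
}

#' Rank-based AUC of the ROC curve
#'
#' AUC by the pairwise rule (ties count 1/2), equivalent to `U / (n1 n2)`
#' from the midrank U statistic. The positive class is `labels == TRUE`;
#' the score direction is a declared input (`"greater"`: larger scores
#' indicate the positive class), never auto-flipped.
#'
#' @param scores Numeric scores.
#' @param labels Logical (or 0/1) class labels.
#' @param direction `"greater"` or `"less"`.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  if (!any(labels) || all(labels)) stop("both classes must be present")
  if (direction == "less") scores <- -scores
  n1 <- sum(labels); n2 <- sum(!labels)
  r <- rank(scores)
  u <- sum(r[labels]) - n1 * (n1 + 1) / 2
  u / (n1 * n2)
}

#' Percentile bootstrap confidence interval for the AUC
#'
#' Resamples (score, label) pairs with replacement `n_boot` times
#' (default 5000); resamples missing a class are redrawn. Returns the
#' percentile 95% interval. Deterministic given `seed`.
#'
#' @inheritParams roc_auc
#' @param n_boot Number of bootstrap resamples.
#' @param seed RNG seed.
#' @param conf Confidence level.
#' @return Numeric `c(lo, hi)`.
#' @export
bootstrap_auc_ci <- function(scores, labels, n_boot = 5000L, seed = 1L,
                             direction = c("greater", "less"), conf = 0.95) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) stop("both classes must be present")
  if (n_boot < 1) stop("n_boot must be >= 1")
  set.seed(as.integer(seed))
  n <- length(scores)
  aucs <- numeric(n_boot)
  for (i in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (any(labels[idx]) && any(!labels[idx])) break
    }
    aucs[i] <- roc_auc(scores[idx], labels[idx], direction)
  }
  a <- (1 - conf) / 2
  stats::quantile(aucs, c(a, 1 - a), names = FALSE, type = 7)
}

#' Optimal cut-point by Youden's J
#'
#' Scans the midpoints between adjacent distinct scores and returns the
#' threshold maximizing `J = sensitivity + specificity - 1`; ties break
#' toward the lower threshold. For `direction = "greater"` a subject is
#' called positive when its score exceeds the threshold (strictly below,
#' for `"less"`).
#'
#' @inheritParams roc_auc
#' @return List with `cutpoint`, `sensitivity`, `specificity`.
#' @export
optimal_cutpoint <- function(scores, labels, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) stop("both classes must be present")
  s <- sort(unique(scores))
  mids <- if (length(s) > 1) (s[-1] + s[-length(s)]) / 2 else numeric(0)
  # boundary thresholds (predict none / all) bound J below by 0
  thr <- c(s[1] - 1, mids, s[length(s)] + 1)
  best <- NULL
  for (t in thr) {
    pred <- if (direction == "greater") scores > t else scores < t
    sens <- mean(pred[labels]); spec <- mean(!pred[!labels])
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12)
      best <- list(cutpoint = t, sensitivity = sens, specificity = spec, j = j)
  }
  best[c("cutpoint", "sensitivity", "specificity")]
}

#' Demographic summary of a label table
#'
#' Counts and integer-rounded percentages of the total for every
#' categorical column.
#'
#' @param labels `data.frame` of per-subject categorical labels.
#' @return Named list of `data.frame`s (`level`, `count`, `percent`).
#' @export
cohort_summary <- function(labels) {
  if (nrow(labels) == 0) stop("empty label table")
  n <- nrow(labels)
  cols <- names(labels)[!vapply(labels, is.numeric, logical(1)) |
                          names(labels) %in% c("type", "grade")]
  out <- lapply(cols, function(cl) {
    tab <- table(as.character(labels[[cl]]), useNA = "no")
    data.frame(level = names(tab), count = as.integer(tab),
               percent = as.integer(round(100 * as.integer(tab) / n)))
  })
  stats::setNames(out, cols)
}

#' Run the full univariate comparison grid
#'
#' One Mann-Whitney test and Cohen's d per (contrast x parameter x
#' characteristic x ROI) cell. No multiple-comparison correction is
#' applied by default (`p_adjust = "none"`); any method of
#' [stats::p.adjust()] may be requested. Cells with undefined statistics
#' are carried as `NA`.
#'
#' @param features Feature table from [build_feature_table()].
#' @param contrasts List of [contrast()]s.
#' @param parameters Parameters tested.
#' @param rois ROIs tested.
#' @param alpha Significance threshold.
#' @param p_adjust Multiple-comparison correction method (default none).
#' @return Tidy `data.frame`, one row per cell: `contrast`, `parameter`,
#'   `characteristic`, `roi`, `n1`, `n2`, `d`, `u`, `p`, `significant`.
#' @export
run_all_tests <- function(features, contrasts = default_contrasts(),
                          parameters = c("s0", "md", "fa", "mk", "mk_a",
                                         "mk_i"),
                          rois = c("whole_tumor", "rim"),
                          alpha = 0.05, p_adjust = "none") {
  rows <- list()
  for (ct in contrasts) {
    sel <- contrast_split(features, ct)
    for (roi in rois) for (p in parameters)
      for (ch in characteristics_order) {
        col <- paste(p, ch, roi, sep = "__")
        if (!col %in% names(features)) next
        xp <- features[[col]][sel$pos]; xn <- features[[col]][sel$neg]
        d <- suppressWarnings(tryCatch(as.numeric(cohens_d(xp, xn)),
                                       error = function(e) NA_real_))
        mw <- tryCatch(mann_whitney(xp, xn),
                       error = function(e) list(u = NA_real_, p = NA_real_))
        rows[[length(rows) + 1L]] <- data.frame(
          contrast = ct$name, parameter = p, characteristic = ch, roi = roi,
          n1 = sum(!is.na(xp)), n2 = sum(!is.na(xn)),
          d = d, u = mw$u, p = mw$p)
      }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = p_adjust)
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  out
}

#' Full ROC characterization of one feature under one contrast
#'
#' Convenience wrapper producing the quantities reported per headline
#' comparison: AUC, bootstrap CI, Youden cut-point with its sensitivity
#' and specificity, and the U test.
#'
#' @param features Feature table.
#' @param ct A [contrast()].
#' @param column Feature column name (`parameter__characteristic__roi`).
#' @param direction Score direction passed to [roc_auc()].
#' @param n_boot,seed Bootstrap settings.
#' @return List with `auc`, `ci`, `cutpoint`, `sensitivity`,
#'   `specificity`, `u`, `p`, `n1`, `n2`.
#' @export
compare_groups <- function(features, ct, column,
                           direction = c("greater", "less"),
                           n_boot = 5000L, seed = 1L) {
  direction <- match.arg(direction)
  sel <- contrast_split(features, ct)
  sc <- features[[column]]
  scores <- c(sc[sel$pos], sc[sel$neg])
  labels <- rep(c(TRUE, FALSE), c(length(sel$pos), length(sel$neg)))
  ok <- !is.na(scores)
  scores <- scores[ok]; labels <- labels[ok]
  mw <- mann_whitney(scores[labels], scores[!labels])
  cp <- optimal_cutpoint(scores, labels, direction)
  list(auc = roc_auc(scores, labels, direction),
       ci = bootstrap_auc_ci(scores, labels, n_boot, seed, direction),
       cutpoint = cp$cutpoint, sensitivity = cp$sensitivity,
       specificity = cp$specificity,
       u = mw$u, p = mw$p, n1 = sum(labels), n2 = sum(!labels))
}
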