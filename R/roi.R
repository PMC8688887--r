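#' Morphological rim ROI around a tumor
#'
#' The rim is the tumor mask dilated by `width_voxels` steps of
#' 26-connectivity (a Chebyshev ball), minus the tumor, intersected with
#' the brain support — a reproducible geometric stand-in for a manually
#' drawn peritumoral ring up to `width_voxels` voxels wide. At 2.3 mm
#' isotropic voxels the default width of 2 reaches 4.6 mm.
#'
#' @param tumor A [roi_mask()] (or logical array) of the tumor.
#' @param brain Logical array (or `roi_mask`) of the brain support.
#' @param width_voxels Ring width in voxels (>= 1).
#' @return A [roi_mask()] of kind `"rim"`, disjoint from the tumor.
#' @export
make_rim_roi <- function(tumor, brain, width_voxels = 2L) {
  tm <- if (inherits(tumor, "roi_mask")) tumor$mask else tumor
  bm <- if (inherits(brain, "roi_mask")) brain$mask else brain
  stopifnot(width_voxels >= 1)
  if (any(tm & !bm)) stop("tumor mask must lie inside the brain support")
  dil <- tm
  for (i in seq_len(width_voxels)) dil <- dilate26(dil)
  rim <- dil & !tm & bm
  if (!any(rim)) stop("empty rim: tumor fills the brain support")
  roi_mask(rim, "rim")
}

# One 26-connectivity dilation step via shifted copies.
dilate26 <- function(m) {
  d <- dim(m)
  out <- m
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    xs <- pmin(pmax(seq_len(d[1]) - dx, 1L), d[1])
    ys <- pmin(pmax(seq_len(d[2]) - dy, 1L), d[2])
    zs <- pmin(pmax(seq_len(d[3]) - dz, 1L), d[3])
    # clamp-shift would duplicate the border plane; build a zero-padded shift
    sh <- array(FALSE, d)
    src_x <- seq_len(d[1]) - dx; src_y <- seq_len(d[2]) - dy
    src_z <- seq_len(d[3]) - dz
    okx <- src_x >= 1 & src_x <= d[1]
    oky <- src_y >= 1 & src_y <= d[2]
    okz <- src_z >= 1 & src_z <= d[3]
    sh[okx, oky, okz] <- m[src_x[okx], src_y[oky], src_z[okz]]
    out <- out | sh
  }
  out
}

characteristics_order <- c("p10", "p25", "p50", "p75", "p90", "std")

#' Distribution characteristics of a parameter map within an ROI
#'
#' Reduces each available parameter map to six distribution
#' characteristics over the ROI voxels: the 10th, 25th, 50th, 75th and
#' 90th percentiles (linear interpolation between order statistics,
#' quantile type 7) and the standard deviation (n - 1 denominator).
#' Voxels flagged by the fitter as not fitted or non-converged
#' (`fit_flags >= 2`), or carrying `NA`, are excluded.
#'
#' @param maps A [parameter_maps()].
#' @param roi A [roi_mask()] (or logical array).
#' @param parameters Character vector of map names to reduce.
#' @return Named numeric vector with entries `parameter__characteristic`
#'   (e.g. `md__p10`), plus attribute `n_voxels` (voxels used per
#'   parameter). All-missing maps give `NA` characteristics with count 0.
#' @export
extract_features <- function(maps, roi,
                             parameters = c("s0", "md", "fa", "mk",
                                            "mk_a", "mk_i")) {
  stopifnot(inherits(maps, "parameter_maps"))
  m <- if (inherits(roi, "roi_mask")) roi$mask else roi
  if (!any(m)) stop("ROI is empty")
  usable <- m
  if (!is.null(maps$fit_flags)) usable <- usable & maps$fit_flags < 2L
  out <- numeric(0)
  counts <- integer(0)
  for (p in parameters) {
    vals <- if (is.null(maps[[p]])) numeric(0) else maps[[p]][usable]
    vals <- vals[!is.na(vals)]
    feat <- if (length(vals) == 0) {
      rep(NA_real_, 6)
    } else {
      c(stats::quantile(vals, c(.10, .25, .50, .75, .90), names = FALSE,
                        type = 7),
        stats::sd(vals))
    }
    names(feat) <- paste(p, characteristics_order, sep = "__")
    out <- c(out, feat)
    counts <- c(counts, stats::setNames(length(vals), p))
  }
  attr(out, "n_voxels") <- counts
  out
}

#' Feature table of a phantom cohort
#'
#' Applies [extract_features()] to each subject's maps in the whole-tumor
#' ROI and the surrounding rim ROI, yielding one row per subject with
#' columns named `parameter__characteristic__roi` plus the group labels.
#'
#' @param maps_list List of [parameter_maps()], one per subject.
#' @param subjects List of `phantom_subject`s (for masks and labels); rim
#'   ROIs are built with [make_rim_roi()].
#' @param parameters Parameter maps to reduce.
#' @param rim_width Rim width in voxels.
#' @return A `data.frame`: label columns `consistency`, `grade`, `type`,
#'   then 6 x `length(parameters)` feature columns per ROI.
#' @export
build_feature_table <- function(maps_list, subjects,
                                parameters = c("s0", "md", "fa", "mk",
                                               "mk_a", "mk_i"),
                                rim_width = 2L) {
  stopifnot(length(maps_list) == length(subjects))
  rows <- lapply(seq_along(subjects), function(i) {
    s <- subjects[[i]]
    rim <- make_rim_roi(s$tumor_mask, s$brain_mask$mask, rim_width)
    ft <- extract_features(maps_list[[i]], s$tumor_mask, parameters)
    fr <- extract_features(maps_list[[i]], rim, parameters)
    names(ft) <- paste0(names(ft), "__whole_tumor")
    names(fr) <- paste0(names(fr), "__rim")
    cbind(data.frame(subject = s$id,
                     consistency = s$labels$consistency,
                     grade = s$labels$grade,
                     type = s$labels$type),
          as.data.frame(t(c(ft, fr))))
  })
  do.call(rbind, rows)
}
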