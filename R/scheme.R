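#' Acquisition scheme for tensor-valued diffusion encoding
#'
#' An acquisition scheme describes one diffusion measurement per row: the
#' b-value `b` (stored internally in ms/um^2; 1 ms/um^2 = 1000 s/mm^2), the
#' b-tensor shape `b_delta` (1 for linear encoding, 0 for spherical encoding,
#' any value in \[-0.5, 1\] accepted), and a gradient direction (a unit
#' vector for linear encoding; arbitrary for spherical encoding, which is
#' direction-free). Measurements sharing the same `(b, b_delta)` are grouped
#' into shells.
#'
#' @param b Numeric vector of b-values in ms/um^2, all >= 0.
#' @param b_delta Numeric vector of b-tensor shapes in \[-0.5, 1\].
#' @param directions `n x 3` matrix of encoding directions.
#' @return An object of class `acq_scheme` with fields `b`, `b_delta`,
#'   `directions`, `shell_id`, `n_meas`, `shells` (per-shell table).
#' @export
acquisition_scheme <- function(b, b_delta, directions) {
  b <- as.numeric(b)
  b_delta <- as.numeric(b_delta)
  directions <- as.matrix(directions)
  n <- length(b)
  if (length(b_delta) != n || nrow(directions) != n || ncol(directions) != 3)
    stop("b, b_delta and directions must describe the same number of measurements")
  if (any(!is.finite(b)) || any(b < 0))
    stop("all b-values must be finite and non-negative")
  if (any(b_delta < -0.5 - 1e-9) || any(b_delta > 1 + 1e-9))
    stop("b_delta must lie in [-0.5, 1]")
  norms <- sqrt(rowSums(directions^2))
  lte <- b > 0 & abs(b_delta) > 1e-12
  if (any(abs(norms[lte] - 1) > 1e-6))
    stop("non-unit direction vector on an anisotropic-encoding (e.g. LTE) row")
  sid <- assign_shells(b, b_delta)
  shells <- unique(data.frame(shell_id = sid, b = b, b_delta = b_delta))
  shells <- shells[order(shells$shell_id), , drop = FALSE]
  shells$n_in_shell <- as.integer(table(factor(sid, levels = shells$shell_id)))
  rownames(shells) <- NULL
  structure(list(b = b, b_delta = b_delta, directions = directions,
                 shell_id = sid, n_meas = n, shells = shells),
            class = "acq_scheme")
}

# Shells are exact (b, b_delta) groups (|db| <= 1e-6 ms/um^2, exact b_delta).
# Ids are assigned in (b, b_delta) order, so they do not depend on row order.
assign_shells <- function(b, b_delta) {
  key_b <- round(b / 1e-6) * 1e-6
  keys <- paste(format(key_b, digits = 15), format(b_delta, digits = 15))
  uk <- unique(data.frame(key = keys, b = key_b, bd = b_delta,
                          stringsAsFactors = FALSE))
  uk <- uk[order(uk$b, uk$bd), , drop = FALSE]
  match(keys, uk$key)
}

#' @export
print.acq_scheme <- function(x, ...) {
  cat("Acquisition scheme:", x$n_meas, "measurements,",
      nrow(x$shells), "shells\n")
  print(x$shells, row.names = FALSE)
  invisible(x)
}

#' The built-in multi-shell LTE+STE protocol
#'
#' Four linear-encoding shells at b = 0.1, 0.7, 1.4 and 2.0 ms/um^2
#' (100/700/1400/2000 s/mm^2) with 6, 6, 12 and 16 directions from the
#' deterministic spread-direction generator, plus four spherical-encoding
#' shells at the same b-values with 6, 6, 12 and 16 repeats: 80 measurements
#' in 8 shells.
#'
#' @return An [acquisition_scheme()] object.
#' @export
default_protocol <- function() {
  b_shell <- c(0.1, 0.7, 1.4, 2.0)
  n_dir <- c(6L, 6L, 12L, 16L)
  b <- bd <- numeric(0)
  dirs <- matrix(numeric(0), 0, 3)
  for (k in seq_along(b_shell)) {           # LTE shells
    g <- spread_directions(n_dir[k])
    dirs <- rbind(dirs, g)
    b <- c(b, rep(b_shell[k], n_dir[k]))
    bd <- c(bd, rep(1, n_dir[k]))
  }
  for (k in seq_along(b_shell)) {           # STE shells (direction-free)
    dirs <- rbind(dirs, matrix(rep(c(0, 0, 1), n_dir[k]), ncol = 3, byrow = TRUE))
    b <- c(b, rep(b_shell[k], n_dir[k]))
    bd <- c(bd, rep(0, n_dir[k]))
  }
  acquisition_scheme(b, bd, dirs)
}

#' Read an acquisition scheme from disk
#'
#' Two dialects are supported. `"native_table"` is a whitespace-delimited
#' text table with one header line and columns `b` (s/mm^2), `b_delta`,
#' `gx`, `gy`, `gz`. `"bval_bvec_bdelta"` takes the path of an FSL-style
#' `.bval` file; the `.bvec` (3 rows) and `.bdelta` (1 row) files are
#' expected next to it with the same stem. b-values are converted to
#' ms/um^2 on load.
#'
#' @param path File path (the `.bval` file for the FSL dialect).
#' @param dialect One of `"native_table"`, `"bval_bvec_bdelta"`.
#' @return An [acquisition_scheme()].
#' @export
load_scheme <- function(path, dialect = c("native_table", "bval_bvec_bdelta")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("scheme file not found: ", path)
  if (dialect == "native_table") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) < 2) stop("scheme file has no data rows: ", path)
    rows <- lapply(seq_along(lines)[-1], function(i) {
      fields <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      vals <- suppressWarnings(as.numeric(fields))
      if (length(vals) != 5 || any(is.na(vals)))
        stop("malformed scheme row at line ", i, " of ", path)
      vals
    })
    tab <- do.call(rbind, rows)
    acquisition_scheme(tab[, 1] / 1000, tab[, 2], tab[, 3:5])
  } else {
    stem <- sub("\\.bval$", "", path)
    bval <- scan(path, quiet = TRUE)
    bvec <- as.matrix(utils::read.table(paste0(stem, ".bvec")))
    bdel <- scan(paste0(stem, ".bdelta"), quiet = TRUE)
    if (nrow(bvec) != 3) stop("bvec file must have 3 rows")
    if (ncol(bvec) != length(bval) || length(bdel) != length(bval))
      stop("bval/bvec/bdelta lengths disagree")
    acquisition_scheme(bval / 1000, bdel, t(bvec))
  }
}

#' Write an acquisition scheme in the native table dialect
#'
#' @param scheme An [acquisition_scheme()].
#' @param path Output file path. b is written in s/mm^2.
#' @export
save_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "acq_scheme"))
  tab <- cbind(scheme$b * 1000, scheme$b_delta, scheme$directions)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("b b_delta gx gy gz", con)
  utils::write.table(format(tab, digits = 17, scientific = FALSE, trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Diffusion-weighted volume
#'
#' Couples a 4D signal array (x, y, z, measurement) with its voxel size and
#' acquisition scheme. The 4th dimension must match `scheme$n_meas`.
#'
#' @param data 4D non-negative numeric array.
#' @param voxel_size Length-3 positive numeric, mm per axis (a scalar is
#'   recycled).
#' @param scheme An [acquisition_scheme()].
#' @return An object of class `dwi_volume`.
#' @export
dwi_volume <- function(data, voxel_size, scheme) {
  stopifnot(inherits(scheme, "acq_scheme"))
  data <- as.array(data)
  if (length(dim(data)) != 4)
    stop("data must be a 4D array (x, y, z, measurement)")
  if (dim(data)[4] != scheme$n_meas)
    stop("4th dimension (", dim(data)[4], ") does not match scheme n_meas (",
         scheme$n_meas, ")")
  voxel_size <- rep(as.numeric(voxel_size), length.out = 3)
  if (any(voxel_size <= 0)) stop("voxel_size must be strictly positive")
  structure(list(data = data, voxel_size = voxel_size, scheme = scheme),
            class = "dwi_volume")
}

#' @export
print.dwi_volume <- function(x, ...) {
  cat("DWI volume:", paste(dim(x$data), collapse = " x "),
      "| voxel", paste(x$voxel_size, collapse = " x "), "mm\n")
  invisible(x)
}

#' Binary region-of-interest mask
#'
#' @param mask Logical 3D array.
#' @param kind ROI kind, e.g. `"whole_tumor"` or `"rim"`.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(mask, kind = c("whole_tumor", "rim", "brain")) {
  kind <- match.arg(kind)
  mask <- as.array(mask)
  if (length(dim(mask)) != 3) stop("mask must be a 3D array")
  storage.mode(mask) <- "logical"
  structure(list(mask = mask, kind = kind), class = "roi_mask")
}

#' Read / write NIfTI volumes
#'
#' `read_volume()` loads a 4D NIfTI as a [dwi_volume()] (a scheme must be
#' supplied for association) or, for 3D files with `scheme = NULL`, returns
#' the raw array plus voxel size. `write_volume()` writes a `dwi_volume`,
#' `roi_mask` or bare array to NIfTI-1.
#'
#' @param path NIfTI file path.
#' @param scheme Optional [acquisition_scheme()] to associate.
#' @return `read_volume`: a `dwi_volume` (4D with scheme) or a list with
#'   `data` and `voxel_size`.
#' @export
read_volume <- function(path, scheme = NULL) {
  img <- RNifti::readNifti(path)
  vox <- RNifti::pixdim(img)[seq_len(min(3, length(RNifti::pixdim(img))))]
  vox <- rep(vox, length.out = 3)
  arr <- as.array(img)
  if (!is.null(scheme)) {
    if (length(dim(arr)) != 4)
      stop("expected a 4D volume to associate with a scheme")
    dwi_volume(arr, vox, scheme)
  } else {
    list(data = arr, voxel_size = vox)
  }
}

#' @param x A `dwi_volume`, `roi_mask`, or numeric array.
#' @param voxel_size Voxel size in mm, used when `x` is a bare array.
#' @rdname read_volume
#' @export
write_volume <- function(x, path, voxel_size = c(1, 1, 1)) {
  if (inherits(x, "dwi_volume")) {
    arr <- x$data; vox <- x$voxel_size
  } else if (inherits(x, "roi_mask")) {
    arr <- array(as.numeric(x$mask), dim = dim(x$mask)); vox <- voxel_size
  } else {
    arr <- as.array(x); vox <- rep(voxel_size, length.out = 3)
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(rep(vox, length.out = 3),
                           rep(1, max(0, length(dim(arr)) - 3)))
  RNifti::writeNifti(img, path)
  invisible(path)
}
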