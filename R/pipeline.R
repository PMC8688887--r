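#' Study configuration
#'
#' Bundles everything one end-to-end run needs: the cohort generator
#' configuration, the acquisition scheme, smoothing and rim settings, the
#' contrasts, and the statistics settings. Fully serializable to JSON
#' (via [save_study_config()] / [load_study_config()]); re-running a
#' persisted config reproduces all outputs bit-identically.
#'
#' @param cohort A [cohort_config()].
#' @param scheme `"default_protocol"` or a path readable by
#'   [load_scheme()].
#' @param sigma_mm Gaussian pre-smoothing SD in mm (0 disables).
#' @param rim_width Rim ROI width in voxels.
#' @param alpha Significance threshold.
#' @param n_boot Bootstrap resamples for headline ROC CIs.
#' @param seed Statistics/noise seed (the cohort has its own master seed).
#' @param write_maps Write per-subject NIfTI maps when running.
#' @return A `study_config` object.
#' @export
study_config <- function(cohort = cohort_config(), scheme = "default_protocol",
                         sigma_mm = 1.6, rim_width = 2L, alpha = 0.05,
                         n_boot = 5000L, seed = 1L, write_maps = FALSE) {
  structure(list(cohort = cohort, scheme = scheme, sigma_mm = sigma_mm,
                 rim_width = as.integer(rim_width), alpha = alpha,
                 n_boot = as.integer(n_boot), seed = as.integer(seed),
                 write_maps = isTRUE(write_maps)),
            class = "study_config")
}

#' Built-in study configurations
#'
#' `"smoke"` is a seconds-scale structural check (4 subjects, 16^3 grid);
#' `"demo"` exercises every stage at a small but meaningful size
#' (12 subjects across six strata, 24^3 grid, SNR 30); `"full"` uses a
#' 30-subject cohort whose consistency/grade/type composition mirrors a
#' surgical meningioma case mix (16 with known consistency: 7 firm,
#' 5 variable, 4 soft; 22 grade I / 8 grade II; 7 types).
#'
#' @param scale One of `"smoke"`, `"demo"`, `"full"`.
#' @param seed Master seed.
#' @return A [study_config()].
#' @export
make_demo_config <- function(scale = c("demo", "smoke", "full"), seed = 1L) {
  scale <- match.arg(scale)
  cc <- switch(scale,
    smoke = cohort_config(strata = demo_strata()[c(1, 3), ],
                          grid = c(16L, 16L, 16L), seed = seed),
    demo = cohort_config(strata = demo_strata(), grid = c(24L, 24L, 24L),
                         seed = seed),
    full = cohort_config(strata = full_strata(), grid = c(24L, 24L, 24L),
                         seed = seed))
  n_boot <- switch(scale, smoke = 200L, demo = 1000L, full = 5000L)
  study_config(cohort = cc, n_boot = n_boot, seed = seed)
}

#' @rdname study_config
#' @param config A `study_config`.
#' @param path JSON file path.
#' @export
save_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  x <- unclass(config)
  x$cohort <- unclass(x$cohort)
  x$cohort$strata <- as.data.frame(x$cohort$strata)
  # named numeric vectors must survive as JSON objects, not arrays
  for (f in c("between_sd", "jitter", "rim_mki_sd"))
    x$cohort[[f]] <- as.list(x$cohort[[f]])
  x$cohort$base <- lapply(x$cohort$base, as.list)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname study_config
#' @export
load_study_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  req <- c("cohort", "scheme", "sigma_mm", "rim_width", "alpha", "n_boot",
           "seed")
  miss <- setdiff(req, names(x))
  if (length(miss)) stop("config is missing fields: ",
                         paste(miss, collapse = ", "))
  cc <- x$cohort
  if (is.data.frame(cc$effects))
    cc$effects <- lapply(seq_len(nrow(cc$effects)),
                         function(i) as.list(cc$effects[i, ]))
  cohort <- cohort_config(
    strata = as.data.frame(cc$strata), grid = cc$grid,
    voxel_size = cc$voxel_size, snr = cc$snr, s0 = cc$s0,
    base = list(tumor = unlist(cc$base$tumor), brain = unlist(cc$base$brain)),
    between_sd = unlist(cc$between_sd), jitter = unlist(cc$jitter),
    effects = cc$effects, rim_mki_sd = unlist(cc$rim_mki_sd),
    dispersion = cc$dispersion, seed = cc$seed)
  study_config(cohort = cohort, scheme = x$scheme, sigma_mm = x$sigma_mm,
               rim_width = x$rim_width, alpha = x$alpha, n_boot = x$n_boot,
               seed = x$seed, write_maps = isTRUE(x$write_maps))
}

fit_subject_maps <- function(vol, mask, sigma_mm) {
  if (sigma_mm > 0) vol <- smooth_volume(vol, sigma_mm)
  qti <- fit_qti(powder_average(vol), mask = mask)
  dti <- fit_dti(vol, mask = mask)
  dki <- fit_dki(vol, mask = mask)
  parameter_maps(s0 = qti$s0, md = qti$md, fa = dti$fa, mk = dki$mk,
                 mk_a = qti$mk_a, mk_i = qti$mk_i,
                 fit_flags = qti$fit_flags, voxel_size = vol$voxel_size)
}

#' Run a full simulated study
#'
#' Executes simulate -> smooth -> fit (cumulant, DTI, DKI) -> ROI features
#' -> group statistics from one [study_config()], writing the feature
#' table, the test table, headline ROC summaries and a run manifest to
#' `out_dir`. Every stage is seeded from the config, so identical configs
#' give byte-identical CSV outputs.
#'
#' @param config A [study_config()].
#' @param out_dir Output directory (created if missing).
#' @param verbose Log stage progress.
#' @return Invisibly, a list with `subjects`, `maps`, `features`, `tests`,
#'   `ranking`, `headline`, `manifest`.
#' @export
run_study <- function(config, out_dir = tempfile("study"), verbose = TRUE) {
  stopifnot(inherits(config, "study_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  scheme <- if (identical(config$scheme, "default_protocol")) default_protocol()
            else load_scheme(config$scheme)

  say("stage simulate: sampling cohort (seed %d)", config$cohort$seed)
  subjects <- sample_cohort(config$cohort)

  maps <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    t0 <- Sys.time()
    vol <- tryCatch(
      simulate_signals(s, scheme, snr = config$cohort$snr,
                       seed = substream_seed(config$seed, i, "noise")),
      error = function(e) stop("stage simulate failed for subject ", s$id,
                               ": ", conditionMessage(e)))
    maps[[i]] <- tryCatch(
      fit_subject_maps(vol, s$brain_mask$mask, config$sigma_mm),
      error = function(e) stop("stage fit failed for subject ", s$id, ": ",
                               conditionMessage(e)))
    n_clamp <- sum(maps[[i]]$fit_flags == 1L)
    n_bad <- sum(maps[[i]]$fit_flags >= 3L)
    say("stage fit: subject %d/%d done in %.1fs (clamped %d, non-converged %d)",
        i, length(subjects), as.numeric(Sys.time() - t0, units = "secs"),
        n_clamp, n_bad)
    if (config$write_maps) {
      sd_ <- file.path(out_dir, sprintf("subject_%02d", s$id))
      dir.create(sd_, showWarnings = FALSE)
      for (nm in c("s0", "md", "fa", "mk", "mk_a", "mk_i"))
        write_volume(maps[[i]][[nm]], file.path(sd_, paste0(nm, ".nii.gz")),
                     voxel_size = s$voxel_size)
      write_volume(array(as.numeric(maps[[i]]$fit_flags), dim = s$grid),
                   file.path(sd_, "fit_flags.nii.gz"),
                   voxel_size = s$voxel_size)
      write_volume(s$tumor_mask, file.path(sd_, "tumor_mask.nii.gz"),
                   voxel_size = s$voxel_size)
    }
  }

  say("stage features: %d subjects, rim width %d", length(subjects),
      config$rim_width)
  features <- tryCatch(
    build_feature_table(maps, subjects, rim_width = config$rim_width),
    error = function(e) stop("stage features failed: ", conditionMessage(e)))
  utils::write.csv(features, file.path(out_dir, "features.csv"),
                   row.names = FALSE)

  say("stage stats: %d contrasts", length(default_contrasts()))
  present <- intersect_contrasts(features, default_contrasts())
  tests <- run_all_tests(features, present, alpha = config$alpha)
  utils::write.csv(tests, file.path(out_dir, "tests.csv"), row.names = FALSE)
  ranking <- rank_characteristics(features, present)

  headline <- headline_comparisons(features, config)
  jsonlite::write_json(headline, file.path(out_dir, "headline.json"),
                       auto_unbox = TRUE, digits = NA)

  manifest <- list(
    package_version = as.character(utils::packageVersion("tvdmri")),
    n_subjects = length(subjects), n_tests = nrow(tests),
    seed = config$seed, cohort_seed = config$cohort$seed,
    config_file = "config.json")
  save_study_config(config, file.path(out_dir, "config.json"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  say("done: outputs in %s", out_dir)
  invisible(list(subjects = subjects, maps = maps, features = features,
                 tests = tests, ranking = ranking, headline = headline,
                 manifest = manifest, out_dir = out_dir))
}

# keep only contrasts whose two groups are nonempty in this cohort
intersect_contrasts <- function(features, contrasts) {
  Filter(function(ct) {
    ok <- tryCatch({ contrast_split(features, ct); TRUE },
                   error = function(e) FALSE)
    ok
  }, contrasts)
}

# The four headline comparisons the pipeline is built around: firm
# consistency via the MK_A/MK 10th percentile (lower indicates firm),
# variable consistency via the MD 10th percentile (lower indicates
# variable), grade II via the rim MK_I standard deviation (higher
# indicates grade II), psammomatous type via the MK_A median (higher
# indicates psammomatous).
headline_comparisons <- function(features, config) {
  specs <- list(
    list(ct = contrast("consistency_firm", "consistency", "firm"),
         column = "mk_a__p10__whole_tumor", direction = "less"),
    list(ct = contrast("consistency_firm", "consistency", "firm"),
         column = "mk__p10__whole_tumor", direction = "less"),
    list(ct = contrast("consistency_variable", "consistency", "variable"),
         column = "md__p10__whole_tumor", direction = "less"),
    list(ct = contrast("grade_II", "grade", "II"),
         column = "mk_i__std__rim", direction = "greater"),
    list(ct = contrast("type_7", "type", 7),
         column = "mk_a__p50__whole_tumor", direction = "greater"))
  out <- list()
  for (sp in specs) {
    res <- tryCatch(
      compare_groups(features, sp$ct, sp$column, sp$direction,
                     n_boot = config$n_boot, seed = config$seed),
      error = function(e) NULL)
    if (!is.null(res))
      out[[paste(sp$ct$name, sp$column, sep = ".")]] <-
        c(list(contrast = sp$ct$name, column = sp$column,
               direction = sp$direction), res)
  }
  out
}
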