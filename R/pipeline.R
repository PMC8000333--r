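#' Build a run configuration
#'
#' Collects every tunable of the end-to-end pipeline with its default.
#' Chromatograms may be supplied directly (`chromatograms` — a named list
#' of [chromatogram()] objects whose `role`/`level` fields drive the run)
#' or simulated from a [synthetic_profile()] when `simulate = TRUE`.
#'
#' @param simulate Generate inputs from the synthetic profile.
#' @param profile [synthetic_profile()] used when simulating.
#' @param chromatograms Named list of [chromatogram()]s (roles
#'   `calibration` / `batch` / `reference` set, calibration `level`s set).
#' @param levels,replicates Calibration design used when simulating.
#' @param batch_profiles List of [batch_profile()]s when simulating.
#' @param baseline [baseline_params()].
#' @param max_peaks,min_height,rt_tolerance,init_hwhm Peak-processing
#'   settings (see [auto_add_peaks()], [match_peaks()]).
#' @param r2_threshold Strict R^2 retention threshold.
#' @param reference_peak Ratio reference peak name, or `NULL` to use the
#'   retained peak with the highest R^2.
#' @param ssim_params Arguments for [ssim_score()].
#' @param seed Integer seed for all simulation randomness.
#' @param out_dir Optional directory for the report tables.
#' @return List of class `"qc_config"`.
#' @export
qc_config <- function(simulate = TRUE, profile = synthetic_profile(),
                      chromatograms = NULL,
                      levels = c(100, 130, 160, 190, 220),
                      replicates = 3L,
                      batch_profiles = NULL,
                      baseline = baseline_params(),
                      max_peaks = 40L, min_height = 1.2e-3,
                      rt_tolerance = 0.15, init_hwhm = 0.06,
                      r2_threshold = 0.99, reference_peak = NULL,
                      ssim_params = list(), seed = 1L, out_dir = NULL) {
  stopifnot(r2_threshold > 0, r2_threshold < 1)
  cfg <- list(simulate = simulate, profile = profile,
              chromatograms = chromatograms, levels = levels,
              replicates = replicates, batch_profiles = batch_profiles,
              baseline = baseline, max_peaks = max_peaks,
              min_height = min_height, rt_tolerance = rt_tolerance,
              init_hwhm = init_hwhm, r2_threshold = r2_threshold,
              reference_peak = reference_peak, ssim_params = ssim_params,
              seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "qc_config"
  cfg
}

# baseline-correct, then fit every run against the discovered reference
# peak set; returns the matched peak table plus per-run fits
process_runs <- function(chroms, cfg, reference_run = 1L,
                         levels = NULL) {
  corrected <- lapply(chroms, subtract_baseline, params = cfg$baseline)
  ref_fit <- auto_add_peaks(corrected[[reference_run]],
                            max_peaks = cfg$max_peaks,
                            min_height = cfg$min_height,
                            init_hwhm = cfg$init_hwhm)
  fits <- vector("list", length(corrected))
  fits[[reference_run]] <- ref_fit
  for (i in seq_along(corrected)) {
    if (i == reference_run) next
    fits[[i]] <- fit_peaks(corrected[[i]], ref_fit)
  }
  pt <- match_peaks(fits, rt_tolerance = cfg$rt_tolerance,
                    reference = reference_run,
                    sample_ids = names(chroms), levels = levels)
  list(peak_table = pt, fits = fits, reference_fit = ref_fit)
}

#' Average univariate concentration estimate of a sample
#'
#' Inverse-predicts the sample's area on every retained calibration model
#' and averages the per-peak estimates.
#'
#' @param models Named list of `"linear_calibration"` objects.
#' @param areas Named area vector of the sample.
#' @return Mean of the per-peak estimates (ug/mL).
#' @export
estimate_concentration <- function(models, areas) {
  a <- unlist(areas)
  mean(vapply(models, function(m)
    inverse_predict(m, a[[m$peak_name]])$estimate, numeric(1)))
}

#' Run the full quality-control pipeline
#'
#' Executes the flowchart end to end: baseline correction, peak discovery
#' on a reference run and refitting of all runs, retention-time matching
#' into a peak table, per-peak linear calibration with the strict R^2
#' filter, inverse prediction of every batch on every retained peak, a
#' SIMPLS PLS model of total content with leave-one-out CV and jack-knife
#' intervals, an ICH-style validation summary from the calibration
#' replicates, and the ratio-based conformity block (similarity battery,
#' ratio-matrix SSIM, PCA).  All randomness is seeded, so identical
#' configurations give identical outputs.
#'
#' @param config A [qc_config()].
#' @return Object of class `"qc_report"`: list with `models_table`,
#'   `interpolation_table`, `pls_table`, `validation_table`,
#'   `similarity_table`, `ssim_table`, plus `calibrations`, `retained`,
#'   `pls`, `conformity`, `peak_tables`, `log`.
#' @export
run_qc <- function(config = qc_config()) {
  stopifnot(inherits(config, "qc_config"))
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))

  if (config$simulate) {
    cal <- make_calibration_series(config$profile, config$levels,
                                   config$replicates, seed = config$seed)
    bats <- if (is.null(config$batch_profiles))
      make_batches(config$profile, seed = config$seed)
    else make_batches(config$profile, config$batch_profiles,
                      seed = config$seed)
    ref_sim <- make_chromatogram(config$profile, 160,
                                 seed = config$seed * 1000L + 999L,
                                 sample_id = "reference",
                                 role = "reference")
    chroms <- c(cal$chromatograms, list(reference = ref_sim$chromatogram),
                bats$chromatograms)
    cal_ids <- names(cal$chromatograms)
    batch_ids <- names(bats$chromatograms)
    cal_levels <- vapply(cal$chromatograms, `[[`, numeric(1), "level")
  } else {
    chroms <- config$chromatograms
    if (is.null(chroms)) stop("no chromatograms supplied")
    roles <- vapply(chroms, `[[`, character(1), "role")
    cal_ids <- names(chroms)[roles == "calibration"]
    batch_ids <- names(chroms)[roles == "batch"]
    if (!any(roles == "reference")) stop("reference required")
    if (!length(cal_ids)) stop("calibration runs required")
    cal_levels <- vapply(chroms[cal_ids], `[[`, numeric(1), "level")
  }
  if (!"reference" %in% names(chroms))
    names(chroms)[vapply(chroms, `[[`, character(1), "role") ==
                    "reference"][1L] <- "reference"
  note("inputs: ", length(cal_ids), " calibration runs, ",
       length(batch_ids), " batches + reference")

  # discovery on the top calibration level (most peaks above threshold)
  ref_run <- which(names(chroms) == cal_ids[which.max(cal_levels)])[1L]
  lv_all <- rep(NA_real_, length(chroms))
  lv_all[match(cal_ids, names(chroms))] <- cal_levels
  pr <- process_runs(chroms, config, reference_run = ref_run,
                     levels = lv_all)
  pt <- pr$peak_table
  note("peaks discovered: ", length(pt$peak_names))

  cal_idx <- match(cal_ids, pt$sample_ids)
  models <- lapply(pt$peak_names, function(pk)
    fit_linear(cal_levels, pt$areas[cal_idx, pk], peak_name = pk))
  names(models) <- pt$peak_names
  retained <- select_calibrated_peaks(models, config$r2_threshold)
  note("calibration models retained (R2 > ", config$r2_threshold, "): ",
       length(retained), " of ", length(models))
  models_table <- do.call(rbind, lapply(models, function(m)
    data.frame(peak = m$peak_name, B0 = m$B0, B1 = m$B1, se_B0 = m$se_B0,
               se_B1 = m$se_B1, R2 = m$R2, Syx = m$Syx,
               LOD = if (m$B1 > 0) lod_loq(m)$lod else NA_real_,
               LOQ = if (m$B1 > 0) lod_loq(m)$loq else NA_real_,
               retained = m$peak_name %in% retained)))
  rownames(models_table) <- NULL

  kept <- models[retained]
  eval_ids <- c("reference", batch_ids)
  interp <- sapply(kept, function(m) vapply(eval_ids, function(id)
    inverse_predict(m, pt$areas[id, m$peak_name])$estimate, numeric(1)))
  interpolation_table <- data.frame(sample = eval_ids,
                                    matrix(interp, nrow = length(eval_ids),
                                           dimnames = list(NULL, retained)),
                                    check.names = FALSE)

  pls <- simpls_fit(pt$areas[cal_idx, , drop = FALSE], cal_levels,
                    n_components = min(4L, length(cal_idx) - 2L))
  pls_pred <- pls_predict(pls, pt$areas[batch_ids, , drop = FALSE],
                          nominal = 160)
  pls_table <- cbind(data.frame(batch = batch_ids), pls_pred)
  note("PLS components selected: ", pls$selected,
       " (fitted R2 ", sprintf("%.4f", pls$R2[pls$selected]), ")")

  val_pred <- do.call(rbind, lapply(cal_ids, function(id) {
    i <- match(id, pt$sample_ids)
    data.frame(level = lv_all[i], run = 1L,
               day = sub(".*_r", "", id),
               condition = "nominal",
               value = estimate_concentration(kept, pt$areas[i, ]))
  }))
  validation_table <- validation_summary(val_pred)

  conf <- conformity_report(pt$areas["reference", ],
                            peak_table(pt$areas[batch_ids, , drop = FALSE],
                                       sample_ids = batch_ids,
                                       peak_names = pt$peak_names),
                            reference_peak = if (is.null(config$reference_peak))
                              retained[which.max(vapply(kept, `[[`,
                                                        numeric(1), "R2"))]
                            else config$reference_peak,
                            peaks = retained,
                            ssim_params = config$ssim_params)
  similarity_table <- conf$table[, setdiff(names(conf$table),
                                           c("ssim", "pca_distance",
                                             "conforming"))]
  ssim_table <- conf$table[, c("batch", "ssim", "conforming")]
  note("lowest SSIM: ",
       conf$table$batch[which.min(conf$table$ssim)])

  report <- structure(list(models_table = models_table,
                           interpolation_table = interpolation_table,
                           pls_table = pls_table,
                           validation_table = as.data.frame(validation_table),
                           similarity_table = similarity_table,
                           ssim_table = ssim_table,
                           calibrations = models, retained = retained,
                           pls = pls, conformity = conf,
                           peak_table = pt, log = log),
                      class = "qc_report")
  if (!is.null(config$out_dir)) {
    write_report_tables(list(models = models_table,
                             interpolations = interpolation_table,
                             pls = pls_table,
                             validation = as.data.frame(validation_table),
                             similarity = similarity_table,
                             ssim = ssim_table),
                        config$out_dir, digits = 4)
    writeLines(log, file.path(config$out_dir, "run_log.txt"))
  }
  report
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC pipeline report\n")
  for (l in x$log) cat("  -", l, "\n")
  invisible(x)
}

#' Package and default-parameter description
#'
#' @return Character vector describing the toolkit version and the default
#'   processing parameters.
#' @export
version_info <- function() {
  v <- tryCatch(as.character(utils::packageVersion("chromaqc")),
                error = function(e) "dev")
  bp <- baseline_params()
  c(paste0("chromaqc ", v),
    sprintf("baseline: lambda_exponent %g, hwi %d, iterations %d, buckets %d",
            bp$lambda_exponent, bp$hwi, bp$iterations, bp$buckets),
    "peaks: min_height 1.2e-3 AU, init_hwhm 0.06 min, rt_tolerance 0.15 min",
    "calibration: R2 retention threshold 0.99 (strict)",
    "ssim: K1 0.01, K2 0.03, global mode")
}
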