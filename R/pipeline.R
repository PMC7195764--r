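#' Load a cohort from a manifest CSV and per-patient beat CSVs
#'
#' Reads `manifest.csv` (columns `patient_id`, `dose_mcg`, optionally
#' `latent_class` and covariates) and one `<patient_id>_beats.csv`
#' (columns `time_s`, `as_value`) per row.  Patients whose beat file is
#' missing, malformed, or too short to cover `skip + window` seconds are
#' excluded with a logged reason — sessions can legitimately be too short
#' or too artifact-ridden to analyze — and the run continues; zero usable
#' patients is fatal.
#'
#' @param manifest_path path to the manifest CSV.
#' @param beats_dir directory holding the beat CSVs (defaults to the
#'   manifest's directory).
#' @param min_duration_s minimum usable session length, seconds
#'   (default 2300 = 300 s skip + 2000 s window).
#' @return a `"cohort"` object; excluded patients are reported in
#'   `attr(, "exclusions")` (data frame patient_id, reason).
#' @export
load_cohort <- function(manifest_path, beats_dir = dirname(manifest_path),
                        min_duration_s = 2300) {
  if (!file.exists(manifest_path)) stop_invalid("manifest not found: ", manifest_path)
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  if (!nrow(manifest)) stop_invalid("manifest is empty")
  if (!all(c("patient_id", "dose_mcg") %in% names(manifest)))
    stop_invalid("manifest must have patient_id and dose_mcg columns")
  patients <- list()
  excl <- list()
  for (i in seq_len(nrow(manifest))) {
    pid <- manifest$patient_id[i]
    path <- file.path(beats_dir, paste0(pid, "_beats.csv"))
    reason <- NULL
    if (!file.exists(path)) {
      reason <- "beat file missing"
    } else {
      beats <- tryCatch(utils::read.csv(path), error = function(e) e)
      if (inherits(beats, "error") ||
          !all(c("time_s", "as_value") %in% names(beats))) {
        reason <- "beat file malformed"
      } else if (nrow(beats) < 2 || max(beats$time_s) < min_duration_s) {
        reason <- sprintf("session too short (%.0f s < %.0f s)",
                          if (nrow(beats)) max(beats$time_s) else 0, min_duration_s)
      } else {
        ser <- tryCatch(beat_series(pid, beats$time_s, beats$as_value),
                        error = function(e) e)
        if (inherits(ser, "error")) reason <- conditionMessage(ser)
      }
    }
    if (is.null(reason)) {
      patients[[length(patients) + 1L]] <- list(
        patient_id = pid, series = ser, dose_mcg = manifest$dose_mcg[i],
        latent_class = if ("latent_class" %in% names(manifest))
          manifest$latent_class[i] else NA_character_)
    } else {
      excl[[length(excl) + 1L]] <- data.frame(patient_id = pid, reason = reason)
      message(sprintf("excluding %s: %s", pid, reason))
    }
  }
  if (!length(patients)) stop_invalid("no usable patients in cohort")
  keep <- vapply(patients, `[[`, "", "patient_id")
  cohort <- structure(list(
    patients = patients,
    manifest = manifest[match(keep, manifest$patient_id), , drop = FALSE],
    config = NULL), class = "cohort")
  attr(cohort, "exclusions") <- if (length(excl)) do.call(rbind, excl) else
    data.frame(patient_id = character(0), reason = character(0))
  cohort
}

#' End-to-end analysis pipeline
#'
#' Runs the selected stages in order — simulate, coherence (which
#' includes resampling), evaluate, nn — writing CSV artifacts and a
#' machine-readable JSON summary to `out_dir`.  Every artifact records
#' the config hash and master seed.  A stage failure aborts with the
#' stage name; artifacts of completed stages are preserved.
#'
#' @param config list with elements `cohort` (a [cohort_config()] or
#'   `NULL` to load data), `window` (a [window_spec()]), `mlp` (an
#'   [mlp_config()]), `thresholds_mcg` (sweep grid), `lag_min_s`,
#'   `lag_max_s`, and optionally `manifest_path` for loading a real
#'   cohort instead of simulating.  See [pipeline_config()].
#' @param out_dir output directory.
#' @param stages character subset of
#'   `c("simulate", "coherence", "evaluate", "nn")`.
#' @return invisibly, the summary list (also written as `summary.json`).
#' @export
run_pipeline <- function(config = pipeline_config(),
                         out_dir = tempfile("ascoh_"),
                         stages = c("simulate", "coherence", "evaluate", "nn")) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  summary <- list(config_hash = hash, seed = config$cohort$seed, stages = stages)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  cohort <- NULL
  if ("simulate" %in% stages) {
    cohort <- stage("simulate", {
      ch <- generate_cohort(config$cohort)
      write_cohort(ch, file.path(out_dir, "cohort"))
      ch
    })
    summary$n_patients <- nrow(cohort$manifest)
  } else if (!is.null(config$manifest_path)) {
    cohort <- stage("load", load_cohort(config$manifest_path))
    summary$n_patients <- nrow(cohort$manifest)
    summary$exclusions <- attr(cohort, "exclusions")
  }
  if (any(c("coherence", "evaluate", "nn") %in% stages) && is.null(cohort))
    stop_invalid("later stages need a cohort: include 'simulate' or set manifest_path")
  if (any(c("evaluate", "nn") %in% stages) && !"coherence" %in% stages)
    stop_invalid("'evaluate' and 'nn' stages require the 'coherence' stage")
  metrics <- NULL
  if ("coherence" %in% stages) {
    metrics <- stage("coherence", cohort_metrics(
      cohort, config$window, rate_hz = config$rate_hz,
      lag_min_s = config$lag_min_s, lag_max_s = config$lag_max_s,
      keep_spectra = "nn" %in% stages))
    write_stamped(metrics, file.path(out_dir, "metrics.csv"), hash)
    summary$metrics <- list(
      mean = mean(metrics$metric), sd = stats::sd(metrics$metric))
  }
  if ("evaluate" %in% stages) {
    stage("evaluate", {
      sweep <- dose_threshold_sweep(metrics, config$thresholds_mcg)
      write_stamped(sweep$table, file.path(out_dir, "dose_sweep.csv"), hash)
      best <- sweep$rocs[[as.character(sweep$best_auc_threshold)]]
      write_stamped(data.frame(cutoff = best$cutoffs, fpr = best$fpr,
                               tpr = best$tpr),
                    file.path(out_dir, "roc_best_threshold.csv"), hash)
      summary$evaluate <- list(
        best_auc_threshold = sweep$best_auc_threshold,
        best_youden_threshold = sweep$best_youden_threshold,
        best_auc = max(sweep$table$auc))
      if (all(c("latent_class") %in% names(metrics)) &&
          length(unique(metrics$latent_class)) == 2) {
        roc_truth <- roc_curve(metrics$metric,
                               as.integer(metrics$latent_class == "severe"))
        summary$evaluate$latent_class_auc <- roc_truth$auc
      }
    })
  }
  if ("nn" %in% stages) {
    stage("nn", {
      spectra <- attr(metrics, "spectra")
      feats <- prepare_inputs(spectra, config$feature_len)
      y <- as.integer(metrics$latent_class == "severe")
      ens <- run_ensemble(feats, y, config$mlp)
      write_stamped(ens$runs, file.path(out_dir, "nn_runs.csv"), hash)
      conv <- check_run_convergence(ens)
      summary$nn <- list(mean_error = ens$mean_error,
                         mean_auc = ens$mean_auc,
                         error_sd = ens$error_sd,
                         error_range = ens$error_range,
                         converged = conv$converged)
    })
  }
  json_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(summary)
}

#' Default pipeline configuration
#'
#' @param cohort a [cohort_config()].
#' @param window a [window_spec()].
#' @param mlp an [mlp_config()].
#' @param thresholds_mcg dose-threshold sweep grid.
#' @param rate_hz resampling rate.
#' @param lag_min_s,lag_max_s coherence-metric bounds.
#' @param feature_len NN input bins.
#' @param manifest_path optional manifest of a recorded cohort.
#' @return list usable by [run_pipeline()].
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            window = window_spec(),
                            mlp = mlp_config(n_runs = 100,
                                             seed = derive_seeds(cohort$seed, 2)[2]),
                            thresholds_mcg = seq(100, 800, by = 50),
                            rate_hz = 10, lag_min_s = 100, lag_max_s = 2000,
                            feature_len = 400,
                            manifest_path = NULL) {
  list(cohort = cohort, window = window, mlp = mlp,
       thresholds_mcg = thresholds_mcg, rate_hz = rate_hz,
       lag_min_s = lag_min_s, lag_max_s = lag_max_s,
       feature_len = feature_len, manifest_path = manifest_path)
}

# CSV writer stamping provenance (config hash) as a leading comment line.
write_stamped <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
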