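#' Configuration for a synthetic AS cohort
#'
#' Bundles every knob of the synthetic-cohort generator.  Defaults encode
#' the statistical skeleton of the clinical setting the package targets:
#' beat trains at heart rates between 70 and 103 bpm, sessions of 2700 s,
#' slow coherent AS modulations with a 3-minute period in the severe
#' class, and a cumulative phenylephrine dose distribution centred near
#' 462 mcg with an SD near 299 mcg once doses are quantized to the 100 mcg
#' bolus grid and clipped at zero.
#'
#' @param n_patients number of patients (>= 2).
#' @param hr_range_bpm numeric length-2, heart-rate bounds in bpm
#'   (positive, low < high).
#' @param duration_s session length in seconds.
#' @param osc_period_s period of the slow AS modulation, seconds.
#' @param amp_severe,amp_mild modulation amplitude (AS units, arbitrary
#'   device scale with baseline 1.0) for the two latent classes.
#' @param noise_sd SD of the AR(1) observation noise (AS units).
#' @param ar_coeff lag-1 autocorrelation of the noise process, in `[0, 1)`.
#' @param baseline constant AS level the modulation rides on.
#' @param dose_intercept_mcg,dose_slope_mcg_per_amp,dose_noise_sd_mcg
#'   parameters of the amplitude-to-dose link: latent dose =
#'   intercept + slope * amplitude + Gaussian noise, clipped at 0 and
#'   rounded to the nearest 100 mcg (phenylephrine is given in 100 mcg
#'   boluses).
#' @param frac_severe proportion of severe patients, in `[0, 1]`.
#' @param artifact_burst `NULL`, or `c(count, magnitude)`: number and size
#'   (AS units) of square motion-artifact bursts confined to the first
#'   300 s of a session.
#' @param seed master RNG seed for the cohort.
#' @return object of class `"cohort_config"` (a validated list).
#' @export
#' @examples
#' cfg <- cohort_config(n_patients = 6, seed = 42)
#' cfg$hr_range_bpm
cohort_config <- function(n_patients = 45,
                          hr_range_bpm = c(70, 103),
                          duration_s = 2700,
                          osc_period_s = 180,
                          amp_severe = 0.5,
                          amp_mild = 0.05,
                          noise_sd = 0.1,
                          ar_coeff = 0.3,
                          baseline = 1.0,
                          dose_intercept_mcg = 185,
                          dose_slope_mcg_per_amp = 1000,
                          dose_noise_sd_mcg = 190,
                          frac_severe = 0.5,
                          artifact_burst = NULL,
                          seed = 1L) {
  if (n_patients < 2) stop_invalid("n_patients must be >= 2, got ", n_patients)
  if (length(hr_range_bpm) != 2 || any(hr_range_bpm <= 0) ||
      hr_range_bpm[1] >= hr_range_bpm[2])
    stop_invalid("hr_range_bpm must be positive bounds with low < high")
  if (osc_period_s <= 0) stop_invalid("osc_period_s must be > 0")
  if (frac_severe < 0 || frac_severe > 1)
    stop_invalid("frac_severe must be in [0, 1]")
  if (ar_coeff < 0 || ar_coeff >= 1) stop_invalid("ar_coeff must be in [0, 1)")
  if (!is.null(artifact_burst) && length(artifact_burst) != 2)
    stop_invalid("artifact_burst must be NULL or c(count, magnitude)")
  structure(list(
    n_patients = as.integer(n_patients), hr_range_bpm = hr_range_bpm,
    duration_s = duration_s, osc_period_s = osc_period_s,
    amp_severe = amp_severe, amp_mild = amp_mild, noise_sd = noise_sd,
    ar_coeff = ar_coeff, baseline = baseline,
    dose_intercept_mcg = dose_intercept_mcg,
    dose_slope_mcg_per_amp = dose_slope_mcg_per_amp,
    dose_noise_sd_mcg = dose_noise_sd_mcg, frac_severe = frac_severe,
    artifact_burst = artifact_burst, seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Construct a beat-by-beat AS series
#'
#' @param patient_id identifier.
#' @param times_s strictly increasing timestamps, seconds from session start.
#' @param values AS values (unitless), same length as `times_s`, all finite.
#' @return object of class `"beat_series"`.
#' @export
beat_series <- function(patient_id, times_s, values) {
  if (length(times_s) != length(values))
    stop_invalid("times_s and values must have equal length")
  if (length(times_s) < 2) stop_invalid("a beat series needs >= 2 beats")
  if (any(diff(times_s) <= 0)) stop_invalid("times_s must be strictly increasing")
  if (!all(is.finite(values))) stop_invalid("AS values must all be finite")
  structure(list(patient_id = patient_id, times_s = as.numeric(times_s),
                 values = as.numeric(values)),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> patient %s: %d beats over %.1f s (mean HR %.1f bpm)\n",
              x$patient_id, length(x$times_s), diff(range(x$times_s)),
              60 / mean(diff(x$times_s))))
  invisible(x)
}

#' Generate beat arrival times from a bounded random heart-rate walk
#'
#' Heart rate follows a reflecting AR(1) walk (step SD 1 bpm per beat,
#' mean-reverting to the mid-range) clipped by reflection into
#' `hr_range_bpm`; each inter-beat interval is `60 / hr` so every implied
#' instantaneous rate stays within the bounds.  With `low == high` the
#' beat train is strictly periodic.
#'
#' @param duration_s session length, seconds (> 0).
#' @param hr_range_bpm heart-rate bounds, bpm.
#' @param seed RNG seed.
#' @return numeric vector of strictly increasing timestamps starting at 0,
#'   covering `[0, duration_s]`.
#' @export
#' @examples
#' tt <- generate_beat_times(60, c(70, 103), seed = 1)
#' range(60 / diff(tt))
generate_beat_times <- function(duration_s, hr_range_bpm = c(70, 103), seed = 1L) {
  if (duration_s <= 0) stop_invalid("duration_s must be > 0, got ", duration_s)
  lo <- hr_range_bpm[1]; hi <- hr_range_bpm[2]
  if (lo > hi || lo <= 0) stop_invalid("invalid hr_range_bpm")
  if (lo == hi) return(seq(0, duration_s, by = 60 / lo))
  mid <- (lo + hi) / 2
  with_seed(seed, {
    n_max <- ceiling(duration_s * hi / 60) + 2L
    hr <- numeric(n_max)
    hr[1] <- runif(1, lo, hi)
    steps <- rnorm(n_max, 0, 1)
    for (i in 2:n_max) {
      h <- mid + 0.98 * (hr[i - 1] - mid) + steps[i]
      # reflect into [lo, hi]
      if (h < lo) h <- lo + (lo - h)
      if (h > hi) h <- hi - (h - hi)
      hr[i] <- min(hi, max(lo, h))
    }
    tt <- cumsum(c(0, 60 / hr[-n_max]))
    tt[tt <= duration_s]
  })
}

#' Generate an AS series on given beat times
#'
#' The value at beat i is
#' `baseline + A * sin(2 * pi * t_i / osc_period_s + phi) + AR(1) noise`,
#' with `A = amp_severe` or `amp_mild` according to `class_label` and a
#' uniformly drawn phase.  Optional square artifact bursts (10 s each) are
#' added at random onsets within the first 300 s.
#'
#' @param beat_times strictly increasing beat timestamps (seconds).
#' @param class_label `"severe"` or `"mild"`.
#' @param config a [cohort_config()].
#' @param seed RNG seed.
#' @param patient_id identifier for the resulting series.
#' @return a [beat_series()].
#' @export
generate_as_series <- function(beat_times, class_label, config, seed = 1L,
                               patient_id = "synthetic") {
  if (!class_label %in% c("severe", "mild"))
    stop_invalid("unknown class_label '", class_label, "'")
  if (any(diff(beat_times) <= 0)) stop_invalid("beat_times must be strictly increasing")
  amp <- if (class_label == "severe") config$amp_severe else config$amp_mild
  n <- length(beat_times)
  with_seed(seed, {
    phi <- runif(1, 0, 2 * pi)
    signal <- config$baseline + amp * sin(2 * pi * beat_times / config$osc_period_s + phi)
    noise <- numeric(n)
    if (config$noise_sd > 0) {
      rho <- config$ar_coeff
      innov_sd <- config$noise_sd * sqrt(1 - rho^2)
      noise[1] <- rnorm(1, 0, config$noise_sd)
      if (n > 1) {
        eps <- rnorm(n - 1, 0, innov_sd)
        for (i in 2:n) noise[i] <- rho * noise[i - 1] + eps[i - 1]
      }
    }
    values <- signal + noise
    if (!is.null(config$artifact_burst) && config$artifact_burst[1] >= 1) {
      n_burst <- round(config$artifact_burst[1])
      mag <- config$artifact_burst[2]
      onsets <- runif(n_burst, 0, max(0, min(300, max(beat_times)) - 10))
      for (on in onsets) {
        hit <- beat_times >= on & beat_times < on + 10
        values[hit] <- values[hit] + mag
      }
    }
    beat_series(patient_id, beat_times, values)
  })
}

#' Map a modulation amplitude to a phenylephrine dose
#'
#' Latent dose = `intercept + slope * amplitude + N(0, noise_sd)`, clipped
#' at zero and rounded to the nearest 100 mcg (the bolus size); zero doses
#' are legitimate — some patients need no vasopressor at all.
#'
#' @param amplitude modulation amplitude (>= 0).
#' @param config a [cohort_config()].
#' @param seed RNG seed.
#' @return dose in mcg (non-negative multiple of 100).
#' @export
#' @examples
#' cfg <- cohort_config(dose_noise_sd_mcg = 0, dose_intercept_mcg = 200,
#'                      dose_slope_mcg_per_amp = 600)
#' assign_dose(2, cfg)  # 1400
assign_dose <- function(amplitude, config, seed = 1L) {
  if (amplitude < 0) stop_invalid("amplitude must be >= 0")
  with_seed(seed, {
    latent <- config$dose_intercept_mcg +
      config$dose_slope_mcg_per_amp * amplitude +
      rnorm(1, 0, config$dose_noise_sd_mcg)
    100 * round(max(0, latent) / 100)
  })
}

#' Generate a full synthetic cohort
#'
#' Draws `n_patients` records: latent class (`round(frac_severe * n)`
#' severe patients via `floor(x + 0.5)`, the rest mild), beat train, AS
#' series, and linked dose.  Deterministic given the config seed; the
#' manifest records the latent class so downstream evaluation can use
#' known truth.
#'
#' @param config a [cohort_config()].
#' @return object of class `"cohort"`: list with `patients` (list of
#'   records, each holding `patient_id`, `series`, `dose_mcg`,
#'   `latent_class`, `amplitude`) and `manifest` (data frame), plus the
#'   generating config.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 4, duration_s = 600, seed = 7))
#' coh$manifest
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  n_severe <- floor(config$frac_severe * n + 0.5)
  classes <- c(rep("severe", n_severe), rep("mild", n - n_severe))
  seeds <- matrix(derive_seeds(config$seed, 3L * n), ncol = 3L)
  patients <- vector("list", n)
  for (i in seq_len(n)) {
    pid <- sprintf("P%02d", i)
    tt <- generate_beat_times(config$duration_s, config$hr_range_bpm,
                              seed = seeds[i, 1])
    ser <- generate_as_series(tt, classes[i], config, seed = seeds[i, 2],
                              patient_id = pid)
    amp <- if (classes[i] == "severe") config$amp_severe else config$amp_mild
    dose <- assign_dose(amp, config, seed = seeds[i, 3])
    patients[[i]] <- list(patient_id = pid, series = ser, dose_mcg = dose,
                          latent_class = classes[i], amplitude = amp)
  }
  manifest <- data.frame(
    patient_id = vapply(patients, `[[`, "", "patient_id"),
    dose_mcg = vapply(patients, `[[`, 0, "dose_mcg"),
    latent_class = vapply(patients, `[[`, "", "latent_class"),
    stringsAsFactors = FALSE
  )
  structure(list(patients = patients, manifest = manifest, config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d patients (%d severe / %d mild), dose mean %.0f mcg, SD %.0f mcg\n",
              nrow(x$manifest), sum(x$manifest$latent_class == "severe"),
              sum(x$manifest$latent_class == "mild"),
              mean(x$manifest$dose_mcg), stats::sd(x$manifest$dose_mcg)))
  invisible(x)
}

#' Write a cohort to per-patient beat CSVs plus a manifest CSV
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in cohort$patients) {
    utils::write.csv(
      data.frame(time_s = p$series$times_s, as_value = p$series$values),
      file.path(dir, paste0(p$patient_id, "_beats.csv")), row.names = FALSE)
  }
  manifest_path <- file.path(dir, "manifest.csv")
  utils::write.csv(cohort$manifest, manifest_path, row.names = FALSE)
  invisible(manifest_path)
}
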