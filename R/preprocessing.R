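#' Analysis-window specification
#'
#' @param skip_initial_s leading seconds to discard before the analysis
#'   window may start (default 300 s: motion artifacts from the patient
#'   settling in concentrate in the first five minutes).
#' @param window_length_s analysis span in seconds (default 2000 s,
#'   about 33 min).
#' @param manual_start_s optional explicit window start overriding
#'   automatic selection (the analogue of choosing the window by eye).
#' @return object of class `"window_spec"`.
#' @export
window_spec <- function(skip_initial_s = 300, window_length_s = 2000,
                        manual_start_s = NULL) {
  if (skip_initial_s < 0 || window_length_s <= 0 ||
      (!is.null(manual_start_s) && manual_start_s < 0))
    stop_invalid("window_spec fields must be non-negative with window_length_s > 0")
  structure(list(skip_initial_s = skip_initial_s,
                 window_length_s = window_length_s,
                 manual_start_s = manual_start_s),
            class = "window_spec")
}

#' Resample a beat series onto a uniform grid by cubic spline
#'
#' Beat-by-beat AS data arrive at the (non-uniform) heart rate; with heart
#' rates of 70--103 bpm the inter-beat variation lives in the 1--2 Hz
#' band, so a 10 Hz grid oversamples the highest embedded frequency five
#' times over.  A natural cubic spline through the beats is evaluated on
#' the half-open grid `start + k / rate_hz`, `k = 0 ... L * rate_hz - 1`,
#' giving exactly `window_length_s * rate_hz` samples (20,000 for the
#' default 2000 s window at 10 Hz).  The interpolant passes through every
#' beat sample exactly.
#'
#' @param series a [beat_series()].
#' @param rate_hz sampling rate, Hz (default 10).
#' @param window a [window_spec()]; the window start is
#'   `manual_start_s` if given, else `skip_initial_s`.
#' @return object of class `"uniform_series"`: `patient_id`, `start_s`,
#'   `rate_hz`, `values`.
#' @export
#' @examples
#' tt <- generate_beat_times(700, c(70, 103), seed = 1)
#' ser <- beat_series("P01", tt, sin(2 * pi * tt / 180))
#' u <- resample_to_uniform(ser, 10, window_spec(0, 60))
#' length(u$values)  # 600
resample_to_uniform <- function(series, rate_hz = 10, window = window_spec()) {
  stopifnot(inherits(series, "beat_series"), inherits(window, "window_spec"))
  if (rate_hz <= 0) stop_invalid("rate_hz must be > 0")
  start <- if (!is.null(window$manual_start_s)) window$manual_start_s else window$skip_initial_s
  end <- start + window$window_length_s
  tmin <- series$times_s[1]; tmax <- series$times_s[length(series$times_s)]
  if (tmin > start || tmax < end)
    stop_insufficient(sprintf(
      "series covers [%.1f, %.1f] s but window requires [%.1f, %.1f] s (short by %.1f s)",
      tmin, tmax, start, end, max(start - tmin, end - tmax)))
  in_win <- series$times_s >= start & series$times_s <= end
  if (sum(in_win) < 4)
    stop_insufficient("cubic spline resampling needs >= 4 beats in the window, have ",
                      sum(in_win))
  n_out <- round(window$window_length_s * rate_hz)
  grid <- start + (seq_len(n_out) - 1) / rate_hz
  f <- stats::splinefun(series$times_s, series$values, method = "natural")
  structure(list(patient_id = series$patient_id, start_s = start,
                 rate_hz = rate_hz, values = f(grid)),
            class = "uniform_series")
}

#' @export
print.uniform_series <- function(x, ...) {
  cat(sprintf("<uniform_series> patient %s: %d samples at %g Hz from t = %g s\n",
              x$patient_id, length(x$values), x$rate_hz, x$start_s))
  invisible(x)
}

#' Find an artifact-free analysis window start
#'
#' Automates the visual screening step: 30 s blocks on a `step_s` grid
#' are flagged as artifact when their median absolute deviation from the
#' series-wide median exceeds `k` times the series-wide MAD (deviation is
#' taken about the global median so a block shifted wholesale by an
#' artifact is still caught).  The returned start is the earliest time at
#' or after `skip_initial_s` whose full `window_length_s` span overlaps
#' no flagged block.  A `manual_start_s` in the window spec
#' short-circuits the search.  If no window qualifies the function falls
#' back to `skip_initial_s` with a warning, mirroring the practice of
#' rejecting such sessions by hand.
#'
#' @param series a [beat_series()].
#' @param window a [window_spec()].
#' @param k MAD multiplier flagging a 30 s block as artifact (default 5).
#' @param step_s candidate-start increment, seconds (default 10).
#' @return window start time in seconds.
#' @export
detect_artifact_free_start <- function(series, window = window_spec(),
                                       k = 5, step_s = 10) {
  stopifnot(inherits(series, "beat_series"), inherits(window, "window_spec"))
  if (!is.null(window$manual_start_s)) return(window$manual_start_s)
  tmax <- series$times_s[length(series$times_s)]
  if (tmax < window$skip_initial_s + window$window_length_s)
    stop_insufficient(sprintf(
      "series length %.1f s < skip (%.1f s) + window (%.1f s)",
      tmax, window$skip_initial_s, window$window_length_s))
  global_med <- stats::median(series$values)
  global_mad <- stats::mad(series$values)
  block_starts <- seq(0, tmax - 30, by = step_s)
  bad <- vapply(block_starts, function(t0) {
    v <- series$values[series$times_s >= t0 & series$times_s < t0 + 30]
    length(v) > 1 &&
      stats::median(abs(v - global_med)) > k * global_mad
  }, logical(1))
  bad_starts <- block_starts[bad]
  candidates <- seq(window$skip_initial_s, tmax - window$window_length_s, by = step_s)
  for (start in candidates) {
    overlaps <- any(bad_starts + 30 > start & bad_starts < start + window$window_length_s)
    if (!overlaps) return(start)
  }
  warning("no artifact-free window found; falling back to skip_initial_s = ",
          window$skip_initial_s)
  window$skip_initial_s
}
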