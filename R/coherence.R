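#' Normalized autocorrelation spectrum of a uniform series
#'
#' Computes the biased, mean-subtracted autocovariance
#' `c(k) = (1/N) * sum_i (x_i - xbar)(x_{i+k} - xbar)` for
#' `k = 0 ... N-1`, normalized to `r(k) = c(k) / c(0)`.  The biased
#' (divide-by-N) estimator keeps every coefficient in `[-1, 1]` and the
#' sequence positive semi-definite.  Computation is by FFT with zero
#' padding to at least `2N` (circular wrap-around removed), which matches
#' the direct O(N^2) sum to floating-point accuracy.
#'
#' For a signal that is self-coherent on some time scale, the spectrum
#' shows large-amplitude coefficients that change sign with lag; for
#' incoherent noise the coefficients collapse toward zero beyond small
#' lags.
#'
#' @param series a `uniform_series` (see [resample_to_uniform()]), or any
#'   list with `values`, `rate_hz` and `patient_id` fields.
#' @return object of class `"acf_spectrum"`: `patient_id`, `lag_s`
#'   (`0, 1/rate, ...`), `coeffs`, `rate_hz`, and `estimator = "biased"`.
#' @export
#' @examples
#' x <- sin(2 * pi * (0:1999) / 100)
#' sp <- autocorrelation_spectrum(list(patient_id = "x", rate_hz = 10, values = x))
#' sp$coeffs[1]  # 1
autocorrelation_spectrum <- function(series) {
  x <- series$values
  n <- length(x)
  if (n < 2) stop_invalid("autocorrelation needs a series of length >= 2")
  x <- x - mean(x)
  c0 <- sum(x^2) / n
  if (c0 == 0)
    stop_degenerate("constant series: autocorrelation (coherence) is undefined")
  m <- stats::nextn(2L * n, 2)
  xf <- stats::fft(c(x, numeric(m - n)))
  acov <- Re(stats::fft(xf * Conj(xf), inverse = TRUE))[seq_len(n)] / m / n
  structure(list(patient_id = series$patient_id,
                 lag_s = (seq_len(n) - 1) / series$rate_hz,
                 coeffs = acov / acov[1],
                 rate_hz = series$rate_hz,
                 estimator = "biased"),
            class = "acf_spectrum")
}

# Direct O(N^2) reference estimator; used as the in-package oracle for the
# FFT route on short series.
autocorrelation_brute <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  acov <- vapply(0:(n - 1), function(k) sum(x[seq_len(n - k)] * x[(k + 1):n]) / n,
                 numeric(1))
  acov / acov[1]
}

#' @export
print.acf_spectrum <- function(x, ...) {
  cat(sprintf("<acf_spectrum> patient %s: %d lags, 0 to %.1f s (%s estimator)\n",
              x$patient_id, length(x$lag_s), max(x$lag_s), x$estimator))
  invisible(x)
}

#' @export
plot.acf_spectrum <- function(x, ...) {
  graphics::plot(x$lag_s, x$coeffs, type = "l", xlab = "lag (s)",
                 ylab = "autocorrelation coefficient",
                 main = paste("AS autocorrelation spectrum,", x$patient_id), ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Absolute-area coherence statistic of an autocorrelation spectrum
#'
#' Integrates `|r(lag)|` by the rectangular rule over the half-open lag
#' interval `[lag_min_s, lag_max_s)` at the spectrum's resolution.  The
#' lower cutoff (default 100 s) discards short-range correlation so the
#' statistic isolates the slow coherent modulations; the default upper
#' end (2000 s) is the end of the spectrum for the standard window.
#' Units are seconds (unitless coefficients integrated over lag seconds);
#' the value is bounded by `lag_max_s - lag_min_s`.
#'
#' @param spectrum an [autocorrelation_spectrum()] result.
#' @param lag_min_s,lag_max_s integration bounds in seconds.
#' @return object of class `"coherence_metric"`: `patient_id`, `value`,
#'   `lag_min_s`, `lag_max_s`.
#' @export
coherence_metric <- function(spectrum, lag_min_s = 100, lag_max_s = 2000) {
  stopifnot(inherits(spectrum, "acf_spectrum"))
  step <- 1 / spectrum$rate_hz
  max_avail <- max(spectrum$lag_s) + step
  if (lag_min_s >= lag_max_s || lag_min_s < 0 || lag_max_s > max_avail + 1e-9)
    stop_invalid(sprintf(
      "lag range [%g, %g) invalid for a spectrum reaching %g s",
      lag_min_s, lag_max_s, max_avail))
  sel <- spectrum$lag_s >= lag_min_s & spectrum$lag_s < lag_max_s
  structure(list(patient_id = spectrum$patient_id,
                 value = sum(abs(spectrum$coeffs[sel])) * step,
                 lag_min_s = lag_min_s, lag_max_s = lag_max_s),
            class = "coherence_metric")
}

#' First zero-crossing of an autocorrelation spectrum
#'
#' The smallest positive lag at which the coefficients change sign, with
#' linear interpolation between the bracketing samples; coefficients of
#' coherent signals cross zero as components interfere.  If the spectrum
#' never changes sign the maximum lag is returned with `crossed = FALSE`.
#'
#' @param spectrum an [autocorrelation_spectrum()] result.
#' @return list with `lag_s` and logical `crossed`.
#' @export
first_zero_crossing <- function(spectrum) {
  stopifnot(inherits(spectrum, "acf_spectrum"))
  r <- spectrum$coeffs; lag <- spectrum$lag_s
  s <- sign(r)
  idx <- which(s[-1] * s[-length(s)] < 0)
  exact <- which(r == 0 & lag > 0)
  if (length(exact) && (!length(idx) || exact[1] <= idx[1]))
    return(list(lag_s = lag[exact[1]], crossed = TRUE))
  if (!length(idx)) return(list(lag_s = lag[length(lag)], crossed = FALSE))
  i <- idx[1]
  frac <- r[i] / (r[i] - r[i + 1])
  list(lag_s = lag[i] + frac * (lag[i + 1] - lag[i]), crossed = TRUE)
}

#' Coherence metrics for every patient of a cohort
#'
#' Convenience wrapper running resampling, autocorrelation and the
#' absolute-area statistic for each patient.
#'
#' @param cohort a [generate_cohort()] result or [load_cohort()] output.
#' @param window a [window_spec()].
#' @param rate_hz resampling rate, Hz.
#' @param lag_min_s,lag_max_s metric integration bounds, seconds.
#' @param keep_spectra if `TRUE`, attach the per-patient spectra (needed
#'   downstream by the neural-network stage).
#' @return data frame with `patient_id`, `dose_mcg`, `latent_class`,
#'   `metric`, `first_crossing_s`; spectra in `attr(, "spectra")` when
#'   requested.
#' @export
cohort_metrics <- function(cohort, window = window_spec(), rate_hz = 10,
                           lag_min_s = 100, lag_max_s = 2000,
                           keep_spectra = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  n <- length(cohort$patients)
  metric <- numeric(n); crossing <- numeric(n)
  spectra <- if (keep_spectra) vector("list", n) else NULL
  for (i in seq_len(n)) {
    u <- resample_to_uniform(cohort$patients[[i]]$series, rate_hz, window)
    sp <- autocorrelation_spectrum(u)
    metric[i] <- coherence_metric(sp, lag_min_s, lag_max_s)$value
    crossing[i] <- first_zero_crossing(sp)$lag_s
    if (keep_spectra) spectra[[i]] <- sp
  }
  out <- data.frame(patient_id = cohort$manifest$patient_id,
                    dose_mcg = cohort$manifest$dose_mcg,
                    latent_class = cohort$manifest$latent_class,
                    metric = metric, first_crossing_s = crossing,
                    stringsAsFactors = FALSE)
  if (keep_spectra) attr(out, "spectra") <- spectra
  out
}
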