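# Independent oracles and small fixtures shared across the suite.

# Brute-force pairwise AUC: mean over all (positive, negative) pairs of
# 1 if the positive scores higher, 1/2 on ties.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# Direct O(N^2) normalized biased autocorrelation (mean-subtracted).
brute_autocorr <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  acov <- vapply(0:(n - 1), function(k) sum(x[seq_len(n - k)] * x[(k + 1):n]) / n,
                 numeric(1))
  acov / acov[1]
}

# Wrap a plain numeric vector as the uniform-series input of the
# spectrum operation.
as_uniform <- function(values, rate_hz = 10, id = "test") {
  list(patient_id = id, rate_hz = rate_hz, values = values)
}

# Build an acf_spectrum object directly from coefficients (synthetic
# spectra for metric tests).
fake_spectrum <- function(coeffs, rate_hz = 10, id = "fake") {
  structure(list(patient_id = id, lag_s = (seq_along(coeffs) - 1) / rate_hz,
                 coeffs = coeffs, rate_hz = rate_hz, estimator = "biased"),
            class = "acf_spectrum")
}

# Two well-separated Gaussian clusters in 2D: linearly separable binary
# problem for network training tests.
separable_data <- function(n_per_class = 30, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(2 * n_per_class, -2, 0.5), n_per_class),
             matrix(rnorm(2 * n_per_class, 2, 0.5), n_per_class))
  list(x = x, y = rep(0:1, each = n_per_class))
}

# Central finite-difference gradient of the MSE loss for every parameter
# of a model; oracle for backpropagation.
fd_gradient <- function(model, x, y, eps = 1e-6) {
  loss_at <- function(m) mean((mlp_forward(m, x) - y)^2)
  num <- list(weights = model$weights, biases = model$biases)
  for (part in c("weights", "biases")) {
    for (l in seq_along(model[[part]])) {
      for (i in seq_along(model[[part]][[l]])) {
        up <- model; up[[part]][[l]][i] <- up[[part]][[l]][i] + eps
        dn <- model; dn[[part]][[l]][i] <- dn[[part]][[l]][i] - eps
        num[[part]][[l]][i] <- (loss_at(up) - loss_at(dn)) / (2 * eps)
      }
    }
  }
  num
}

# Worst relative discrepancy between backprop and finite differences.
# The denominator is floored at 1e-4: below that scale the central
# difference itself is dominated by floating-point cancellation (~1e-11
# absolute at eps = 1e-6), so a pure ratio would measure FD noise, not
# gradient error.
max_grad_rel_err <- function(model, x, y) {
  ana <- ascoh:::mlp_gradient(model, x, y)
  num <- fd_gradient(model, x, y)
  worst <- 0
  for (part in c("weights", "biases")) {
    for (l in seq_along(num[[part]])) {
      a <- ana[[part]][[l]]; b <- num[[part]][[l]]
      worst <- max(worst, abs(a - b) / pmax(1e-4, abs(b)))
    }
  }
  worst
}

# Small cohort config with short sessions, for fast pipeline tests.
tiny_cohort_config <- function(n_patients = 8, seed = 1, ...) {
  cohort_config(n_patients = n_patients, duration_s = 700, seed = seed, ...)
}
tiny_window <- function() window_spec(skip_initial_s = 60, window_length_s = 500)
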