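#' Block-average autocorrelation spectra into a feature matrix
#'
#' Each spectrum is reduced to `feature_len` equal-width lag bins by block
#' averaging, then every feature column is standardized to zero mean and
#' unit variance across the cohort (constant columns become zero).  The
#' centering/scaling parameters are attached so the transform can be
#' reused on new spectra.
#'
#' @param spectra list of [autocorrelation_spectrum()] results, all the
#'   same length.
#' @param feature_len number of lag bins (default 400; must not exceed
#'   the spectrum length).
#' @return numeric matrix, one row per spectrum, with attributes
#'   `center` and `scale`.
#' @export
prepare_inputs <- function(spectra, feature_len = 400) {
  lens <- vapply(spectra, function(s) length(s$coeffs), 0L)
  if (length(unique(lens)) != 1)
    stop_invalid("all spectra must have the same length")
  n_lag <- lens[1]
  if (feature_len > n_lag)
    stop_invalid("feature_len exceeds spectrum length")
  edges <- floor((0:feature_len) * n_lag / feature_len)
  feats <- t(vapply(spectra, function(s) {
    vapply(seq_len(feature_len),
           function(j) mean(s$coeffs[(edges[j] + 1):edges[j + 1]]), 0)
  }, numeric(feature_len)))
  center <- colMeans(feats)
  scale <- apply(feats, 2, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  out <- sweep(sweep(feats, 2, center), 2, scale, "/")
  rownames(out) <- vapply(spectra, function(s) as.character(s$patient_id), "")
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  out
}

#' Training configuration for the feed-forward network
#'
#' Defaults follow the training protocol the package reproduces: a single
#' hidden layer of 12 log-sigmoid nodes, learning rate 0.01, full-batch
#' gradient descent on mean-squared error, random 0.7/0.15/0.15
#' train/validation/test splits, early stopping after 6 epochs without
#' validation improvement, and 500-run ensembles.
#'
#' @param hidden_layers integer vector of hidden-node counts, one entry
#'   per hidden layer.
#' @param learning_rate gradient-descent step size (> 0).
#' @param max_epochs maximum full-batch epochs per run.
#' @param patience_epochs epochs without validation improvement before a
#'   run stops.
#' @param split_ratios train/validation/test proportions (positive,
#'   summing to 1).
#' @param n_runs ensemble size.
#' @param seed master seed for the ensemble.
#' @return object of class `"mlp_config"`.
#' @export
mlp_config <- function(hidden_layers = 12, learning_rate = 0.01,
                       max_epochs = 1000, patience_epochs = 6,
                       split_ratios = c(0.7, 0.15, 0.15),
                       n_runs = 500, seed = 1L) {
  if (any(hidden_layers < 1)) stop_invalid("hidden node counts must be >= 1")
  if (learning_rate <= 0) stop_invalid("learning_rate must be > 0")
  if (length(split_ratios) != 3 || any(split_ratios <= 0) ||
      abs(sum(split_ratios) - 1) > 1e-9)
    stop_invalid("split_ratios must be 3 positive numbers summing to 1")
  structure(list(hidden_layers = as.integer(hidden_layers),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience_epochs = as.integer(patience_epochs),
                 split_ratios = split_ratios,
                 n_runs = as.integer(n_runs), seed = as.integer(seed)),
            class = "mlp_config")
}

logsig <- function(z) 1 / (1 + exp(-z))

#' Initialize network parameters
#'
#' Weights drawn uniformly on `(-1/sqrt(fan_in), +1/sqrt(fan_in))`,
#' biases zero; deterministic given the seed.
#'
#' @param input_dim number of input features.
#' @param hidden_layers integer vector of hidden-node counts.
#' @param seed RNG seed.
#' @return object of class `"mlp_model"`: lists `weights` and `biases`
#'   (layer `l` weight matrix is `fan_in x fan_out`).
#' @export
init_mlp <- function(input_dim, hidden_layers = 12, seed = 1L) {
  dims <- c(input_dim, hidden_layers, 1L)
  with_seed(seed, {
    weights <- biases <- vector("list", length(dims) - 1L)
    for (l in seq_along(weights)) {
      fan_in <- dims[l]
      lim <- 1 / sqrt(fan_in)
      weights[[l]] <- matrix(runif(fan_in * dims[l + 1], -lim, lim),
                             nrow = fan_in)
      biases[[l]] <- numeric(dims[l + 1])
    }
    structure(list(weights = weights, biases = biases, dims = dims),
              class = "mlp_model")
  })
}

# Forward pass keeping activations (inputs included as activations[[1]]).
mlp_activations <- function(model, x) {
  a <- list(x)
  for (l in seq_along(model$weights)) {
    z <- a[[l]] %*% model$weights[[l]] +
      matrix(model$biases[[l]], nrow(x), ncol(model$weights[[l]]), byrow = TRUE)
    a[[l + 1]] <- logsig(z)
  }
  a
}

#' Forward pass of the network
#'
#' Layer-wise affine map followed by the log-sigmoid activation through
#' every hidden layer and the single output node; outputs are strictly
#' inside (0, 1).
#'
#' @param model an [init_mlp()] model.
#' @param x numeric matrix (rows = samples) or vector (one sample).
#' @return numeric vector of outputs in (0, 1).
#' @export
mlp_forward <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (!all(is.finite(x))) stop_invalid("non-finite network input")
  if (ncol(x) != model$dims[1])
    stop_invalid("input has ", ncol(x), " features; model expects ", model$dims[1])
  a <- mlp_activations(model, x)
  drop(a[[length(a)]])
}

# Backpropagation of the mean-squared-error loss over the full batch.
# Returns per-parameter gradients and the loss at the current parameters.
mlp_gradient <- function(model, x, y) {
  n <- nrow(x)
  a <- mlp_activations(model, x)
  L <- length(model$weights)
  out <- a[[L + 1]]
  loss <- mean((out - y)^2)
  delta <- 2 * (out - y) / n * out * (1 - out)
  gw <- gb <- vector("list", L)
  for (l in L:1) {
    gw[[l]] <- crossprod(a[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1)
      delta <- (delta %*% t(model$weights[[l]])) * a[[l]] * (1 - a[[l]])
  }
  list(weights = gw, biases = gb, loss = loss)
}

#' One full-batch gradient-descent step
#'
#' The batch size equals the sample size: a single step uses every
#' training sample.  Loss is the mean squared difference between the
#' continuous network output and the 0/1 target.
#'
#' @param model an [init_mlp()] model.
#' @param x feature matrix.
#' @param y 0/1 targets.
#' @param learning_rate step size.
#' @return list with the updated `model` and the `loss` before the update.
#' @export
train_step <- function(model, x, y, learning_rate) {
  if (!all(y %in% c(0, 1))) stop_invalid("targets must be 0/1")
  g <- mlp_gradient(model, x, y)
  for (l in seq_along(model$weights)) {
    model$weights[[l]] <- model$weights[[l]] - learning_rate * g$weights[[l]]
    model$biases[[l]] <- model$biases[[l]] - learning_rate * g$biases[[l]]
  }
  list(model = model, loss = g$loss)
}

# Random train/val/test split with floor rule: test and validation sizes
# are floored, the remainder trains (45 -> 33/6/6).  Retries until the
# training set holds both classes.
split_indices <- function(y, split_ratios, max_retries = 100) {
  n <- length(y)
  n_test <- floor(split_ratios[3] * n)
  n_val <- floor(split_ratios[2] * n)
  if (n_test < 1 || n_val < 1 || n - n_test - n_val < 1)
    stop_invalid("cohort too small for the requested split ratios")
  for (i in seq_len(max_retries)) {
    idx <- sample.int(n)
    test <- idx[seq_len(n_test)]
    val <- idx[n_test + seq_len(n_val)]
    train <- idx[-seq_len(n_test + n_val)]
    if (length(unique(y[train])) == 2)
      return(list(train = train, val = val, test = test))
  }
  stop(errorCondition("could not draw a training split containing both classes",
                      class = c("ascoh_degenerate_cohort", "error")))
}

#' Fit the feed-forward network with the single-run protocol
#'
#' One complete training run: random 0.7/0.15/0.15
#' train/validation/test split, full-batch gradient descent on MSE at the
#' configured learning rate, early stopping once validation MSE fails to
#' improve for `patience_epochs` epochs (the best-validation parameters
#' are restored), then evaluation on the held-out test set by mean
#' absolute classification error (`mean(|output - target|)`, in `[0, 1]`)
#' and by the AUC of the continuous outputs as scores.
#'
#' @param x feature matrix, rows = subjects.
#' @param y 0/1 targets (1 = severe).
#' @param config an [mlp_config()]; its `seed` drives the split and the
#'   weight initialization.
#' @param seed optional override of `config$seed` for this run.
#' @return object of class `"mlp_net"`: the fitted `model`, `split`,
#'   `epochs`, `train_loss` history, `best_val_mse`, `test_error`,
#'   `test_auc` (`NA` if the test split is single-class), plus the data
#'   and config used.
#' @export
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(40, -2), 20), matrix(rnorm(40, 2), 20))
#' fit <- mlp_net(x, rep(0:1, each = 20), mlp_config(hidden_layers = 4, seed = 3))
#' fit$test_error
mlp_net <- function(x, y, config = mlp_config(), seed = NULL) {
  stopifnot(inherits(config, "mlp_config"))
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (nrow(x) != length(y)) stop_invalid("x rows and y length differ")
  if (!all(y %in% c(0, 1))) stop_invalid("targets must be 0/1")
  run_seed <- if (is.null(seed)) config$seed else as.integer(seed)
  with_seed(run_seed, {
    sp <- split_indices(y, config$split_ratios)
    model <- init_mlp(ncol(x), config$hidden_layers,
                      seed = sample.int(.Machine$integer.max - 1L, 1))
    xtr <- x[sp$train, , drop = FALSE]; ytr <- y[sp$train]
    xva <- x[sp$val, , drop = FALSE];  yva <- y[sp$val]
    best_val <- Inf; best_model <- model; stall <- 0L
    train_loss <- numeric(0)
    epoch <- 0L
    while (epoch < config$max_epochs) {
      epoch <- epoch + 1L
      st <- train_step(model, xtr, ytr, config$learning_rate)
      model <- st$model
      train_loss[epoch] <- st$loss
      val_mse <- mean((mlp_forward(model, xva) - yva)^2)
      if (val_mse < best_val) {
        best_val <- val_mse
        best_model <- model
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$patience_epochs) break
      }
    }
    model <- best_model
    out_test <- mlp_forward(model, x[sp$test, , drop = FALSE])
    yte <- y[sp$test]
    test_auc <- if (length(unique(yte)) == 2)
      roc_curve(out_test, yte)$auc else NA_real_
    structure(list(model = model, split = sp, epochs = epoch,
                   train_loss = train_loss, best_val_mse = best_val,
                   test_error = mean(abs(out_test - yte)),
                   test_auc = test_auc, test_outputs = out_test,
                   test_targets = yte,
                   x = x, y = y, config = config, seed = run_seed),
              class = "mlp_net")
  })
}

#' @export
print.mlp_net <- function(x, ...) {
  cat(sprintf(
    "<mlp_net> %s network (%d inputs), %d epochs; test error %.3f, test AUC %s\n",
    paste(x$config$hidden_layers, collapse = "-"), x$model$dims[1], x$epochs,
    x$test_error,
    if (is.na(x$test_auc)) "NA (single-class test set)" else sprintf("%.3f", x$test_auc)))
  invisible(x)
}

#' @export
summary.mlp_net <- function(object, ...) {
  cat("Feed-forward network (log-sigmoid activations, MSE loss)\n")
  cat(sprintf("  architecture : %s\n",
              paste(object$model$dims, collapse = " -> ")))
  cat(sprintf("  parameters   : %d\n",
              sum(vapply(object$model$weights, length, 0L)) +
                sum(vapply(object$model$biases, length, 0L))))
  cat(sprintf("  split        : %d train / %d val / %d test\n",
              length(object$split$train), length(object$split$val),
              length(object$split$test)))
  cat(sprintf("  epochs       : %d (patience %d)\n", object$epochs,
              object$config$patience_epochs))
  cat(sprintf("  best val MSE : %.4f\n", object$best_val_mse))
  cat(sprintf("  test error   : %.4f\n", object$test_error))
  cat(sprintf("  test AUC     : %s\n",
              if (is.na(object$test_auc)) "NA" else sprintf("%.4f", object$test_auc)))
  invisible(object)
}

#' @export
coef.mlp_net <- function(object, ...) {
  list(weights = object$model$weights, biases = object$model$biases)
}

#' @export
predict.mlp_net <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$x
  mlp_forward(object$model, as.matrix(newdata))
}

#' @export
fitted.mlp_net <- function(object, ...) predict(object)

#' @export
residuals.mlp_net <- function(object, ...) object$y - fitted(object)

#' @export
plot.mlp_net <- function(x, ...) {
  graphics::plot(seq_along(x$train_loss), x$train_loss, type = "l",
                 xlab = "epoch", ylab = "training MSE",
                 main = "Training loss", ...)
  invisible(x)
}
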