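#' Multi-run training ensemble
#'
#' Because each training run is a gradient search in a high-dimensional
#' space, some runs end in poor local minima while others classify well;
#' single runs are therefore unreliable and performance is summarized
#' over an ensemble of independently seeded runs (500 in the reference
#' protocol).  Each run draws its own random split and weight
#' initialization from a child seed of the master seed.
#'
#' @param x feature matrix.
#' @param y 0/1 targets.
#' @param config an [mlp_config()]; `config$n_runs` runs are performed.
#' @return object of class `"run_ensemble"`: `runs` (data frame with
#'   seed, epochs, test_error, test_auc per run), aggregates
#'   `mean_error`, `error_sd`, `error_range`, `mean_auc` (mean of
#'   per-run test AUCs, degenerate runs excluded), `n_degenerate`, and
#'   `pooled_roc` (ROC over all test-set outputs concatenated across
#'   runs).
#' @export
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(40, -2), 20), matrix(rnorm(40, 2), 20))
#' ens <- run_ensemble(x, rep(0:1, each = 20),
#'                     mlp_config(hidden_layers = 4, n_runs = 5, seed = 2))
#' ens$mean_auc
run_ensemble <- function(x, y, config = mlp_config()) {
  stopifnot(inherits(config, "mlp_config"))
  seeds <- derive_seeds(config$seed, config$n_runs)
  runs <- vector("list", config$n_runs)
  pooled_out <- pooled_lab <- numeric(0)
  for (i in seq_len(config$n_runs)) {
    fit <- mlp_net(x, y, config, seed = seeds[i])
    runs[[i]] <- data.frame(seed = seeds[i], epochs = fit$epochs,
                            test_error = fit$test_error,
                            test_auc = fit$test_auc)
    pooled_out <- c(pooled_out, fit$test_outputs)
    pooled_lab <- c(pooled_lab, fit$test_targets)
  }
  runs <- do.call(rbind, runs)
  aucs <- runs$test_auc[!is.na(runs$test_auc)]
  pooled_roc <- if (length(unique(pooled_lab)) == 2)
    roc_curve(pooled_out, pooled_lab) else NULL
  structure(list(runs = runs,
                 mean_error = mean(runs$test_error),
                 error_sd = stats::sd(runs$test_error),
                 error_range = diff(range(runs$test_error)),
                 mean_auc = if (length(aucs)) mean(aucs) else NA_real_,
                 n_degenerate = sum(is.na(runs$test_auc)),
                 pooled_roc = pooled_roc,
                 config = config),
            class = "run_ensemble")
}

#' @export
print.run_ensemble <- function(x, ...) {
  cat(sprintf(
    "<run_ensemble> %d runs (%s network): mean error %.3f (SD %.3f, range %.3f), mean AUC %.3f%s\n",
    nrow(x$runs), paste(x$config$hidden_layers, collapse = "-"),
    x$mean_error, x$error_sd, x$error_range, x$mean_auc,
    if (x$n_degenerate) sprintf(", %d degenerate run(s)", x$n_degenerate) else ""))
  invisible(x)
}

#' Has the run ensemble converged?
#'
#' The reference protocol extends the number of runs until the standard
#' deviation of the run errors is about one tenth of the maximum error
#' range observed.  This check applies that rule with a 1.5x tolerance
#' factor: converged iff `SD(errors) <= 0.1 * range(errors) * 1.5`.
#'
#' @param ensemble a [run_ensemble()] result.
#' @return list with `converged`, `error_sd`, `error_range`; a warning is
#'   emitted when fewer than 10 runs back the estimate.
#' @export
check_run_convergence <- function(ensemble) {
  stopifnot(inherits(ensemble, "run_ensemble"))
  if (nrow(ensemble$runs) < 2) stop_invalid("need >= 2 runs to assess convergence")
  if (nrow(ensemble$runs) < 10)
    warning("convergence assessed on fewer than 10 runs; SD and range are unstable")
  list(converged = ensemble$error_sd <= 0.1 * ensemble$error_range * 1.5,
       error_sd = ensemble$error_sd,
       error_range = ensemble$error_range)
}

#' Node/depth/threshold architecture sweep
#'
#' Trains a run ensemble for every combination of hidden-layer width,
#' depth (the same width repeated), and dose threshold, and reports mean
#' error and mean AUC surfaces.  For depths beyond 1 the single-layer
#' minus deeper difference surfaces are included (negative error
#' difference means the deeper network errs more).  Cells whose ensemble
#' fails (e.g. a threshold collapsing the labels) are flagged, not fatal.
#'
#' @param x feature matrix.
#' @param dose_mcg per-subject cumulative doses used to form labels.
#' @param node_grid hidden-layer widths to try.
#' @param depth_grid numbers of hidden layers to try.
#' @param thresholds_mcg dose thresholds to try.
#' @param config an [mlp_config()]; `hidden_layers` is overridden per
#'   cell, the rest (runs, rates, seed) applies to every cell.
#' @return object of class `"sweep_surface"`: `cells` data frame
#'   (nodes, depth, threshold_mcg, mean_error, mean_auc, failed) and
#'   `differences` (single-layer minus deeper, by nodes x threshold and
#'   depth), plus the grids.
#' @export
architecture_sweep <- function(x, dose_mcg, node_grid = c(2, 4, 8, 12, 16),
                               depth_grid = 1, thresholds_mcg = 400,
                               config = mlp_config()) {
  if (!length(node_grid) || !length(depth_grid) || !length(thresholds_mcg))
    stop_invalid("node, depth and threshold grids must be nonempty")
  grid <- expand.grid(nodes = node_grid, depth = depth_grid,
                      threshold_mcg = thresholds_mcg)
  grid$mean_error <- NA_real_
  grid$mean_auc <- NA_real_
  grid$failed <- FALSE
  for (i in seq_len(nrow(grid))) {
    y <- label_by_dose(dose_mcg, grid$threshold_mcg[i])
    cell_cfg <- config
    cell_cfg$hidden_layers <- rep(as.integer(grid$nodes[i]), grid$depth[i])
    res <- tryCatch(run_ensemble(x, y, cell_cfg), error = function(e) e)
    if (inherits(res, "error")) {
      grid$failed[i] <- TRUE
      next
    }
    grid$mean_error[i] <- res$mean_error
    grid$mean_auc[i] <- res$mean_auc
  }
  differences <- NULL
  if (any(depth_grid > 1) && 1 %in% depth_grid) {
    single <- grid[grid$depth == 1, ]
    deeper <- grid[grid$depth > 1, ]
    key <- function(d) paste(d$nodes, d$threshold_mcg)
    m <- match(key(deeper), key(single))
    differences <- data.frame(
      nodes = deeper$nodes, depth = deeper$depth,
      threshold_mcg = deeper$threshold_mcg,
      error_diff = single$mean_error[m] - deeper$mean_error,
      auc_diff = single$mean_auc[m] - deeper$mean_auc)
  }
  structure(list(cells = grid, differences = differences,
                 node_grid = node_grid, depth_grid = depth_grid,
                 thresholds_mcg = thresholds_mcg, config = config),
            class = "sweep_surface")
}

#' @export
print.sweep_surface <- function(x, ...) {
  cat(sprintf("<sweep_surface> %d cells (%d nodes x %d depths x %d thresholds)\n",
              nrow(x$cells), length(x$node_grid), length(x$depth_grid),
              length(x$thresholds_mcg)))
  print(x$cells, row.names = FALSE)
  invisible(x)
}
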