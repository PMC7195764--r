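test_that("spectra are block-averaged then standardized into features", {
  # 3 spectra of length 20 -> 4 bins of 5: bins equal brute-force means
  set.seed(1)
  raw <- replicate(3, rnorm(20), simplify = FALSE)
  spectra <- lapply(seq_along(raw), function(i) fake_spectrum(raw[[i]], id = i))
  feats <- prepare_inputs(spectra, feature_len = 4)
  manual <- t(vapply(raw, function(r)
    vapply(1:4, function(j) mean(r[(5 * j - 4):(5 * j)]), 0), numeric(4)))
  manual_std <- scale(manual)
  expect_equal(unname(feats), unname(manual_std[, ]), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(feats, "center"), colMeans(manual))
  # feature_len equal to the spectrum length: identity up to standardization
  full <- prepare_inputs(spectra, feature_len = 20)
  expect_equal(unname(full), unname(scale(do.call(rbind, raw))[, ]),
               tolerance = 1e-12, ignore_attr = TRUE)
  # constant spectrum contributes constant bins (standardized to zero)
  flat <- prepare_inputs(list(fake_spectrum(rep(1, 20)),
                              fake_spectrum(rep(1, 20))), 4)
  expect_true(all(flat == 0))
  expect_error(prepare_inputs(list(fake_spectrum(1:5), fake_spectrum(1:6))),
               class = "ascoh_invalid_argument")
  expect_error(prepare_inputs(spectra, 21), class = "ascoh_invalid_argument")
})

test_that("initialization is deterministic, bounded, and symmetric at zero", {
  m1 <- init_mlp(10, c(5, 3), seed = 7)
  m2 <- init_mlp(10, c(5, 3), seed = 7)
  expect_identical(m1, m2)
  for (l in seq_along(m1$weights)) {
    expect_true(all(abs(m1$weights[[l]]) < 1 / sqrt(m1$dims[l])))
    expect_true(all(m1$biases[[l]] == 0))
  }
  # all-zero weights: every sigmoid sees 0 -> output 0.5
  m0 <- m1
  for (l in seq_along(m0$weights)) m0$weights[[l]][] <- 0
  expect_equal(mlp_forward(m0, matrix(rnorm(30), 3)), rep(0.5, 3))
})

test_that("the forward pass matches a hand computation and stays in (0,1)", {
  sig <- function(z) 1 / (1 + exp(-z))
  m <- init_mlp(2, 1, seed = 1)
  m$weights[[1]] <- matrix(c(0.3, -0.2), 2, 1)
  m$biases[[1]] <- 0.1
  m$weights[[2]] <- matrix(0.7, 1, 1)
  m$biases[[2]] <- -0.4
  x <- c(1.5, -2)
  hand <- sig(0.7 * sig(0.3 * 1.5 - 0.2 * -2 + 0.1) - 0.4)
  expect_equal(mlp_forward(m, x), hand, tolerance = 1e-12)

  mm <- init_mlp(4, c(6, 3), seed = 2)
  out <- mlp_forward(mm, matrix(rnorm(40), 10))
  expect_true(all(out > 0 & out < 1))
  expect_error(mlp_forward(mm, matrix(c(NA, rnorm(3)), 1)),
               class = "ascoh_invalid_argument")
})

test_that("permuting hidden nodes with matched weights leaves outputs unchanged", {
  m <- init_mlp(3, 5, seed = 3)
  perm <- c(4, 1, 5, 2, 3)
  mp <- m
  mp$weights[[1]] <- m$weights[[1]][, perm]
  mp$biases[[1]] <- m$biases[[1]][perm]
  mp$weights[[2]] <- m$weights[[2]][perm, , drop = FALSE]
  x <- matrix(rnorm(12), 4)
  expect_equal(mlp_forward(m, x), mlp_forward(mp, x), tolerance = 1e-12)
})

test_that("backprop gradients match central finite differences", {
  set.seed(4)
  worst <- 0
  for (i in 1:15) {
    d <- sample(2:5, 1)
    depth <- sample(1:2, 1)
    hidden <- sample(2:4, depth, replace = TRUE)
    x <- matrix(rnorm(6 * d), 6)
    y <- c(0, 1, sample(0:1, 4, replace = TRUE))
    m <- init_mlp(d, hidden, seed = i)
    worst <- max(worst, max_grad_rel_err(m, x, y))
  }
  expect_lt(worst, 1e-5)
})

test_that("a training step descends and a zero learning rate is a null step", {
  set.seed(5)
  x <- matrix(rnorm(20), 10)
  y <- rep(0:1, 5)
  m <- init_mlp(2, 4, seed = 6)
  expect_identical(train_step(m, x, y, 0)$model, m)
  # with a small step the full-batch loss is non-increasing over 10 steps
  losses <- numeric(11)
  cur <- m
  for (i in 1:11) {
    st <- train_step(cur, x, y, 0.001)
    losses[i] <- st$loss
    cur <- st$model
  }
  expect_true(all(diff(losses) <= 1e-12))
  expect_error(train_step(m, x, c(rep(0.5, 10)), 0.1),
               class = "ascoh_invalid_argument")
})

test_that("single runs split 45 subjects 33/6/6 and are seed-deterministic", {
  set.seed(7)
  x <- matrix(rnorm(45 * 4), 45)
  y <- c(rep(0, 22), rep(1, 23))
  cfg <- mlp_config(hidden_layers = 4, max_epochs = 50)
  fit <- mlp_net(x, y, cfg, seed = 11)
  expect_length(fit$split$train, 33)
  expect_length(fit$split$val, 6)
  expect_length(fit$split$test, 6)
  fit2 <- mlp_net(x, y, cfg, seed = 11)
  expect_identical(fit$model, fit2$model)
  expect_identical(fit$test_error, fit2$test_error)
  expect_true(fit$test_error >= 0 && fit$test_error <= 1)
  # residuals/predict/coef surface
  expect_equal(residuals(fit), y - predict(fit))
  expect_named(coef(fit), c("weights", "biases"))
})

test_that("separable two-feature data trains to a small test error", {
  dat <- separable_data(30, seed = 8)
  cfg <- mlp_config(hidden_layers = 12, learning_rate = 0.5)
  errs <- vapply(1:3, function(s) mlp_net(dat$x, dat$y, cfg, seed = s)$test_error, 0)
  expect_true(all(errs < 0.05))
})

test_that("ensembles aggregate runs reproducibly", {
  dat <- separable_data(15, seed = 9)
  cfg1 <- mlp_config(hidden_layers = 3, learning_rate = 0.5, max_epochs = 60,
                     n_runs = 1, seed = 21)
  ens1 <- run_ensemble(dat$x, dat$y, cfg1)
  expect_equal(ens1$mean_error, ens1$runs$test_error[1])
  expect_equal(ens1$error_range, 0)
  cfg5 <- mlp_config(hidden_layers = 3, learning_rate = 0.5, max_epochs = 60,
                     n_runs = 5, seed = 22)
  ens5a <- run_ensemble(dat$x, dat$y, cfg5)
  ens5b <- run_ensemble(dat$x, dat$y, cfg5)
  expect_identical(ens5a$runs, ens5b$runs)
  expect_true(all(ens5a$runs$test_error >= 0 & ens5a$runs$test_error <= 1))
  expect_s3_class(ens5a$pooled_roc, "roc_result")
})

test_that("run convergence follows the SD-to-range rule", {
  fake_ens <- function(errors) {
    structure(list(runs = data.frame(seed = seq_along(errors), epochs = 1,
                                     test_error = errors, test_auc = 0.9),
                   error_sd = sd(errors), error_range = diff(range(errors))),
              class = "run_ensemble")
  }
  # identical errors: SD 0 <= 0 -> converged
  expect_true(check_run_convergence(fake_ens(rep(0.2, 20)))$converged)
  # uniform errors on [0,1]: SD ~ 0.289 vs 0.15 * range ~ 1 -> not converged
  set.seed(10)
  expect_false(check_run_convergence(fake_ens(runif(200)))$converged)
  expect_warning(check_run_convergence(fake_ens(c(0.1, 0.1))), "fewer than 10")
  expect_error(check_run_convergence(fake_ens(0.1)), class = "ascoh_invalid_argument")
})

test_that("the architecture sweep reduces to a single ensemble on a 1x1 grid", {
  dat <- separable_data(15, seed = 12)
  dose <- ifelse(dat$y == 1, 800, 100)
  cfg <- mlp_config(hidden_layers = 99, learning_rate = 0.5, max_epochs = 60,
                    n_runs = 3, seed = 30)
  sw <- architecture_sweep(dat$x, dose, node_grid = 12, depth_grid = 1,
                           thresholds_mcg = 400, config = cfg)
  cfg12 <- cfg; cfg12$hidden_layers <- 12L
  ref <- run_ensemble(dat$x, label_by_dose(dose, 400), cfg12)
  expect_equal(sw$cells$mean_error, ref$mean_error)
  expect_equal(sw$cells$mean_auc, ref$mean_auc)
  expect_null(sw$differences)
})

test_that("difference surfaces are single-layer minus deeper, cell by cell", {
  dat <- separable_data(15, seed = 13)
  dose <- ifelse(dat$y == 1, 800, 100)
  cfg <- mlp_config(learning_rate = 0.5, max_epochs = 40, n_runs = 2, seed = 31)
  sw <- architecture_sweep(dat$x, dose, node_grid = c(2, 4), depth_grid = c(1, 2),
                           thresholds_mcg = c(300, 500), config = cfg)
  expect_equal(nrow(sw$cells), 8)
  expect_false(any(sw$cells$failed))
  for (j in seq_len(nrow(sw$differences))) {
    d <- sw$differences[j, ]
    single <- sw$cells[sw$cells$depth == 1 & sw$cells$nodes == d$nodes &
                         sw$cells$threshold_mcg == d$threshold_mcg, ]
    deeper <- sw$cells[sw$cells$depth == d$depth & sw$cells$nodes == d$nodes &
                         sw$cells$threshold_mcg == d$threshold_mcg, ]
    expect_equal(d$error_diff, single$mean_error - deeper$mean_error)
    expect_equal(d$auc_diff, single$mean_auc - deeper$mean_auc)
  }
  # a threshold collapsing the labels flags the cell instead of failing
  sw2 <- suppressWarnings(
    architecture_sweep(dat$x, dose, node_grid = 2, depth_grid = 1,
                       thresholds_mcg = c(400, 5000), config = cfg))
  expect_true(sw2$cells$failed[sw2$cells$threshold_mcg == 5000])
})
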