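test_that("dose labelling uses a strict > threshold rule", {
  expect_equal(label_by_dose(c(200, 1400), 400), c(0L, 1L))
  expect_equal(label_by_dose(c(0, 100, 700), 0), c(0L, 1L, 1L))
  expect_equal(label_by_dose(400, 400), 0L)  # dose at threshold: mild
  expect_error(label_by_dose(100, -1), class = "ascoh_invalid_argument")
})

test_that("rank AUC matches brute-force pairwise comparison and handles ties", {
  expect_equal(roc_curve(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_curve(c(3, 1, 2, 4), c(0, 1, 0, 1))$auc, 0.5)
  expect_equal(roc_curve(rep(2, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)
  set.seed(1)
  for (i in 1:25) {
    n <- sample(6:30, 1)
    scores <- sample(1:10, n, replace = TRUE)      # ties likely
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    r <- roc_curve(scores, labels)
    expect_equal(r$auc, brute_auc(scores, labels))
  }
  expect_error(roc_curve(1:4, rep(1, 4)), class = "ascoh_degenerate_labels")
})

test_that("curve trapezoid equals rank AUC on tie-free data, and relabeling flips AUC", {
  set.seed(2)
  for (i in 1:10) {
    n <- sample(8:40, 1)
    scores <- rnorm(n)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    r <- roc_curve(scores, labels)
    trap <- sum(diff(r$fpr) * (head(r$tpr, -1) + tail(r$tpr, -1)) / 2)
    expect_equal(trap, r$auc, tolerance = 1e-9)
    expect_equal(roc_curve(scores, 1 - labels)$auc, 1 - r$auc, tolerance = 1e-9)
    # curve runs monotonically from (0,0) to (1,1)
    expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
    expect_equal(c(r$fpr[length(r$fpr)], r$tpr[length(r$tpr)]), c(1, 1))
    expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
  }
})

test_that("the Youden optimum is the maximum ROC-diagonal vertical distance", {
  set.seed(3)
  for (i in 1:10) {
    scores <- rnorm(30)
    labels <- c(0, 1, sample(0:1, 28, replace = TRUE))
    r <- roc_curve(scores, labels)
    expect_equal(r$youden_j, max(r$tpr - r$fpr), tolerance = 1e-12)
    y <- youden_optimum(r)
    expect_equal(y$j, y$sensitivity + y$specificity - 1, tolerance = 1e-12)
  }
  # perfect classifier attains J = 1
  expect_equal(roc_curve(1:10, rep(0:1, each = 5))$youden_j, 1)
  # random scores vs labels at large n: J near 0
  set.seed(4)
  r0 <- roc_curve(rnorm(2000), sample(0:1, 2000, replace = TRUE))
  expect_lt(r0$youden_j, 0.1)
})

test_that("dose-threshold sweep finds the separating gap of a step-function cohort", {
  # severe patients dosed >= 600, mild <= 400: any threshold in the gap
  # labels identically, and the metric separates perfectly there
  # within-class metric order is scrambled so sub- and super-gap
  # thresholds cannot also classify perfectly
  metrics <- data.frame(
    metric = c(13, 10, 11, 12, 35, 30, 31, 32),
    dose_mcg = c(100, 200, 300, 400, 600, 700, 800, 900))
  sw <- dose_threshold_sweep(metrics, seq(100, 800, by = 100))
  expect_s3_class(sw, "dose_sweep")
  gap <- sw$table$threshold_mcg >= 400 & sw$table$threshold_mcg < 600
  expect_true(all(sw$table$auc[gap] == 1))
  expect_true(all(sw$table$auc[!gap] < 1))
  expect_true(sw$best_auc_threshold >= 400 && sw$best_auc_threshold < 600)
  expect_error(dose_threshold_sweep(metrics, 400), class = "ascoh_invalid_argument")
  # a threshold beyond every dose collapses to one class -> skipped with warning
  expect_warning(sw2 <- dose_threshold_sweep(metrics, c(400, 2000)),
                 "single class")
  expect_equal(nrow(sw2$table), 1)
})

test_that("baseline correlations reproduce degenerate-covariate handling", {
  set.seed(5)
  n <- 45
  records <- data.frame(
    dose_mcg = sample(seq(0, 1200, by = 100), n, replace = TRUE),
    pre_op_systole = rnorm(n, 129, 19),
    copd = rep(0, n))
  records$self <- records$dose_mcg
  tab <- baseline_correlations(records,
                               c("pre_op_systole", "copd", "self"))
  expect_equal(tab$r[tab$covariate == "self"], 1)
  expect_equal(tab$note[tab$covariate == "copd"], "no positive patients")
  expect_true(is.na(tab$r[tab$covariate == "copd"]))
  expect_true(tab$p[tab$covariate == "pre_op_systole"] >= 0 &&
                tab$p[tab$covariate == "pre_op_systole"] <= 1)
})

test_that("covariates independent of dose rarely show |r| > 0.3 at n = 45", {
  hits <- vapply(1:100, function(seed) {
    set.seed(seed)
    rec <- data.frame(dose_mcg = 100 * rpois(45, 4.6), cov = rnorm(45))
    abs(baseline_correlations(rec, "cov")$r) <= 0.3
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("AUC sample size reproduces the printed minimum and behaves monotonically", {
  n <- auc_sample_size(0.85, 0.025, alpha = 0.01, power = 0.95,
                       allocation_ratio = 1)
  expect_gte(n, 33)
  # independent re-derivation of the test-framing formula
  v <- function(A) (A / (2 - A) - A^2) + (2 * A^2 / (1 + A) - A^2)
  n_pos <- (qnorm(0.99) * sqrt(v(0.5)) + qnorm(0.95) * sqrt(v(0.85)))^2 / 0.35^2
  expect_equal(as.integer(n), as.integer(ceiling(2 * n_pos)))
  # precision framing: doubling the margin strictly shrinks the answer
  n1 <- auc_sample_size(0.85, 0.025, method = "precision")
  n2 <- auc_sample_size(0.85, 0.05, method = "precision")
  expect_lt(n2, n1)
  # higher power needs more subjects
  expect_gt(auc_sample_size(0.85, 0.025, power = 0.99),
            auc_sample_size(0.85, 0.025, power = 0.8))
  expect_error(auc_sample_size(0.4, 0.025), class = "ascoh_invalid_argument")
  expect_error(auc_sample_size(0.85, 0), class = "ascoh_invalid_argument")
  expect_error(auc_sample_size(0.85, 0.025, alpha = 0.7),
               class = "ascoh_invalid_argument")
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(6)
  for (i in 1:5) {
    scores <- rnorm(40)
    labels <- c(0, 1, sample(0:1, 38, replace = TRUE))
    ref <- suppressMessages(as.numeric(pROC::auc(labels, scores,
                                                 direction = "<", quiet = TRUE)))
    expect_equal(roc_curve(scores, labels)$auc, ref, tolerance = 1e-12)
  }
})
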