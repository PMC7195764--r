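#' Label patients as severe by a phenylephrine-dose threshold
#'
#' Severe (label 1) means cumulative dose strictly greater than the
#' threshold; a dose exactly at the threshold is mild (the "<= t vs > t"
#' split).
#'
#' @param dose_mcg numeric vector of cumulative doses (mcg).
#' @param dose_threshold_mcg threshold in mcg (>= 0).
#' @return integer vector of 0/1 labels.
#' @export
#' @examples
#' label_by_dose(c(200, 1400), 400)  # 0 1
label_by_dose <- function(dose_mcg, dose_threshold_mcg) {
  if (dose_threshold_mcg < 0) stop_invalid("dose threshold must be >= 0")
  as.integer(dose_mcg > dose_threshold_mcg)
}

#' ROC curve, AUC and Youden optimum for a continuous score
#'
#' The score orientation is fixed a priori: higher scores predict the
#' positive (severe) class.  AUC is the rank (Mann-Whitney) statistic
#' with ties credited 1/2; the curve sweeps every distinct score cutoff
#' (predict positive when score > cutoff), so with tie-free scores the
#' trapezoid of the curve equals the rank AUC.  The Youden index
#' `J = sensitivity + specificity - 1` is maximized over curve points;
#' ties are broken toward higher specificity (lower false-positive rate).
#'
#' @param scores numeric scores, one per subject.
#' @param labels 0/1 labels (1 = severe); both classes must be present.
#' @param dose_threshold_mcg optional annotation: the dose threshold that
#'   produced `labels`.
#' @return object of class `"roc_result"`: `fpr`, `tpr`, `cutoffs`,
#'   `auc`, `youden_j`, `optimal_cutoff`, `sensitivity`, `specificity`,
#'   `n_pos`, `n_neg`, `dose_threshold_mcg`.
#' @export
#' @examples
#' r <- roc_curve(c(1, 2, 3, 4), c(0, 0, 1, 1))
#' r$auc  # 1
roc_curve <- function(scores, labels, dose_threshold_mcg = NA_real_) {
  if (length(scores) != length(labels))
    stop_invalid("scores and labels must have equal length")
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop(errorCondition(
      "both classes must be present to form a ROC curve",
      class = c("ascoh_degenerate_labels", "error")))
  # rank/Mann-Whitney AUC, ties half-credited
  r <- rank(scores)
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  # curve over all distinct cutoffs, descending: positive iff score >= cutoff,
  # so the curve runs from (0,0) at +Inf to (1,1) at the minimum score
  cuts <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(cuts, function(ct) sum(scores >= ct & labels == 1L) / n_pos, 0)
  fpr <- vapply(cuts, function(ct) sum(scores >= ct & labels == 0L) / n_neg, 0)
  j <- tpr - fpr
  best <- which(j == max(j))
  best <- best[which.min(fpr[best])]          # ties -> higher specificity
  structure(list(fpr = fpr, tpr = tpr, cutoffs = cuts, auc = auc,
                 youden_j = j[best], optimal_cutoff = cuts[best],
                 sensitivity = tpr[best], specificity = 1 - fpr[best],
                 n_pos = n_pos, n_neg = n_neg,
                 dose_threshold_mcg = dose_threshold_mcg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result> AUC = %.3f (n+ = %d, n- = %d); Youden J = %.3f at cutoff %.4g (sens %.2f, spec %.2f)\n",
    x$auc, x$n_pos, x$n_neg, x$youden_j, x$optimal_cutoff,
    x$sensitivity, x$specificity))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "false-positive rate", ylab = "true-positive rate",
                 main = sprintf("ROC (AUC = %.2f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Youden optimum of a ROC result
#'
#' @param roc a [roc_curve()] result.
#' @return list with `cutoff`, `j`, `sensitivity`, `specificity`.
#' @export
youden_optimum <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  list(cutoff = roc$optimal_cutoff, j = roc$youden_j,
       sensitivity = roc$sensitivity, specificity = roc$specificity)
}

#' ROC analysis across a grid of dose thresholds
#'
#' Repeats the ROC/Youden analysis for each dosage threshold, reporting
#' which thresholds maximize AUC and the Youden index.  A threshold whose
#' labelling collapses to a single class is skipped with a warning.
#'
#' @param metrics data frame with `metric` and `dose_mcg` columns (e.g.
#'   from [cohort_metrics()]).
#' @param thresholds_mcg numeric vector of >= 2 dose thresholds.
#' @return object of class `"dose_sweep"`: `table` (data frame with
#'   threshold, auc, youden_j, sensitivity, specificity, n_pos, n_neg),
#'   `rocs` (list of `roc_result`), `best_auc_threshold`,
#'   `best_youden_threshold`.
#' @export
dose_threshold_sweep <- function(metrics, thresholds_mcg = seq(100, 800, by = 50)) {
  if (length(thresholds_mcg) < 2)
    stop_invalid("need >= 2 thresholds for a sweep")
  rows <- list(); rocs <- list()
  for (th in thresholds_mcg) {
    lab <- label_by_dose(metrics$dose_mcg, th)
    if (length(unique(lab)) < 2) {
      warning(sprintf("threshold %g mcg yields a single class; skipped", th))
      next
    }
    roc <- roc_curve(metrics$metric, lab, dose_threshold_mcg = th)
    rocs[[as.character(th)]] <- roc
    rows[[as.character(th)]] <- data.frame(
      threshold_mcg = th, auc = roc$auc, youden_j = roc$youden_j,
      sensitivity = roc$sensitivity, specificity = roc$specificity,
      n_pos = roc$n_pos, n_neg = roc$n_neg)
  }
  if (!length(rows)) stop_invalid("every threshold yielded a single class")
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, rocs = rocs,
                 best_auc_threshold = tab$threshold_mcg[which.max(tab$auc)],
                 best_youden_threshold = tab$threshold_mcg[which.max(tab$youden_j)]),
            class = "dose_sweep")
}

#' @export
print.dose_sweep <- function(x, ...) {
  cat(sprintf("<dose_sweep> %d thresholds; AUC max at %g mcg, Youden max at %g mcg\n",
              nrow(x$table), x$best_auc_threshold, x$best_youden_threshold))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Correlate baseline covariates with phenylephrine dose
#'
#' Pearson correlation (point-biserial for 0/1 covariates) of each
#' covariate with cumulative dose, with a two-sided t-approximation
#' p-value and no multiplicity correction.  Covariates with no variance
#' (e.g. a comorbidity with no positive patients) are flagged instead of
#' correlated.
#'
#' @param records data frame with a `dose_mcg` column and one column per
#'   covariate.
#' @param covariates character vector of covariate column names; defaults
#'   to every column except `patient_id`, `dose_mcg`, `latent_class`,
#'   `metric`, `first_crossing_s`.
#' @return data frame with `covariate`, `r`, `p`, `note`.
#' @export
baseline_correlations <- function(records, covariates = NULL) {
  if (is.null(covariates))
    covariates <- setdiff(names(records),
                          c("patient_id", "dose_mcg", "latent_class",
                            "metric", "first_crossing_s"))
  if (!length(covariates)) stop_invalid("no covariate columns found")
  out <- data.frame(covariate = covariates, r = NA_real_, p = NA_real_,
                    note = "", stringsAsFactors = FALSE)
  for (i in seq_along(covariates)) {
    v <- records[[covariates[i]]]
    if (length(unique(v)) < 2) {
      out$note[i] <- if (all(v == 0)) "no positive patients" else "no variance"
      next
    }
    ct <- stats::cor.test(v, records$dose_mcg, method = "pearson")
    out$r[i] <- unname(ct$estimate)
    out$p[i] <- ct$p.value
  }
  out
}

#' Minimum sample size for an AUC study
#'
#' Normal-approximation sample size using the Hanley-McNeil AUC variance
#' in its exponential-distribution form, `Q1 = A / (2 - A)`,
#' `Q2 = 2 A^2 / (1 + A)`, with per-positive-subject variance
#' `v(A) = (Q1 - A^2) + (Q2 - A^2) / allocation_ratio`.
#'
#' Two framings are available:
#' \describe{
#'   \item{`"test"` (default)}{one-sided level-`alpha` test of
#'     `H0: AUC = null_auc` (default 0.5) against the target AUC at the
#'     requested power:
#'     `n_pos = (z_{1-alpha} sqrt(v(null)) + z_{power} sqrt(v(target)))^2 /
#'     (target - null)^2`, total `ceiling(n_pos * (1 + 1/ratio))`.  The
#'     `margin` argument is not used by this framing.}
#'   \item{`"precision"`}{sample size making a two-sided `1 - alpha`
#'     confidence interval for the AUC no wider than `margin` on each
#'     side: `n_pos = z_{1-alpha/2}^2 v(target) / margin^2`.}
#' }
#'
#' @param target_auc anticipated AUC, in (0.5, 1).
#' @param margin half-width of the AUC estimate (used by the precision
#'   framing).
#' @param alpha type-I error rate.
#' @param power desired power (test framing).
#' @param allocation_ratio ratio of negative to positive subjects.
#' @param null_auc null AUC for the test framing.
#' @param method `"test"` or `"precision"`.
#' @return minimum total number of subjects (integer).
#' @export
#' @examples
#' auc_sample_size(0.85, 0.025, alpha = 0.01, power = 0.95)  # 33
auc_sample_size <- function(target_auc, margin, alpha = 0.01, power = 0.95,
                            allocation_ratio = 1, null_auc = 0.5,
                            method = c("test", "precision")) {
  method <- match.arg(method)
  if (target_auc <= 0.5 || target_auc >= 1)
    stop_invalid("target_auc must be in (0.5, 1)")
  if (margin <= 0) stop_invalid("margin must be > 0")
  if (alpha <= 0 || alpha >= 0.5 || power <= 0.5 || power >= 1)
    stop_invalid("need 0 < alpha < 0.5 and 0.5 < power < 1")
  if (allocation_ratio <= 0) stop_invalid("allocation_ratio must be > 0")
  v <- function(A) {
    q1 <- A / (2 - A); q2 <- 2 * A^2 / (1 + A)
    (q1 - A^2) + (q2 - A^2) / allocation_ratio
  }
  n_pos <- if (method == "test") {
    if (null_auc >= target_auc) stop_invalid("null_auc must be < target_auc")
    (stats::qnorm(1 - alpha) * sqrt(v(null_auc)) +
       stats::qnorm(power) * sqrt(v(target_auc)))^2 / (target_auc - null_auc)^2
  } else {
    stats::qnorm(1 - alpha / 2)^2 * v(target_auc) / margin^2
  }
  n <- as.integer(ceiling(n_pos * (1 + 1 / allocation_ratio)))
  attr(n, "method") <- method
  attr(n, "variance_form") <- "Hanley-McNeil exponential (Q1, Q2)"
  n
}
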