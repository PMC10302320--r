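# Evaluation suite: regression metrics, interpretability ROC and balanced
# accuracy, feature-subgroup ROCs, repeat-threshold curves and the
# false-decision correlation.

#' Regression agreement metrics
#'
#' Root-mean-square error, mean absolute error and Pearson correlation
#' between reference labels and predicted quality values.
#'
#' @param y_true,y_pred Equal-length numeric vectors (>= 2).
#' @return Named vector `rmse`, `mae`, `rho`.
#' @export
regression_metrics <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2)
  if (stats::sd(y_true) == 0 || stats::sd(y_pred) == 0)
    stop("degenerate input: correlation undefined for constant vector",
         call. = FALSE)
  c(rmse = sqrt(mean((y_pred - y_true)^2)),
    mae = mean(abs(y_pred - y_true)),
    rho = stats::cor(y_true, y_pred))
}

#' ROC for the interpretable-vs-uninterpretable decision
#'
#' The positive class is *uninterpretable* (label 3); higher quality-index
#' scores indicate worse quality. Sensitivities/specificities over all score
#' thresholds with trapezoidal AUC.
#'
#' @param scores Numeric quality scores.
#' @param labels Ordinal labels 0-3 (or logical/0-1 uninterpretable flags).
#' @return List of class `aisqa_roc`: `fpr`, `tpr`, `thresholds`, `auc`.
#' @export
interpretability_roc <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else round(labels) == 3
  if (length(unique(pos)) < 2)
    stop("both classes must be present", call. = FALSE)
  r <- pROC::roc(response = factor(pos, levels = c(FALSE, TRUE)),
                 predictor = scores, direction = "<", quiet = TRUE)
  structure(list(fpr = 1 - r$specificities, tpr = r$sensitivities,
                 thresholds = r$thresholds,
                 auc = as.numeric(pROC::auc(r)), roc_obj = r),
            class = "aisqa_roc")
}

#' Balanced accuracy at a threshold
#'
#' `(sensitivity + specificity) / 2` for the uninterpretable decision at a
#' given score threshold; when no threshold is given, the Youden-optimal
#' threshold of the ROC is used (and returned as an attribute).
#'
#' @param scores,labels As in [interpretability_roc()].
#' @param threshold Optional score threshold (predict positive when
#'   `score > threshold`).
#' @return Balanced accuracy in `[0, 1]` with attribute `threshold`.
#' @export
balanced_accuracy_at <- function(scores, labels, threshold = NULL) {
  pos <- if (is.logical(labels)) labels else round(labels) == 3
  if (length(unique(pos)) < 2)
    stop("both classes must be present", call. = FALSE)
  if (is.null(threshold)) {
    roc <- interpretability_roc(scores, labels)
    j <- roc$tpr - roc$fpr
    threshold <- roc$thresholds[which.max(j)]
  }
  pred <- scores > threshold
  sens <- mean(pred[pos]); spec <- mean(!pred[!pos])
  structure((sens + spec) / 2, threshold = threshold)
}

#' Per-subgroup ROC comparison
#'
#' Trains one quality model per feature subgroup (statistical, time-domain,
#' frequency-domain, morphology) plus the all-feature model, on the same
#' train/test split, kernel and seed, and evaluates the uninterpretable
#' ROC of each on the common test set.
#'
#' @param features Feature data frame with `label` column (canonical
#'   columns).
#' @param kernel Kernel name.
#' @param holdout_fraction,seed Split parameters.
#' @return Named list (`statistical`, `time`, `frequency`, `morphology`,
#'   `all`), each `list(auc, roc, model)`.
#' @export
subgroup_roc <- function(features, kernel = "exponential",
                         holdout_fraction = 0.2, seed = 1) {
  sp <- split_holdout(features, holdout_fraction, seed)
  groups <- c(aisqa_feature_groups, list(all = seq_along(aisqa_feature_names)))
  lapply(groups, function(cols) {
    nm <- aisqa_feature_names[cols]
    fit <- aisqa(as.matrix(sp$train[, nm, drop = FALSE]), sp$train$label,
                 kernel = kernel, cv_folds = 0, seed = seed)
    sc <- predict(fit, as.matrix(sp$test[, nm, drop = FALSE]))
    roc <- interpretability_roc(sc, sp$test$label)
    list(auc = roc$auc, roc = roc, model = fit)
  })
}

#' Repeat-threshold trade-off curve
#'
#' For the policy "repeat the measurement when the quality index exceeds
#' *t*", computes over a uniform threshold grid on `[0, 3]` the fraction of
#' measurements that would be repeated and the fraction of recordings that
#' carry a false device decision *and* would not be repeated (remaining
#' false classifications).
#'
#' @param scores Quality scores in `[0, 3]`.
#' @param false_flags Logical: the device decision was false.
#' @param n_grid Number of thresholds (default 301).
#' @return Data frame of class `repeat_curve`: `threshold`, `pct_repeated`,
#'   `pct_remaining_false` (fractions of all recordings).
#' @export
repeat_threshold_curve <- function(scores, false_flags, n_grid = 301) {
  stopifnot(is.logical(false_flags), length(scores) == length(false_flags),
            all(scores >= 0 & scores <= 3))
  thr <- seq(0, 3, length.out = n_grid)
  pct_rep <- vapply(thr, function(t) mean(scores > t), numeric(1))
  pct_false <- vapply(thr, function(t) mean(false_flags & scores <= t),
                      numeric(1))
  structure(data.frame(threshold = thr, pct_repeated = pct_rep,
                       pct_remaining_false = pct_false),
            class = c("repeat_curve", "data.frame"))
}

#' Correlation between false device decisions and quality scores
#'
#' Point-biserial (Pearson) correlation between the binary false-decision
#' flag and a signal-quality index, with the two-sided test p-value. A
#' positive correlation means worse-rated recordings are misclassified more
#' often.
#'
#' @param quality_scores Numeric quality index (expert label or model score).
#' @param false_flags Logical false-decision flags.
#' @return List `rho`, `p_value`.
#' @export
false_decision_correlation <- function(quality_scores, false_flags) {
  stopifnot(is.logical(false_flags))
  if (length(quality_scores) < 10 || length(unique(false_flags)) < 2 ||
      stats::sd(quality_scores) == 0)
    stop("degenerate input for false-decision correlation", call. = FALSE)
  ct <- stats::cor.test(quality_scores, as.numeric(false_flags))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Evaluate a fitted model on a labelled feature table
#'
#' Bundles the regression metrics, the uninterpretable ROC/AUC and the
#' balanced accuracy at the Youden threshold.
#'
#' @param model An `aisqa` fit.
#' @param features Feature data frame with `label`.
#' @return List of class `eval_report`: `rmse`, `mae`, `pearson_rho`,
#'   `balanced_accuracy`, `ba_threshold`, `auc`, `roc`, `n`.
#' @export
evaluate_model <- function(model, features) {
  y <- features$label
  sc <- predict(model, features)
  m <- regression_metrics(y, sc)
  rep <- list(rmse = unname(m["rmse"]), mae = unname(m["mae"]),
              pearson_rho = unname(m["rho"]),
              balanced_accuracy = NA_real_, ba_threshold = NA_real_,
              auc = NA_real_, roc = NULL, n = length(y))
  if (length(unique(round(y) == 3)) == 2) {
    roc <- interpretability_roc(sc, y)
    ba <- balanced_accuracy_at(sc, y)
    rep$auc <- roc$auc; rep$roc <- roc
    rep$balanced_accuracy <- as.numeric(ba)
    rep$ba_threshold <- attr(ba, "threshold")
  }
  structure(rep, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "AISQA evaluation (n = %d): RMSE %.3f, MAE %.3f, rho %.3f\n",
    x$n, x$rmse, x$mae, x$pearson_rho))
  if (is.finite(x$auc))
    cat(sprintf("  uninterpretable ROC: AUC %.3f, BA %.3f at t = %.2f\n",
                x$auc, x$balanced_accuracy, x$ba_threshold))
  invisible(x)
}
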