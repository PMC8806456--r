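## Diagnostic evaluation: confusion counts, the
## sensitivity/specificity/PPV/NPV/accuracy panel, ROC/AUC, the merged-layer
## width search, and the connection-pattern ablation harness.

#' Confusion counts at a threshold
#'
#' Scores at or above the threshold are called positive (the `>=`
#' convention, so a score exactly at the threshold is a positive call).
#'
#' @param scores Predicted positive-class probabilities.
#' @param labels Binary 0/1 labels, same length, non-empty.
#' @param threshold Decision threshold (default 0.5).
#' @return An object of class `confusion_counts` with fields `TP`, `FP`,
#'   `TN`, `FN`.
#' @export
confusion <- function(scores, labels, threshold = 0.5) {
  n <- length(scores)
  if (n == 0 || length(labels) != n)
    stop("scores and labels must be non-empty and of equal length")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  pred <- scores >= threshold
  structure(list(
    TP = sum(pred & labels == 1), FP = sum(pred & labels == 0),
    TN = sum(!pred & labels == 0), FN = sum(!pred & labels == 1)
  ), class = "confusion_counts")
}

#' Diagnostic metric panel from confusion counts
#'
#' Computes sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, PPV
#' `TP/(TP+FP)`, NPV `TN/(TN+FN)` and accuracy `(TP+TN)/n`.  A metric whose
#' denominator is zero is reported as `NA` (undefined, not 0) and listed in
#' the `undefined` field.
#'
#' @param counts A `confusion_counts` object.
#' @param auc Optional AUC to include in the panel (filled separately by
#'   [roc_auc()]).
#' @return An object of class `metric_report`.
#' @export
metric_panel <- function(counts, auc = NA_real_) {
  stopifnot(inherits(counts, "confusion_counts"))
  n <- counts$TP + counts$FP + counts$TN + counts$FN
  div <- function(num, den) if (den == 0) NA_real_ else num / den
  rep_ <- list(
    sensitivity = div(counts$TP, counts$TP + counts$FN),
    specificity = div(counts$TN, counts$TN + counts$FP),
    ppv = div(counts$TP, counts$TP + counts$FP),
    npv = div(counts$TN, counts$TN + counts$FN),
    accuracy = div(counts$TP + counts$TN, n),
    auc = auc
  )
  rep_$undefined <- names(rep_)[vapply(rep_, is.na, logical(1))][
    names(rep_)[vapply(rep_, is.na, logical(1))] != "auc"]
  structure(rep_, class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "undefined", sprintf("%.4f", v))
  cat(sprintf("sensitivity %s  specificity %s  PPV %s  NPV %s  accuracy %s  AUC %s\n",
              fmt(x$sensitivity), fmt(x$specificity), fmt(x$ppv), fmt(x$npv),
              fmt(x$accuracy), fmt(x$auc)))
  invisible(x)
}

#' ROC curve and AUC
#'
#' Sweeps all distinct score thresholds to build the ROC curve (anchored at
#' (0,0) and (1,1), both coordinates non-decreasing; tied scores are grouped,
#' which is the trapezoid/midpoint tie convention) and integrates it by the
#' trapezoid rule.
#'
#' @param scores Predicted positive-class probabilities.
#' @param labels Binary 0/1 labels; both classes must be present.
#' @return `list(curve, auc)` where `curve` is a `data.frame` with columns
#'   `threshold`, `fpr`, `tpr`.
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels) || length(scores) == 0)
    stop("scores and labels must be non-empty and of equal length")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("ROC requires both classes to be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) sum(scores >= t & labels == 1), numeric(1)) / n_pos, 1)
  fpr <- c(0, vapply(thr, function(t) sum(scores >= t & labels == 0), numeric(1)) / n_neg, 1)
  curve <- data.frame(threshold = c(Inf, thr, -Inf), fpr = fpr, tpr = tpr)
  auc <- sum(diff(curve$fpr) * (head(curve$tpr, -1) + curve$tpr[-1]) / 2)
  list(curve = curve, auc = auc)
}

#' Rank-statistic (Mann-Whitney) AUC
#'
#' The tie-corrected probability that a random positive scores above a
#' random negative (ties counted half).  Used as an independent cross-check
#' of the trapezoid AUC from [roc_auc()]; the two agree to floating-point
#' accuracy.
#'
#' @inheritParams roc_auc
#' @return Scalar AUC.
#' @export
auc_rank <- function(scores, labels) {
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop("AUC requires both classes to be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Evaluate a model on a labeled tensor set
#'
#' @param model An initialized `fmc_model`.
#' @param x Input batch `(H, W, C, N)`.
#' @param y Binary labels.
#' @param threshold Decision threshold for the confusion counts.
#' @return A `metric_report` with AUC filled; the ROC curve is attached as
#'   `attr(report, "roc")` and scores as `attr(report, "scores")`.
#' @export
evaluate_model <- function(model, x, y, threshold = 0.5) {
  scores <- predict(model, x)
  roc <- roc_auc(scores, y)
  rep_ <- metric_panel(confusion(scores, y, threshold), auc = roc$auc)
  attr(rep_, "roc") <- roc$curve
  attr(rep_, "scores") <- scores
  rep_
}

#' Default merged-layer width candidates
#'
#' Powers of two from 32 to 4096 — the sweep used to select the merged
#' layer's dimension.
#' @return Integer vector of 8 widths.
#' @export
default_width_candidates <- function() as.integer(2^(5:12))

#' Merged-layer width search
#'
#' Trains one model per candidate width (same seed and config for each) and
#' selects the width with the highest validation-set classification
#' accuracy, breaking ties toward the smallest width.  A width whose
#' training fails is excluded with a warning.
#'
#' @param splits Tensor splits as produced by [load_split_tensors()].
#' @param base_spec An [architecture_spec()]; its `merged_width` is swept.
#' @param config A [train_config()].
#' @param widths Candidate widths (default [default_width_candidates()]).
#' @param accuracy_fn Optional oracle `function(width) -> accuracy` used in
#'   place of training (harness testing).
#' @return An object of class `width_search_result`: a `data.frame`
#'   (`width`, `val_accuracy`) with the chosen width in
#'   `attr(, "selected")`.
#' @export
width_search <- function(splits, base_spec, config, widths = default_width_candidates(),
                         accuracy_fn = NULL) {
  if (length(widths) == 0) stop("no candidate widths")
  acc <- rep(NA_real_, length(widths))
  for (i in seq_along(widths)) {
    if (!is.null(accuracy_fn)) {
      acc[i] <- accuracy_fn(widths[i])
      next
    }
    sp <- base_spec
    sp$merged_width <- as.integer(widths[i])
    res <- tryCatch({
      model <- build_architecture(sp, seed = config$seed)
      fit <- train(model, splits, config)
      vp <- predict(fit$model, splits$validation$x)
      mean((vp >= 0.5) == (splits$validation$y == 1))
    }, error = function(e) {
      warning(sprintf("width %d failed: %s", widths[i], conditionMessage(e)))
      NA_real_
    })
    acc[i] <- res
  }
  tab <- data.frame(width = widths, val_accuracy = acc)
  ok <- which(!is.na(acc))
  if (!length(ok)) stop("all candidate widths failed")
  best <- ok[order(-acc[ok], widths[ok])][1]
  structure(tab, selected = widths[best], class = c("width_search_result", "data.frame"))
}

#' Connection-pattern ablation
#'
#' Trains one model per wiring variant on the same splits, seed, and
#' configuration, and reports the test-split metric panel per variant.  A
#' variant whose training fails is reported with `NA` metrics.
#'
#' @param splits Tensor splits (train/validation/test).
#' @param config A [train_config()].
#' @param variants Character vector of variants (default A..E plus FMC).
#' @param base_spec An [architecture_spec()] supplying the shared geometry;
#'   only its `variant` is changed per row.
#' @return A `data.frame` with one row per variant: `variant`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `accuracy`, `auc`.
#' @export
run_ablation <- function(splits, config,
                         variants = c("A", "B", "C", "D", "E", "FMC"),
                         base_spec = architecture_spec("FMC", profile = "tiny")) {
  rows <- lapply(variants, function(v) {
    out <- tryCatch({
      spec <- base_spec
      spec$variant <- match.arg(v, VARIANTS)
      model <- build_architecture(spec, seed = config$seed)
      fit <- train(model, splits, config)
      rep_ <- evaluate_model(fit$model, splits$test$x, splits$test$y)
      data.frame(variant = v, sensitivity = rep_$sensitivity,
                 specificity = rep_$specificity, ppv = rep_$ppv, npv = rep_$npv,
                 accuracy = rep_$accuracy, auc = rep_$auc,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      warning(sprintf("variant %s failed: %s", v, conditionMessage(e)))
      data.frame(variant = v, sensitivity = NA_real_, specificity = NA_real_,
                 ppv = NA_real_, npv = NA_real_, accuracy = NA_real_,
                 auc = NA_real_, stringsAsFactors = FALSE)
    })
    out
  })
  do.call(rbind, rows)
}
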