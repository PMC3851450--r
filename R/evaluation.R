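## Evaluation machinery: confusion counts, the seven derived metrics
## (sensitivity, specificity, accuracy, precision, rate of false prediction,
## error rate, Matthews correlation coefficient), ROC/AUC, stratified k-fold
## cross-validation and decision-threshold scans.

#' Confusion counts for a binary prediction
#'
#' @param truth,predicted equal-length label vectors.
#' @param positive the positive-class label.
#' @return a `confusion_counts` list with integer `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(truth, predicted, positive) {
  if (length(truth) != length(predicted))
    stop_data("truth and predicted must have equal length")
  if (length(truth) < 1L) stop_data("need at least one sample")
  tp <- sum(truth == positive & predicted == positive)
  fp <- sum(truth != positive & predicted == positive)
  tn <- sum(truth != positive & predicted != positive)
  fn <- sum(truth == positive & predicted != positive)
  structure(list(TP = as.integer(tp), FP = as.integer(fp),
                 TN = as.integer(tn), FN = as.integer(fn)),
            class = "confusion_counts")
}

#' Confusion counts from explicit cell values
#' @param TP,FP,TN,FN non-negative integer cell counts.
#' @return a `confusion_counts` list.
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  v <- c(TP, FP, TN, FN)
  if (any(v < 0) || any(v != round(v))) stop_usage("counts must be non-negative integers")
  structure(list(TP = as.integer(TP), FP = as.integer(FP),
                 TN = as.integer(TN), FN = as.integer(FN)),
            class = "confusion_counts")
}

#' Derived performance metrics from confusion counts
#'
#' Computes the standard binary evaluation parameters, percentages on a
#' 0–100 scale:
#' sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/total`, precision `TP/(TP+FP)`, rate of false prediction
#' `FP/(TP+FP)` (the complement of precision), error rate `(FP+FN)/total`
#' (the complement of accuracy), and the Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))` in \[-1, 1\].
#' When any MCC marginal factor is zero the coefficient is reported as 0
#' (the random-prediction value); ratios with empty denominators are `NaN`.
#'
#' @param counts a `confusion_counts` object.
#' @return a `metrics_report` list with fields `sensitivity`, `specificity`,
#'   `accuracy`, `precision`, `rfp`, `error_rate` (percent) and `mcc`.
#' @export
metrics <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; tn <- counts$TN; fn <- counts$FN
  total <- tp + fp + tn + fn
  if (total < 1L) stop_data("confusion counts sum to zero")
  sn <- if (tp + fn > 0) 100 * tp / (tp + fn) else NaN
  sp <- if (tn + fp > 0) 100 * tn / (tn + fp) else NaN
  acc <- 100 * (tp + tn) / total
  prec <- if (tp + fp > 0) 100 * tp / (tp + fp) else NaN
  rfp <- if (tp + fp > 0) 100 * fp / (tp + fp) else NaN
  er <- 100 * (fp + fn) / total
  denom <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom)
  structure(list(sensitivity = sn, specificity = sp, accuracy = acc,
                 precision = prec, rfp = rfp, error_rate = er, mcc = mcc,
                 counts = counts),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "Sn %.2f%%  Sp %.2f%%  Acc %.2f%%  MCC %.2f  Precision %.2f%%  RFP %.2f%%  ER %.2f%%\n",
    x$sensitivity, x$specificity, x$accuracy, x$mcc, x$precision, x$rfp,
    x$error_rate))
  invisible(x)
}

#' ROC curve and AUC from decision scores
#'
#' Sweeps the decision threshold over all distinct scores, yielding the
#' (FPR, TPR) curve from (0,0) to (1,1); the area under the curve is
#' computed by the trapezoidal rule, which equals the rank statistic (the
#' probability that a random positive outscores a random negative, ties
#' counting one half).
#'
#' @param truth label vector.
#' @param scores numeric decision values, higher = more positive.
#' @param positive positive-class label.
#' @return a `roc_curve` list with `fpr`, `tpr`, `thresholds`, `auc`.
#' @export
roc <- function(truth, scores, positive) {
  if (length(truth) != length(scores)) stop_data("length mismatch")
  is_pos <- truth == positive
  np <- sum(is_pos); nn <- sum(!is_pos)
  if (np == 0L || nn == 0L)
    stop_data("ROC requires both classes present")
  o <- order(scores, decreasing = TRUE)
  sp <- is_pos[o]; sc <- scores[o]
  tp_cum <- cumsum(sp); fp_cum <- cumsum(!sp)
  last <- c(sc[-1] != sc[-length(sc)], TRUE)  # keep last index of each tie group
  tpr <- c(0, tp_cum[last] / np)
  fpr <- c(0, fp_cum[last] / nn)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(list(fpr = fpr, tpr = tpr,
                 thresholds = c(Inf, sc[last]), auc = auc),
            class = "roc_curve")
}

#' Stratified k-fold cross-validation
#'
#' Splits the data into k class-stratified folds (fold sizes differ by at
#' most one per class), trains on k-1 folds and tests on the held-out fold,
#' so every sample is tested exactly once. For binary problems, per-fold
#' [metrics] reports plus a pooled report from the summed confusion counts
#' (micro pooling) are returned; for multiclass, per-fold accuracies plus a
#' pooled [multiclass_metrics] report.
#'
#' @param x feature matrix.
#' @param y label vector (length `nrow(x)`).
#' @param trainer function `(x_train, y_train) -> model`.
#' @param predictor function `(model, x_test) -> label vector`.
#' @param k folds (default 5); every class must have at least k members.
#' @param seed fold-assignment seed.
#' @param positive positive label for binary metrics (default: first label
#'   encountered).
#' @return list with `folds` (assignment vector), `predictions` (one label
#'   per sample), `per_fold`, `pooled`, and `accuracy` (pooled percent).
#' @export
kfold_cv <- function(x, y, trainer, predictor, k = 5L, seed = 1L,
                     positive = NULL) {
  y <- as.character(y)
  classes <- unique(y)
  tab <- table(y)
  if (any(tab < k))
    stop_data(sprintf("class '%s' has fewer than k=%d members",
                      names(tab)[which(tab < k)[1]], k))
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in classes) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  pred <- character(length(y))
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    test <- fold == f
    model <- trainer(x[!test, , drop = FALSE], y[!test])
    pf <- predictor(model, x[test, , drop = FALSE])
    pred[test] <- pf
    if (length(classes) == 2L) {
      pos <- positive %||% classes[1]
      per_fold[[f]] <- metrics(confusion(y[test], pf, pos))
    } else {
      per_fold[[f]] <- list(accuracy = 100 * mean(pf == y[test]))
    }
  }
  if (length(classes) == 2L) {
    pos <- positive %||% classes[1]
    pooled <- metrics(confusion(y, pred, pos))
    acc <- pooled$accuracy
  } else {
    pooled <- multiclass_metrics(y, pred, classes)
    acc <- 100 * mean(pred == y)
  }
  list(folds = fold, predictions = pred, per_fold = per_fold,
       pooled = pooled, accuracy = acc)
}

#' Decision-threshold scan
#'
#' Evaluates a binary model at every threshold on a grid (default -1.2 to
#' 1.2 in steps of 0.1, 25 rows). As the threshold rises, sensitivity is
#' non-increasing and specificity non-decreasing.
#'
#' @param model a `binary_model`.
#' @param x feature matrix.
#' @param truth label vector.
#' @param lo,hi,step threshold grid.
#' @return data frame: `threshold`, `sensitivity`, `specificity`,
#'   `accuracy`, `precision`, `rfp`, `error_rate`, `mcc`.
#' @export
threshold_scan <- function(model, x, truth, lo = -1.2, hi = 1.2, step = 0.1) {
  if (lo >= hi) stop_usage("lo must be < hi")
  dv <- decision_values(model, x)
  thresholds <- seq(lo, hi, by = step)
  rows <- lapply(thresholds, function(t) {
    pred <- ifelse(dv >= t, model$positive_label, model$negative_label)
    m <- metrics(confusion(truth, pred, model$positive_label))
    data.frame(threshold = t, sensitivity = m$sensitivity,
               specificity = m$specificity, accuracy = m$accuracy,
               precision = m$precision, rfp = m$rfp,
               error_rate = m$error_rate, mcc = m$mcc)
  })
  do.call(rbind, rows)
}

#' One-vs-rest metrics for a multiclass prediction
#'
#' Treats each class in turn as positive against all others and reports its
#' binary [metrics]; the overall report is the unweighted (macro) average
#' over classes. Macro averaging is a deliberate, documented choice — other
#' aggregation rules (micro, weighted) give different overall numbers.
#'
#' @param truth,predicted label vectors.
#' @param classes the full class set.
#' @return list with `per_class` (named list of `metrics_report`), `overall`
#'   (macro-averaged fields), and `accuracy` (plain multiclass accuracy %).
#' @export
multiclass_metrics <- function(truth, predicted, classes = sort(unique(truth))) {
  if (length(truth) != length(predicted)) stop_data("length mismatch")
  if (length(unique(truth)) < 2L) stop_data("need >= 2 classes in truth")
  if (!all(predicted %in% classes))
    stop_data("predicted label outside the declared class set")
  per_class <- lapply(classes, function(cl)
    metrics(confusion(truth, predicted, cl)))
  names(per_class) <- classes
  fields <- c("sensitivity", "specificity", "accuracy", "precision",
              "rfp", "error_rate", "mcc")
  overall <- lapply(fields, function(f)
    mean(vapply(per_class, `[[`, numeric(1), f)))
  names(overall) <- fields
  list(per_class = per_class, overall = overall,
       accuracy = 100 * mean(predicted == truth))
}

#' Write a metrics report (or threshold-scan table) as TSV/JSON
#' @param report a `metrics_report`.
#' @param path output path; format chosen by extension (.json or .tsv).
#' @return invisibly, `path`.
#' @export
write_report <- function(report, path) {
  vals <- report[c("sensitivity", "specificity", "accuracy", "precision",
                   "rfp", "error_rate", "mcc")]
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    df <- data.frame(metric = names(vals), value = unlist(vals))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
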