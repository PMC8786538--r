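# Evaluation metrics: confusion counts, the full detection report and
# signal-pair reconstruction scores.

#' Confusion counts from binary label vectors
#'
#' @param labels_true,labels_pred binary (0/1) vectors of equal length.
#' @return object of class `confusion_counts` with fields `ta_p` (true
#'   positives), `fa_p` (false positives), `ta_n` (true negatives), `fa_n`
#'   (false negatives).
#' @export
confusion <- function(labels_true, labels_pred) {
  if (length(labels_true) != length(labels_pred))
    stop_arg("label vectors must have equal length")
  if (!all(labels_true %in% c(0, 1)) || !all(labels_pred %in% c(0, 1)))
    stop_arg("labels must be binary 0/1")
  structure(list(
    ta_p = sum(labels_true == 1 & labels_pred == 1),
    fa_p = sum(labels_true == 0 & labels_pred == 1),
    ta_n = sum(labels_true == 0 & labels_pred == 0),
    fa_n = sum(labels_true == 1 & labels_pred == 0)),
    class = "confusion_counts")
}

# Safe ratio: zero denominator yields the undefined marker NA, never an error.
.ratio <- function(num, den) if (den > 0) num / den else NA_real_

#' Full detection report from confusion counts
#'
#' Standard definitions throughout: accuracy, precision, sensitivity
#' (recall), specificity, FPR = 1 - specificity, FNR = 1 - sensitivity,
#' NPV, FDR = 1 - precision, F1 and Matthews correlation. Any metric with a
#' zero denominator is reported as `NA` (undefined marker). The detection
#' fitness is `fr1 = 1 / (accuracy + precision)`, the quantity minimized by
#' the hyperparameter tuner; it is at least 0.5 since both rates are <= 1.
#'
#' @param c a `confusion_counts` object.
#' @return object of class `detection_report` (a named list of rates).
#' @export
detection_report <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  tp <- c$ta_p; fp <- c$fa_p; tn <- c$ta_n; fn <- c$fa_n
  total <- tp + fp + tn + fn
  if (total < 1) stop_arg("confusion counts sum to zero")
  accuracy <- .ratio(tp + tn, total)
  precision <- .ratio(tp, tp + fp)
  sensitivity <- .ratio(tp, tp + fn)
  specificity <- .ratio(tn, tn + fp)
  npv <- .ratio(tn, tn + fn)
  f1 <- .ratio(2 * tp, 2 * tp + fp + fn)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else NA_real_
  fr1 <- if (!is.na(accuracy) && !is.na(precision) && accuracy + precision > 0)
    1 / (accuracy + precision) else 1e6
  structure(list(
    accuracy = accuracy, precision = precision,
    sensitivity = sensitivity, specificity = specificity,
    fpr = if (is.na(specificity)) NA_real_ else 1 - specificity,
    fnr = if (is.na(sensitivity)) NA_real_ else 1 - sensitivity,
    npv = npv,
    fdr = if (is.na(precision)) NA_real_ else 1 - precision,
    f1 = f1, mcc = mcc, fitness_fr1 = fr1,
    counts = c), class = "detection_report")
}

#' @export
print.detection_report <- function(x, ...) {
  cat("<detection_report>\n")
  for (k in setdiff(names(x), "counts"))
    cat(sprintf("  %-12s %s\n", k, format(x[[k]], digits = 4)))
  invisible(x)
}

#' Reconstruction scores for a retrieved/clean signal pair
#'
#' @param retrieved,clean numeric vectors of equal length (>= 2).
#' @return object of class `signal_pair_scores` with `mae` (mean absolute
#'   error), `rmse` (root mean square error) and `corr` (Pearson correlation;
#'   `NA` when `clean` is constant).
#' @export
signal_scores <- function(retrieved, clean) {
  if (length(retrieved) != length(clean)) stop_arg("signals must have equal length")
  if (length(clean) < 2) stop_arg("signals must have length >= 2")
  d <- retrieved - clean
  corr <- if (stats::sd(clean) > 0 && stats::sd(retrieved) > 0)
    stats::cor(retrieved, clean) else NA_real_
  structure(list(mae = mean(abs(d)), rmse = sqrt(mean(d^2)), corr = corr),
            class = "signal_pair_scores")
}

#' Write a detection report as structured text plus a one-row CSV summary
#' @param report a `detection_report`.
#' @param path base path; `<path>.txt` and `<path>.csv` are written.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "detection_report"))
  keys <- setdiff(names(report), "counts")
  lines <- vapply(keys, function(k) sprintf("%s: %.6g", k, report[[k]]), "")
  writeLines(lines, paste0(path, ".txt"))
  row <- as.data.frame(report[keys])
  data.table::fwrite(row, paste0(path, ".csv"))
  invisible(path)
}
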