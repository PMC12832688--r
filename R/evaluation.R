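# Evaluation statistics with pneumonia as the positive class: confusion
# matrix, per-class precision/recall/F1 with macro and support-weighted
# aggregates, ROC/AUC by trapezoid over tie-grouped thresholds, and
# McNemar's paired test on discordant predictions.
#
# Positive-class convention (authoritative throughout the package):
#   TP = pneumonia predicted pneumonia, FN = pneumonia predicted normal,
#   FP = normal predicted pneumonia,    TN = normal predicted normal.

#' Construct a confusion matrix
#'
#' @param tp,fn,fp,tn Nonnegative integer counts, pneumonia positive.
#' @return A list of class `"confusion_matrix"`.
#' @examples
#' confusion_matrix(372, 18, 39, 195)
#' @export
confusion_matrix <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0) || any(counts != floor(counts)))
    stopf("confusion counts must be nonnegative integers")
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(true = c("pneumonia", "normal"),
                              predicted = c("pneumonia", "normal")))
  print(m)
  invisible(x)
}

#' Confusion matrix from scores
#'
#' Predicts pneumonia iff `score >= threshold` and tallies counts against
#' the true labels.
#'
#' @param y_true Binary truth (1/`"pneumonia"` = positive).
#' @param scores Numeric scores in `[0, 1]`.
#' @param threshold Decision threshold (default 0.5).
#' @return A [confusion_matrix()].
#' @export
confusion <- function(y_true, scores, threshold = 0.5) {
  y <- as_binary_labels(y_true)
  if (length(y) != length(scores)) stopf("y_true and scores lengths differ")
  if (length(y) == 0) stopf("empty input")
  pred <- as.integer(scores >= threshold)
  confusion_matrix(sum(y == 1 & pred == 1), sum(y == 1 & pred == 0),
                   sum(y == 0 & pred == 1), sum(y == 0 & pred == 0))
}

as_binary_labels <- function(y) {
  if (is.character(y) || is.factor(y))
    as.integer(tolower(as.character(y)) == "pneumonia")
  else as.integer(y != 0)
}

#' Classification report
#'
#' Per-class precision, recall, F1 and support, overall accuracy, and macro
#' (unweighted) plus weighted (support-weighted) averages. Scores with a
#' zero denominator are reported as 0 and flagged via the
#' `zero_denominator` attribute.
#'
#' @param cm A [confusion_matrix()].
#' @return A list of class `"class_report"`: `per_class` data frame (rows
#'   `normal`, `pneumonia`), `accuracy`, `macro`, `weighted`, `support`.
#' @examples
#' rep <- report(confusion_matrix(372, 18, 39, 195))
#' round(rep$accuracy, 2)  # 0.91
#' @export
report <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$fn + cm$fp + cm$tn
  if (total == 0) stopf("all-zero confusion matrix")
  zero_flag <- FALSE
  safe_div <- function(num, den) {
    if (den == 0) { zero_flag <<- TRUE; return(0) }
    num / den
  }
  prec_pos <- safe_div(cm$tp, cm$tp + cm$fp)
  rec_pos <- safe_div(cm$tp, cm$tp + cm$fn)
  prec_neg <- safe_div(cm$tn, cm$tn + cm$fn)
  rec_neg <- safe_div(cm$tn, cm$tn + cm$fp)
  f1 <- function(p, r) if (p + r == 0) { zero_flag <<- TRUE; 0 }
  else 2 * p * r / (p + r)
  per_class <- data.frame(
    class = c("normal", "pneumonia"),
    precision = c(prec_neg, prec_pos),
    recall = c(rec_neg, rec_pos),
    f1 = c(f1(prec_neg, rec_neg), f1(prec_pos, rec_pos)),
    support = c(cm$fp + cm$tn, cm$tp + cm$fn),
    stringsAsFactors = FALSE)
  w <- per_class$support / total
  out <- list(per_class = per_class,
              accuracy = (cm$tp + cm$tn) / total,
              macro = c(precision = mean(per_class$precision),
                        recall = mean(per_class$recall),
                        f1 = mean(per_class$f1)),
              weighted = c(precision = sum(w * per_class$precision),
                           recall = sum(w * per_class$recall),
                           f1 = sum(w * per_class$f1)),
              support = total)
  attr(out, "zero_denominator") <- zero_flag
  class(out) <- "class_report"
  out
}

#' @export
print.class_report <- function(x, digits = 2, ...) {
  pc <- x$per_class
  pc[, 2:4] <- lapply(pc[, 2:4], round_half_up, digits = digits)
  print.data.frame(pc, row.names = FALSE)
  cat(sprintf("accuracy: %s  (n = %d)\n",
              format(round_half_up(x$accuracy, digits)), x$support))
  cat(sprintf("macro    p/r/f1: %s\n",
              paste(format(round_half_up(x$macro, digits)), collapse = " / ")))
  cat(sprintf("weighted p/r/f1: %s\n",
              paste(format(round_half_up(x$weighted, digits)),
                    collapse = " / ")))
  invisible(x)
}

#' ROC curve and AUC
#'
#' Sweeps all distinct score values as thresholds (ties grouped into one
#' step), accumulating true/false-positive rates, and integrates the area
#' under the curve by the trapezoidal rule. Equals the Mann-Whitney
#' pair-counting estimator with ties counted one half.
#'
#' @param y_true Binary truth (1/`"pneumonia"` = positive).
#' @param scores Numeric scores.
#' @return A list of class `"roc_result"`: `thresholds`, `fpr`, `tpr`,
#'   `auc`.
#' @export
roc_auc <- function(y_true, scores) {
  y <- as_binary_labels(y_true)
  if (length(y) != length(scores)) stopf("y_true and scores lengths differ")
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0)
    stopf("AUC undefined: both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  grp <- !duplicated(ss)
  tp <- cumsum(ys == 1); fp <- cumsum(ys == 0)
  last <- c(which(grp[-1]) , length(ss))  # last index of each tie group
  tpr <- c(0, tp[last] / n_pos)
  fpr <- c(0, fp[last] / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = c(Inf, ss[last]), fpr = fpr, tpr = tpr,
                 auc = auc),
            class = "roc_result")
}

#' McNemar's paired test
#'
#' Tests whether two classifiers' error patterns differ using the
#' discordant-pair counts `b` (first correct, second wrong) and `c` (first
#' wrong, second correct): chi-squared = `(b-c)^2/(b+c)`, or with continuity
#' correction `(|b-c|-1)^2/(b+c)` (numerator floored at 0), referred to the
#' chi-squared distribution with 1 degree of freedom.
#'
#' @param b,c Discordant-pair counts.
#' @param corrected Apply the continuity correction (default `TRUE`).
#' @param alpha Significance level reported (default 0.05).
#' @return A list of class `"mcnemar_result"`: `b`, `c`, `chi2`, `p`,
#'   `corrected`, `significant`.
#' @examples
#' mcnemar(15, 5, corrected = FALSE)$chi2  # 5
#' @export
mcnemar <- function(b, c, corrected = TRUE, alpha = 0.05) {
  if (b < 0 || c < 0 || b != floor(b) || c != floor(c))
    stopf("b and c must be nonnegative integers")
  if (b + c == 0) stopf("test undefined: no discordant pairs")
  num <- if (corrected) max(abs(b - c) - 1, 0)^2 else (b - c)^2
  chi2 <- num / (b + c)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  structure(list(b = b, c = c, chi2 = chi2, p = p,
                 corrected = isTRUE(corrected), significant = p < alpha),
            class = "mcnemar_result")
}

#' Discordant-pair counts of two prediction vectors
#'
#' @param y_true Binary truth.
#' @param pred_a,pred_b Hard predictions of the two models (same coding as
#'   `y_true`).
#' @return Integer vector `c(b, c)`: `b` = A correct & B wrong, `c` = A
#'   wrong & B correct.
#' @export
discordants <- function(y_true, pred_a, pred_b) {
  y <- as_binary_labels(y_true)
  a <- as_binary_labels(pred_a); bb <- as_binary_labels(pred_b)
  if (length(y) != length(a) || length(y) != length(bb))
    stopf("prediction vectors must match y_true in length")
  ok_a <- a == y; ok_b <- bb == y
  c(b = sum(ok_a & !ok_b), c = sum(!ok_a & ok_b))
}

#' Write a classification report as JSON and text
#'
#' @param rep A [report()] result.
#' @param json_path,text_path Optional output files.
#' @return The report, invisibly.
#' @export
write_report <- function(rep, json_path = NULL, text_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(list(per_class = rep$per_class,
                              accuracy = rep$accuracy,
                              macro = as.list(rep$macro),
                              weighted = as.list(rep$weighted),
                              support = rep$support),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(text_path)) {
    con <- file(text_path, "w"); on.exit(close(con))
    sink(con); print(rep); sink()
  }
  invisible(rep)
}
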