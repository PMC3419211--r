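# -- confusion-matrix bookkeeping, Recall and Mean error (balanced error rate)

#' Confusion counts
#'
#' @param tp,fp,tn,fn non-negative integer counts; at least one must be
#'   positive. Positives are HGT genes, negatives native genes.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  v <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  stopifnot(all(v >= 0), sum(v) >= 1)
  structure(as.list(v), class = "confusion_counts")
}

# counts from truth/prediction label vectors (positive class = HGT)
confusion_from_labels <- function(truth, pred) {
  confusion_counts(tp = sum(truth == "HGT" & pred == "HGT"),
                   fp = sum(truth == "NATIVE" & pred == "HGT"),
                   tn = sum(truth == "NATIVE" & pred == "NATIVE"),
                   fn = sum(truth == "HGT" & pred == "NATIVE"))
}

#' Recall (detection rate), in percent
#'
#' `100 * TP / (TP + FN)`: the fraction of true horizontally transferred
#' genes that are detected. FP/TN do not enter.
#'
#' @param c a [confusion_counts()].
#' @return Percent in `[0, 100]`.
#' @export
recall_pct <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  if (c$tp + c$fn == 0) stop("recall undefined: no positive examples")
  100 * c$tp / (c$tp + c$fn)
}

#' Mean error (balanced error rate), in percent
#'
#' `100 * 0.5 * (FN/(FN+TP) + FP/(FP+TN))`: the average of the
#' false-negative and false-positive rates, equal to 100 minus balanced
#' accuracy in percent.
#'
#' @inheritParams recall_pct
#' @return Percent in `[0, 100]`.
#' @export
mean_error_pct <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  if (c$tp + c$fn == 0 || c$tn + c$fp == 0)
    stop("mean error undefined: a class is empty")
  100 * 0.5 * (c$fn / (c$fn + c$tp) + c$fp / (c$fp + c$tn))
}

#' Aggregate per-fold confusion counts
#'
#' Macro average: Recall and Mean error are computed per fold and their
#' arithmetic means reported (pooling counts across folds is available
#' with `pooled = TRUE`).
#'
#' @param folds non-empty list of [confusion_counts()].
#' @param pooled if TRUE, additionally report metrics on summed counts.
#' @return An object of class `eval_result` with elements `per_fold`,
#'   `recall_pct`, `mean_error_pct`.
#' @export
aggregate_folds <- function(folds, pooled = FALSE) {
  stopifnot(length(folds) >= 1)
  rec <- vapply(folds, recall_pct, numeric(1))
  err <- vapply(folds, mean_error_pct, numeric(1))
  out <- structure(list(per_fold = folds,
                        recall_pct = mean(rec),
                        mean_error_pct = mean(err)),
                   class = "eval_result")
  if (pooled) {
    tot <- confusion_counts(tp = sum(vapply(folds, `[[`, numeric(1), "tp")),
                            fp = sum(vapply(folds, `[[`, numeric(1), "fp")),
                            tn = sum(vapply(folds, `[[`, numeric(1), "tn")),
                            fn = sum(vapply(folds, `[[`, numeric(1), "fn")))
    out$pooled_recall_pct <- recall_pct(tot)
    out$pooled_mean_error_pct <- mean_error_pct(tot)
  }
  out
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("eval_result over %d fold(s): Recall %.2f%%, Mean error %.2f%%\n",
              length(x$per_fold), x$recall_pct, x$mean_error_pct))
  invisible(x)
}

# half-up rounding to `digits` decimals (table formatting convention)
round_half_up <- function(x, digits = 2) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Average improvement between two result tables
#'
#' Given paired `(Recall, Mean error)` rows before and after an
#' intervention (e.g. all features vs the selected subset), returns the
#' mean per-row Recall improvement (`after - before`) and mean Mean-error
#' reduction (`before - after`), each half-up rounded to 2 decimals as in
#' published summary tables.
#'
#' @param before,after data frames (or matrices) with columns
#'   `recall` and `mean_error`, equal row counts.
#' @return `c(recall_delta, mean_error_delta)`.
#' @export
table_deltas <- function(before, after) {
  before <- as.data.frame(before); after <- as.data.frame(after)
  stopifnot(nrow(before) == nrow(after), nrow(before) >= 1,
            all(c("recall", "mean_error") %in% names(before)),
            all(c("recall", "mean_error") %in% names(after)))
  c(recall_delta = round_half_up(mean(after$recall - before$recall)),
    mean_error_delta = round_half_up(mean(before$mean_error - after$mean_error)))
}
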