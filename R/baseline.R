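# -- single-signature multiple-threshold baseline detector

#' Multiple-threshold sweep on one atypicality feature
#'
#' A simplified single-signature detector used as the comparison arm for
#' the combined classifier: genes whose score on one feature exceeds the
#' p-th upper-tail percentile of the genome's score distribution are
#' called HGT (scores equal to the cutoff are flagged, so percentile 0
#' flags every gene), for each percentile in the sweep. Confusion counts, Recall
#' and Mean error are reported per threshold, together with the
#' best-Recall row (ties broken by lower Mean error, then lower
#' percentile). Flagged sets are nested: raising the percentile can only
#' shrink the called set.
#'
#' @param dataset an [hgt_dataset()] with known HGT/NATIVE labels.
#' @param feature one of [hgt_feature_names()].
#' @param percentiles increasing percentile cutoffs in `[0, 100)`.
#' @return An object of class `threshold_sweep` with elements `feature`,
#'   `table` (one row per percentile) and `best` (row index of the best
#'   Recall).
#' @export
threshold_sweep <- function(dataset, feature,
                            percentiles = c(80, 85, 90, 92.5, 95, 97.5, 99)) {
  stopifnot(inherits(dataset, "hgt_dataset"))
  if (!feature %in% colnames(dataset$x))
    stop("unknown feature '", feature, "'; valid names: ",
         paste(colnames(dataset$x), collapse = ", "))
  stopifnot(all(diff(percentiles) > 0), all(percentiles >= 0),
            all(percentiles < 100))
  if (!all(c("HGT", "NATIVE") %in% dataset$label))
    stop("both classes must be present and labelled")
  scores <- dataset$x[, feature]
  rows <- lapply(percentiles, function(p) {
    cut <- quantile(scores, p / 100, names = FALSE)
    pred <- ifelse(scores >= cut, "HGT", "NATIVE")
    cc <- confusion_from_labels(dataset$label, pred)
    data.frame(percentile = p, cutoff = cut, n_flagged = sum(pred == "HGT"),
               tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn,
               recall = recall_pct(cc), mean_error = mean_error_pct(cc))
  })
  tab <- do.call(rbind, rows)
  best <- order(-tab$recall, tab$mean_error, tab$percentile)[1]
  structure(list(feature = feature, table = tab, best = best),
            class = "threshold_sweep")
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat(sprintf("threshold_sweep on %s: best Recall %.2f%% (Mean error %.2f%%) at percentile %g\n",
              x$feature, x$table$recall[x$best], x$table$mean_error[x$best],
              x$table$percentile[x$best]))
  invisible(x)
}
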