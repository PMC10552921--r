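# Nucleotide-level benchmarking of a predicted annotation against a
# reference annotation: per-base confusion counts via interval algebra
# (IRanges), then the six standard metrics. Strand is ignored (masking is
# strandless) and TN covers every unannotated base of the genome.

#' Per-base confusion counts
#'
#' Both interval sets are merged (overlaps unioned) per sequence, then each
#' base of every sequence is classified: TP in both, FP prediction only,
#' FN truth only, TN neither.
#'
#' @param truth,pred Tibbles with `seq_id`, `start`, `end` (0-based
#'   half-open).
#' @param seq_lengths Named integer vector of sequence lengths (bp); every
#'   annotated sequence must be present.
#' @return A one-row tibble `TP`, `FP`, `FN`, `TN` (bp).
#' @export
confusion_counts <- function(truth, pred, seq_lengths) {
  anns <- unique(c(truth$seq_id, pred$seq_id))
  missing_seq <- setdiff(anns, names(seq_lengths))
  if (length(missing_seq)) {
    abort(paste0("confusion_counts: sequence '", missing_seq[1],
                 "' not in seq_lengths"))
  }
  bad_t <- truth$end > seq_lengths[truth$seq_id]
  bad_p <- pred$end > seq_lengths[pred$seq_id]
  if (any(bad_t) || any(bad_p)) {
    abort("confusion_counts: interval outside sequence bounds")
  }
  tp <- fp <- fn <- 0
  for (sid in names(seq_lengths)) {
    ir_t <- IRanges::reduce(to_iranges(truth[truth$seq_id == sid, ]))
    ir_p <- IRanges::reduce(to_iranges(pred[pred$seq_id == sid, ]))
    both <- IRanges::intersect(ir_t, ir_p)
    tp <- tp + sum(IRanges::width(both))
    fp <- fp + sum(IRanges::width(ir_p)) - sum(IRanges::width(both))
    fn <- fn + sum(IRanges::width(ir_t)) - sum(IRanges::width(both))
  }
  total <- sum(seq_lengths)
  tibble(TP = as.integer(tp), FP = as.integer(fp), FN = as.integer(fn),
         TN = as.integer(total - tp - fp - fn))
}

to_iranges <- function(tbl) {
  if (nrow(tbl) == 0) return(IRanges::IRanges())
  IRanges::IRanges(start = tbl$start + 1L, end = tbl$end)
}

#' Metrics from confusion counts
#'
#' sensitivity = TP/(TP+FN); specificity = TN/(FP+TN);
#' accuracy = (TP+TN)/(TP+TN+FP+FN); precision = TP/(TP+FP);
#' FDR = 1 - precision; F1 = 2TP/(2TP+FP+FN). A metric whose denominator
#' is zero is reported as `NA` and listed in the `undefined` attribute —
#' never coerced to 0.
#'
#' @param TP,FP,FN,TN Non-negative base counts (or a one-row tibble in
#'   `TP`).
#' @return An `ltr_benchmark` object: a list with `counts` and `metrics`
#'   tibbles.
#' @export
metrics_from_counts <- function(TP, FP = NULL, FN = NULL, TN = NULL) {
  if (is.data.frame(TP)) {
    cnt <- TP; TP <- cnt$TP; FP <- cnt$FP; FN <- cnt$FN; TN <- cnt$TN
  }
  if (any(c(TP, FP, FN, TN) < 0)) abort("metrics_from_counts: negative count")
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  sensitivity <- safe_div(TP, TP + FN)
  specificity <- safe_div(TN, FP + TN)
  accuracy <- safe_div(TP + TN, TP + TN + FP + FN)
  precision <- safe_div(TP, TP + FP)
  f1 <- safe_div(2 * TP, 2 * TP + FP + FN)
  fdr <- if (is.na(precision)) NA_real_ else 1 - precision
  metrics <- tibble(sensitivity = sensitivity, specificity = specificity,
                    accuracy = accuracy, precision = precision,
                    FDR = fdr, F1 = f1)
  undefined <- names(metrics)[vapply(metrics, is.na, logical(1))]
  structure(
    list(counts = tibble(TP = TP, FP = FP, FN = FN, TN = TN),
         metrics = metrics, undefined = undefined),
    class = "ltr_benchmark"
  )
}

#' Benchmark a predicted annotation
#'
#' Convenience wrapper chaining [confusion_counts()] and
#' [metrics_from_counts()].
#'
#' @inheritParams confusion_counts
#' @return An `ltr_benchmark` object.
#' @export
benchmark_annotation <- function(truth, pred, seq_lengths) {
  metrics_from_counts(confusion_counts(truth, pred, seq_lengths))
}

#' @export
print.ltr_benchmark <- function(x, ...) {
  cat("<ltr_benchmark>\n")
  cat(sprintf("  TP=%d FP=%d FN=%d TN=%d bp\n", x$counts$TP, x$counts$FP,
              x$counts$FN, x$counts$TN))
  m <- x$metrics
  for (k in names(m)) {
    cat(sprintf("  %-12s %s\n", k,
                ifelse(is.na(m[[k]]), "undefined", sprintf("%.4f", m[[k]]))))
  }
  invisible(x)
}

#' Tidy a benchmark result
#'
#' @param x An `ltr_benchmark` object.
#' @param ... Unused.
#' @return A long tibble `metric`, `value`.
#' @export
tidy.ltr_benchmark <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' @rdname tidy.ltr_benchmark
#' @return `glance()`: a one-row tibble of counts and metrics.
#' @export
glance.ltr_benchmark <- function(x, ...) {
  dplyr::bind_cols(x$counts, x$metrics)
}

#' Write a benchmark as a one-row TSV
#'
#' @param x An `ltr_benchmark` object.
#' @param path Output path.
#' @export
write_benchmark_tsv <- function(x, path) {
  write_tsv_plain(glance(x), path)
}
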