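#' Route code suggestions into auto-coded vs expert-review queues
#'
#' Records whose rank-1 confidence is at least the threshold are coded
#' automatically with that code fixed; the rest keep their full suggestion
#' list for expert review. Note the convention: confidence equal to the
#' threshold auto-codes (the threshold is lower-inclusive). Thresholds
#' above 1 are clamped to 1.
#'
#' @param suggestions data frame from [predict_topk()] (`entry_id`,
#'   `rank`, `code`, `confidence`).
#' @param threshold confidence threshold in `[0, 1]`; default 0.95, the
#'   conventional operating point.
#' @return list with `auto_coded` (one row per auto-coded record) and
#'   `review_queue` (all suggestion rows of the remaining records).
#' @export
route <- function(suggestions, threshold = 0.95) {
  stopifnot(is.data.frame(suggestions),
            all(c("entry_id", "rank", "code", "confidence") %in%
                  names(suggestions)))
  threshold <- min(max(threshold, 0), 1)
  top <- suggestions[suggestions$rank == 1L, , drop = FALSE]
  if (anyDuplicated(top$entry_id)) {
    stop_data("multiple rank-1 suggestions for one entry")
  }
  auto_ids <- top$entry_id[top$confidence >= threshold]
  list(auto_coded = top[top$entry_id %in% auto_ids, , drop = FALSE],
       review_queue = suggestions[!suggestions$entry_id %in% auto_ids, ,
                                  drop = FALSE])
}

#' Group suggestions into 5% confidence bins
#'
#' Twenty bins cover 0-100%: `[0,5), [5,10), ..., [90,95), [95,100]`; bin
#' edges are lower-inclusive and the top bin is closed. When correctness
#' is known, per-bin accuracy is reported (NA for empty bins).
#'
#' @param confidence numeric vector of rank-1 confidence scores in
#'   `[0, 1]`, or a suggestions data frame (its rank-1 rows are used).
#' @param correct optional logical vector: was the suggestion correct?
#'   Must align with `confidence`.
#' @return data frame with 20 rows: `lo`, `hi` (percent), `count`,
#'   `proportion`, `accuracy` (percent or NA).
#' @export
bin_by_confidence <- function(confidence, correct = NULL) {
  if (is.data.frame(confidence)) {
    confidence <- confidence$confidence[confidence$rank == 1L]
  }
  confidence <- as.numeric(confidence)
  if (any(!is.finite(confidence)) || any(confidence < 0 | confidence > 1)) {
    stop_data("confidence scores must lie in [0, 1]")
  }
  if (!is.null(correct) && length(correct) != length(confidence)) {
    stop_data("`correct` must align with `confidence`")
  }
  # epsilon guards against values like 0.35 whose *20 lands just below an
  # integer in floating point; 0.95+ falls in the closed top bin
  idx <- pmin(floor(confidence * 20 + 1e-9) + 1L, 20L)
  count <- tabulate(idx, nbins = 20L)
  total <- length(confidence)
  acc <- rep(NA_real_, 20L)
  if (!is.null(correct)) {
    for (b in which(count > 0L)) {
      acc[b] <- 100 * mean(correct[idx == b])
    }
  }
  data.frame(lo = seq(0, 95, by = 5), hi = seq(5, 100, by = 5),
             count = count,
             proportion = if (total) count / total else rep(0, 20L),
             accuracy = acc)
}

#' Estimate the minimum human workload reduction
#'
#' If `fraction_above` percent of suggestions clear the confidence
#' threshold and `accuracy_above` percent of those are correct, then
#' auto-coding removes `fraction_above * accuracy_above / 100` percent of
#' the records from the expert's queue without loss (the incorrect
#' auto-coded remainder still needs correcting, hence "minimum").
#' Reported to one decimal, the conventional precision.
#'
#' @param fraction_above percent of suggestions at or above the threshold.
#' @param accuracy_above percent correct among those.
#' @return workload reduction in percent, one decimal.
#' @export
#' @examples
#' estimate_workload_reduction(57.41, 97.02)  # 55.7
estimate_workload_reduction <- function(fraction_above, accuracy_above) {
  for (v in list(fraction_above, accuracy_above)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) ||
        v < 0 || v > 100) {
      stop_data("inputs must be single percentages in [0, 100]")
    }
  }
  round(fraction_above * accuracy_above / 100, 1)
}

#' Measure workload reduction on scored suggestions
#'
#' Computes the fraction of suggestions at or above the threshold, their
#' accuracy, and the implied minimum workload reduction, from data.
#'
#' @param confidence rank-1 confidence scores in `[0, 1]`.
#' @param correct logical vector: was the rank-1 suggestion correct?
#' @param threshold confidence threshold in `[0, 1]`.
#' @return list with `threshold`, `fraction_above`, `accuracy_above`
#'   (both percent) and `reduction` (percent, one decimal).
#' @export
workload_estimate <- function(confidence, correct, threshold = 0.95) {
  stopifnot(length(confidence) == length(correct), length(confidence) > 0)
  above <- confidence >= threshold
  fraction_above <- 100 * mean(above)
  accuracy_above <- if (any(above)) 100 * mean(correct[above]) else NA_real_
  list(threshold = threshold,
       fraction_above = fraction_above,
       accuracy_above = accuracy_above,
       reduction = if (is.na(accuracy_above)) 0 else
         estimate_workload_reduction(fraction_above, accuracy_above))
}
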