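#' Per-nucleotide event rates
#'
#' The event rate (drop-off rate for stop-based chemistries, mutation rate
#' for mutational profiling) at a position is the event count divided by the
#' read coverage. Positions with coverage below `max(1, min_coverage)` carry
#' an explicit missing marker (`NA`) that is propagated, never silently
#' zeroed, through every later stage.
#'
#' @param x A [count_table()].
#' @param sample_id One sample id present in `x`.
#' @param min_coverage Minimum coverage for a rate to be defined (default 0,
#'   i.e. any covered position qualifies; coverage 0 is always missing).
#'
#' @return A `rate_track`: data frame with columns `transcript`, `position`,
#'   `rate` (in `[0, 1]` or `NA`) plus a `coverage` column retained for
#'   pairing comparisons downstream.
#' @export
compute_event_rate <- function(x, sample_id, min_coverage = 0) {
  stopifnot(inherits(x, "count_table"))
  if (!sample_id %in% table_samples(x)) {
    stop("unknown sample: ", sample_id, call. = FALSE)
  }
  cov <- x$coverage[, sample_id]
  ev <- x$events[, sample_id]
  rate <- ifelse(cov >= max(1, min_coverage), ev / cov, NA_real_)
  structure(
    data.frame(transcript = x$info$transcript, position = x$info$position,
               rate = rate, coverage = cov, stringsAsFactors = FALSE),
    class = c("rate_track", "data.frame"))
}

check_aligned <- function(a, b) {
  if (!identical(a$transcript, b$transcript) ||
      !identical(a$position, b$position)) {
    stop("rate tracks are not aligned on transcript and position",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Normalize event rates to a denatured control
#'
#' For mutational-profiling data a chemically denatured, fully reactive
#' sample measures the per-position ceiling of the mutation rate; dividing
#' treated and control rates by the denatured rate removes sequence-dependent
#' detection biases. The denatured rate is floored to keep the ratio finite
#' and the result is capped so that downstream log-ratios remain bounded.
#'
#' @param rates,denatured_rates Aligned `rate_track`s (same transcripts and
#'   positions, in order).
#' @param floor Lower bound applied to the denatured rate before division
#'   (default `1e-3`). Must be positive.
#' @param cap Upper clip for the normalized rate (default 10).
#' @return A `rate_track` with `rate` replaced by the normalized rate;
#'   positions where the denatured rate is missing become missing.
#' @export
denatured_normalize <- function(rates, denatured_rates, floor = 1e-3,
                                cap = 10) {
  stopifnot(floor > 0, cap > 0)
  check_aligned(rates, denatured_rates)
  den <- pmax(denatured_rates$rate, floor)
  out <- rates
  out$rate <- pmin(rates$rate / den, cap)
  out$rate[is.na(denatured_rates$rate)] <- NA_real_
  out
}
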