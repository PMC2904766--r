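## Minimum-description-length accounting: when an alignment beats the null
## model, per-sequence inclusion thresholds, and the cost of describing the
## pattern width.

#' Description-length gain of an alignment over the null
#'
#' The difference, in bits, between the description length of the data under
#' the unrelated-sequences theory and under the theory that one width-`W`
#' segment per included sequence is related:
#' `gain = S - sum_k log2(L_k - W + 1) - l(W)`,
#' where `S` is the aggregate column score of the alignment, `L_k - W + 1`
#' is the number of possible start positions (the effective length), and
#' `l(W)` is the width description cost: `log2 W_max` when all feasible
#' widths are taken as equally likely (`width_cost_mode = "uniform"`), 0 in
#' `"none"` mode. Positive gain prefers the relatedness theory.
#'
#' @param score Aggregate alignment score `S` in bits.
#' @param lengths Lengths `L_k` of the included sequences.
#' @param width Pattern width `W`.
#' @param width_cost_mode `"uniform"` or `"none"`.
#' @param w_max Maximum feasible width used in uniform mode; defaults to
#'   `min(lengths)`.
#' @return Gain in bits.
#' @export
description_gain <- function(score, lengths, width,
                             width_cost_mode = c("uniform", "none"),
                             w_max = NULL) {
  width_cost_mode <- match.arg(width_cost_mode)
  lengths <- as.numeric(lengths)
  if (length(lengths) && any(width > lengths)) {
    stop("width exceeds an included sequence length")
  }
  lw <- if (width_cost_mode == "uniform") {
    if (is.null(w_max)) w_max <- if (length(lengths)) min(lengths) else width
    log2(w_max)
  } else 0
  score - sum(log2(lengths - width + 1)) - lw
}

#' Score threshold for including a sequence
#'
#' A sequence's incremental alignment score must exceed
#' `log2(L_eff) + log2((1 - pi) / pi)` bits for its inclusion to shorten the
#' total description: `log2 L_eff` pays for the segment's start position and
#' the prior-odds term rewards sequences expected to carry the pattern.
#' Returns `-Inf` when `pi = 1` (always include) and `Inf` when `pi = 0`.
#'
#' @param l_eff Effective length `L - W + 1` (>= 1).
#' @param inclusion_prior Prior probability `pi` in `[0, 1]` that the
#'   sequence carries the pattern.
#' @return Threshold in bits.
#' @export
inclusion_threshold <- function(l_eff, inclusion_prior = 0.5) {
  if (any(l_eff < 1)) stop("effective length must be >= 1")
  if (any(inclusion_prior < 0 | inclusion_prior > 1)) {
    stop("inclusion prior must lie in [0, 1]")
  }
  ifelse(inclusion_prior == 1, -Inf,
         ifelse(inclusion_prior == 0, Inf,
                log2(l_eff) + log2((1 - inclusion_prior) / inclusion_prior)))
}

#' Optimal contiguous extent along a fixed diagonal
#'
#' Given per-column scores for all candidate columns at fixed relative
#' offsets, finds the contiguous interval with maximal aggregate score. The
#' empty interval (score 0) is permitted; ties are broken towards the
#' leftmost start, then the shortest interval.
#'
#' @param column_scores Numeric vector of per-column scores (bits).
#' @return A list with `start`, `end` (1-based inclusive; `start = 1L,
#'   end = 0L` for the empty interval) and `score`.
#' @export
optimal_extent_on_diagonal <- function(column_scores) {
  n <- length(column_scores)
  best_score <- 0
  best_start <- 1L
  best_end <- 0L
  run_score <- 0
  run_start <- 1L
  for (i in seq_len(n)) {
    if (run_score < 0) {   # restart: a negative prefix never helps
      run_score <- 0
      run_start <- i
    }
    run_score <- run_score + column_scores[i]
    better <- run_score > best_score + 1e-12 ||
      (abs(run_score - best_score) <= 1e-12 && best_end > 0L &&
         (run_start < best_start ||
            (run_start == best_start && i < best_end)))
    if (better) {
      best_score <- run_score
      best_start <- run_start
      best_end <- i
    }
  }
  list(start = best_start, end = best_end, score = best_score)
}
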