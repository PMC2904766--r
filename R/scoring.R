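## BILD column scores and the per-column quantities derived from them:
## incremental letter scores (PSSM entries), column-column scores, and the
## mean incremental / normalized summaries used for position-specific gap
## costs.

#' BILD score of one alignment column
#'
#' The log-odds, in bits, of the column's letter counts under the
#' relatedness model (prior integrated out) against the i.i.d. background:
#' `S = log2 P(counts | prior) - sum_j c_j log2 p_j`. The score is invariant
#' under permutation of the column's letters and decomposes into a sum of
#' incremental letter scores for any observation order.
#'
#' @param prior A [dirichlet_mixture()].
#' @param counts Numeric count vector (fractional counts allowed), or letters
#'   accepted by [count_vector()] if `alphabet` is given.
#' @param background Strictly positive background probabilities.
#' @return Score in bits; 0 for an empty column.
#' @examples
#' a <- dna_alphabet()
#' u <- dirichlet_mixture(1, c(1, 1, 1, 1))
#' column_score(u, count_vector("AATC", a), a$background)  # log2(256/420)
#' @export
column_score <- function(prior, counts, background) {
  stopifnot_mixture(prior)
  counts <- check_counts(counts, ncol(prior$alpha))
  if (any(background <= 0)) stop("background must be strictly positive")
  column_marginal(prior, counts, log = TRUE) / log(2) -
    sum(counts * log2(background))
}

#' Incremental letter score against a column
#'
#' The bit score for adding one (possibly fractional) observation of `letter`
#' to a column whose counts are already absorbed into the prior: the
#' sequence-to-profile substitution score. Satisfies
#' `column_score(counts + w e_a) - column_score(counts)` exactly.
#'
#' @inheritParams column_score
#' @param letter 1-based letter index.
#' @param weight Observation weight in (0, 1].
#' @export
incremental_letter_score <- function(prior, counts, letter, background,
                                     weight = 1) {
  post <- posterior_from_counts(prior, check_counts(counts, ncol(prior$alpha)))
  log2(predictive_probability(post, letter, weight)) -
    weight * log2(background[check_letter(letter, post)])
}

## Vector of unit-weight incremental scores for every letter of the alphabet:
## one PSSM row. log2 of posterior predictive over background.
incremental_score_row <- function(prior, counts, background) {
  post <- posterior_from_counts(prior, counts)
  log2(predictive_distribution(post)) - log2(background)
}

#' Column-column alignment score
#'
#' The bit score for aligning two columns: the score of their concatenation
#' minus the scores of the parts, `S(x + y) - S(x) - S(y)`. Symmetric in its
#' arguments; aligning against an empty column scores 0.
#'
#' @inheritParams column_score
#' @param counts_x,counts_y Count vectors over the same alphabet.
#' @export
column_column_score <- function(prior, counts_x, counts_y, background) {
  column_score(prior, counts_x + counts_y, background) -
    column_score(prior, counts_x, background) -
    column_score(prior, counts_y, background)
}

#' Profile models
#'
#' An ordered set of alignment columns over a shared alphabet and prior.
#' Each column stores its constituent observations as (sequence id, letter,
#' weight) triples, so that leave-one-out score matrices are exact rather
#' than approximate.
#'
#' @param prior A [dirichlet_mixture()].
#' @param alphabet A [bild_alphabet()].
#' @param observations A list with one element per column; each element is a
#'   data.frame with columns `seq` (id), `letter` (index, NA allowed for
#'   skipped ambiguity codes) and `weight`.
#' @param background Background probabilities for scoring; defaults to the
#'   alphabet's.
#' @return An object of class `bild_profile` with cached per-column counts.
#' @export
bild_profile <- function(prior, alphabet, observations,
                         background = alphabet$background) {
  stopifnot_mixture(prior, n_letters(alphabet))
  W <- length(observations)
  if (W < 1L) stop("a profile needs at least one column")
  counts <- t(vapply(observations, function(ob) {
    count_vector(ob$letter, alphabet, ob$weight)
  }, numeric(n_letters(alphabet))))
  structure(list(prior = prior, alphabet = alphabet, background = background,
                 observations = observations, counts = counts, width = W),
            class = "bild_profile")
}

## profile from an ungapped alignment: one window of width W per included
## sequence starting at offsets (1-based).
profile_from_offsets <- function(seqs, offsets, W, prior,
                                 background = seqs$alphabet$background) {
  inc <- which(!is.na(offsets))
  obs <- lapply(seq_len(W), function(j) {
    data.frame(
      seq = seqs$id[inc],
      letter = vapply(inc, function(k) seqs$residues[[k]][offsets[k] + j - 1L],
                      integer(1)),
      weight = seqs$weight[inc])
  })
  bild_profile(prior, seqs$alphabet, obs, background)
}

#' @export
print.bild_profile <- function(x, ...) {
  cat("BILD profile:", x$width, "columns,",
      sum(x$counts) / max(1, x$width), "mean observations per column\n")
  invisible(x)
}

## counts matrix with one sequence's observations removed (exact removal via
## the stored per-observation lists).
counts_excluding <- function(profile, seq_id) {
  counts <- profile$counts
  for (j in seq_len(profile$width)) {
    ob <- profile$observations[[j]]
    hit <- ob$seq == seq_id & !is.na(ob$letter)
    if (any(hit)) {
      rem <- count_vector(ob$letter[hit], profile$alphabet, ob$weight[hit])
      counts[j, ] <- counts[j, ] - rem
    }
  }
  pmax(counts, 0)
}

#' Position-specific score matrix from a profile
#'
#' Builds the `W x r` matrix of incremental BILD letter scores, optionally
#' after exact removal of one sequence's observations (the leave-one-out
#' matrix used when realigning that sequence). Also returns the per-column
#' summaries: the column BILD score `S_j`, the background-mean incremental
#' score `s_bar_j = sum_a p_a log2(phat_a / p_a)` (always non-positive), and
#' the normalized score `s_prime_j = S_j / n_j`.
#'
#' @param profile A [bild_profile()].
#' @param exclude_sequence_id Id of a sequence to remove first, or `NULL`.
#' @return A list with `pssm` (W x r, bits), `score` (per-column BILD score),
#'   `s_bar`, `s_prime`, and the counts matrix used.
#' @export
build_pssm <- function(profile, exclude_sequence_id = NULL) {
  counts <- if (is.null(exclude_sequence_id)) {
    profile$counts
  } else {
    present <- any(vapply(profile$observations, function(ob) {
      any(ob$seq == exclude_sequence_id)
    }, logical(1)))
    if (!present) {
      message("sequence '", exclude_sequence_id,
              "' not present in profile; nothing removed")
    }
    counts_excluding(profile, exclude_sequence_id)
  }
  pssm_from_counts(profile$prior, counts, profile$background)
}

pssm_from_counts <- function(prior, counts, background) {
  W <- nrow(counts)
  r <- ncol(counts)
  pssm <- matrix(0, W, r)
  score <- numeric(W)
  s_bar <- numeric(W)
  for (j in seq_len(W)) {
    pssm[j, ] <- incremental_score_row(prior, counts[j, ], background)
    score[j] <- column_score(prior, counts[j, ], background)
    s_bar[j] <- sum(background * pssm[j, ])
  }
  n <- rowSums(counts)
  list(pssm = pssm, score = score, s_bar = s_bar,
       s_prime = ifelse(n > 0, score / n, 0), counts = counts)
}
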