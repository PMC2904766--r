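## Gibbs sampler for ungapped local multiple alignment. The objective is the
## aggregate BILD score of the aligned columns minus the description-length
## costs for segment start positions, inclusion indicators and pattern width.

## PSSM matrix only (no per-column summaries); fast path for single-Dirichlet
## priors where the posterior predictive is (alpha + c) / (alpha* + n).
pssm_matrix <- function(prior, counts_mat, background) {
  if (n_components(prior) == 1L) {
    a <- prior$alpha[1L, ]
    num <- sweep(counts_mat, 2L, a, `+`)
    pred <- num / (prior$alpha_star[1L] + rowSums(counts_mat))
    sweep(log2(pred), 2L, log2(background), `-`)
  } else {
    t(apply(counts_mat, 1L, function(cc) {
      incremental_score_row(prior, cc, background)
    }))
  }
}

## incremental BILD score of every width-W window of a sequence against a
## PSSM: s(x) = sum_j pssm[j, res[x + j - 1]].
window_scores <- function(pssm, res) {
  W <- nrow(pssm)
  nx <- length(res) - W + 1L
  if (nx < 1L) return(numeric(0))
  sc <- numeric(nx)
  for (j in seq_len(W)) {
    lj <- res[j:(j + nx - 1L)]
    v <- pssm[j, lj]
    v[is.na(lj)] <- 0     # skipped ambiguity codes contribute nothing
    sc <- sc + v
  }
  sc
}

window_counts <- function(res, offset, W, alphabet, weight = 1) {
  count_vector(res[offset:(offset + W - 1L)], alphabet, weight)
}

counts_matrix_from_offsets <- function(seqs, offsets, W) {
  r <- n_letters(seqs$alphabet)
  counts <- matrix(0, W, r)
  for (k in which(!is.na(offsets))) {
    res <- seqs$residues[[k]]
    for (j in seq_len(W)) {
      l <- res[offsets[k] + j - 1L]
      if (!is.na(l)) counts[j, l] <- counts[j, l] + seqs$weight[k]
    }
  }
  counts
}

## odds term log2((1-pi)/pi), clamped so objectives stay finite
log_odds_excl <- function(p) {
  pmin(pmax(log2((1 - p) / p), -1e6), 1e6)
}

## MDL-adjusted objective of an alignment state (recomputed from scratch)
state_objective <- function(seqs, offsets, W, prior, background) {
  inc <- which(!is.na(offsets))
  if (length(inc) == 0L) return(0)
  counts <- counts_matrix_from_offsets(seqs, offsets, W)
  S <- sum(vapply(seq_len(W), function(j) {
    column_score(prior, counts[j, ], background)
  }, numeric(1)))
  L <- seq_lengths(seqs)[inc]
  S - sum(log2(L - W + 1) + log_odds_excl(seqs$inclusion_prior[inc])) -
    log2(min(L))
}

#' Sample one sequence's offset (or exclusion) given the others
#'
#' Draws a start position with probability proportional to
#' `2^(s(x)/temperature)`, where `s(x)` is the incremental BILD score of the
#' width-`W` window at `x` against the profile built from the other
#' sequences. When exclusion is allowed, an "exclude" outcome competes with
#' weight `2^(threshold/temperature)`, with the threshold from
#' [inclusion_threshold()].
#'
#' @param res Integer residue vector of the sequence being sampled.
#' @param pssm Leave-one-out PSSM (W x r, bits).
#' @param temperature Sampling temperature; as it tends to 0 the argmax is
#'   taken.
#' @param exclude_threshold Inclusion threshold in bits, or `NULL` to forbid
#'   exclusion.
#' @return The sampled 1-based offset, or `NA` for exclusion.
#' @export
sample_offset <- function(res, pssm, temperature = 1,
                          exclude_threshold = NULL) {
  s <- window_scores(pssm, res)
  if (length(s) == 0L) {
    warning("sequence shorter than profile width; excluded")
    return(NA_integer_)
  }
  if (!is.null(exclude_threshold)) {
    if (exclude_threshold == Inf) return(NA_integer_)
    if (exclude_threshold == -Inf) exclude_threshold <- NULL
  }
  v <- s
  if (!is.null(exclude_threshold)) v <- c(v, exclude_threshold)
  if (temperature <= 1e-9) {
    pick <- which(v >= max(v) - 1e-12)
    pick <- if (length(pick) > 1L) pick[sample.int(length(pick), 1L)] else pick
  } else {
    lw <- v / temperature
    p <- 2^(lw - max(lw))
    pick <- sample.int(length(v), 1L, prob = p)
  }
  if (!is.null(exclude_threshold) && pick == length(v)) NA_integer_
  else as.integer(pick)
}

#' Re-optimize the alignment width along the implied diagonal
#'
#' With offsets fixed, scores every candidate column the offsets allow
#' (current columns plus both flanks), finds the maximal-sum contiguous
#' interval subject to the width bounds, and shifts offsets and width
#' accordingly. The objective never decreases under this move; an empty
#' optimal interval leaves the state unchanged (flagged).
#'
#' @param seqs A [bild_sequences()].
#' @param offsets Integer offsets (NA = excluded).
#' @param W Current width.
#' @param prior,background Scoring model.
#' @param min_width,max_width Width bounds.
#' @return A list with `offsets`, `W`, `changed` and `empty` flags.
#' @export
update_width <- function(seqs, offsets, W, prior, background,
                         min_width = 2L, max_width = Inf) {
  inc <- which(!is.na(offsets))
  if (length(inc) == 0L) {
    return(list(offsets = offsets, W = W, changed = FALSE, empty = TRUE))
  }
  L <- seq_lengths(seqs)[inc]
  x <- offsets[inc]
  a <- min(x) - 1L                      # available left extension
  b <- min(L - (x + W - 1L))            # available right extension
  a <- min(a, max_width)
  b <- min(b, max_width)
  rel <- (-a):(W - 1L + b)              # candidate columns, 0-based rel. start
  cs <- vapply(rel, function(d) {
    letters <- vapply(seq_along(inc), function(i) {
      seqs$residues[[inc[i]]][x[i] + d]
    }, integer(1))
    column_score(prior, count_vector(letters, seqs$alphabet,
                                     seqs$weight[inc]), background)
  }, numeric(1))
  ext <- optimal_extent_on_diagonal(cs)
  len <- ext$end - ext$start + 1L
  if (ext$end == 0L) {
    return(list(offsets = offsets, W = W, changed = FALSE, empty = TRUE))
  }
  if (len < min_width || len > max_width) {
    ## constrained search over all intervals with admissible length
    n <- length(cs)
    P <- c(0, cumsum(cs))
    best <- -Inf; bs <- 1L; bl <- W
    for (l in seq(min_width, min(max_width, n))) {
      sums <- P[(l + 1L):(n + 1L)] - P[1:(n - l + 1L)]
      i <- which.max(sums)
      if (sums[i] > best + 1e-12) { best <- sums[i]; bs <- i; bl <- l }
    }
    ext <- list(start = bs, end = bs + bl - 1L, score = best)
    len <- bl
  }
  d0 <- rel[ext$start]
  new_off <- offsets
  new_off[inc] <- x + d0
  list(offsets = new_off, W = len,
       changed = !(len == W && d0 == 0L), empty = FALSE)
}

#' Gibbs sampler for ungapped local multiple alignment
#'
#' Lawrence-style Gibbs sampling with BILD-score window weights: each sweep
#' visits the sequences in random order, rebuilds the leave-one-out profile,
#' and resamples the sequence's offset (optionally against an exclusion
#' outcome priced by the description-length inclusion threshold). Every
#' `width_update_every` sweeps the width is re-optimized along the implied
#' diagonal. The best MDL-adjusted state over all restarts is returned.
#' Exclusion sampling is disabled for the first quarter of each restart's
#' sweeps so a profile can form.
#'
#' @param seqs A [bild_sequences()] (at least 2 sequences).
#' @param prior A [dirichlet_mixture()].
#' @param seed Integer seed; same seed and inputs give identical output.
#' @param restarts,sweeps Number of random restarts and sweeps per restart.
#' @param min_width,max_width Width bounds; the initial width is their
#'   midpoint (capped by the shortest sequence).
#' @param temperature Gibbs temperature (1 = exact conditional sampling).
#' @param anneal If `TRUE`, temperature decays geometrically towards 0 over
#'   the final 10\% of sweeps.
#' @param exclusion Allow sequences to drop out of the alignment.
#' @param background Background probabilities; defaults to the prior's
#'   implied background.
#' @param width_update_every Sweeps between width updates.
#' @param patience Stop a restart after this many sweeps without improvement.
#' @return A list of class `bild_gibbs` with `width`, `offsets` (NA =
#'   excluded), `objective` (MDL-adjusted bits), and `per_sequence`, a
#'   data.frame of per-sequence incremental scores adjusted by the log
#'   effective length.
#' @export
run_sampler <- function(seqs, prior, seed = NULL, restarts = 10L,
                        sweeps = 200L, min_width = 8L, max_width = 60L,
                        temperature = 1, anneal = FALSE, exclusion = TRUE,
                        background = NULL, width_update_every = 5L,
                        patience = 50L) {
  stopifnot_mixture(prior, n_letters(seqs$alphabet))
  if (is.null(background)) background <- implied_background(prior)
  L <- seq_lengths(seqs)
  if (sum(L >= min_width) < 2L) {
    stop("need at least two sequences at least min_width long")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(seqs)
  W0 <- min(as.integer(round((min_width + max_width) / 2)), min(L))
  best <- list(objective = -Inf)

  for (rs in seq_len(restarts)) {
    W <- W0
    offsets <- vapply(seq_len(n), function(k) {
      if (L[k] < W) NA_integer_ else sample.int(L[k] - W + 1L, 1L)
    }, integer(1))
    counts <- counts_matrix_from_offsets(seqs, offsets, W)
    best_obj_rs <- -Inf
    stall <- 0L
    for (sw in seq_len(sweeps)) {
      temp <- temperature
      if (anneal && sw > 0.9 * sweeps) {
        frac <- (sw - 0.9 * sweeps) / (0.1 * sweeps)
        temp <- temperature * 0.05^frac
      }
      allow_excl <- exclusion && sw > 0.25 * sweeps
      for (k in sample.int(n)) {
        if (L[k] < W) { offsets[k] <- NA_integer_; next }
        if (!is.na(offsets[k])) {
          counts <- counts - counts_matrix_from_offsets(
            seqs_subset_stub(seqs, k), offsets[k], W)
        }
        pssm <- pssm_matrix(prior, counts, background)
        thr <- if (allow_excl) {
          inclusion_threshold(L[k] - W + 1, seqs$inclusion_prior[k])
        } else NULL
        offsets[k] <- suppressWarnings(
          sample_offset(seqs$residues[[k]], pssm, temp, thr))
        if (!is.na(offsets[k])) {
          counts <- counts + counts_matrix_from_offsets(
            seqs_subset_stub(seqs, k), offsets[k], W)
        }
      }
      if (sw %% width_update_every == 0L) {
        upd <- update_width(seqs, offsets, W, prior, background,
                            min_width, min(max_width, min(L)))
        if (upd$changed) {
          offsets <- upd$offsets
          W <- upd$W
          counts <- counts_matrix_from_offsets(seqs, offsets, W)
        }
      }
      obj <- state_objective(seqs, offsets, W, prior, background)
      if (obj > best_obj_rs + 1e-9) {
        best_obj_rs <- obj
        stall <- 0L
      } else stall <- stall + 1L
      if (obj > best$objective + 1e-9) {
        best <- list(objective = obj, offsets = offsets, W = W)
      }
      if (stall >= patience) break
    }
  }
  finish_gibbs(seqs, prior, background, best)
}

## single-sequence view used for incremental count bookkeeping
seqs_subset_stub <- function(seqs, k) {
  structure(list(id = seqs$id[k], residues = seqs$residues[k],
                 weight = seqs$weight[k],
                 inclusion_prior = seqs$inclusion_prior[k],
                 alphabet = seqs$alphabet),
            class = "bild_sequences")
}

finish_gibbs <- function(seqs, prior, background, best) {
  offsets <- best$offsets
  W <- best$W
  inc <- which(!is.na(offsets))
  L <- seq_lengths(seqs)
  per <- data.frame(seq_id = seqs$id, offset = offsets,
                    adjusted_score = NA_real_)
  counts <- counts_matrix_from_offsets(seqs, offsets, W)
  for (k in inc) {
    own <- counts_matrix_from_offsets(seqs_subset_stub(seqs, k), offsets[k], W)
    loo <- counts - own
    pssm <- pssm_matrix(prior, loo, background)
    s <- window_scores(pssm, seqs$residues[[k]])[offsets[k]]
    per$adjusted_score[k] <- s - log2(L[k] - W + 1)
  }
  structure(list(width = W, offsets = offsets, objective = best$objective,
                 per_sequence = per, counts = counts, prior = prior,
                 background = background),
            class = "bild_gibbs")
}

#' @export
print.bild_gibbs <- function(x, ...) {
  cat("Gibbs alignment: width", x$width, "| included",
      sum(!is.na(x$offsets)), "of", length(x$offsets),
      sprintf("| objective %.2f bits\n", x$objective))
  invisible(x)
}
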