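## Program 1: iterative gapped local multiple alignment. Each round rebuilds
## a leave-one-out BILD PSSM per sequence, realigns the whole profile to the
## best segment of the sequence by semi-global (Erickson-Sellers) dynamic
## programming with asymmetric affine gap costs, retains positive-score hits
## for the next profile, and stops when the MDL-adjusted objective stops
## increasing.

#' Affine gap parameters
#'
#' Costs in bits: an insertion of length `l` into the motif costs
#' `ins_open + ins_extend * l`; a deletion of `l` profile columns costs
#' `del_open + del_extend * l`. Under the mapping `extend = -log2 q`,
#' `open + extend = -log2(f (1 - q))` these correspond to a gap initiation
#' frequency `f` per motif position and mean length `1 / (1 - q)`; the
#' defaults give insertions at frequency 0.87\% with mean length about 6.3
#' and deletions at 0.28\% with mean length 2.0. `no_gap_penalty` is the cost
#' of *not* opening a gap at an aligned letter, `-log2(1 - f_ins - f_del)`
#' by default, so that bit scores retain their probabilistic meaning.
#'
#' @param ins_open,ins_extend,del_open,del_extend Gap costs in bits.
#' @param no_gap_penalty Per-aligned-letter penalty; `NULL` computes the
#'   default from the gap frequencies.
#' @param report_threshold Minimum bit score for a hit to be reported.
#' @param symmetric If `TRUE`, deletion costs are set equal to insertion
#'   costs (for benchmarks whose generator makes no insertion/deletion
#'   asymmetry).
#' @return An object of class `gap_params`.
#' @export
gap_params <- function(ins_open = 9.25, ins_extend = 0.25,
                       del_open = 8.5, del_extend = 1.0,
                       no_gap_penalty = NULL, report_threshold = -25,
                       symmetric = FALSE) {
  if (symmetric) {
    del_open <- ins_open
    del_extend <- ins_extend
  }
  if (ins_extend <= 0 || del_extend <= 0) stop("extend costs must be > 0")
  if (ins_open < 0 || del_open < 0) stop("open costs must be >= 0")
  gp <- list(ins_open = ins_open, ins_extend = ins_extend,
             del_open = del_open, del_extend = del_extend,
             report_threshold = report_threshold, symmetric = symmetric)
  if (is.null(no_gap_penalty)) {
    fr <- gap_frequencies(gp)
    no_gap_penalty <- -log2(1 - fr$ins$frequency - fr$del$frequency)
  }
  if (no_gap_penalty < 0) stop("no_gap_penalty must be >= 0")
  gp$no_gap_penalty <- no_gap_penalty
  class(gp) <- "gap_params"
  gp
}

#' @rdname gap_params
#' @param params A `gap_params` object.
#' @return `gap_frequencies()` returns, for each gap type, the implied
#'   initiation frequency per motif position and mean gap length.
#' @export
gap_frequencies <- function(params) {
  one <- function(open, extend) {
    q <- 2^(-extend)
    list(frequency = 2^(-(open + extend)) / (1 - q),
         mean_length = 1 / (1 - q))
  }
  list(ins = one(params$ins_open, params$ins_extend),
       del = one(params$del_open, params$del_extend))
}

## Core vectorized Gotoh-style DP. del_ext may be a per-column vector and
## ins_allowed a logical vector over the W-1 internal junctions (used by the
## profile HMM); for Program 1 both are uniform. Returns matrices for
## traceback.
semiglobal_dp <- function(pssm, res, eps, ins_open, ins_ext, del_open,
                          del_ext, ins_allowed = NULL) {
  W <- nrow(pssm)
  L <- length(res)
  del_ext <- rep_len(del_ext, W)
  if (is.null(ins_allowed)) ins_allowed <- rep(TRUE, max(0L, W - 1L))
  M <- matrix(-Inf, W + 1L, L + 1L)
  D <- matrix(-Inf, W + 1L, L + 1L)
  I <- matrix(-Inf, W + 1L, L + 1L)
  idx <- seq_len(L)
  for (j in seq_len(W)) {
    emis <- pssm[j, res]
    emis[is.na(res)] <- 0
    if (j == 1L) {
      bprev <- rep(0, L + 1L)      # free left flank
      miprev <- rep(0, L + 1L)
      dprev <- rep(-Inf, L + 1L)
    } else {
      bprev <- pmax(M[j, ], D[j, ], I[j, ])
      miprev <- pmax(M[j, ], I[j, ])
      dprev <- D[j, ]
    }
    M[j + 1L, ] <- c(-Inf, bprev[idx] + emis - eps)
    D[j + 1L, ] <- pmax(miprev - (del_open + del_ext[j]),
                        dprev - del_ext[j])
    if (j < W && ins_allowed[j]) {
      g <- pmax(M[j + 1L, ], D[j + 1L, ]) - ins_open + (0:L) * ins_ext
      I[j + 1L, ] <- c(-Inf, cummax(g)[idx] - idx * ins_ext)
    }
  }
  list(M = M, D = D, I = I, W = W, L = L)
}

semiglobal_traceback <- function(dp, pssm, res, eps, ins_open, ins_ext,
                                 del_open, del_ext) {
  W <- dp$W; L <- dp$L
  del_ext <- rep_len(del_ext, W)
  M <- dp$M; D <- dp$D; I <- dp$I
  fin <- pmax(M[W + 1L, ], D[W + 1L, ])
  i <- which.max(fin) - 1L            # smallest i among ties
  score <- fin[i + 1L]
  state <- if (M[W + 1L, i + 1L] >= D[W + 1L, i + 1L] - 1e-9) "M" else "D"
  j <- W
  path <- character(0)
  tol <- 1e-6
  near <- function(a, b) is.finite(a) && abs(a - b) < tol
  while (j >= 1L) {
    if (state == "M") {
      path <- c("M", path)
      emis <- if (is.na(res[i])) 0 else pssm[j, res[i]]
      tgt <- M[j + 1L, i + 1L] - emis + eps
      i <- i - 1L
      if (j == 1L) { j <- 0L; break }
      state <- if (near(M[j, i + 1L], tgt)) "M"
      else if (near(D[j, i + 1L], tgt)) "D"
      else "I"
      j <- j - 1L
    } else if (state == "D") {
      path <- c("D", path)
      v <- D[j + 1L, i + 1L]
      if (j == 1L) { j <- 0L; break }
      state <- if (near(M[j, i + 1L], v + del_open + del_ext[j])) "M"
      else if (near(D[j, i + 1L], v + del_ext[j])) "D"
      else "I"
      j <- j - 1L
    } else {                           # insertion after column j
      path <- c("I", path)
      v <- I[j + 1L, i + 1L]
      i <- i - 1L
      state <- if (near(M[j + 1L, i + 1L], v + ins_open + ins_ext)) "M"
      else if (near(D[j + 1L, i + 1L], v + ins_open + ins_ext)) "D"
      else "I"
    }
  }
  n_consumed <- sum(path != "D")
  end <- which.max(fin) - 1L
  start <- end - n_consumed + 1L
  list(start = as.integer(start), end = as.integer(end),
       path = paste(path, collapse = ""), score = score)
}

#' Semi-global alignment of a profile to a sequence
#'
#' Aligns the *entire* profile (every column matched or deleted, terminal
#' deletions charged like internal ones) to the best-scoring segment of the
#' sequence, with free sequence flanks — a generalization of the
#' Erickson-Sellers algorithm with affine, possibly asymmetric, gap costs.
#' The no-gap penalty is assessed at every letter aligned to a column. Ties
#' are broken deterministically: Match over Delete over Insert, and smaller
#' end coordinate among equal-scoring segments.
#'
#' @param pssm `W x r` matrix of incremental letter scores (bits).
#' @param params A [gap_params()].
#' @param res Integer residue-index vector (NA entries score 0).
#' @return A list (`start`, `end`, `path`, `score`): 1-based inclusive
#'   segment bounds (empty segment has `end < start`), an M/I/D path whose
#'   M+D count equals `W`, and the bit score.
#' @export
semiglobal_align <- function(pssm, params, res) {
  dp <- semiglobal_dp(pssm, res, params$no_gap_penalty, params$ins_open,
                      params$ins_extend, params$del_open, params$del_extend)
  semiglobal_traceback(dp, pssm, res, params$no_gap_penalty,
                       params$ins_open, params$ins_extend,
                       params$del_open, params$del_extend)
}

#' Greedy multi-hit scan of a sequence
#'
#' Repeatedly takes the best semi-global hit, masks its segment, and realigns
#' on the unmasked remainder, until the best score drops below the reporting
#' threshold (or the best hit consumes no residues). Hits never overlap.
#'
#' @inheritParams semiglobal_align
#' @param report_threshold Minimum score to keep scanning; defaults to the
#'   `gap_params` value.
#' @param align_fun Aligner to use on each unmasked stretch; defaults to
#'   [semiglobal_align()]. (The profile-HMM pipeline passes its Viterbi
#'   aligner here.)
#' @param max_hits Safety cap on reported hits.
#' @return A list of hit lists as returned by the aligner, best first, each
#'   with segment coordinates in the original sequence.
#' @export
greedy_scan <- function(pssm, params, res, report_threshold = NULL,
                        align_fun = NULL, max_hits = 25L) {
  if (is.null(report_threshold)) report_threshold <- params$report_threshold
  if (is.null(align_fun)) {
    align_fun <- function(res) semiglobal_align(pssm, params, res)
  }
  L <- length(res)
  masked <- rep(FALSE, L)
  hits <- list()
  repeat {
    runs <- unmasked_runs(masked)
    best <- NULL
    for (rn in runs) {
      h <- align_fun(res[rn$from:rn$to])
      h$start <- h$start + rn$from - 1L
      h$end <- h$end + rn$from - 1L
      if (is.null(best) || h$score > best$score + 1e-12) best <- h
    }
    if (is.null(best) || best$score < report_threshold ||
        best$end < best$start) break
    hits[[length(hits) + 1L]] <- best
    masked[best$start:best$end] <- TRUE
    if (length(hits) >= max_hits || all(masked)) break
  }
  hits
}

unmasked_runs <- function(masked) {
  L <- length(masked)
  runs <- list()
  i <- 1L
  while (i <= L) {
    if (!masked[i]) {
      j <- i
      while (j < L && !masked[j + 1L]) j <- j + 1L
      runs[[length(runs) + 1L]] <- list(from = i, to = j)
      i <- j + 1L
    } else i <- i + 1L
  }
  runs
}

## rebuild a profile from retained hits: M states contribute observations to
## their columns, insertions and deletions contribute nothing.
profile_from_hits <- function(seqs, hits, W, prior, background) {
  obs <- replicate(W, data.frame(seq = character(0), letter = integer(0),
                                 weight = numeric(0)), simplify = FALSE)
  for (i in seq_len(nrow(hits))) {
    k <- match(hits$seq_id[i], seqs$id)
    res <- seqs$residues[[k]]
    pos <- hits$start[i]
    j <- 0L
    for (st in strsplit(hits$path[i], "")[[1]]) {
      if (st == "M") {
        j <- j + 1L
        obs[[j]] <- rbind(obs[[j]], data.frame(
          seq = seqs$id[k], letter = res[pos], weight = seqs$weight[k]))
        pos <- pos + 1L
      } else if (st == "D") {
        j <- j + 1L
      } else pos <- pos + 1L
    }
  }
  bild_profile(prior, seqs$alphabet, obs, background)
}

hits_to_frame <- function(hit_lists, ids) {
  rows <- list()
  for (k in seq_along(hit_lists)) {
    for (h in hit_lists[[k]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = ids[k], start = h$start, end = h$end,
        score_bits = h$score, path = h$path)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), score_bits = numeric(0),
                      path = character(0)))
  }
  do.call(rbind, rows)
}

## objective of a round: retained (positive-score) hits, each paying the
## description cost of its start position and, for the m-th instance within a
## sequence, a Poisson(1) instance-count prior increment of log2(m) bits;
## plus the uniform width cost.
round_objective <- function(hits, seqs, W) {
  if (nrow(hits) == 0L) return(-Inf)
  L <- seq_lengths(seqs)
  obj <- 0
  for (k in unique(hits$seq_id)) {
    hk <- hits[hits$seq_id == k, , drop = FALSE]
    hk <- hk[order(-hk$score_bits), , drop = FALSE]
    Lk <- L[match(k, seqs$id)]
    m <- seq_len(nrow(hk))
    obj <- obj + sum(hk$score_bits - log2(max(Lk - W + 1, 1)) - log2(m))
  }
  obj - log2(min(L))
}

#' Iterative gapped realignment (Program 1 main loop)
#'
#' Starting from an ungapped alignment (typically [run_sampler()] output),
#' each round removes one sequence at a time from the profile, builds the
#' exact leave-one-out PSSM, realigns the sequence — all sequences are
#' realigned, whether or not they previously carried a hit — and retains
#' positive-scoring hits to form the next profile. The loop stops when the
#' MDL-adjusted objective (hit scores minus start-position, instance and
#' width description costs) no longer increases.
#'
#' @param seqs A [bild_sequences()].
#' @param init A `bild_gibbs` result, or a list with `offsets` and `width`.
#' @param prior A [dirichlet_mixture()].
#' @param params A [gap_params()].
#' @param multi Search for multiple non-overlapping instances per sequence.
#' @param max_rounds Round cap (the best round is returned with a warning if
#'   the objective is still oscillating).
#' @param background Defaults to the prior's implied background.
#' @param align_engine Internal: `"affine"` (Program 1) or an HMM builder
#'   function (used by [run_program2()]).
#' @return A list of class `bild_alignment`: `profile`, `hits` (data.frame,
#'   scores down to the reporting threshold), `retained` (the positive-score
#'   hits the final profile is built from), `objective`, `rounds`.
#' @export
iterate_alignment <- function(seqs, init, prior, params, multi = FALSE,
                              max_rounds = 30L, background = NULL,
                              align_engine = "affine") {
  if (is.null(background)) background <- implied_background(prior)
  offsets <- init$offsets
  W <- if (!is.null(init$width)) init$width else init$W
  profile <- profile_from_offsets(seqs, offsets, W, prior, background)
  empty <- hits_to_frame(list(), character(0))
  best <- list(objective = -Inf, hits = empty, retained = empty,
               profile = profile, rounds = 0L)
  prev_obj <- -Inf
  for (round in seq_len(max_rounds)) {
    out <- realign_all(seqs, profile, params, multi, align_engine)
    retained <- out$hits[out$hits$score_bits > 0, , drop = FALSE]
    obj <- round_objective(retained, seqs, profile$width)
    if (obj > best$objective + 1e-9) {
      best <- list(objective = obj, hits = out$hits, retained = retained,
                   profile = profile, rounds = round)
    }
    if (!(obj > prev_obj + 1e-9)) break
    prev_obj <- obj
    if (nrow(retained) == 0L) {
      warning("no positive-scoring hits; stopping")
      break
    }
    profile <- profile_from_hits(seqs, retained, profile$width, prior,
                                 background)
    if (round == max_rounds) {
      warning("objective still increasing after max_rounds; returning best")
    }
  }
  reported <- best$hits[best$hits$score_bits >= params$report_threshold, ,
                        drop = FALSE]
  ## the returned profile is the one the reported hits were scored against,
  ## so every hit score is exactly recomputable from its path
  structure(list(profile = best$profile, hits = reported,
                 retained = best$retained, objective = best$objective,
                 rounds = best$rounds, params = params,
                 background = background),
            class = "bild_alignment")
}

## one full realignment pass over all sequences
realign_all <- function(seqs, profile, params, multi, align_engine) {
  hit_lists <- vector("list", length(seqs))
  for (k in seq_along(seqs$residues)) {
    counts <- counts_excluding(profile, seqs$id[k])
    info <- pssm_from_counts(profile$prior, counts, profile$background)
    align_fun <- if (identical(align_engine, "affine")) {
      function(res) semiglobal_align(info$pssm, params, res)
    } else {
      hmm <- align_engine(info)
      function(res) viterbi_semiglobal(hmm, res)
    }
    res <- seqs$residues[[k]]
    if (multi) {
      hit_lists[[k]] <- greedy_scan(info$pssm, params, res,
                                    align_fun = align_fun)
    } else {
      h <- align_fun(res)
      hit_lists[[k]] <- if (h$score >= params$report_threshold &&
                            h$end >= h$start) list(h) else list()
    }
  }
  list(hits = hits_to_frame(hit_lists, seqs$id))
}

#' @export
print.bild_alignment <- function(x, ...) {
  cat("Gapped alignment: width", x$profile$width, "|", nrow(x$hits),
      sprintf("hits | objective %.2f bits | %d round(s)\n",
              x$objective, x$rounds))
  invisible(x)
}

#' Optimize the profile width at its ends
#'
#' Greedily adds or removes one column at either end of the profile while
#' the MDL-adjusted objective improves, realigning all sequences after every
#' change. New terminal columns take their observations from the residues
#' flanking the current hits. Idempotent at a local optimum.
#'
#' @param alignment A `bild_alignment` from [iterate_alignment()].
#' @param seqs The sequences it was built from.
#' @param params A [gap_params()].
#' @param max_steps Cap on accepted changes.
#' @return An updated `bild_alignment`.
#' @export
adjust_width <- function(alignment, seqs, params, max_steps = 8L) {
  cur <- alignment
  for (step in seq_len(max_steps)) {
    cands <- width_candidates(cur, seqs)
    improved <- FALSE
    for (cand in cands) {
      out <- realign_all(seqs, cand, params, multi = FALSE, "affine")
      retained <- out$hits[out$hits$score_bits > 0, , drop = FALSE]
      obj <- round_objective(retained, seqs, cand$width)
      if (obj > cur$objective + 1e-9) {
        cur <- structure(list(profile = cand, hits = out$hits[
          out$hits$score_bits >= params$report_threshold, , drop = FALSE],
          retained = retained, objective = obj, rounds = cur$rounds,
          params = params, background = cur$background),
          class = "bild_alignment")
        improved <- TRUE
        break
      }
    }
    if (!improved) break
  }
  cur
}

## candidate profiles with one column added or removed at either end
width_candidates <- function(alignment, seqs) {
  prof <- alignment$profile
  hits <- alignment$retained
  prior <- prof$prior
  bg <- prof$background
  cands <- list()
  if (prof$width > 2L) {
    cands$shrink_left <- bild_profile(prior, prof$alphabet,
                                      prof$observations[-1L], bg)
    cands$shrink_right <- bild_profile(prior, prof$alphabet,
                                       prof$observations[-prof$width], bg)
  }
  if (nrow(hits)) {
    for (side in c("left", "right")) {
      ob <- flank_observations(hits, seqs, side)
      if (nrow(ob) > 0L) {
        newobs <- if (side == "left") c(list(ob), prof$observations)
        else c(prof$observations, list(ob))
        cands[[paste0("extend_", side)]] <-
          bild_profile(prior, prof$alphabet, newobs, bg)
      }
    }
  }
  cands
}

flank_observations <- function(hits, seqs, side) {
  rows <- list()
  for (i in seq_len(nrow(hits))) {
    k <- match(hits$seq_id[i], seqs$id)
    res <- seqs$residues[[k]]
    pos <- if (side == "left") hits$start[i] - 1L else hits$end[i] + 1L
    if (pos >= 1L && pos <= length(res) && !is.na(res[pos])) {
      rows[[length(rows) + 1L]] <- data.frame(
        seq = seqs$id[k], letter = res[pos], weight = seqs$weight[k])
    }
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(seq = character(0), letter = integer(0),
                  weight = numeric(0))
}

#' Run the full gapped alignment pipeline (Program 1)
#'
#' Gibbs sampling for a provisional ungapped core, iterative gapped
#' realignment with asymmetric affine gap costs, and optional terminal width
#' adjustment.
#'
#' @inheritParams run_sampler
#' @param params A [gap_params()].
#' @param multi Allow multiple instances per sequence.
#' @param adjust Run [adjust_width()] after convergence.
#' @param ... Passed to [run_sampler()].
#' @return A `bild_alignment`.
#' @export
run_program1 <- function(seqs, prior, params = gap_params(), seed = NULL,
                         multi = FALSE, adjust = TRUE, background = NULL,
                         ...) {
  gb <- run_sampler(seqs, prior, seed = seed, background = background, ...)
  al <- iterate_alignment(seqs, gb, prior, params, multi = multi,
                          background = background)
  if (adjust) al <- adjust_width(al, seqs, params)
  al
}
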