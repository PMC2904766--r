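## Program 2: a profile HMM whose position-specific gap costs are derived
## from column BILD scores. Deleting a column costs more the more
## informative the column is (extension cost c * |s_bar_j|); insertions are
## forbidden inside tight clusters of highly conserved columns (normalized
## score s_prime above a threshold T). The alignment step is a semi-global
## Viterbi pass with the same contract as Program 1's DP.

#' Build a profile HMM from column scores
#'
#' Emission scores are the incremental BILD PSSM entries. The
#' deletion-extension cost through column `j` is `c * |s_bar_j|`, where
#' `s_bar_j` is the (always non-positive) background-mean incremental score
#' of the column; the deletion existence cost is uniform. Insertions are
#' disallowed at every junction lying between two columns `a < b` with
#' `b - a <= 2` whose normalized scores both exceed the threshold `T`;
#' elsewhere insertion existence/extension costs are uniform. The permission
#' flags depend only on the profile, never on the query sequence.
#'
#' @param info Per-column score information from [build_pssm()] (fields
#'   `pssm`, `s_bar`, `s_prime`).
#' @param c_mult Deletion-extension multiplier `c` (> 0, default 2.5).
#' @param threshold Normalized-score threshold `T` in bits (>= 0, default 1).
#' @param del_open Deletion existence cost in bits.
#' @param ins_open,ins_extend Insertion costs in bits.
#' @param no_gap_penalty Per-aligned-letter no-gap cost; defaults to the
#'   [gap_params()] default.
#' @return An object of class `bild_hmm`.
#' @export
build_hmm <- function(info, c_mult = 2.5, threshold = 1, del_open = 8.5,
                      ins_open = 9.25, ins_extend = 0.25,
                      no_gap_penalty = NULL) {
  if (c_mult <= 0) stop("c_mult must be > 0")
  if (threshold < 0) stop("threshold must be >= 0")
  if (is.null(no_gap_penalty)) no_gap_penalty <- gap_params()$no_gap_penalty
  W <- nrow(info$pssm)
  del_ext <- c_mult * abs(info$s_bar)
  ins_allowed <- insertion_permissions(info$s_prime, threshold)
  structure(list(pssm = info$pssm, del_ext = del_ext, del_open = del_open,
                 ins_open = ins_open, ins_extend = ins_extend,
                 ins_allowed = ins_allowed, no_gap_penalty = no_gap_penalty,
                 c_mult = c_mult, threshold = threshold, width = W),
            class = "bild_hmm")
}

## junction j (between columns j and j+1) is forbidden iff some pair a <= j <
## b with b - a <= 2 has both normalized scores above the threshold
insertion_permissions <- function(s_prime, threshold) {
  W <- length(s_prime)
  if (W < 2L) return(logical(0))
  allowed <- rep(TRUE, W - 1L)
  hi <- s_prime > threshold
  for (a in seq_len(W - 1L)) {
    for (b in (a + 1L):min(W, a + 2L)) {
      if (hi[a] && hi[b]) allowed[a:(b - 1L)] <- FALSE
    }
  }
  allowed
}

#' @export
print.bild_hmm <- function(x, ...) {
  cat("Profile HMM:", x$width, "columns | c =", x$c_mult,
      "| insertions allowed at", sum(x$ins_allowed), "of",
      length(x$ins_allowed), "junctions\n")
  invisible(x)
}

#' Export an HMM as a plain-text table
#'
#' One row per column with the emission scores, deletion-extension cost and
#' the insert-permission flag of the junction that follows it.
#'
#' @param hmm A [build_hmm()] result.
#' @param alphabet Alphabet supplying column names for the emissions.
#' @param path Output TSV file.
#' @export
write_hmm <- function(hmm, alphabet, path) {
  df <- as.data.frame(round(hmm$pssm, 4))
  names(df) <- alphabet$letters
  df$del_ext <- round(hmm$del_ext, 4)
  df$ins_allowed_after <- c(hmm$ins_allowed, NA)
  utils::write.table(cbind(column = seq_len(hmm$width), df), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Semi-global Viterbi alignment through a profile HMM
#'
#' Same contract as [semiglobal_align()]: every column is matched or
#' deleted, sequence flanks are free, and the maximal-score path is returned
#' — but deletion-extension costs are per-column and insertions occur only
#' at permitted junctions. With uniform costs and all junctions permitted
#' the score equals [semiglobal_align()]'s. This is an independent scalar
#' state-machine implementation, deliberately not sharing code with the
#' vectorized affine DP.
#'
#' @param hmm A [build_hmm()] result.
#' @param res Integer residue-index vector.
#' @return A hit list (`start`, `end`, `path`, `score`).
#' @export
viterbi_semiglobal <- function(hmm, res) {
  W <- hmm$width
  L <- length(res)
  eps <- hmm$no_gap_penalty
  io <- hmm$ins_open; ie <- hmm$ins_extend
  do <- hmm$del_open; de <- hmm$del_ext
  allowed <- hmm$ins_allowed
  NEG <- -Inf
  M <- matrix(NEG, W + 1L, L + 1L)
  D <- matrix(NEG, W + 1L, L + 1L)
  I <- matrix(NEG, W + 1L, L + 1L)
  ptrM <- matrix(NA_character_, W + 1L, L + 1L)
  ptrD <- matrix(NA_character_, W + 1L, L + 1L)
  ptrI <- matrix(NA_character_, W + 1L, L + 1L)
  for (jj in 2L:(W + 1L)) {
    j <- jj - 1L
    for (ii in 1L:(L + 1L)) {
      i <- ii - 1L
      ## match: consumes res[i], needs i >= 1
      if (i >= 1L) {
        emis <- if (is.na(res[i])) 0 else hmm$pssm[j, res[i]]
        if (j == 1L) {
          M[jj, ii] <- emis - eps          # free left flank
          ptrM[jj, ii] <- "S"
        } else {
          v <- M[jj - 1L, ii - 1L]; b <- "M"
          if (D[jj - 1L, ii - 1L] > v) { v <- D[jj - 1L, ii - 1L]; b <- "D" }
          if (I[jj - 1L, ii - 1L] > v) { v <- I[jj - 1L, ii - 1L]; b <- "I" }
          M[jj, ii] <- v + emis - eps
          ptrM[jj, ii] <- b
        }
      }
      ## delete column j: no residue consumed
      if (j == 1L) {
        D[jj, ii] <- -(do + de[j])
        ptrD[jj, ii] <- "S"
      } else {
        v <- M[jj - 1L, ii] - (do + de[j]); b <- "M"
        if (D[jj - 1L, ii] - de[j] > v) { v <- D[jj - 1L, ii] - de[j]; b <- "D" }
        if (I[jj - 1L, ii] - (do + de[j]) > v) {
          v <- I[jj - 1L, ii] - (do + de[j]); b <- "I"
        }
        D[jj, ii] <- v
        ptrD[jj, ii] <- b
      }
      ## insert after column j (internal junctions only, if permitted)
      if (j < W && allowed[j] && i >= 1L) {
        v <- M[jj, ii - 1L] - (io + ie); b <- "M"
        if (D[jj, ii - 1L] - (io + ie) > v) {
          v <- D[jj, ii - 1L] - (io + ie); b <- "D"
        }
        if (I[jj, ii - 1L] - ie > v) { v <- I[jj, ii - 1L] - ie; b <- "I" }
        I[jj, ii] <- v
        ptrI[jj, ii] <- b
      }
    }
  }
  fin <- pmax(M[W + 1L, ], D[W + 1L, ])
  ii <- which.max(fin)
  score <- fin[ii]
  state <- if (M[W + 1L, ii] >= D[W + 1L, ii] - 1e-12) "M" else "D"
  ## traceback via explicit pointers
  jj <- W + 1L
  path <- character(0)
  i_end <- ii - 1L
  repeat {
    if (state == "M") {
      path <- c("M", path)
      nxt <- ptrM[jj, ii]
      jj <- jj - 1L; ii <- ii - 1L
    } else if (state == "D") {
      path <- c("D", path)
      nxt <- ptrD[jj, ii]
      jj <- jj - 1L
    } else {
      path <- c("I", path)
      nxt <- ptrI[jj, ii]
      ii <- ii - 1L
    }
    if (nxt == "S") break
    state <- nxt
  }
  n_consumed <- sum(path != "D")
  list(start = as.integer(i_end - n_consumed + 1L), end = as.integer(i_end),
       path = paste(path, collapse = ""), score = score)
}

#' Run the profile-HMM pipeline (Program 2)
#'
#' Proceeds exactly as [run_program1()], except that inside each realignment
#' round the current profile's column scores are turned into a profile HMM
#' with [build_hmm()] and sequences are realigned by [viterbi_semiglobal()]
#' instead of the affine-gap DP. The HMM is rebuilt every round.
#'
#' @inheritParams run_program1
#' @param c_mult,threshold,del_open HMM parameters (see [build_hmm()]).
#' @return A `bild_alignment`.
#' @export
run_program2 <- function(seqs, prior, params = gap_params(), c_mult = 2.5,
                         threshold = 1, del_open = 8.5, seed = NULL,
                         multi = FALSE, background = NULL, ...) {
  gb <- run_sampler(seqs, prior, seed = seed, background = background, ...)
  engine <- function(info) {
    build_hmm(info, c_mult = c_mult, threshold = threshold,
              del_open = del_open, ins_open = params$ins_open,
              ins_extend = params$ins_extend,
              no_gap_penalty = params$no_gap_penalty)
  }
  iterate_alignment(seqs, gb, prior, params, multi = multi,
                    background = background, align_engine = engine)
}
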