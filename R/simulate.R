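## Motif-implant simulators. Datasets are generated under the model the
## scoring assumes: per-column multinomials drawn from the prior, letters
## i.i.d. from them, implanted into i.i.d. background sequence; a gapped
## variant adds geometric insertions at junctions and deletions of motif
## columns; shuffled negative controls preserve composition exactly.

#' Specification of a motif-implant dataset
#'
#' @param n_sequences Number of sequences.
#' @param length Sequence length (before insertions/deletions).
#' @param width Motif width `W` (must not exceed `length`).
#' @param prior [dirichlet_mixture()] the per-column multinomials are drawn
#'   from.
#' @param alphabet A [bild_alphabet()].
#' @param motif_fraction Fraction of sequences carrying the motif.
#' @param ins_rate Insertion initiation probability per internal junction of
#'   an implanted motif.
#' @param ins_mean Mean insertion length (geometric).
#' @param del_rate Deletion initiation probability per motif column.
#' @param del_mean Mean deletion length (geometric).
#' @param background Background letter distribution; defaults to the prior's
#'   implied background.
#' @return An `implant_spec` list.
#' @export
implant_spec <- function(n_sequences, length, width, prior,
                         alphabet = dna_alphabet(), motif_fraction = 1,
                         ins_rate = 0, ins_mean = 6.3, del_rate = 0,
                         del_mean = 2.0, background = NULL) {
  if (width > length) stop("motif width exceeds sequence length")
  if (any(c(motif_fraction, ins_rate, del_rate) < 0) ||
      any(c(motif_fraction, ins_rate, del_rate) > 1)) {
    stop("fractions and rates must lie in [0, 1]")
  }
  if (is.null(background)) background <- implied_background(prior)
  structure(list(n_sequences = n_sequences, length = length, width = width,
                 prior = prior, alphabet = alphabet,
                 motif_fraction = motif_fraction, ins_rate = ins_rate,
                 ins_mean = ins_mean, del_rate = del_rate,
                 del_mean = del_mean, background = background),
            class = "implant_spec")
}

rgeom_len <- function(n, mean_len) {
  ## geometric length on {1, 2, ...} with the requested mean
  if (mean_len <= 1) return(rep(1L, n))
  1L + stats::rgeom(n, prob = 1 / mean_len)
}

#' Generate an ungapped motif-implant dataset
#'
#' Draws one multinomial per motif column from the prior, implants a motif
#' realization at a uniform random offset in each carrier sequence, and fills
#' the rest with i.i.d. background letters.
#'
#' @param spec An [implant_spec()].
#' @param seed Mandatory integer seed.
#' @return A list with `sequences` (a [bild_sequences()]), `truth` (a
#'   data.frame with `seq_id`, `carrier`, `offset`), and `motif_columns`
#'   (the sampled multinomials, `W x r`).
#' @export
generate_ungapped <- function(spec, seed) {
  set.seed(seed)
  rho <- sample_multinomials(spec$width, spec$prior)
  n <- spec$n_sequences
  carrier <- stats::runif(n) < spec$motif_fraction
  r <- n_letters(spec$alphabet)
  res <- vector("list", n)
  offset <- rep(NA_integer_, n)
  for (k in seq_len(n)) {
    s <- sample.int(r, spec$length, replace = TRUE, prob = spec$background)
    if (carrier[k]) {
      offset[k] <- sample.int(spec$length - spec$width + 1L, 1L)
      motif <- vapply(seq_len(spec$width), function(j) {
        sample.int(r, 1L, prob = rho[j, ])
      }, integer(1))
      s[offset[k]:(offset[k] + spec$width - 1L)] <- motif
    }
    res[[k]] <- s
  }
  seqs <- bild_sequences(res, spec$alphabet)
  list(sequences = seqs,
       truth = data.frame(seq_id = seqs$id, carrier = carrier,
                          offset = offset),
       motif_columns = rho)
}

#' Generate a gapped motif-implant dataset
#'
#' As [generate_ungapped()], but each implanted motif may lose columns to
#' deletions (initiated per column at `del_rate`, geometric run lengths) and
#' gain insertions of background letters at internal junctions (initiated at
#' `ins_rate`, geometric lengths). The truth table records the per-sequence
#' edit path over M/I/D relative to the motif columns. A sequence whose
#' motif would be entirely deleted is resampled (with a warning).
#'
#' @inheritParams generate_ungapped
#' @return A list with `sequences`, `truth` (adds `path` and `motif_end`),
#'   and `motif_columns`.
#' @export
generate_gapped <- function(spec, seed) {
  set.seed(seed)
  W <- spec$width
  rho <- sample_multinomials(W, spec$prior)
  n <- spec$n_sequences
  carrier <- stats::runif(n) < spec$motif_fraction
  r <- n_letters(spec$alphabet)
  res <- vector("list", n)
  offset <- rep(NA_integer_, n)
  paths <- rep(NA_character_, n)
  for (k in seq_len(n)) {
    if (!carrier[k]) {
      res[[k]] <- sample.int(r, spec$length, replace = TRUE,
                             prob = spec$background)
      next
    }
    for (attempt in 1:50) {
      deleted <- sample_deletions(W, spec$del_rate, spec$del_mean)
      if (!all(deleted)) break
      if (attempt == 50) warning("could not avoid deleting every column")
    }
    pieces <- character(0)
    body <- integer(0)
    for (j in seq_len(W)) {
      if (deleted[j]) {
        pieces <- c(pieces, "D")
      } else {
        body <- c(body, sample.int(r, 1L, prob = rho[j, ]))
        pieces <- c(pieces, "M")
      }
      if (j < W && spec$ins_rate > 0 && stats::runif(1) < spec$ins_rate) {
        l <- rgeom_len(1L, spec$ins_mean)
        body <- c(body, sample.int(r, l, replace = TRUE,
                                   prob = spec$background))
        pieces <- c(pieces, strrep("I", l))
      }
    }
    path <- paste(pieces, collapse = "")
    flank_total <- max(spec$length - length(body), 2L)
    left <- sample.int(flank_total - 1L, 1L)
    right <- flank_total - left
    res[[k]] <- c(sample.int(r, left, replace = TRUE, prob = spec$background),
                  body,
                  sample.int(r, right, replace = TRUE,
                             prob = spec$background))
    offset[k] <- left + 1L
    paths[k] <- path
  }
  seqs <- bild_sequences(res, spec$alphabet)
  motif_len <- ifelse(is.na(paths), NA_integer_,
                      nchar(gsub("D", "", paths)))
  list(sequences = seqs,
       truth = data.frame(seq_id = seqs$id, carrier = carrier,
                          offset = offset, path = paths,
                          motif_end = offset + motif_len - 1L),
       motif_columns = rho)
}

sample_deletions <- function(W, rate, mean_len) {
  deleted <- rep(FALSE, W)
  if (rate <= 0) return(deleted)
  j <- 1L
  while (j <= W) {
    if (!deleted[j] && stats::runif(1) < rate) {
      l <- rgeom_len(1L, mean_len)
      deleted[j:min(W, j + l - 1L)] <- TRUE
      j <- j + l
    } else j <- j + 1L
  }
  deleted
}

#' Composition-preserving shuffled negative controls
#'
#' Concatenates all input letters, permutes the combined string, and cuts it
#' back into the original lengths; the output letter multiset is exactly the
#' input's, per-record lengths are preserved.
#'
#' @param seqs A [bild_sequences()].
#' @param seed Integer seed.
#' @return A [bild_sequences()] of shuffled records (ids suffixed
#'   `_shuffled`).
#' @export
shuffle_negatives <- function(seqs, seed) {
  set.seed(seed)
  all_res <- unlist(seqs$residues)
  shuffled <- sample(all_res)
  lens <- seq_lengths(seqs)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  res <- lapply(seq_along(lens), function(k) shuffled[starts[k]:ends[k]])
  bild_sequences(res, seqs$alphabet, ids = paste0(seqs$id, "_shuffled"),
                 weights = seqs$weight,
                 inclusion_priors = seqs$inclusion_prior)
}
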