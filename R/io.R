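## File I/O: FASTA sequence sets, UCSC-style Dirichlet mixture parameter
## flat files, hit reports (TSV) and A2M alignment output.
## Coordinates are 0-free: everything in memory is 1-based R indexing;
## reports are 1-based inclusive.

#' Read unaligned sequences from a FASTA file
#'
#' Parsing is delegated to \code{Biostrings::readBStringSet}; residues are
#' mapped to canonical alphabet indices. Under the default `"skip"` ambiguity
#' policy, characters outside the alphabet contribute zero observation weight;
#' under `"strict"` they are an error naming the sequence and position.
#'
#' @param path FASTA file.
#' @param alphabet A [bild_alphabet()].
#' @param weights,inclusion_priors Per-sequence values, recycled (see
#'   [bild_sequences()]).
#' @param ambiguity `"skip"` or `"strict"`.
#' @return A [bild_sequences()] object, records in file order.
#' @export
read_fasta <- function(path, alphabet, weights = 1, inclusion_priors = 0.5,
                       ambiguity = c("skip", "strict")) {
  ambiguity <- match.arg(ambiguity)
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("no sequences in ", path)
  chr <- as.character(ss)
  ids <- sub("\\s.*$", "", names(ss))
  bild_sequences(chr, alphabet, ids = ids, weights = weights,
                 inclusion_priors = inclusion_priors, ambiguity = ambiguity)
}

#' Write sequences to FASTA
#'
#' @param seqs A [bild_sequences()] object.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  chr <- vapply(seqs$residues, decode_residues, character(1),
                alphabet = seqs$alphabet)
  ss <- Biostrings::BStringSet(stats::setNames(chr, seqs$id))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a Dirichlet mixture from a UCSC-style flat file
#'
#' The dialect is plain text with, per component, a line `Mixture= w` followed
#' by `Alpha= a* a_1 ... a_r`, where the first number after `Alpha=` is the
#' parameter sum. The reader checks the recorded sum against the recomputed
#' one (tolerance 1e-6) and renormalizes the mixture weights, warning if they
#' do not already sum to 1. The letter order must match the alphabet
#' (alphabetical one-letter amino acid order for proteins, A,C,G,T for DNA);
#' any `Order=` or comment lines are ignored.
#'
#' @param path Parameter file.
#' @param alphabet A [bild_alphabet()] defining `r` and the letter order.
#' @return A [dirichlet_mixture()].
#' @export
read_mixture_file <- function(path, alphabet) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  wl <- grep("^\\s*Mixture\\s*=", lines, value = TRUE)
  al <- grep("^\\s*Alpha\\s*=", lines, value = TRUE)
  if (length(wl) == 0L || length(wl) != length(al)) {
    stop("malformed mixture file: need paired Mixture=/Alpha= lines")
  }
  num <- function(s) as.numeric(strsplit(trimws(sub("^[^=]*=", "", s)),
                                         "\\s+")[[1]])
  weights <- vapply(wl, function(s) num(s)[1], numeric(1), USE.NAMES = FALSE)
  r <- n_letters(alphabet)
  alpha <- matrix(NA_real_, length(al), r)
  for (k in seq_along(al)) {
    v <- num(al[k])
    if (length(v) != r + 1L) {
      stop(sprintf("component %d has %d parameters; alphabet expects %d",
                   k, length(v) - 1L, r))
    }
    if (any(v[-1] <= 0)) stop(sprintf("component %d has a non-positive alpha", k))
    if (abs(v[1] - sum(v[-1])) > 1e-6 * max(1, v[1])) {
      stop(sprintf("component %d: recorded alpha* %.8g != recomputed %.8g",
                   k, v[1], sum(v[-1])))
    }
    alpha[k, ] <- v[-1]
  }
  if (any(weights <= 0)) stop("non-positive mixture weight")
  dirichlet_mixture(weights, alpha)
}

#' @rdname read_mixture_file
#' @param mixture A [dirichlet_mixture()] to write.
#' @export
write_mixture_file <- function(mixture, path, alphabet = NULL) {
  stopifnot_mixture(mixture)
  lines <- character(0)
  if (!is.null(alphabet)) {
    lines <- c(lines, paste0("Order= ", paste(alphabet$letters, collapse = " ")))
  }
  fmt <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  for (k in seq_len(n_components(mixture))) {
    lines <- c(lines,
               paste0("Mixture= ", fmt(mixture$weights[k])),
               paste0("Alpha= ", fmt(mixture$alpha_star[k]), " ",
                      paste(fmt(mixture$alpha[k, ]), collapse = " ")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write aligned hits to a TSV report
#'
#' One row per hit with columns `seq_id`, `start`, `end` (1-based inclusive;
#' an all-deletion hit has `end < start`), `score_bits` (2 decimals) and
#' `path` (string over M/I/D). Rows are ordered by sequence id, then start.
#'
#' @param hits A data.frame of hits as produced by the aligners.
#' @param path Output file.
#' @export
write_hits <- function(hits, path) {
  cols <- c("seq_id", "start", "end", "score_bits", "path")
  if (nrow(hits) == 0L) {
    hits <- data.frame(seq_id = character(0), start = integer(0),
                       end = integer(0), score_bits = numeric(0),
                       path = character(0))
  }
  hits <- hits[order(hits$seq_id, hits$start), cols, drop = FALSE]
  hits$score_bits <- sprintf("%.2f", hits$score_bits)
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write hits as an A2M alignment
#'
#' Upper-case letters are residues aligned to profile columns, `-` marks a
#' deleted column, and lower-case letters are insertions; every row therefore
#' has the same number of match+delete states.
#'
#' @param hits A data.frame of hits with `seq_id`, `start` and `path` columns.
#' @param seqs The [bild_sequences()] the hits refer to.
#' @param path Output file.
#' @export
write_a2m <- function(hits, seqs, path) {
  out <- character(0)
  for (i in seq_len(nrow(hits))) {
    k <- match(hits$seq_id[i], seqs$id)
    res <- seqs$residues[[k]]
    pos <- hits$start[i]
    chars <- character(0)
    for (st in strsplit(hits$path[i], "")[[1]]) {
      if (st == "M") {
        chars <- c(chars, toupper(seqs$alphabet$letters[res[pos]]))
        pos <- pos + 1L
      } else if (st == "I") {
        chars <- c(chars, tolower(seqs$alphabet$letters[res[pos]]))
        pos <- pos + 1L
      } else {
        chars <- c(chars, "-")
      }
    }
    out <- c(out, paste0(">", hits$seq_id[i], "/", hits$start[i], "-",
                         hits$end[i]),
             paste(chars, collapse = ""))
  }
  writeLines(out, path)
  invisible(path)
}
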