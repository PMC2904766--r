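#' Residue alphabets
#'
#' An alphabet is an ordered set of residue symbols together with strictly
#' positive background probabilities that sum to one. All scoring in the
#' package is expressed relative to these background probabilities.
#'
#' @param letters Character vector of unique single-character symbols.
#' @param background Numeric vector of background probabilities, one per
#'   letter. Defaults to uniform.
#' @return An object of class `bild_alphabet` with elements `letters`
#'   (canonical, upper case) and `background`.
#' @examples
#' dna_alphabet()
#' bild_alphabet(c("H", "P"), c(0.4, 0.6))
#' @export
bild_alphabet <- function(letters, background = NULL) {
  letters <- toupper(as.character(letters))
  r <- length(letters)
  if (r < 2L) stop("an alphabet needs at least 2 letters")
  if (anyDuplicated(letters)) stop("alphabet letters must be unique")
  if (any(nchar(letters) != 1L)) stop("alphabet letters must be single characters")
  if (is.null(background)) background <- rep(1 / r, r)
  background <- as.numeric(background)
  if (length(background) != r) stop("background must have one entry per letter")
  if (any(background <= 0)) stop("background probabilities must be strictly positive")
  if (abs(sum(background) - 1) > 1e-12) {
    stop("background probabilities must sum to 1")
  }
  structure(list(letters = letters, background = background),
            class = "bild_alphabet")
}

#' @rdname bild_alphabet
#' @export
dna_alphabet <- function(background = NULL) {
  bild_alphabet(c("A", "C", "G", "T"), background)
}

#' @rdname bild_alphabet
#' @details `protein_alphabet()` orders the 20 amino acids alphabetically by
#'   one-letter code (A, C, D, ..., Y), the order assumed for mixture parameter
#'   files read by [read_mixture_file()].
#' @export
protein_alphabet <- function(background = NULL) {
  bild_alphabet(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], background)
}

#' @export
print.bild_alphabet <- function(x, ...) {
  cat("Alphabet of", length(x$letters), "letters:",
      paste(x$letters, collapse = ""), "\n")
  cat("Background:", paste(formatC(x$background, digits = 4, format = "g"),
                           collapse = " "), "\n")
  invisible(x)
}

n_letters <- function(alphabet) length(alphabet$letters)

#' Encode residue characters as canonical letter indices
#'
#' Lookup is case-insensitive. Characters outside the alphabet are treated
#' according to `ambiguity`: `"skip"` maps them to `NA` (they then contribute
#' zero observation weight to every count), `"strict"` raises an error naming
#' the offending position.
#'
#' @param chars Character vector of single residues, or a single string.
#' @param alphabet A [bild_alphabet()].
#' @param ambiguity `"skip"` or `"strict"`.
#' @param what Label used in error messages (e.g. a sequence id).
#' @return Integer vector of 1-based letter indices, `NA` for skipped codes.
#' @export
encode_residues <- function(chars, alphabet, ambiguity = c("skip", "strict"),
                            what = "sequence") {
  ambiguity <- match.arg(ambiguity)
  if (length(chars) == 1L && nchar(chars[1L]) > 1L) {
    chars <- strsplit(chars, "")[[1L]]
  }
  idx <- match(toupper(chars), alphabet$letters)
  if (ambiguity == "strict" && anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop(sprintf("illegal character '%s' in %s at position %d",
                 chars[bad], what, bad))
  }
  idx
}

decode_residues <- function(idx, alphabet, na_char = "X") {
  out <- alphabet$letters[idx]
  out[is.na(idx)] <- na_char
  paste(out, collapse = "")
}

#' Sequence sets
#'
#' A light container for unaligned sequences: ids, encoded residues, a
#' per-letter observation weight in (0, 1] and a prior inclusion probability
#' used by the description-length machinery.
#'
#' @param x Character vector of sequences (named or not), or a list of
#'   integer residue-index vectors.
#' @param alphabet A [bild_alphabet()].
#' @param ids Optional ids; defaults to names of `x` or `seq1`, `seq2`, ...
#' @param weights Per-sequence observation weights in (0, 1], recycled.
#' @param inclusion_priors Per-sequence prior probabilities of carrying the
#'   pattern, in `[0, 1]`, recycled. Default 0.5.
#' @param ambiguity Passed to [encode_residues()].
#' @return An object of class `bild_sequences`.
#' @export
bild_sequences <- function(x, alphabet, ids = NULL, weights = 1,
                           inclusion_priors = 0.5,
                           ambiguity = c("skip", "strict")) {
  ambiguity <- match.arg(ambiguity)
  if (is.character(x)) {
    if (is.null(ids)) ids <- names(x)
    res <- lapply(seq_along(x), function(i) {
      encode_residues(x[[i]], alphabet, ambiguity,
                      what = if (is.null(ids)) paste0("sequence ", i) else ids[[i]])
    })
  } else if (is.list(x)) {
    res <- lapply(x, as.integer)
  } else {
    stop("x must be a character vector or a list of index vectors")
  }
  n <- length(res)
  if (n == 0L) stop("empty sequence set")
  if (any(lengths(res) < 1L)) stop("sequences must be non-empty")
  if (is.null(ids)) ids <- paste0("seq", seq_len(n))
  weights <- rep_len(as.numeric(weights), n)
  inclusion_priors <- rep_len(as.numeric(inclusion_priors), n)
  if (any(weights <= 0 | weights > 1)) stop("weights must lie in (0, 1]")
  if (any(inclusion_priors < 0 | inclusion_priors > 1)) {
    stop("inclusion priors must lie in [0, 1]")
  }
  structure(list(id = as.character(ids), residues = res, weight = weights,
                 inclusion_prior = inclusion_priors, alphabet = alphabet),
            class = "bild_sequences")
}

#' @export
length.bild_sequences <- function(x) length(x$residues)

#' @export
print.bild_sequences <- function(x, ...) {
  cat(length(x), "sequences over alphabet",
      paste(x$alphabet$letters, collapse = ""), "\n")
  cat("lengths:", paste(utils::head(lengths(x$residues), 8), collapse = " "),
      if (length(x) > 8) "..." else "", "\n")
  invisible(x)
}

seq_lengths <- function(seqs) lengths(seqs$residues)
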