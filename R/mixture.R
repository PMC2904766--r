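#' Dirichlet mixture priors
#'
#' A Dirichlet mixture is a weighted sum of `M` Dirichlet densities over the
#' simplex of multinomial distributions on `r` letters. It is the prior placed
#' on the letter distribution of a "true" alignment column; all column scores
#' in the package are computed by integrating it out.
#'
#' @param weights Positive mixture weights, renormalized to sum to 1 (a
#'   warning is emitted if they do not already).
#' @param alpha An `M x r` matrix of strictly positive Dirichlet parameters
#'   (one row per component), or a vector for a single component.
#' @return An object of class `dirichlet_mixture` with elements `weights`,
#'   `alpha`, and cached row sums `alpha_star`.
#' @examples
#' dirichlet_mixture(1, c(1, 1, 1, 1))            # uniform DNA prior
#' symmetric_dirichlet(0.5, 4)                    # concentration 0.5, uniform center
#' @export
dirichlet_mixture <- function(weights, alpha) {
  if (is.vector(alpha)) alpha <- matrix(alpha, nrow = 1L)
  alpha <- as.matrix(alpha)
  weights <- as.numeric(weights)
  if (length(weights) != nrow(alpha)) {
    stop("need one mixture weight per component")
  }
  if (any(weights <= 0)) stop("mixture weights must be positive")
  if (any(alpha <= 0)) stop("Dirichlet parameters must be strictly positive")
  s <- sum(weights)
  if (abs(s - 1) > 1e-12) {
    if (abs(s - 1) > 1e-6) {
      warning(sprintf("mixture weights sum to %.6g; renormalizing", s))
    }
    weights <- weights / s
  }
  structure(list(weights = weights, alpha = alpha,
                 alpha_star = rowSums(alpha)),
            class = "dirichlet_mixture")
}

#' @rdname dirichlet_mixture
#' @param alpha_star Total concentration of a symmetric prior.
#' @param r Alphabet size.
#' @param center Optional center-of-mass vector (defaults to uniform); the
#'   component parameters are `alpha_star * center`.
#' @export
symmetric_dirichlet <- function(alpha_star, r = 4L, center = NULL) {
  if (is.null(center)) center <- rep(1 / r, r)
  if (abs(sum(center) - 1) > 1e-12) stop("center must sum to 1")
  dirichlet_mixture(1, alpha_star * center)
}

#' @export
print.dirichlet_mixture <- function(x, digits = 4, ...) {
  M <- length(x$weights)
  cat("Dirichlet mixture:", M, "component(s) over", ncol(x$alpha), "letters\n")
  for (k in seq_len(M)) {
    cat(sprintf("  m=%.*g  alpha*=%.*g  center=(%s)\n", digits, x$weights[k],
                digits, x$alpha_star[k],
                paste(formatC(x$alpha[k, ] / x$alpha_star[k], digits = 3,
                              format = "g"), collapse = " ")))
  }
  invisible(x)
}

n_components <- function(m) length(m$weights)

stopifnot_mixture <- function(m, r = NULL) {
  if (!inherits(m, "dirichlet_mixture")) stop("not a dirichlet_mixture")
  if (!is.null(r) && ncol(m$alpha) != r) {
    stop("mixture alphabet size does not match")
  }
  invisible(m)
}

#' Count vectors
#'
#' The (possibly fractionally weighted) letter counts of one alignment column.
#' Plain numeric vectors of length `r` are accepted everywhere; this helper
#' builds one from observed letters.
#'
#' @param letters Integer letter indices (NA entries are dropped) or a
#'   character vector/string to be encoded.
#' @param alphabet A [bild_alphabet()].
#' @param weights Observation weights, recycled over letters.
#' @return Numeric vector of length `r` of summed weights per letter.
#' @export
count_vector <- function(letters, alphabet, weights = 1) {
  if (is.character(letters)) letters <- encode_residues(letters, alphabet)
  letters <- as.integer(letters)
  weights <- rep_len(as.numeric(weights), length(letters))
  keep <- !is.na(letters)
  counts <- numeric(n_letters(alphabet))
  if (any(keep)) {
    tab <- tapply(weights[keep], letters[keep], sum)
    counts[as.integer(names(tab))] <- as.numeric(tab)
  }
  counts
}

check_counts <- function(counts, r) {
  counts <- as.numeric(counts)
  if (length(counts) != r) stop("count vector has wrong length")
  if (any(counts < 0)) stop("counts must be non-negative")
  counts
}
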