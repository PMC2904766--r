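## Dirichlet-mixture machinery: predictive probabilities, posterior updates
## (unit and fractional), aggregated column marginals, prior diagnostics.
## All probability arithmetic is done in log space through lgamma(); Gamma is
## never evaluated directly, so columns with hundreds of weighted observations
## are safe.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## log of the fractional-observation Bayes factor for every component:
## f_k(j, w) = Gamma(a_kj + w) Gamma(a*_k) / (Gamma(a_kj) Gamma(a*_k + w)).
## At w = 1 this reduces to a_kj / a*_k; as w -> 0 it tends to 1.
log_obs_factor <- function(mixture, letter, weight) {
  a <- mixture$alpha[, letter]
  as <- mixture$alpha_star
  lgamma(a + weight) - lgamma(a) + lgamma(as) - lgamma(as + weight)
}

check_weight <- function(weight) {
  if (!is.numeric(weight) || length(weight) != 1L || weight <= 0 || weight > 1) {
    stop("observation weight must lie in (0, 1]")
  }
  weight
}

check_letter <- function(letter, mixture) {
  letter <- as.integer(letter)
  if (is.na(letter) || letter < 1L || letter > ncol(mixture$alpha)) {
    stop("invalid letter index")
  }
  letter
}

#' Predictive probability of the next observation
#'
#' Probability of observing `letter` (with observation weight `weight`) under
#' a Dirichlet-mixture distribution over column multinomials. For unit weight
#' this is the mixture of component means `sum_k m_k alpha_kj / alpha*_k`; a
#' fractional observation uses the gamma-ratio factor instead, which tends to
#' 1 as the weight tends to 0. Unit-weight probabilities sum to 1 over the
#' alphabet.
#'
#' @param mixture A [dirichlet_mixture()] (prior or posterior).
#' @param letter 1-based letter index.
#' @param weight Observation weight in (0, 1].
#' @return A probability (for fractional weights, the marginal-likelihood
#'   factor of the fractional observation).
#' @export
predictive_probability <- function(mixture, letter, weight = 1) {
  stopifnot_mixture(mixture)
  check_weight(weight)
  letter <- check_letter(letter, mixture)
  sum(mixture$weights * exp(log_obs_factor(mixture, letter, weight)))
}

## predictive distribution over the whole alphabet (unit weight): the
## mixture-weighted component means. Used for PSSM construction.
predictive_distribution <- function(mixture) {
  as.numeric(mixture$weights %*% (mixture$alpha / mixture$alpha_star))
}

#' Bayesian update and downdate by a single (possibly fractional) observation
#'
#' Updating multiplies each mixture weight by its component's observation
#' factor, renormalizes, and adds `weight` to the observed letter's parameter
#' in every component. The procedure is exactly invertible given the letter
#' and weight; `downdate_posterior()` performs the inversion.
#'
#' @inheritParams predictive_probability
#' @return A new `dirichlet_mixture`.
#' @export
update_posterior <- function(mixture, letter, weight = 1) {
  stopifnot_mixture(mixture)
  check_weight(weight)
  letter <- check_letter(letter, mixture)
  lw <- log(mixture$weights) + log_obs_factor(mixture, letter, weight)
  w <- exp(lw - logsumexp(lw))
  alpha <- mixture$alpha
  alpha[, letter] <- alpha[, letter] + weight
  dirichlet_mixture(w, alpha)
}

#' @rdname update_posterior
#' @export
downdate_posterior <- function(mixture, letter, weight = 1) {
  stopifnot_mixture(mixture)
  check_weight(weight)
  letter <- check_letter(letter, mixture)
  alpha <- mixture$alpha
  if (any(alpha[, letter] - weight <= 0)) {
    stop("downdate would make a Dirichlet parameter non-positive")
  }
  alpha[, letter] <- alpha[, letter] - weight
  down <- dirichlet_mixture(mixture$weights, alpha)
  lw <- log(mixture$weights) - log_obs_factor(down, letter, weight)
  down$weights <- exp(lw - logsumexp(lw))
  down
}

## log marginal probability of a whole count vector under one component:
## log [ Gamma(a*) / Gamma(a* + n) * prod_j Gamma(a_j + c_j) / Gamma(a_j) ].
component_log_marginal <- function(alpha, alpha_star, counts) {
  n <- sum(counts)
  lgamma(alpha_star) - lgamma(alpha_star + n) +
    sum(lgamma(alpha + counts) - lgamma(alpha))
}

#' Marginal probability of an alignment column
#'
#' The probability, under the relatedness model, of observing a column with
#' the given letter counts: for a single Dirichlet this is the aggregated
#' closed form `Gamma(a*)/Gamma(a*+n) * prod_j Gamma(a_j+c_j)/Gamma(a_j)`;
#' for a mixture, the weight-averaged component values. Equals the product of
#' sequential predictive probabilities in any observation order.
#'
#' @param mixture A [dirichlet_mixture()].
#' @param counts Numeric count vector (fractional counts allowed).
#' @param log Return the natural-log value instead.
#' @return The (log) marginal probability; 1 (0) for empty counts.
#' @export
column_marginal <- function(mixture, counts, log = FALSE) {
  stopifnot_mixture(mixture)
  counts <- check_counts(counts, ncol(mixture$alpha))
  lm <- vapply(seq_len(n_components(mixture)), function(k) {
    component_log_marginal(mixture$alpha[k, ], mixture$alpha_star[k], counts)
  }, numeric(1))
  out <- logsumexp(log(mixture$weights) + lm)
  if (log) out else exp(out)
}

## posterior mixture after absorbing a whole count vector at once:
## weights re-weighted by component marginals, parameters shifted by counts.
posterior_from_counts <- function(mixture, counts) {
  counts <- check_counts(counts, ncol(mixture$alpha))
  if (sum(counts) == 0) return(mixture)
  lm <- vapply(seq_len(n_components(mixture)), function(k) {
    component_log_marginal(mixture$alpha[k, ], mixture$alpha_star[k], counts)
  }, numeric(1))
  lw <- log(mixture$weights) + lm
  dirichlet_mixture(exp(lw - logsumexp(lw)),
                    sweep(mixture$alpha, 2L, counts, `+`))
}

#' Background distribution implied by a prior
#'
#' The expected letter frequencies of a multinomial drawn from the mixture:
#' `p_i = sum_k m_k alpha_ki / alpha*_k`.
#'
#' @param mixture A [dirichlet_mixture()].
#' @return A probability vector over the alphabet.
#' @export
implied_background <- function(mixture) {
  stopifnot_mixture(mixture)
  predictive_distribution(mixture)
}

#' Relative entropy of the pairwise substitution matrix implied by a prior
#'
#' Two letters drawn from the same prior-sampled multinomial have joint
#' "target" frequencies `q_ij = E[rho_i rho_j]`, which under a Dirichlet
#' mixture are available in closed form:
#' `q_ij = sum_k m_k alpha_ki (alpha_kj + [i==j]) / (alpha*_k (alpha*_k + 1))`.
#' The log-odds of `q` against the product background is a classical
#' substitution matrix; its relative entropy
#' `H = sum_ij q_ij log2(q_ij / (p_i p_j))` calibrates the evolutionary depth
#' of the prior.
#'
#' @param mixture A [dirichlet_mixture()].
#' @param background Strictly positive background probabilities; defaults to
#'   [implied_background()].
#' @return A list with `H` (bits) and the symmetric target-frequency matrix
#'   `q` (entries sum to 1).
#' @export
implied_pair_relative_entropy <- function(mixture, background = NULL) {
  stopifnot_mixture(mixture)
  r <- ncol(mixture$alpha)
  if (is.null(background)) background <- implied_background(mixture)
  if (length(background) != r || any(background <= 0)) {
    stop("background must be strictly positive over the alphabet")
  }
  q <- matrix(0, r, r)
  for (k in seq_len(n_components(mixture))) {
    a <- mixture$alpha[k, ]
    as <- mixture$alpha_star[k]
    qk <- (tcrossprod(a) + diag(a, r)) / (as * (as + 1))
    q <- q + mixture$weights[k] * qk
  }
  pp <- tcrossprod(background)
  list(H = sum(q * log2(q / pp)), q = q)
}

#' Mean relative entropy of prior-drawn multinomials
#'
#' The expected Kullback-Leibler divergence, in bits, of a column distribution
#' drawn from the prior to the background: the per-column information
#' available from a deep, accurate alignment. For each component the digamma
#' closed form is
#' `(1/ln 2) sum_i (a_i/a*) (psi(a_i + 1) - psi(a* + 1)) - sum_i (a_i/a*) log2 p_i`,
#' and the mixture value is the weight-averaged sum.
#'
#' @inheritParams implied_pair_relative_entropy
#' @return Mean relative entropy in bits (non-negative).
#' @export
mean_relative_entropy <- function(mixture, background = NULL) {
  stopifnot_mixture(mixture)
  r <- ncol(mixture$alpha)
  if (is.null(background)) background <- implied_background(mixture)
  if (length(background) != r || any(background <= 0)) {
    stop("background must be strictly positive over the alphabet")
  }
  per_comp <- vapply(seq_len(n_components(mixture)), function(k) {
    a <- mixture$alpha[k, ]
    as <- mixture$alpha_star[k]
    ctr <- a / as
    sum(ctr * (digamma(a + 1) - digamma(as + 1))) / log(2) -
      sum(ctr * log2(background))
  }, numeric(1))
  sum(mixture$weights * per_comp)
}

#' Sample multinomials from a Dirichlet mixture
#'
#' Draws column distributions by choosing a component according to its weight
#' and normalizing independent gamma variates. Used by the data simulator and
#' by Monte-Carlo cross-checks of the analytic diagnostics.
#'
#' @param n Number of draws.
#' @param mixture A [dirichlet_mixture()].
#' @return An `n x r` matrix whose rows are multinomial distributions.
#' @export
sample_multinomials <- function(n, mixture) {
  stopifnot_mixture(mixture)
  r <- ncol(mixture$alpha)
  comp <- sample.int(n_components(mixture), n, replace = TRUE,
                     prob = mixture$weights)
  g <- matrix(stats::rgamma(n * r, shape = mixture$alpha[comp, ]), n, r)
  g / rowSums(g)
}
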