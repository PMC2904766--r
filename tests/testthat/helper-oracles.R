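# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: alignment scores come from exhaustive path
# enumeration, column marginals from the sequential chain rule, diagnostics
# from Monte-Carlo simplex sampling, interval search from full enumeration.

dna <- dna_alphabet()
uniform_dna_prior <- dirichlet_mixture(1, c(1, 1, 1, 1))
toy_mixture <- dirichlet_mixture(c(0.5, 0.5), rbind(c(2, 1, 1, 1),
                                                    c(1, 1, 1, 2)))

# chain-rule oracle: marginal probability of a letter multiset as the
# product of sequential predictive probabilities, updating after each
# observation (any order; callers pass permutations).
chain_rule_marginal <- function(mixture, letters, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(letters))
  p <- 1
  for (i in seq_along(letters)) {
    p <- p * predictive_probability(mixture, letters[i], weights[i])
    mixture <- update_posterior(mixture, letters[i], weights[i])
  }
  p
}

# exhaustive interval search with the same tie conventions as the package:
# empty interval preferred at score 0; then leftmost start, then shortest.
brute_best_interval <- function(scores) {
  n <- length(scores)
  best <- list(start = 1L, end = 0L, score = 0)
  for (s in seq_len(n)) {
    for (e in s:n) {
      sc <- sum(scores[s:e])
      if (sc > best$score + 1e-12) {
        best <- list(start = s, end = e, score = sc)
      }
    }
  }
  best
}

# score an M/I/D path against a PSSM from a given start position; -Inf for
# structurally invalid paths (wrong column count, out-of-range residues,
# insertion at a forbidden or terminal junction).
score_path <- function(pssm, path, res, start, eps, io, ie, do_, de,
                       allowed = NULL) {
  W <- nrow(pssm); L <- length(res)
  de <- rep_len(de, W)
  if (is.null(allowed)) allowed <- rep(TRUE, max(0, W - 1))
  st <- strsplit(path, "")[[1]]
  j <- 0L; pos <- start; sc <- 0
  i <- 1L; n <- length(st)
  while (i <= n) {
    if (st[i] == "M") {
      j <- j + 1L
      if (j > W || pos > L || pos < 1) return(-Inf)
      e <- if (is.na(res[pos])) 0 else pssm[j, res[pos]]
      sc <- sc + e - eps
      pos <- pos + 1L; i <- i + 1L
    } else if (st[i] == "D") {
      sc <- sc - do_
      while (i <= n && st[i] == "D") {
        j <- j + 1L
        if (j > W) return(-Inf)
        sc <- sc - de[j]
        i <- i + 1L
      }
    } else {
      if (j < 1 || j >= W || !allowed[j]) return(-Inf)
      l <- 0L
      while (i <= n && st[i] == "I") {
        if (pos > L) return(-Inf)
        l <- l + 1L; pos <- pos + 1L; i <- i + 1L
      }
      sc <- sc - io - l * ie
    }
  }
  if (j != W) return(-Inf)
  sc
}

# exhaustive semi-global optimum over all segments and paths (W <= 3,
# L <= 6 keeps this a few thousand candidates).
brute_semiglobal <- function(pssm, res, eps, io, ie, do_, de,
                             allowed = NULL) {
  W <- nrow(pssm); L <- length(res)
  best <- -Inf
  states <- expand.grid(rep(list(c("M", "D")), W), stringsAsFactors = FALSE)
  nj <- max(0, W - 1)
  ins <- if (nj > 0) expand.grid(rep(list(0:L), nj)) else NULL
  n_ins <- if (is.null(ins)) 1L else nrow(ins)
  for (si in seq_len(nrow(states))) {
    for (ii in seq_len(n_ins)) {
      path <- character(0)
      for (j in seq_len(W)) {
        path <- c(path, states[si, j])
        if (!is.null(ins) && j < W && ins[ii, j] > 0) {
          path <- c(path, rep("I", ins[ii, j]))
        }
      }
      p <- paste(path, collapse = "")
      for (start in 1:(L + 1)) {
        s <- score_path(pssm, p, res, start, eps, io, ie, do_, de, allowed)
        if (s > best) best <- s
      }
    }
  }
  best
}

# bare HMM object for cross-checks without going through a profile
raw_hmm <- function(pssm, del_ext, del_open, ins_open, ins_extend,
                    ins_allowed, eps) {
  structure(list(pssm = pssm, del_ext = rep_len(del_ext, nrow(pssm)),
                 del_open = del_open, ins_open = ins_open,
                 ins_extend = ins_extend, ins_allowed = ins_allowed,
                 no_gap_penalty = eps, width = nrow(pssm)),
            class = "bild_hmm")
}

# exact rational chain-rule scores for the two worked DNA columns under the
# uniform Dirichlet prior: marginals 1/420 and 1/140 against (1/4)^4.
worked_column_score <- function(column) {
  counts <- count_vector(column, dna)
  marg <- 1; post <- c(1, 1, 1, 1)
  for (l in encode_residues(column, dna)) {
    marg <- marg * post[l] / sum(post)
    post[l] <- post[l] + 1
  }
  log2(marg) - sum(counts * log2(0.25))
}

# map recovered M-state residues to true motif columns; returns the fraction
# matched under the best single register shift.
residue_recovery <- function(alignment, dataset) {
  truth <- dataset$truth
  total <- 0L
  pairs <- list()
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    if (!isTRUE(tr$carrier)) next
    pos <- tr$offset; tc <- integer(0); tp <- integer(0); j <- 0L
    for (st in strsplit(tr$path, "")[[1]]) {
      if (st == "M") {
        j <- j + 1L; tc <- c(tc, j); tp <- c(tp, pos); pos <- pos + 1L
      } else if (st == "D") j <- j + 1L else pos <- pos + 1L
    }
    total <- total + length(tp)
    h <- alignment$hits[alignment$hits$seq_id == tr$seq_id, , drop = FALSE]
    if (nrow(h) == 0L) next
    h <- h[which.max(h$score_bits), ]
    pos <- h$start; j <- 0L
    for (st in strsplit(h$path, "")[[1]]) {
      if (st == "M") {
        j <- j + 1L
        m <- match(pos, tp)
        if (!is.na(m)) pairs[[length(pairs) + 1L]] <- c(tc[m], j)
        pos <- pos + 1L
      } else if (st == "D") j <- j + 1L else pos <- pos + 1L
    }
  }
  if (length(pairs) == 0L) return(0)
  pm <- do.call(rbind, pairs)
  max(table(pm[, 1] - pm[, 2])) / total
}
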