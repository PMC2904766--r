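test_that("column scores reproduce the exact worked values", {
  bg <- dna$background
  s_aatc <- column_score(uniform_dna_prior, count_vector("AATC", dna), bg)
  s_aaac <- column_score(uniform_dna_prior, count_vector("AAAC", dna), bg)
  expect_equal(s_aatc, log2(256 / 420), tolerance = 1e-12)
  expect_equal(s_aaac, log2(256 / 140), tolerance = 1e-12)
  # against the independent rational chain-rule oracle
  expect_equal(s_aatc, worked_column_score("AATC"), tolerance = 1e-12)
  expect_equal(s_aaac, worked_column_score("AAAC"), tolerance = 1e-12)
})

test_that("single letters score zero when the prior center is the background", {
  for (m in list(symmetric_dirichlet(0.5, 4), symmetric_dirichlet(3, 4))) {
    for (l in 1:4) {
      cc <- numeric(4); cc[l] <- 1
      expect_equal(column_score(m, cc, rep(0.25, 4)), 0, tolerance = 1e-12)
      expect_equal(incremental_letter_score(m, rep(0, 4), l, rep(0.25, 4)),
                   0, tolerance = 1e-12)
    }
  }
})

test_that("column scores are invariant under permutation of observations", {
  set.seed(11)
  for (i in 1:12) {
    letters <- sample.int(4, sample(2:8, 1), replace = TRUE)
    w <- if (i %% 2) 1 else runif(length(letters), 0.3, 1)
    s <- column_score(toy_mixture, count_vector(letters, dna, w),
                      dna$background)
    perm <- sample(length(letters))
    s2 <- column_score(toy_mixture,
                       count_vector(letters[perm], dna,
                                    rep_len(w, length(letters))[perm]),
                       dna$background)
    expect_equal(s, s2, tolerance = 1e-12)
  }
})

test_that("background-generated columns have negative expected score", {
  # exact enumeration over all 4^n columns of i.i.d. uniform letters
  for (n in 2:4) {
    cols <- expand.grid(rep(list(1:4), n))
    es <- sum(apply(cols, 1, function(col) {
      (0.25^n) * column_score(uniform_dna_prior, count_vector(col, dna),
                              rep(0.25, 4))
    }))
    expect_lt(es, 0)
  }
})

test_that("incremental scores decompose column scores additively", {
  bg <- dna$background
  # worked PSSM row: posterior alpha (4,2,1,1) after AAAC gives predictive
  # (1/2, 1/4, 1/8, 1/8) and scores (+1, 0, -1, -1) against uniform
  counts <- count_vector("AAAC", dna)
  expect_equal(
    vapply(1:4, function(l) {
      incremental_letter_score(uniform_dna_prior, counts, l, bg)
    }, numeric(1)),
    c(1, 0, -1, -1), tolerance = 1e-12)
  # defining identity score("AAT") - score("AA") = incremental T after "AA"
  expect_equal(
    column_score(toy_mixture, count_vector("AAT", dna), bg) -
      column_score(toy_mixture, count_vector("AA", dna), bg),
    incremental_letter_score(toy_mixture, count_vector("AA", dna),
                             encode_residues("T", dna), bg),
    tolerance = 1e-12)
  # fractional observations obey the same identity
  set.seed(13)
  for (i in 1:8) {
    base <- count_vector(sample.int(4, 3, replace = TRUE), dna)
    l <- sample.int(4, 1); w <- runif(1, 0.2, 1)
    plus <- base; plus[l] <- plus[l] + w
    expect_equal(
      incremental_letter_score(toy_mixture, base, l, bg, weight = w),
      column_score(toy_mixture, plus, bg) -
        column_score(toy_mixture, base, bg),
      tolerance = 1e-10)
  }
})

test_that("column-column scores are symmetric and reduce to pair log-odds", {
  bg <- dna$background
  x <- count_vector("AA", dna); y <- count_vector("TC", dna)
  expect_equal(column_column_score(uniform_dna_prior, x, y, bg),
               column_column_score(uniform_dna_prior, y, x, bg),
               tolerance = 1e-12)
  expect_equal(column_column_score(uniform_dna_prior, x, rep(0, 4), bg), 0,
               tolerance = 1e-12)
  # S(x+y) - S(x) - S(y) by direct evaluation
  expect_equal(column_column_score(uniform_dna_prior, x, x, bg),
               column_score(uniform_dna_prior, 2 * x, bg) -
                 2 * column_score(uniform_dna_prior, x, bg),
               tolerance = 1e-12)
  # for single letters, equals the pairwise substitution score
  # log2(q_ab / (p_a p_b)) implied by the prior, with p the prior's own
  # implied background (the scoring background cancels in the difference)
  q <- implied_pair_relative_entropy(toy_mixture)$q
  pb <- implied_background(toy_mixture)
  for (a in 1:4) for (b in 1:4) {
    ca <- numeric(4); ca[a] <- 1
    cb <- numeric(4); cb[b] <- 1
    expect_equal(column_column_score(toy_mixture, ca, cb, bg),
                 log2(q[a, b] / (pb[a] * pb[b])), tolerance = 1e-10)
  }
})

test_that("leave-one-out PSSMs remove and restore sequences exactly", {
  prior <- uniform_dna_prior
  s <- bild_sequences(c(a = "AACG", b = "AACG", c = "AACG", d = "CACG"), dna)
  prof <- profile_from_offsets(s, c(1L, 1L, 1L, 1L), 4L, prior)
  # excluding the C-bearing sequence leaves the AAA posterior in column 1
  loo <- build_pssm(prof, "d")
  expect_equal(loo$counts[1, ], c(3, 0, 0, 0))
  expect_equal(loo$pssm[1, ],
               vapply(1:4, function(l) {
                 incremental_letter_score(prior, c(3, 0, 0, 0), l,
                                          dna$background)
               }, numeric(1)), tolerance = 1e-12)
  # excluding an absent id is a no-op with a message
  expect_message(full2 <- build_pssm(prof, "nope"), "not present")
  expect_equal(full2$pssm, build_pssm(prof)$pssm, tolerance = 1e-12)
  # a single-sequence profile excluding that sequence is the bare prior:
  # all-zero PSSM when the center equals the background
  p1 <- profile_from_offsets(bild_sequences(c(z = "ACGT"), dna),
                             1L, 4L, prior)
  bare <- build_pssm(p1, "z")
  expect_equal(max(abs(bare$pssm)), 0, tolerance = 1e-12)
})

test_that("per-column summaries behave as documented", {
  s <- bild_sequences(c(a = "AAAA", b = "AAAA", c = "AATA"), dna)
  prof <- profile_from_offsets(s, c(1L, 1L, 1L), 4L, uniform_dna_prior)
  info <- build_pssm(prof)
  # s_bar is always non-positive; zero iff predictive equals background
  expect_true(all(info$s_bar <= 1e-12))
  empty <- build_pssm(
    profile_from_offsets(bild_sequences(c(x = "A"), dna), 1L, 1L,
                         uniform_dna_prior), "x")
  expect_equal(empty$s_bar, 0, tolerance = 1e-12)
  # normalized score is the column score per observation
  expect_equal(info$s_prime, info$score / 3, tolerance = 1e-12)
})
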