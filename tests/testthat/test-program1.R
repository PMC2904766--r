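strong_prior <- symmetric_dirichlet(0.2, 4)

test_that("default gap costs reproduce the stated gap statistics", {
  fr <- gap_frequencies(gap_params())
  # insertions: 9.25 + 0.25 l bits <-> frequency 0.87% per motif position
  expect_equal(fr$ins$frequency, 0.0087, tolerance = 0.02)
  # deletions: 8.5 + 1.0 l bits <-> frequency 0.28%, mean length 2.0
  expect_equal(fr$del$frequency, 0.0028, tolerance = 0.02)
  expect_equal(fr$del$mean_length, 2.0, tolerance = 0.02)
  # no-gap penalty is the log probability of not initiating a gap
  expect_equal(gap_params()$no_gap_penalty,
               -log2(1 - fr$ins$frequency - fr$del$frequency),
               tolerance = 1e-12)
  # symmetric mode copies insertion costs to deletions
  gs <- gap_params(symmetric = TRUE)
  expect_equal(gs$del_open, gs$ins_open)
  expect_equal(gs$del_extend, gs$ins_extend)
  expect_error(gap_params(ins_extend = 0), "extend")
})

test_that("semi-global alignment solves the worked toy instances", {
  pssm <- rbind(c(2, -1, -1, -1), c(-1, -1, 2, -1))
  gp <- gap_params(2, 1, 2, 1, no_gap_penalty = 0)
  h <- semiglobal_align(pssm, gp, encode_residues("AAG", dna))
  expect_equal(h[c("start", "end", "path")],
               list(start = 2L, end = 3L, path = "MM"))
  expect_equal(h$score, 4)
  # matching a poor letter beats deleting the column (1 vs -1)
  h2 <- semiglobal_align(pssm, gp, encode_residues("AC", dna))
  expect_equal(h2$path, "MM")
  expect_equal(h2$score, 1)
  # single-column profile, single matching letter
  h3 <- semiglobal_align(matrix(c(2, -1, -1, -1), 1), gp,
                         encode_residues("A", dna))
  expect_equal(h3$path, "M")
  expect_equal(h3$score, 2)
})

test_that("semi-global DP equals exhaustive path enumeration", {
  set.seed(51)
  for (t in 1:40) {
    W <- sample(1:3, 1); L <- sample(1:6, 1)
    pssm <- matrix(round(rnorm(W * 4, 0, 2), 2), W, 4)
    io <- round(runif(1, 0, 4), 2); ie <- round(runif(1, 0.1, 2), 2)
    do_ <- round(runif(1, 0, 4), 2); de <- round(runif(1, 0.1, 2), 2)
    eps <- round(runif(1, 0, 0.5), 2)
    res <- sample.int(4, L, replace = TRUE)
    gp <- gap_params(io, ie, do_, de, no_gap_penalty = eps)
    h <- semiglobal_align(pssm, gp, res)
    expect_equal(h$score, brute_semiglobal(pssm, res, eps, io, ie, do_, de),
                 tolerance = 1e-9)
    # the reported path re-scores to the reported score
    expect_equal(score_path(pssm, h$path, res, h$start, eps, io, ie,
                            do_, de), h$score, tolerance = 1e-9)
    # path structure: M+D count = W, M+I count = segment length
    st <- strsplit(h$path, "")[[1]]
    expect_equal(sum(st != "I"), W)
    expect_equal(sum(st != "D"), max(0L, h$end - h$start + 1L))
  }
})

test_that("splitting an insertion never improves an affine score", {
  set.seed(52)
  gp <- gap_params(3, 0.5, 3, 0.5, no_gap_penalty = 0)
  # one insertion of length l costs open + l*ext; two cost an extra open
  expect_lt(-(2 * gp$ins_open + 4 * gp$ins_extend),
            -(gp$ins_open + 4 * gp$ins_extend))
  # and optimal paths re-score exactly under the affine scorer
  for (t in 1:10) {
    pssm <- matrix(round(rnorm(12, 0, 2), 1), 3, 4)
    res <- sample.int(4, 6, replace = TRUE)
    h <- semiglobal_align(pssm, gp, res)
    expect_equal(score_path(pssm, h$path, res, h$start, 0, 3, 0.5, 3, 0.5),
                 h$score, tolerance = 1e-9)
  }
})

test_that("greedy scanning finds both implanted copies and never overlaps", {
  set.seed(53)
  # protein-scale margins: a strong 12-column motif implanted twice,
  # 50 background letters apart; chance windows score deeply negative
  aa <- protein_alphabet()
  prior20 <- symmetric_dirichlet(1, 20)
  rho <- sample_multinomials(12, symmetric_dirichlet(0.05, 20))
  motif <- apply(rho, 1, which.max)
  bg <- function(n) sample.int(20, n, replace = TRUE)
  res <- c(bg(10), motif, bg(50), motif, bg(10))
  counts <- diag(20)[motif, , drop = FALSE] * 6  # 6 pseudo-observations
  info <- bild:::pssm_from_counts(prior20, counts, aa$background)
  gp <- gap_params()
  hits <- greedy_scan(info$pssm, gp, res, report_threshold = 0)
  expect_equal(length(hits), 2L)
  starts <- sort(vapply(hits, `[[`, integer(1), "start"))
  expect_equal(starts, c(11L, 73L))
  # non-overlap by construction
  expect_true(hits[[1]]$end < hits[[2]]$start ||
                hits[[2]]$end < hits[[1]]$start)
})

test_that("background-only sequences rarely produce positive-threshold hits", {
  set.seed(54)
  aa <- protein_alphabet()
  prior20 <- symmetric_dirichlet(1, 20)
  rho <- sample_multinomials(16, symmetric_dirichlet(0.1, 20))
  counts <- 8 * rho
  info <- bild:::pssm_from_counts(prior20, counts, aa$background)
  gp <- gap_params()
  n_hit <- 0L
  for (i in 1:40) {
    res <- sample.int(20, 120, replace = TRUE)
    hits <- greedy_scan(info$pssm, gp, res, report_threshold = 0)
    if (length(hits) > 0L) n_hit <- n_hit + 1L
  }
  expect_lte(n_hit / 40, 0.05)
})

test_that("iterative realignment converges with non-decreasing objective", {
  spec <- implant_spec(12, 150, 16, strong_prior, dna,
                       ins_rate = 0.02, ins_mean = 4)
  d <- generate_gapped(spec, seed = 55)
  g <- run_sampler(d$sequences, strong_prior, seed = 56, restarts = 3,
                   sweeps = 60, min_width = 10, max_width = 24)
  al <- iterate_alignment(d$sequences, g, strong_prior, gap_params())
  expect_s3_class(al, "bild_alignment")
  expect_gt(al$objective, 0)
  # every reported hit's score is recomputable from its path
  for (i in seq_len(nrow(al$hits))) {
    k <- match(al$hits$seq_id[i], d$sequences$id)
    loo <- bild:::pssm_from_counts(strong_prior,
                                   bild:::counts_excluding(al$profile,
                                                           al$hits$seq_id[i]),
                                   al$profile$background)
    gp <- gap_params()
    expect_equal(score_path(loo$pssm, al$hits$path[i],
                            d$sequences$residues[[k]], al$hits$start[i],
                            gp$no_gap_penalty, gp$ins_open, gp$ins_extend,
                            gp$del_open, gp$del_extend),
                 al$hits$score_bits[i], tolerance = 1e-8)
  }
  # convergence is a fixed point: one more realignment pass against the
  # returned profile reproduces the converged objective exactly
  out <- bild:::realign_all(d$sequences, al$profile, gap_params(), FALSE,
                            "affine")
  retained <- out$hits[out$hits$score_bits > 0, , drop = FALSE]
  expect_equal(bild:::round_objective(retained, d$sequences,
                                      al$profile$width),
               al$objective, tolerance = 1e-8)
})

test_that("width adjustment trims uninformative and adds conserved columns", {
  spec <- implant_spec(10, 120, 14, strong_prior, dna)
  d <- generate_ungapped(spec, seed = 57)
  g <- run_sampler(d$sequences, strong_prior, seed = 58, restarts = 3,
                   sweeps = 50, min_width = 8, max_width = 20)
  al <- iterate_alignment(d$sequences, g, strong_prior, gap_params())

  # force a too-narrow profile: drop the first true column, then adjust
  narrow <- iterate_alignment(
    d$sequences,
    list(offsets = d$truth$offset + 1L, width = 13L),
    strong_prior, gap_params())
  adj <- adjust_width(narrow, d$sequences, gap_params())
  expect_gte(adj$objective, narrow$objective)
  expect_gte(adj$profile$width, narrow$profile$width)

  # adjustment at a local optimum is idempotent
  adj2 <- adjust_width(adj, d$sequences, gap_params())
  expect_equal(adj2$objective, adj$objective, tolerance = 1e-9)
  expect_equal(adj2$profile$width, adj$profile$width)
})
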