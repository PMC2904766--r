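strong_prior <- symmetric_dirichlet(0.2, 4)

toy_info <- function(s_bar, s_prime, W = length(s_bar)) {
  list(pssm = matrix(0, W, 4), s_bar = s_bar, s_prime = s_prime)
}

test_that("HMM construction derives gap costs from column scores", {
  # deletion extension through a column is c * |s_bar|
  h <- build_hmm(toy_info(c(-0.25, -1), c(0, 0)), c_mult = 2.5)
  expect_equal(h$del_ext, c(0.625, 2.5))
  # s_prime (1.2, 0.1, 1.3) with T = 1: the straddling pair (1,3) forbids
  # both internal junctions
  h <- build_hmm(toy_info(c(-1, -1, -1), c(1.2, 0.1, 1.3)), threshold = 1)
  expect_equal(h$ins_allowed, c(FALSE, FALSE))
  # adjacent pair rule
  h <- build_hmm(toy_info(rep(-1, 4), c(1.5, 1.5, 0.2, 0.2)), threshold = 1)
  expect_equal(h$ins_allowed, c(FALSE, TRUE, TRUE))
  # all s_prime at or below threshold: every junction permits insertion
  h <- build_hmm(toy_info(rep(-1, 3), c(1, 0.5, 1)), threshold = 1)
  expect_equal(h$ins_allowed, c(TRUE, TRUE))
  expect_error(build_hmm(toy_info(-1, 0), c_mult = 0), "c_mult")
  expect_error(build_hmm(toy_info(-1, 0), threshold = -1), "threshold")
})

test_that("insertion permissions depend only on the profile, not the query", {
  info <- toy_info(rep(-0.5, 5), c(1.2, 0.3, 1.1, 1.3, 0.2))
  h <- build_hmm(info)
  flags <- h$ins_allowed
  set.seed(61)
  for (i in 1:5) {
    res <- sample.int(4, sample(3:10, 1), replace = TRUE)
    viterbi_semiglobal(h, res)
    expect_identical(h$ins_allowed, flags)
  }
})

test_that("Viterbi equals exhaustive enumeration with position-specific costs", {
  set.seed(62)
  for (t in 1:40) {
    W <- sample(1:3, 1); L <- sample(1:6, 1)
    pssm <- matrix(round(rnorm(W * 4, 0, 2), 2), W, 4)
    io <- round(runif(1, 0, 4), 2); ie <- round(runif(1, 0.1, 2), 2)
    do_ <- round(runif(1, 0, 4), 2)
    de <- round(runif(W, 0.1, 2), 2)
    eps <- round(runif(1, 0, 0.5), 2)
    allowed <- if (W > 1) runif(W - 1) > 0.3 else logical(0)
    res <- sample.int(4, L, replace = TRUE)
    hmm <- raw_hmm(pssm, de, do_, io, ie, allowed, eps)
    h <- viterbi_semiglobal(hmm, res)
    expect_equal(h$score,
                 brute_semiglobal(pssm, res, eps, io, ie, do_, de, allowed),
                 tolerance = 1e-9)
    expect_equal(score_path(pssm, h$path, res, h$start, eps, io, ie, do_,
                            de, allowed), h$score, tolerance = 1e-9)
    # forbidden insertions never appear in emitted paths
    if (W > 1 && any(!allowed)) {
      st <- strsplit(h$path, "")[[1]]
      j <- 0L
      for (s in st) {
        if (s %in% c("M", "D")) j <- j + 1L
        else expect_true(allowed[j])
      }
    }
  }
})

test_that("uniform-cost Viterbi matches the affine semi-global DP", {
  set.seed(63)
  for (t in 1:20) {
    W <- sample(2:6, 1); L <- sample(4:12, 1)
    pssm <- matrix(round(rnorm(W * 4, 0, 2), 2), W, 4)
    io <- round(runif(1, 1, 6), 2); ie <- round(runif(1, 0.1, 1.5), 2)
    do_ <- round(runif(1, 1, 6), 2); de <- round(runif(1, 0.1, 1.5), 2)
    eps <- 0.02
    res <- sample.int(4, L, replace = TRUE)
    gp <- gap_params(io, ie, do_, de, no_gap_penalty = eps)
    hmm <- raw_hmm(pssm, de, do_, io, ie, rep(TRUE, W - 1), eps)
    expect_equal(viterbi_semiglobal(hmm, res)$score,
                 semiglobal_align(pssm, gp, res)$score, tolerance = 1e-8)
  }
})

test_that("insertions route around forbidden junctions to the optimum", {
  # 3 columns wanting A,C,G; insertion forbidden between columns 1-2;
  # sequence carries an extra letter that must go to junction 2 or a flank
  pssm <- matrix(-3, 3, 4)
  pssm[cbind(1:3, 1:3)] <- 4
  hmm <- raw_hmm(pssm, 1, 2, 1.5, 0.5, c(FALSE, TRUE), 0)
  res <- encode_residues("ATCTG", dna)
  h <- viterbi_semiglobal(hmm, res)
  expect_equal(h$score,
               brute_semiglobal(pssm, res, 0, 1.5, 0.5, 2, 1,
                                c(FALSE, TRUE)), tolerance = 1e-9)
  # the extra T between A and C cannot be inserted at junction 1
  st <- strsplit(h$path, "")[[1]]
  j <- 0L
  for (s in st) {
    if (s %in% c("M", "D")) j <- j + 1L else expect_gte(j, 2L)
  }
})

test_that("raising the deletion multiplier protects informative columns", {
  set.seed(64)
  # profile with two highly informative columns amid weak ones
  s_bar <- c(-0.1, -1.5, -0.1, -1.5, -0.1)
  pssm <- matrix(round(rnorm(20, -0.5, 1), 2), 5, 4)
  res <- sample.int(4, 3, replace = TRUE)  # short: forces deletions
  del_hi <- function(cm) {
    h <- build_hmm(list(pssm = pssm, s_bar = s_bar, s_prime = rep(0, 5)),
                   c_mult = cm, del_open = 1, ins_open = 2, ins_extend = 0.5,
                   no_gap_penalty = 0)
    path <- strsplit(viterbi_semiglobal(h, res)$path, "")[[1]]
    j <- 0L; n <- 0L
    for (s in path) {
      if (s %in% c("M", "D")) j <- j + 1L
      if (s == "D" && abs(s_bar[j]) > stats::median(abs(s_bar))) n <- n + 1L
    }
    n
  }
  counts <- vapply(c(0.5, 1, 2.5, 5), del_hi, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the HMM pipeline matches Program 1 on insertion-free data", {
  spec <- implant_spec(10, 120, 14, strong_prior, dna)
  d <- generate_ungapped(spec, seed = 65)
  al1 <- run_program1(d$sequences, strong_prior, seed = 66, restarts = 3,
                      sweeps = 50, min_width = 10, max_width = 20,
                      adjust = FALSE)
  al2 <- run_program2(d$sequences, strong_prior, seed = 66, restarts = 3,
                      sweeps = 50, min_width = 10, max_width = 20)
  expect_lt(abs(al1$objective - al2$objective), 1)
  # determinism under a fixed seed
  al2b <- run_program2(d$sequences, strong_prior, seed = 66, restarts = 3,
                       sweeps = 50, min_width = 10, max_width = 20)
  expect_identical(al2$hits, al2b$hits)
})

test_that("long insertions land in permitted low-conservation junctions", {
  set.seed(67)
  # strong motif; one sequence carries a 15-letter central insertion
  spec <- implant_spec(12, 140, 16, strong_prior, dna)
  d <- generate_ungapped(spec, seed = 68)
  seqs <- d$sequences
  k <- 3L
  off <- d$truth$offset[k]
  res <- seqs$residues[[k]]
  ins <- sample.int(4, 15, replace = TRUE)
  cut <- off + 8L  # middle of the motif
  seqs$residues[[k]] <- c(res[1:(cut - 1L)], ins, res[cut:length(res)])
  al <- run_program2(seqs, strong_prior, seed = 69, restarts = 3,
                     sweeps = 50, min_width = 12, max_width = 20)
  h <- al$hits[al$hits$seq_id == seqs$id[k], , drop = FALSE]
  expect_gte(nrow(h), 1L)
  # the hit either spans the insertion as a single I-run or stops beside it
  expect_true(any(grepl("I{10,}", h$path)) || all(!grepl("I", h$path)))
})

test_that("HMM export writes a readable plain-text table", {
  f <- withr::local_tempfile(fileext = ".tsv")
  h <- build_hmm(toy_info(c(-0.5, -1), c(0.2, 1.4)))
  write_hmm(h, dna, f)
  tab <- utils::read.delim(f)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$del_ext, c(1.25, 2.5))
})
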