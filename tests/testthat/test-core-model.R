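test_that("error_prob maps PHRED scores to error probabilities", {
  expect_equal(error_prob(0), 1.0)
  expect_equal(error_prob(10), 0.1)
  expect_equal(error_prob(20), 0.01)
  expect_equal(error_prob(c(0, 10, 20)), c(1, 0.1, 0.01))
  expect_error(error_prob(-1), "PHRED")
})

test_that("match_prob scores adaptor-template alignment positions", {
  expect_equal(match_prob("A", "A", 20, FALSE), 0.99)
  expect_equal(match_prob("A", "C", 20, FALSE), 0.01 / 3)
  expect_equal(match_prob("A", "C", 57, TRUE), 0.25)
  expect_equal(match_prob("G", "G", 12, TRUE), 0.25)
  ## N is uninformative on either side
  expect_equal(match_prob("N", "A", 20, FALSE), 0.25)
  expect_equal(match_prob("A", "N", 20, FALSE), 0.25)
  ## qualities below the floor behave like quality 2
  expect_equal(match_prob("A", "A", 0, FALSE), match_prob("A", "A", 2, FALSE))
  expect_error(match_prob("A", "B", 20, FALSE), "bases")
})

test_that("adaptor_loglik is the per-base product over the read suffix", {
  r <- read_record("r", "ACGT", rep(20, 4))
  ## start at the read end: empty product
  expect_identical(adaptor_loglik(r, "AG", 4), 0)
  ## mixed match / mismatch / beyond-adaptor positions
  expect_equal(adaptor_loglik(r, "AG", 0),
               log(0.99) + log(0.01 / 3) + 2 * log(0.25))
  ## a perfect adaptor suffix
  r2 <- read_record("r2", "TTTTTACGTG", rep(20, 10))
  expect_equal(adaptor_loglik(r2, "ACGTG", 5), 5 * log(0.99))
  expect_error(adaptor_loglik(r, "AG", 5), "start")
  expect_error(adaptor_loglik(r, "AG", -1), "start")
})

test_that("overlap_base_loglik marginalises over the template base", {
  expect_equal(overlap_base_loglik("A", 20, "A", 20),
               log(0.25 * (0.99^2 + 3 * (0.01 / 3)^2)))
  expect_equal(overlap_base_loglik("A", 20, "C", 20),
               log(0.25 * (2 * 0.99 * (0.01 / 3) + 2 * (0.01 / 3)^2)))
  ## symmetric in the two observations, on a grid of cases
  set.seed(11)
  for (k in 1:50) {
    b <- sample(c("A", "C", "G", "T", "N"), 2, replace = TRUE)
    q <- sample(0:40, 2, replace = TRUE)
    expect_equal(overlap_base_loglik(b[1], q[1], b[2], q[2]),
                 overlap_base_loglik(b[2], q[2], b[1], q[1]))
  }
  ## agrees with the brute-force four-nucleotide sum
  for (k in 1:25) {
    b <- sample(c("A", "C", "G", "T"), 2, replace = TRUE)
    q <- sample(2:40, 2, replace = TRUE)
    expect_equal(overlap_base_loglik(b[1], q[1], b[2], q[2]),
                 log(oracle_overlap(b[1], q[1], b[2], q[2])))
  }
})

test_that("reverse_complement flips bases and qualities together", {
  r <- reverse_complement(read_record("r", "ACGT", c(10, 20, 30, 40)))
  expect_equal(r$bases, "ACGT")           # ACGT is its own revcomp
  expect_equal(r$quals, c(40L, 30L, 20L, 10L))
  rn <- reverse_complement(read_record("r", "AAN", c(5, 6, 7)))
  expect_equal(rn$bases, "NTT")
  expect_equal(rn$quals, c(7L, 6L, 5L))
  orig <- read_record("r", "GATTACA", 1:7)
  expect_equal(reverse_complement(reverse_complement(orig)), orig)
  expect_error(read_record("r", "AXGT", rep(10, 4)), "bases")
})

test_that("length_loglik matches the boundary geometry", {
  set.seed(21)
  a <- adaptor_pair()
  pr <- make_random_pair(12, 9)
  u <- length_prior("uniform")
  L <- 21
  ## i = l1 + l2: no adaptor, no overlap, all singly covered
  expect_equal(length_loglik(pr$r1, pr$r2, a, L, u),
               -log(L + 2) + L * log(0.25))
  ## i = 0: pure adaptor dimer, value is prior + both full adaptor terms
  expect_equal(length_loglik(pr$r1, pr$r2, a, 0, u),
               -log(L + 2) + adaptor_loglik(pr$r1, a$a1, 0) +
                 adaptor_loglik(pr$r2, a$a2, 0))
  expect_error(length_loglik(pr$r1, pr$r2, a, 22, u), "0..l1\\+l2")
})

test_that("adaptor-dimer reads are recognised as length 0", {
  a <- adaptor_pair()
  r1 <- read_record("d", substr(a$a1, 1, 20), rep(40, 20))
  r2 <- read_record("d", substr(a$a2, 1, 20), rep(40, 20))
  p <- posterior_profile(r1, r2, a, length_prior("uniform"))
  expect_equal(p$best_i, 0L)
  expect_equal(p$log_post[1],
               -log(42) + adaptor_loglik(r1, a$a1, 0) +
                 adaptor_loglik(r2, a$a2, 0))
})

test_that("no_merge_loglik is prior tail mass times (1/4)^(l1+l2)", {
  pr <- make_random_pair(10, 10)
  ## degenerate tail mass 1: log-normal prior far above the read span
  big <- length_prior("lognormal", mu = 50, sigma = 0.1)
  expect_equal(no_merge_loglik(pr$r1, pr$r2, big), 20 * log(0.25))
  ln <- length_prior("lognormal", mu = 3.8, sigma = 0.3)
  expect_equal(no_merge_loglik(pr$r1, pr$r2, ln),
               log(1 - plnorm(20, 3.8, 0.3)) + 20 * log(0.25))
  ## tail mass decreases as the combined read length grows
  tm <- sapply(c(20, 50, 100, 200), tail_mass, prior = ln)
  expect_true(all(diff(tm) < 0))
})

test_that("posterior_profile agrees with per-hypothesis length_loglik", {
  set.seed(31)
  a <- adaptor_pair("ACGGTTAC", "TGGCCATA")
  for (prior in list(length_prior("uniform"),
                     length_prior("lognormal", 3.0, 0.4))) {
    pr <- make_random_pair(14, 11)
    p <- posterior_profile(pr$r1, pr$r2, a, prior)
    direct <- sapply(0:25, function(i) {
      length_loglik(pr$r1, pr$r2, a, i, prior)
    })
    expect_equal(p$log_post, direct, tolerance = 1e-12)
    expect_equal(p$log_no_merge, no_merge_loglik(pr$r1, pr$r2, prior))
  }
})

test_that("the normalised posterior over all hypotheses sums to one", {
  set.seed(41)
  pr <- make_clean_pair(rand_seq(35), 60)
  p <- posterior_profile(pr$r1, pr$r2)
  expect_equal(sum(readmerge:::.normalized_posterior(p)), 1,
               tolerance = 1e-9)
  expect_true(p$log_odds >= 0)
})

test_that("a noiseless overlapping pair recovers the true length", {
  set.seed(51)
  pr <- make_clean_pair(rand_seq(30), 50)
  p <- posterior_profile(pr$r1, pr$r2)
  expect_equal(p$best_i, 30L)
  expect_false(p$best_is_no_merge)
  expect_gt(p$log_odds, log(20))
})

test_that("swapping the reads (and adaptors) leaves the profile invariant", {
  set.seed(61)
  a <- adaptor_pair()
  for (mol_len in c(25, 60, 130)) {
    pr <- make_clean_pair(rand_seq(mol_len), 80, q = 30)
    swapped <- adaptor_pair(a$a2, a$a1)
    p1 <- posterior_profile(pr$r1, pr$r2, a)
    p2 <- posterior_profile(pr$r2, pr$r1, swapped)
    expect_equal(p1$log_post, p2$log_post, tolerance = 1e-12)
    expect_equal(p1$best_i, p2$best_i)
  }
})

test_that("decide applies the 1-in-20 ambiguity guard", {
  mk <- function(log_post, log_no_merge) {
    readmerge:::.build_posterior(log_post, log_no_merge, 5L, 5L, "pair")
  }
  ## clear winner: ratio exp(-9) is far below 1/20
  d <- decide(mk(c(-1, rep(-10, 9)), -10))
  expect_equal(d$decision, "merged")
  expect_equal(d$inferred_length, 0L)
  ## exact tie: ratio 1 exceeds any threshold < 1
  expect_equal(decide(mk(c(-1, -1, rep(-10, 8)), -10))$decision,
               "ambiguous")
  ## at threshold 1 the guard can never fire
  expect_equal(decide(mk(c(-1, -1, rep(-10, 8)), -10), 1)$decision,
               "merged")
  ## winning no-merge hypothesis keeps the pair
  expect_equal(decide(mk(rep(-10, 10), -1))$decision, "kept_as_pair")
  expect_error(decide(mk(c(-1, rep(-10, 9)), -10), 0), "ratio_threshold")
})

test_that("single-end profiles find the adaptor start", {
  set.seed(71)
  a1 <- DEFAULT_ADAPTOR1
  mol <- rand_seq(60)
  t <- substr(paste0(mol, a1, rand_seq(40)), 1, 100)
  r <- read_record("s", t, rep(40, 100))
  p <- single_end_profile(r, a1, length_prior("uniform"))
  expect_equal(p$best_i, 60L)
  d <- decide(p)
  expect_equal(d$decision, "trimmed_single")
  ## i = l entry is prior + l * log(1/4) (no adaptor observed)
  expect_equal(p$log_post[101], -log(102) + 100 * log(0.25))
  ## a read with no adaptor content: no-trim wins or the guard fires
  rn <- read_record("n", rand_seq(100), rep(40, 100))
  pn <- single_end_profile(rn, a1, length_prior("uniform"))
  dn <- decide(pn)
  expect_true(pn$best_is_no_merge || dn$decision == "ambiguous")
})

test_that("posterior_profile matches the brute-force oracle on short reads", {
  set.seed(81)
  for (k in 1:20) {
    pr <- make_random_pair(sample(4:15, 1), sample(4:15, 1))
    a <- adaptor_pair(rand_seq(sample(3:10, 1)), rand_seq(sample(3:10, 1)))
    prior <- if (k %% 2) length_prior("uniform") else
      length_prior("lognormal", 2.5, 0.5)
    p <- posterior_profile(pr$r1, pr$r2, a, prior)
    o <- oracle_posterior(pr$r1, pr$r2, a$a1, a$a2, prior)
    expect_equal(exp(p$log_post), o$probs, tolerance = 1e-9)
    expect_equal(exp(p$log_no_merge), o$no_merge, tolerance = 1e-9)
  }
})
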