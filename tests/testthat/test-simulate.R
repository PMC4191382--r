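test_that("noiseless reads are molecule + adaptor + padding by construction", {
  a <- adaptor_pair()
  cfg <- sim_config(n_pairs = 5, read_len = 100, error_rate = 0,
                    length_dist = list(kind = "empirical", lengths = 30L),
                    seed = 3)
  sim <- simulate_pairs(cfg)
  for (k in 1:5) {
    mol <- sim$truth$true_sequence[k]
    expect_equal(nchar(mol), 30L)
    expect_equal(substr(sim$r1[[k]]$bases, 1, 30), mol)
    expect_equal(substr(sim$r1[[k]]$bases, 31, 64), a$a1)
    expect_equal(substr(sim$r2[[k]]$bases, 1, 30), oracle_revcomp(mol))
    expect_equal(substr(sim$r2[[k]]$bases, 31, 64), a$a2)
    expect_equal(nchar(sim$r1[[k]]$bases), 100L)
  }
})

test_that("long molecules fill the whole read", {
  cfg <- sim_config(n_pairs = 3, read_len = 50, error_rate = 0,
                    length_dist = list(kind = "empirical",
                                       lengths = 120L), seed = 4)
  sim <- simulate_pairs(cfg)
  for (k in 1:3) {
    mol <- sim$truth$true_sequence[k]
    expect_equal(sim$r1[[k]]$bases, substr(mol, 1, 50))
    expect_equal(sim$r2[[k]]$bases,
                 substr(oracle_revcomp(mol), 1, 50))
  }
})

test_that("simulation is reproducible from the seed", {
  cfg <- sim_config(n_pairs = 20, read_len = 60, error_rate = 0.05,
                    seed = 99)
  s1 <- simulate_pairs(cfg)
  s2 <- simulate_pairs(cfg)
  expect_identical(s1, s2)
  s3 <- simulate_pairs(sim_config(n_pairs = 20, read_len = 60,
                                  error_rate = 0.05, seed = 100))
  expect_false(identical(s1$truth$true_sequence, s3$truth$true_sequence))
})

test_that("injected error rate is recovered within binomial noise", {
  rate <- 0.05
  n <- 600L
  rl <- 100L
  cfg <- sim_config(n_pairs = n, read_len = rl, error_rate = rate,
                    length_dist = list(kind = "empirical",
                                       lengths = 150L), seed = 12)
  sim <- simulate_pairs(cfg)
  mism <- 0L
  for (k in seq_len(n)) {
    tmpl <- substr(sim$truth$true_sequence[k], 1, rl)
    mism <- mism + sum(strsplit(sim$r1[[k]]$bases, "")[[1]] !=
                         strsplit(tmpl, "")[[1]])
  }
  total <- n * rl
  tol <- 3 * sqrt(rate * (1 - rate) / total)
  expect_lt(abs(mism / total - rate), tol)
})

test_that("erroneous bases receive lower quality scores than correct ones", {
  cfg <- sim_config(n_pairs = 200, read_len = 80, error_rate = 0.1,
                    length_dist = list(kind = "empirical",
                                       lengths = 120L), seed = 13)
  sim <- simulate_pairs(cfg)
  qerr <- c()
  qok <- c()
  for (k in seq_along(sim$r1)) {
    tmpl <- strsplit(substr(sim$truth$true_sequence[k], 1, 80), "")[[1]]
    got <- strsplit(sim$r1[[k]]$bases, "")[[1]]
    bad <- got != tmpl
    qerr <- c(qerr, sim$r1[[k]]$quals[bad])
    qok <- c(qok, sim$r1[[k]]$quals[!bad])
  }
  expect_lt(mean(qerr), mean(qok) - 10)
})

test_that("truth table is internally consistent", {
  sim <- simulate_pairs(sim_config(n_pairs = 50, seed = 5))
  expect_equal(nchar(sim$truth$true_sequence), sim$truth$true_length)
  expect_equal(anyDuplicated(sim$truth$id), 0L)
  expect_equal(vapply(sim$r1, `[[`, character(1), "id"), sim$truth$id)
})

test_that("molecules can be drawn from a reference FASTA, skipping N", {
  fa <- tempfile(fileext = ".fa")
  set.seed(6)
  writeLines(c(">chr_test",
               paste0(rand_seq(300), "NNNNN", rand_seq(50))), fa)
  cfg <- sim_config(n_pairs = 30, read_len = 40, reference = fa,
                    length_dist = list(kind = "empirical",
                                       lengths = 25:35), seed = 7)
  sim <- simulate_pairs(cfg)
  expect_false(any(grepl("N", sim$truth$true_sequence)))
  expect_error(
    simulate_pairs(sim_config(n_pairs = 2, reference = fa,
                              length_dist = list(kind = "empirical",
                                                 lengths = 500L),
                              seed = 8)),
    "shorter")
})

test_that("empirical quality profiles drive emitted scores", {
  prof <- data.frame(qual = c(40L, 12L), error = c(FALSE, TRUE),
                     freq = c(1, 1))
  cfg <- sim_config(n_pairs = 40, read_len = 50, error_rate = 0.2,
                    length_dist = list(kind = "empirical",
                                       lengths = 80L),
                    qual_profile = prof, seed = 9)
  sim <- simulate_pairs(cfg)
  expect_true(all(unlist(lapply(sim$r1, `[[`, "quals")) %in% c(40L, 12L)))
})

test_that("simulate_single builds trimming ground truth", {
  cfg <- sim_config(n_pairs = 10, read_len = 100, error_rate = 0,
                    length_dist = list(kind = "empirical", lengths = 55L),
                    seed = 10)
  sim <- simulate_single(cfg)
  a1 <- adaptor_pair()$a1
  expect_equal(substr(sim$reads[[1]]$bases, 1, 55),
               sim$truth$true_sequence[1])
  expect_equal(substr(sim$reads[[1]]$bases, 56, 89), a1)
})

test_that("score_reconstruction computes the headline metrics", {
  truth <- data.frame(id = c("a", "b", "c"),
                      true_length = c(4L, 5L, 300L),
                      true_sequence = c("ACGT", "GGTTA", "TTTT"),
                      stringsAsFactors = FALSE)
  res_of <- function(decision, seq = NULL, len = NA_integer_, lim = 200L) {
    r <- structure(list(decision = decision, inferred_length = len,
                        log_odds = 10, sequence = seq),
                   class = "merge_result")
    attr(r, "combined_read_len") <- lim
    r
  }
  ## perfect output
  out <- list(res_of("merged", read_record("a", "ACGT", rep(40, 4)), 4L),
              res_of("merged", read_record("b", "GGTTA", rep(40, 5)), 5L),
              res_of("ambiguous"))
  sc <- score_reconstruction(truth, out)
  expect_equal(sc$perfect_fraction, 2 / 3)
  expect_equal(sc$correct_length_fraction, 2 / 3)
  expect_equal(sc$ambiguous_count, 1L)
  expect_equal(sc$false_merge_count, 0L)
  ## a merged call for a long molecule is a false merge
  out[[3]] <- res_of("merged", read_record("c", "TCGA", rep(40, 4)), 4L)
  expect_equal(score_reconstruction(truth, out)$false_merge_count, 1L)
  ## everything ambiguous
  out0 <- list(res_of("ambiguous"), res_of("ambiguous"),
               res_of("ambiguous"))
  sc0 <- score_reconstruction(truth, out0)
  expect_equal(sc0$perfect_fraction, 0)
  expect_equal(sc0$correct_length_fraction, 0)
  expect_equal(sc0$ambiguous_count, 3L)
  ## misaligned identifiers are an error
  bad <- list(res_of("merged", read_record("zzz", "ACGT", rep(40, 4)), 4L),
              res_of("ambiguous"), res_of("ambiguous"))
  expect_error(score_reconstruction(truth, bad), "identifiers")
})
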