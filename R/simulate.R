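## Read-pair simulator with known ground truth.
##
## Emulates paired-end sequencing of a library whose molecules may be
## shorter than the read length: read 1 is the molecule prefix followed
## by adaptor 1 (and, if the adaptor is exhausted, random bases, as on a
## real run where the sequencer keeps reading past the adaptor); read 2
## is the reverse complement suffix followed by adaptor 2 likewise.
## Substitution errors are injected independently per base; qualities
## are drawn from separate parametric distributions for correct and
## erroneous calls, or from an empirical profile table.

#' Simulation configuration
#'
#' Defines the conditions under which read pairs are generated. The
#' default molecule-length distribution is log-normal with `mu = 3.8`,
#' `sigma = 0.3` on the log scale (median about 45 bp, almost all mass
#' below 100 bp), the short, narrow distribution characteristic of
#' degraded ancient-DNA libraries; reads are 100 bp.
#'
#' @param n_pairs Number of read pairs to simulate.
#' @param read_len Read length in bp (both mates).
#' @param adaptors An [adaptor_pair()].
#' @param length_dist Either `list(kind = "lognormal", mu =, sigma =)`
#'   or `list(kind = "empirical", lengths = <integer vector>)` sampled
#'   uniformly with replacement.
#' @param error_rate Per-base substitution probability in `[0, 1)`,
#'   applied independently to every base of both reads (molecule,
#'   adaptor and padding alike).
#' @param qual_correct,qual_error `c(mean =, sd =)` of the PHRED score
#'   distribution for correct and for erroneous base calls (normal,
#'   rounded, clamped to `qual_range`). Erroneous calls tend to receive
#'   lower scores, as on a real instrument.
#' @param qual_range Two integers, the clamp range of emitted scores.
#' @param qual_profile Optional empirical profile: a data frame with
#'   columns `qual`, `error` (logical or 0/1) and `freq`; when given it
#'   replaces the parametric quality distributions.
#' @param reference Optional path to a FASTA file; molecules are drawn
#'   from random positions of its sequences, skipping windows containing
#'   `N`. `NULL` (default) generates independent random molecules.
#' @param gc GC fraction for random molecules (default 0.5).
#' @param seed Integer seed; the whole simulation is reproducible from
#'   it (single R Mersenne-Twister stream).
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_pairs = 1000L,
                       read_len = 100L,
                       adaptors = adaptor_pair(),
                       length_dist = list(kind = "lognormal",
                                          mu = 3.8, sigma = 0.3),
                       error_rate = 0,
                       qual_correct = c(mean = 37, sd = 2),
                       qual_error = c(mean = 18, sd = 5),
                       qual_range = c(2L, 41L),
                       qual_profile = NULL,
                       reference = NULL,
                       gc = 0.5,
                       seed = 1L) {
  stopifnot(n_pairs >= 1L, read_len >= 1L,
            inherits(adaptors, "adaptor_pair"),
            error_rate >= 0, error_rate < 1,
            gc > 0, gc < 1)
  if (!length_dist$kind %in% c("lognormal", "empirical")) {
    stop("length_dist$kind must be 'lognormal' or 'empirical'")
  }
  if (length_dist$kind == "empirical" &&
      (length(length_dist$lengths) < 1L || any(length_dist$lengths < 1L))) {
    stop("empirical length distribution needs positive lengths")
  }
  if (!is.null(qual_profile)) {
    if (!all(c("qual", "error", "freq") %in% names(qual_profile))) {
      stop("qual_profile needs columns qual, error, freq")
    }
  }
  structure(list(n_pairs = as.integer(n_pairs),
                 read_len = as.integer(read_len),
                 adaptors = adaptors, length_dist = length_dist,
                 error_rate = error_rate, qual_correct = qual_correct,
                 qual_error = qual_error,
                 qual_range = as.integer(qual_range),
                 qual_profile = qual_profile,
                 reference = reference, gc = gc,
                 seed = as.integer(seed)),
            class = "sim_config")
}

.draw_lengths <- function(cfg, n) {
  ld <- cfg$length_dist
  if (ld$kind == "lognormal") {
    pmax(1L, as.integer(round(stats::rlnorm(n, ld$mu, ld$sigma))))
  } else {
    ## sample.int with explicit indices: safe for length-1 pools
    pool <- as.integer(ld$lengths)
    pool[sample.int(length(pool), n, replace = TRUE)]
  }
}

.random_seq <- function(n_bases, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(NUCS, n_bases, replace = TRUE, prob = p), collapse = "")
}

## draw one molecule of each requested length from a reference sequence
## set, skipping windows with N (resampled up to a cap)
.molecules_from_reference <- function(ref_path, lens, max_tries = 50L) {
  ref <- Biostrings::readDNAStringSet(ref_path)
  widths <- Biostrings::width(ref)
  vapply(lens, function(len) {
    ok <- which(widths >= len)
    if (length(ok) == 0L) {
      stop("reference shorter than requested molecule length ", len)
    }
    for (t in seq_len(max_tries)) {
      s <- if (length(ok) == 1L) ok else sample(ok, 1L)
      pos <- sample.int(widths[s] - len + 1L, 1L)
      mol <- as.character(Biostrings::subseq(ref[[s]], pos, pos + len - 1L))
      if (!grepl("N", mol, fixed = TRUE)) return(mol)
    }
    stop("could not draw an N-free window of length ", len,
         " in ", max_tries, " tries")
  }, character(1))
}

.sample_quals <- function(n, err, cfg) {
  if (!is.null(cfg$qual_profile)) {
    pr <- cfg$qual_profile
    sub <- pr[as.logical(pr$error) == err, , drop = FALSE]
    if (nrow(sub) == 0L) sub <- pr
    as.integer(sub$qual[sample.int(nrow(sub), n, replace = TRUE,
                                   prob = sub$freq)])
  } else {
    par <- if (err) cfg$qual_error else cfg$qual_correct
    q <- round(stats::rnorm(n, par[["mean"]], par[["sd"]]))
    as.integer(pmin(pmax(q, cfg$qual_range[1L]), cfg$qual_range[2L]))
  }
}

## build one sequenced read from a template: inject substitutions at the
## configured rate and attach qualities; returns list(bases=, quals=)
.sequence_read <- function(template, cfg) {
  ch <- .chars(template)
  n <- length(ch)
  err <- stats::runif(n) < cfg$error_rate
  if (any(err)) {
    ch[err] <- vapply(ch[err],
                      function(b) sample(setdiff(NUCS, b), 1L),
                      character(1))
  }
  list(bases = paste(ch, collapse = ""),
       quals = ifelse(err, .sample_quals(n, TRUE, cfg),
                      .sample_quals(n, FALSE, cfg)))
}

#' Simulate read pairs with known ground truth
#'
#' Draws molecule lengths and sequences per the configuration, builds
#' the two reads (molecule + adaptor + random padding, truncated to the
#' read length), injects substitution errors independently per base and
#' attaches quality scores. Fully reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list with elements `r1`, `r2` (lists of [read_record()]s)
#'   and `truth` (a data frame with columns `id`, `true_length`,
#'   `true_sequence`).
#' @seealso [write_simulation()] to emit FASTQ plus a truth TSV,
#'   [score_reconstruction()] to evaluate merge output against the
#'   truth.
#' @export
simulate_pairs <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_pairs
  rl <- config$read_len
  lens <- .draw_lengths(config, n)
  mols <- if (is.null(config$reference)) {
    vapply(lens, function(l) .random_seq(l, config$gc), character(1))
  } else {
    .molecules_from_reference(config$reference, lens)
  }
  ids <- sprintf("sim_%06d", seq_len(n))
  a1 <- config$adaptors$a1
  a2 <- config$adaptors$a2
  r1 <- vector("list", n)
  r2 <- vector("list", n)
  for (k in seq_len(n)) {
    mol <- mols[k]
    t1 <- .read_template(mol, a1, rl, config$gc)
    t2 <- .read_template(.revcomp_chr(mol), a2, rl, config$gc)
    s1 <- .sequence_read(t1, config)
    s2 <- .sequence_read(t2, config)
    r1[[k]] <- read_record(ids[k], s1$bases, s1$quals)
    r2[[k]] <- read_record(ids[k], s2$bases, s2$quals)
  }
  list(r1 = r1, r2 = r2,
       truth = data.frame(id = ids, true_length = lens,
                          true_sequence = mols,
                          stringsAsFactors = FALSE))
}

## molecule strand + adaptor + random padding, truncated to read length
.read_template <- function(strand, adaptor, rl, gc) {
  t <- substr(strand, 1L, rl)
  if (nchar(t) < rl) t <- substr(paste0(t, adaptor), 1L, rl)
  if (nchar(t) < rl) t <- paste0(t, .random_seq(rl - nchar(t), gc))
  t
}

#' Simulate a single-end read set with known trim points
#'
#' Single-read analogue of [simulate_pairs()]: each read is the molecule
#' prefix followed by the adaptor and random padding, truncated to the
#' read length.
#'
#' @param config A [sim_config()]; only `adaptors$a1` is used.
#' @return A list with elements `reads` (list of [read_record()]s) and
#'   `truth` as in [simulate_pairs()].
#' @export
simulate_single <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_pairs
  rl <- config$read_len
  lens <- .draw_lengths(config, n)
  mols <- if (is.null(config$reference)) {
    vapply(lens, function(l) .random_seq(l, config$gc), character(1))
  } else {
    .molecules_from_reference(config$reference, lens)
  }
  ids <- sprintf("sim_%06d", seq_len(n))
  reads <- vector("list", n)
  for (k in seq_len(n)) {
    s <- .sequence_read(.read_template(mols[k], config$adaptors$a1, rl,
                                       config$gc), config)
    reads[[k]] <- read_record(ids[k], s$bases, s$quals)
  }
  list(reads = reads,
       truth = data.frame(id = ids, true_length = lens,
                          true_sequence = mols,
                          stringsAsFactors = FALSE))
}

#' Write a simulation to FASTQ files plus a truth table
#'
#' @param sim Result of [simulate_pairs()].
#' @param fq1,fq2 Output FASTQ paths (gzip if the name ends in `.gz`).
#' @param truth_tsv Output path for the tab-separated truth table
#'   (columns `id`, `true_length`, `true_sequence`).
#' @param offset PHRED offset for the FASTQ output.
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, fq1, fq2, truth_tsv, offset = 33L) {
  write_fastq(sim$r1, fq1, offset = offset)
  write_fastq(sim$r2, fq2, offset = offset)
  utils::write.table(sim$truth, truth_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fq1, fq2, truth_tsv))
}

#' Score reconstructed sequences against the simulation truth
#'
#' A merged sequence is *perfect* when it equals the true molecule
#' exactly, and *correct-length* when its length matches the true
#' length. A *false merge* is a merged call for a molecule whose true
#' length exceeds the combined read length (so no overlap or adaptor
#' was actually present). Fractions are over all pairs.
#'
#' @param truth Truth data frame from [simulate_pairs()].
#' @param outcomes Result of [merge_reads()] on the simulated reads (or
#'   any list of `merge_result`s named/ordered like `truth$id`, each
#'   with the reconstructed `sequence` filled in).
#' @return A list of metrics: `n`, `merged_count`, `ambiguous_count`,
#'   `kept_count`, `perfect_fraction`, `mismatched_fraction` (merged
#'   with >= 1 mismatch), `correct_length_fraction`,
#'   `false_merge_count`.
#' @export
score_reconstruction <- function(truth, outcomes) {
  res <- if (!is.null(outcomes$results)) outcomes$results else outcomes
  if (length(res) != nrow(truth)) {
    stop("truth table and outcomes differ in length")
  }
  ids <- vapply(res, function(r) {
    if (!is.null(r$sequence)) r$sequence$id else NA_character_
  }, character(1))
  known <- !is.na(ids)
  if (any(known & ids != truth$id)) {
    stop("identifiers of outcomes do not align with the truth table")
  }
  dec <- vapply(res, `[[`, character(1), "decision")
  merged <- dec %in% c("merged", "trimmed_single")
  n <- nrow(truth)
  perfect <- logical(n)
  correct_len <- logical(n)
  false_merge <- logical(n)
  for (k in which(merged)) {
    s <- res[[k]]$sequence
    correct_len[k] <- nchar(s$bases) == truth$true_length[k]
    perfect[k] <- correct_len[k] && s$bases == truth$true_sequence[k]
    lim <- attr(res[[k]], "combined_read_len")
    if (!is.null(lim)) false_merge[k] <- truth$true_length[k] > lim
  }
  list(n = n,
       merged_count = sum(merged),
       ambiguous_count = sum(dec == "ambiguous"),
       kept_count = sum(dec == "kept_as_pair"),
       perfect_fraction = mean(perfect),
       mismatched_fraction = mean(merged & !perfect),
       correct_length_fraction = mean(correct_len),
       false_merge_count = sum(false_merge))
}
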