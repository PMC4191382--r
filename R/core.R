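## Core length-inference model.
##
## For a read pair (r1, r2) with adaptors (a1, a2), every candidate
## molecule length i in 0..l1+l2 is scored as
##
##   log P(i | data) = log prior(i)
##                   + adaptor term of r1 beyond position min(i, l1)
##                   + adaptor term of r2 beyond position min(i, l2)
##                   + overlap term over molecule positions covered by
##                     both reads
##                   + log(1/4) per molecule position covered by exactly
##                     one read
##
## Geometry (0-based, half-open): read 1 covers molecule positions
## [0, min(l1, i)); reverse-complemented read 2 covers [max(0, i - l2), i).
## Every hypothesis thus explains exactly l1 + l2 observed bases, which
## makes the hypotheses directly comparable, including the no-merge
## hypothesis (molecule longer than l1 + l2): prior tail mass times
## (1/4)^(l1+l2).

LOG_QUARTER <- log(0.25)

## qualities below 2 are floored before entering the model so that
## 1 - p_e > p_e / 3 always holds (a match is always evidence of a match)
QUAL_FLOOR <- 2L

.pe_floored <- function(q) 10^(-pmax(q, QUAL_FLOOR) / 10)

#' Sequencing error probability of a PHRED score
#'
#' @param q Non-negative integer PHRED score(s).
#' @return `10^(-q/10)`, the probability the base call is wrong.
#' @examples
#' error_prob(c(0, 10, 20, 30))
#' @export
error_prob <- function(q) {
  if (anyNA(q) || any(q < 0)) stop("PHRED scores must be >= 0")
  10^(-q / 10)
}

#' Probability of a read base given an adaptor template base
#'
#' Scores one read position against the adaptor expected at that
#' position: a matching base has probability `1 - p_e(q)`, a mismatching
#' one `p_e(q)/3` (errors are equally likely to produce each of the three
#' other bases). Positions past the adaptor's end have no template and
#' score 1/4; an `N` on either side is an uninformative observation and
#' also scores 1/4. Qualities below 2 are floored at 2.
#'
#' @param adaptor_base,read_base Single bases in `{A,C,G,T,N}`
#'   (vectorised).
#' @param q PHRED score(s) of the read base.
#' @param beyond_adaptor Logical; `TRUE` for read positions past the end
#'   of the adaptor sequence.
#' @return Probability in (0, 1].
#' @examples
#' match_prob("A", "A", 20, FALSE) # 0.99
#' match_prob("A", "C", 20, FALSE) # 0.01/3
#' match_prob("A", "C", 20, TRUE)  # 0.25
#' @export
match_prob <- function(adaptor_base, read_base, q, beyond_adaptor) {
  if (anyNA(q) || any(q < 0)) stop("PHRED scores must be >= 0")
  .check_bases(c(adaptor_base, read_base))
  pe <- .pe_floored(q)
  out <- ifelse(adaptor_base == read_base, 1 - pe, pe / 3)
  out[adaptor_base == "N" | read_base == "N"] <- 0.25
  out[rep_len(beyond_adaptor, length(out))] <- 0.25
  out
}

.check_bases <- function(b) {
  bad <- !(b %in% c("A", "C", "G", "T", "N"))
  if (any(bad)) stop("bases must be in {A,C,G,T,N}, got: ",
                     paste(unique(b[bad]), collapse = ", "))
  invisible(TRUE)
}

#' Log likelihood of a read suffix given an adaptor template
#'
#' Aligns adaptor position 0 to read position `start` (0-based) and sums
#' log [match_prob()] over read positions `start..length(read)-1`; read
#' positions past the adaptor's end contribute `log(1/4)`. Insertions and
#' deletions are not modelled. `start == length(read)` gives the empty
#' product, 0.
#'
#' @param read A [read_record()].
#' @param adaptor Adaptor base string over `{A,C,G,T}`.
#' @param start 0-based read position where the adaptor is assumed to
#'   begin, in `0..length(read)`.
#' @return Log probability (`<= 0`).
#' @examples
#' r <- read_record("r", "ACGT", rep(20, 4))
#' adaptor_loglik(r, "AG", 0)  # log(0.99) + log(0.01/3) + 2*log(0.25)
#' adaptor_loglik(r, "AG", 4)  # 0
#' @export
adaptor_loglik <- function(read, adaptor, start) {
  stopifnot(inherits(read, "read_record"))
  l <- nchar(read$bases)
  if (length(start) != 1L || is.na(start) || start < 0 || start > l) {
    stop("'start' must be in 0..length(read)")
  }
  start <- as.integer(start)
  if (start == l) return(0)
  k <- (start + 1L):l           # 1-based read positions
  rch <- .chars(read$bases)[k]
  pe <- .pe_floored(read$quals[k])
  d <- k - start                # 1-based adaptor positions
  ach <- .chars(adaptor)
  beyond <- d > length(ach)
  tmpl <- rep("N", length(d))   # placeholder, overridden by beyond flag
  tmpl[!beyond] <- ach[d[!beyond]]
  sum(log(match_prob(tmpl, rch, read$quals[k], beyond)))
}

#' Log likelihood that two overlapping base observations share a template
#'
#' Marginalises over the unknown template nucleotide `n`:
#' `log sum_n (1/4) * P(b1 | n) * P(b2 | n)` where `P(b | n)` is
#' `1 - p_e(q)` on a match and `p_e(q)/3` otherwise. An `N` observation
#' contributes 1/4 for every `n`. Symmetric in the two observations.
#' Qualities below 2 are floored at 2.
#'
#' @param b1,b2 Bases in `{A,C,G,T,N}` (vectorised).
#' @param q1,q2 PHRED scores of the two observations.
#' @return Log probability.
#' @examples
#' overlap_base_loglik("A", 20, "A", 20)
#' overlap_base_loglik("A", 20, "C", 20)
#' @export
overlap_base_loglik <- function(b1, q1, b2, q2) {
  .check_bases(c(b1, b2))
  if (anyNA(c(q1, q2)) || any(c(q1, q2) < 0)) {
    stop("PHRED scores must be >= 0")
  }
  p1 <- .pe_floored(q1)
  p2 <- .pe_floored(q2)
  ## S = sum_n P(b1|n) P(b2|n); overlap prob = S / 4
  s <- ifelse(b1 == b2,
              (1 - p1) * (1 - p2) + p1 * p2 / 3,
              (1 - p1) * p2 / 3 + (p1 / 3) * (1 - p2) +
                2 * (p1 / 3) * (p2 / 3))
  s[b1 == "N" | b2 == "N"] <- 0.25
  log(s) + LOG_QUARTER
}

#' Adaptor pair
#'
#' Holds the adaptor expected at the 3' end of read 1 (`a1`) and of
#' read 2 (`a2`). The defaults are the standard Illumina TruSeq
#' read-through sequences; override them for other library preparations.
#'
#' @param a1,a2 Adaptor base strings over `{A,C,G,T}`, non-empty.
#' @return An object of class `adaptor_pair`.
#' @examples
#' adaptor_pair()
#' @export
adaptor_pair <- function(a1 = DEFAULT_ADAPTOR1, a2 = DEFAULT_ADAPTOR2) {
  if (!is.character(a1) || nchar(a1) == 0L ||
      !is.character(a2) || nchar(a2) == 0L) {
    stop("both adaptor sequences must be non-empty strings")
  }
  a1 <- toupper(a1)
  a2 <- toupper(a2)
  if (!grepl("^[ACGT]+$", a1) || !grepl("^[ACGT]+$", a2)) {
    stop("adaptor sequences must be over {A,C,G,T}")
  }
  structure(list(a1 = a1, a2 = a2), class = "adaptor_pair")
}

#' @rdname adaptor_pair
#' @format NULL
#' @export
DEFAULT_ADAPTOR1 <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC"

#' @rdname adaptor_pair
#' @format NULL
#' @export
DEFAULT_ADAPTOR2 <- "AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGTA"

#' @export
print.adaptor_pair <- function(x, ...) {
  cat("<adaptor_pair>\n  a1: ", x$a1, "\n  a2: ", x$a2, "\n", sep = "")
  invisible(x)
}

## ---- fast per-pair machinery -------------------------------------------

## All adaptor log-likelihood starts at once. Returns A[i+1] =
## adaptor_loglik(read, adaptor, i) for i = 0..l. Implemented as diagonal
## sums of the (read position k0) x (adaptor offset d0) score matrix,
## where hypothesis start i collects all entries with k0 - d0 == i.
.adaptor_logliks_all <- function(rch, pe, ach) {
  l <- length(rch)
  if (l == 0L) return(0)
  la <- min(length(ach), l)
  M <- matrix(LOG_QUARTER, nrow = l, ncol = l)
  if (la > 0L) {
    amat <- matrix(ach[seq_len(la)], nrow = l, ncol = la, byrow = TRUE)
    rmat <- matrix(rch, nrow = l, ncol = la)
    pmat <- matrix(pe, nrow = l, ncol = la)
    v <- ifelse(amat == rmat, log1p(-pmat), log(pmat / 3))
    v[amat == "N" | rmat == "N"] <- LOG_QUARTER
    M[, seq_len(la)] <- v
  }
  g <- as.vector(row(M) - col(M))   # k0 - d0
  keep <- g >= 0L
  s <- rowsum(as.vector(M)[keep], g[keep])
  A <- numeric(l + 1L)
  A[as.integer(rownames(s)) + 1L] <- s[, 1L]
  A                                  # A[l + 1] stays 0 (empty product)
}

## All overlap sums at once. OV[i+1] = sum of overlap_base_loglik over
## molecule positions covered by both reads under hypothesis i. Read 1
## position p0 pairs with reverse-complemented read 2 position j0 exactly
## when p0 - j0 == i - l2, i.e. hypothesis i is one diagonal of the
## l1 x l2 pairwise score matrix.
.overlap_logliks_all <- function(ch1, pe1, ch2rc, pe2rc, L) {
  l1 <- length(ch1)
  l2 <- length(ch2rc)
  OV <- numeric(L + 1L)
  if (l1 == 0L || l2 == 0L) return(OV)
  b1 <- matrix(ch1, l1, l2)
  b2 <- matrix(ch2rc, l1, l2, byrow = TRUE)
  p1 <- matrix(pe1, l1, l2)
  p2 <- matrix(pe2rc, l1, l2, byrow = TRUE)
  s <- ifelse(b1 == b2,
              (1 - p1) * (1 - p2) + p1 * p2 / 3,
              (1 - p1) * p2 / 3 + (p1 / 3) * (1 - p2) +
                2 * (p1 / 3) * (p2 / 3))
  s[b1 == "N" | b2 == "N"] <- 0.25
  v <- log(s) + LOG_QUARTER
  g <- as.vector(row(v) - col(v))    # p0 - j0 = i - l2
  sums <- rowsum(as.vector(v), g)
  i_of_g <- as.integer(rownames(sums)) + l2
  ok <- i_of_g >= 0L & i_of_g <= L
  OV[i_of_g[ok] + 1L] <- sums[ok, 1L]
  OV
}

## floored error probabilities + character vectors for one pair,
## shared by the fast path
.pair_data <- function(r1, r2) {
  list(ch1 = .chars(r1$bases), pe1 = .pe_floored(r1$quals),
       ch2rc = .chars(.revcomp_chr(r2$bases)),
       pe2rc = .pe_floored(rev(r2$quals)),
       l1 = nchar(r1$bases), l2 = nchar(r2$bases))
}

#' Unnormalised log posterior of one candidate molecule length
#'
#' Direct evaluation of the model for a single candidate length `i`:
#' log prior plus the two adaptor terms, the overlap term over the
#' doubly covered molecule positions, and `log(1/4)` per singly covered
#' position. `i = 0` is the adaptor-dimer hypothesis (both reads are
#' pure adaptor). [posterior_profile()] evaluates all `i` at once and is
#' what callers normally want; this function is the per-hypothesis
#' definition.
#'
#' @param r1,r2 The read pair as [read_record()]s (`r2` as sequenced,
#'   i.e. not reverse complemented).
#' @param adaptors An [adaptor_pair()].
#' @param i Candidate molecule length, `0..l1+l2`.
#' @param prior A [length_prior()].
#' @return Unnormalised log posterior.
#' @export
length_loglik <- function(r1, r2, adaptors, i, prior) {
  stopifnot(inherits(r1, "read_record"), inherits(r2, "read_record"),
            inherits(adaptors, "adaptor_pair"),
            inherits(prior, "length_prior"))
  l1 <- nchar(r1$bases)
  l2 <- nchar(r2$bases)
  L <- l1 + l2
  if (length(i) != 1L || is.na(i) || i < 0 || i > L) {
    stop("'i' must be in 0..l1+l2")
  }
  i <- as.integer(i)
  rc2 <- reverse_complement(r2)
  a_term <- adaptor_loglik(r1, adaptors$a1, min(i, l1)) +
    adaptor_loglik(r2, adaptors$a2, min(i, l2))
  ov_lo <- max(0L, i - l2)
  ov_hi <- min(l1, i)
  ov <- 0
  n_ov <- max(0L, ov_hi - ov_lo)
  if (n_ov > 0L) {
    m <- ov_lo:(ov_hi - 1L)          # molecule positions, 0-based
    ch1 <- .chars(r1$bases)[m + 1L]
    chrc <- .chars(rc2$bases)[m - (i - l2) + 1L]
    ov <- sum(overlap_base_loglik(ch1, r1$quals[m + 1L],
                                  chrc, rc2$quals[m - (i - l2) + 1L]))
  }
  lp <- if (prior$kind == "uniform") -log(L + 2) else
    lognormal_logpdf(max(i, 0.5), prior$mu, prior$sigma)
  lp + a_term + ov + (i - n_ov) * LOG_QUARTER
}

#' Log likelihood of the no-merge hypothesis
#'
#' The molecule is longer than `l1 + l2`: no adaptor is present and the
#' reads cannot overlap, so each of the `l1 + l2` observed bases is an
#' independent observation of an a-priori uniform base (`1/4` each), and
#' the prior factor is the tail mass of the length prior beyond
#' `l1 + l2` ([tail_mass()]).
#'
#' @inheritParams length_loglik
#' @return Log probability.
#' @export
no_merge_loglik <- function(r1, r2, prior) {
  stopifnot(inherits(r1, "read_record"), inherits(r2, "read_record"),
            inherits(prior, "length_prior"))
  L <- nchar(r1$bases) + nchar(r2$bases)
  .logprior_no_merge(prior, L) + L * LOG_QUARTER
}

#' Posterior profile over all candidate molecule lengths
#'
#' Evaluates the unnormalised log posterior of every candidate molecule
#' length `i = 0..l1+l2` plus the no-merge hypothesis, and records the
#' maximum-a-posteriori hypothesis and the log-odds of the best over the
#' second-best hypothesis (the quantity the ambiguity guard in
#' [decide()] tests). Exact float ties resolve to the smallest length.
#'
#' @inheritParams length_loglik
#' @return An object of class `length_posterior` with elements
#'   `log_post` (numeric vector indexed by `i = 0..l1+l2`),
#'   `log_no_merge`, `best_i` (`NA` when the no-merge hypothesis wins),
#'   `best_is_no_merge`, `log_odds` (`>= 0`), `l1`, `l2` and `type`
#'   (`"pair"`).
#' @examples
#' a <- adaptor_pair("ACGTACGTAC", "TGCATGCATG")
#' r1 <- read_record("m", "TTGACACGTACGTAC", rep(30, 15))
#' r2 <- read_record("m", "GTCAATGCATGCATG", rep(30, 15))
#' posterior_profile(r1, r2, a, length_prior("uniform"))
#' @export
posterior_profile <- function(r1, r2, adaptors = adaptor_pair(),
                              prior = length_prior("uniform")) {
  stopifnot(inherits(r1, "read_record"), inherits(r2, "read_record"),
            inherits(adaptors, "adaptor_pair"),
            inherits(prior, "length_prior"))
  pd <- .pair_data(r1, r2)
  if (pd$l1 == 0L || pd$l2 == 0L) stop("both reads must be non-empty")
  L <- pd$l1 + pd$l2
  i <- 0:L
  A1 <- .adaptor_logliks_all(pd$ch1, pd$pe1, .chars(adaptors$a1))
  A2 <- .adaptor_logliks_all(.chars(r2$bases), .pe_floored(r2$quals),
                             .chars(adaptors$a2))
  OV <- .overlap_logliks_all(pd$ch1, pd$pe1, pd$ch2rc, pd$pe2rc, L)
  n_ov <- pmax(0L, pmin(pd$l1, i) - pmax(0L, i - pd$l2))
  log_post <- .logprior_grid(prior, L) +
    A1[pmin(i, pd$l1) + 1L] + A2[pmin(i, pd$l2) + 1L] +
    OV + (i - n_ov) * LOG_QUARTER
  log_no_merge <- .logprior_no_merge(prior, L) + L * LOG_QUARTER
  .build_posterior(log_post, log_no_merge, pd$l1, pd$l2, "pair")
}

.build_posterior <- function(log_post, log_no_merge, l1, l2, type) {
  all_log <- c(log_post, log_no_merge)
  best <- which.max(all_log)          # first max: smallest i wins ties
  second <- max(all_log[-best])
  n_len <- length(log_post)
  structure(list(
    log_post = log_post,
    log_no_merge = log_no_merge,
    best_i = if (best <= n_len) best - 1L else NA_integer_,
    best_is_no_merge = best > n_len,
    log_odds = all_log[best] - second,
    l1 = l1, l2 = l2, type = type
  ), class = "length_posterior")
}

#' @export
print.length_posterior <- function(x, ...) {
  hyp <- if (x$type == "single") "no-trim" else "no-merge"
  cat("<length_posterior> (", x$type, " mode, ",
      length(x$log_post) + 1L, " hypotheses)\n", sep = "")
  if (x$best_is_no_merge) {
    cat("  MAP hypothesis: ", hyp, "\n", sep = "")
  } else {
    cat("  MAP molecule length: ", x$best_i, " bp\n", sep = "")
  }
  cat(sprintf("  log-odds best vs second best: %.3f (ratio %.3g)\n",
              x$log_odds, exp(-x$log_odds)))
  invisible(x)
}

#' @export
as.data.frame.length_posterior <- function(x, ...) {
  data.frame(
    hypothesis = c(as.character(seq_along(x$log_post) - 1L),
                   if (x$type == "single") "no_trim" else "no_merge"),
    log_posterior = c(x$log_post, x$log_no_merge),
    stringsAsFactors = FALSE
  )
}

#' Plot the log-posterior landscape of a profile
#'
#' Log posterior against candidate molecule length; the dashed line is
#' the no-merge (or, for single reads, no-trim) hypothesis. A read pair
#' from a short molecule shows a single sharp peak; a pair from a
#' molecule longer than the combined read length shows a flat landscape
#' at or below the dashed line.
#'
#' @param x A `length_posterior`.
#' @param ... Passed to [plot()].
#' @export
plot.length_posterior <- function(x, ...) {
  i <- seq_along(x$log_post) - 1L
  plot(i, x$log_post, type = "l", xlab = "candidate molecule length (bp)",
       ylab = "log posterior (unnormalised)", ...)
  graphics::abline(h = x$log_no_merge, lty = 2)
  if (!x$best_is_no_merge) {
    graphics::points(x$best_i, x$log_post[x$best_i + 1L], pch = 19)
  }
  invisible(x)
}

## normalised posterior over all hypotheses (log-sum-exp)
.normalized_posterior <- function(profile) {
  all_log <- c(profile$log_post, profile$log_no_merge)
  m <- max(all_log)
  p <- exp(all_log - m)
  p / sum(p)
}

#' Decide merge / trim / keep from a posterior profile
#'
#' Applies the ambiguity guard: if the likelihood ratio of the
#' second-best to the best hypothesis exceeds `ratio_threshold`
#' (default 1 in 20), the call is too uncertain and the pair is passed
#' through unmerged. Otherwise the winning hypothesis determines the
#' outcome: the no-merge hypothesis keeps the pair, a length hypothesis
#' merges (or, in single-read mode, trims) at the MAP length. The
#' reconstructed sequence is filled in later by [merge_pair()].
#'
#' @param profile A [posterior_profile()] or [single_end_profile()]
#'   result.
#' @param ratio_threshold Ambiguity guard in `(0, 1]`; a merge is
#'   rejected when second-best/best exceeds it. At 1 the guard never
#'   fires (the ratio cannot exceed 1).
#' @return An object of class `merge_result` with elements `decision`
#'   (`"merged"`, `"ambiguous"`, `"kept_as_pair"` or `"trimmed_single"`),
#'   `inferred_length` (`NA` unless a length hypothesis won), `log_odds`
#'   and `sequence` (`NULL` until filled in).
#' @export
decide <- function(profile, ratio_threshold = 0.05) {
  stopifnot(inherits(profile, "length_posterior"))
  if (length(ratio_threshold) != 1L || is.na(ratio_threshold) ||
      ratio_threshold <= 0 || ratio_threshold > 1) {
    stop("'ratio_threshold' must be in (0, 1]")
  }
  single <- identical(profile$type, "single")
  if (exp(-profile$log_odds) > ratio_threshold) {
    decision <- "ambiguous"
    len <- NA_integer_
  } else if (profile$best_is_no_merge) {
    ## molecule longer than the data: pass through unmodified
    decision <- "kept_as_pair"
    len <- NA_integer_
  } else {
    decision <- if (single) "trimmed_single" else "merged"
    len <- profile$best_i
  }
  structure(list(decision = decision, inferred_length = len,
                 log_odds = profile$log_odds, sequence = NULL),
            class = "merge_result")
}

#' @export
print.merge_result <- function(x, ...) {
  cat("<merge_result> ", x$decision, sep = "")
  if (!is.na(x$inferred_length)) {
    cat(", inferred length ", x$inferred_length, " bp", sep = "")
  }
  cat(sprintf(" (log-odds %.2f)\n", x$log_odds))
  if (!is.null(x$sequence)) print(x$sequence)
  invisible(x)
}

#' Posterior profile for a single read
#'
#' Single-end analogue of [posterior_profile()]: candidate trim points
#' `i = 0..l` score `log prior(i) + i*log(1/4)` for the molecule part
#' plus the adaptor term from position `i` on; the molecule-longer-than-
#' the-read hypothesis uses the prior tail mass beyond `l` and
#' `l*log(1/4)`. [decide()] applies unchanged and yields
#' `"trimmed_single"` when a trim point wins.
#'
#' @param read A non-empty [read_record()].
#' @param adaptor Adaptor string expected at the 3' end.
#' @param prior A [length_prior()].
#' @return A `length_posterior` with `type = "single"`.
#' @export
single_end_profile <- function(read, adaptor = DEFAULT_ADAPTOR1,
                               prior = length_prior("uniform")) {
  stopifnot(inherits(read, "read_record"))
  l <- nchar(read$bases)
  if (l == 0L) stop("read must be non-empty")
  i <- 0:l
  A <- .adaptor_logliks_all(.chars(read$bases), .pe_floored(read$quals),
                            .chars(toupper(adaptor)))
  lp <- if (prior$kind == "uniform") rep(-log(l + 2), l + 1L) else
    lognormal_logpdf(pmax(i, 0.5), prior$mu, prior$sigma)
  log_post <- lp + i * LOG_QUARTER + A
  log_no_trim <- .logprior_no_merge(prior, l) + l * LOG_QUARTER
  .build_posterior(log_post, log_no_trim, l, 0L, "single")
}
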