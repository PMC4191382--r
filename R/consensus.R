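## Consensus calling for molecule positions sequenced by both reads.
##
## With two observations (b1, q1) and (b2, q2) of the same template base,
## the posterior of each nucleotide n is
##   p(n | b1, b2) = p(b1|n) p(b2|n) p(n) / sum_m p(b1|m) p(b2|m) p(m)
## with p(n) = 1/4 for all n. The reported quality is the PHRED scaling
## of the posterior error probability
##   p(-n | b1, b2) = sum_{m != n} p(b1,b2|m) / sum_m p(b1,b2|m).

NUCS <- c("A", "C", "G", "T")

#' Probability of observing a base given the true nucleotide
#'
#' `1 - p_e(q)` when the observed base equals the true nucleotide,
#' `p_e(q)/3` otherwise; sums to 1 over the four possible observations.
#' Qualities below 2 are floored at 2.
#'
#' @param b Observed base in `{A,C,G,T}` (vectorised).
#' @param q PHRED score of the observation.
#' @param n Hypothesised true nucleotide.
#' @return Probability.
#' @examples
#' obs_likelihood("A", 20, "A") # 0.99
#' obs_likelihood("A", 20, "C") # 0.01/3
#' @export
obs_likelihood <- function(b, q, n) {
  .check_bases(c(b, n))
  if (anyNA(q) || any(q < 0)) stop("PHRED scores must be >= 0")
  pe <- .pe_floored(q)
  ifelse(b == n, 1 - pe, pe / 3)
}

## vectorised consensus over aligned base/quality vectors; returns
## list(base=, qual=). Implements the posterior argmax with the
## tie-to-read-1 rule and the N rules.
.consensus_vec <- function(b1, q1, b2, q2, qual_cap = 60L) {
  n <- length(b1)
  if (n == 0L) return(list(base = character(0), qual = integer(0)))
  base <- character(n)
  qual <- integer(n)

  n1 <- b1 == "N"
  n2 <- b2 == "N"
  both_n <- n1 & n2
  one_n <- xor(n1, n2)
  base[both_n] <- "N"
  qual[both_n] <- 2L
  base[one_n] <- ifelse(n1[one_n], b2[one_n], b1[one_n])
  qual[one_n] <- as.integer(ifelse(n1[one_n], q2[one_n], q1[one_n]))

  ok <- !(n1 | n2)
  if (any(ok)) {
    p1 <- .pe_floored(q1[ok])
    p2 <- .pe_floored(q2[ok])
    ## joint likelihood p(b1,b2|n) for n = A,C,G,T (columns)
    lik <- sapply(NUCS, function(nt) {
      ifelse(b1[ok] == nt, 1 - p1, p1 / 3) *
        ifelse(b2[ok] == nt, 1 - p2, p2 / 3)
    })
    lik <- matrix(lik, ncol = 4L)
    denom <- rowSums(lik)
    best <- max.col(lik, ties.method = "first")
    ## exact posterior ties go to the base observed on read 1
    i1 <- match(b1[ok], NUCS)
    rows <- seq_len(nrow(lik))
    tie_to_1 <- lik[cbind(rows, i1)] == lik[cbind(rows, best)]
    best[tie_to_1] <- i1[tie_to_1]
    err <- (denom - lik[cbind(rows, best)]) / denom
    q <- ifelse(err <= 0, Inf, -10 * log10(err))
    base[ok] <- NUCS[best]
    qual[ok] <- as.integer(pmin(round(q), qual_cap))
  }
  list(base = base, qual = qual)
}

#' Consensus base call from two observations of the same position
#'
#' Computes the posterior over the four nucleotides by Bayes' rule with
#' a uniform 1/4 nucleotide prior, returns the MAP nucleotide and the
#' PHRED scaling of its posterior error probability
#' `sum_{m != n} p(b1,b2|m) / sum_m p(b1,b2|m)`, capped at `qual_cap`.
#'
#' Special cases: an exact posterior tie (conflicting bases with equal
#' qualities) returns the base observed on read 1; if one observation is
#' `N` the other base is returned with its original quality; two `N`s
#' return `N` with quality 2.
#'
#' @param b1,b2 Observed bases in `{A,C,G,T,N}`.
#' @param q1,q2 Their PHRED scores.
#' @param qual_cap Maximum reported consensus quality (default 60);
#'   keeps agreeing high-quality observations within the encodable
#'   FASTQ range.
#' @return A list with elements `base` and `qual`.
#' @examples
#' consensus_call("A", 20, "A", 20)  # agreement raises the quality
#' consensus_call("A", 30, "C", 10)  # higher-quality observation wins
#' @export
consensus_call <- function(b1, q1, b2, q2, qual_cap = 60L) {
  stopifnot(length(b1) == 1L, length(b2) == 1L)
  .check_bases(c(b1, b2))
  if (anyNA(c(q1, q2)) || any(c(q1, q2) < 0)) {
    stop("PHRED scores must be >= 0")
  }
  out <- .consensus_vec(b1, q1, b2, q2, qual_cap = qual_cap)
  list(base = out$base, qual = out$qual)
}

#' Assemble the reconstructed molecule from a read pair
#'
#' Builds the molecule of inferred length `i`: positions covered only by
#' read 1 keep its base and quality, positions covered only by the
#' reverse-complemented read 2 keep its base and quality, and doubly
#' covered positions get a [consensus_call()]. The identifier is taken
#' from read 1.
#'
#' @param r1,r2 The read pair as [read_record()]s (`r2` as sequenced).
#' @param i Inferred molecule length, `0..l1+l2`.
#' @param qual_cap Consensus quality cap, see [consensus_call()].
#' @return A [read_record()] of length `i`.
#' @export
merge_pair <- function(r1, r2, i, qual_cap = 60L) {
  stopifnot(inherits(r1, "read_record"), inherits(r2, "read_record"))
  l1 <- nchar(r1$bases)
  l2 <- nchar(r2$bases)
  if (length(i) != 1L || is.na(i) || i < 0 || i > l1 + l2) {
    stop("inferred length 'i' must be in 0..l1+l2")
  }
  i <- as.integer(i)
  if (i == 0L) return(read_record(r1$id, "", integer(0)))
  rc2 <- reverse_complement(r2)
  p <- 0:(i - 1L)                    # molecule positions
  in1 <- p < l1
  in2 <- p >= i - l2
  j2 <- p - (i - l2)                 # position in rc2 where covered
  base <- character(i)
  qual <- integer(i)
  only1 <- in1 & !in2
  only2 <- in2 & !in1
  both <- in1 & in2
  ch1 <- .chars(r1$bases)
  chrc <- .chars(rc2$bases)
  base[only1] <- ch1[p[only1] + 1L]
  qual[only1] <- r1$quals[p[only1] + 1L]
  base[only2] <- chrc[j2[only2] + 1L]
  qual[only2] <- rc2$quals[j2[only2] + 1L]
  if (any(both)) {
    cc <- .consensus_vec(ch1[p[both] + 1L], r1$quals[p[both] + 1L],
                         chrc[j2[both] + 1L], rc2$quals[j2[both] + 1L],
                         qual_cap = qual_cap)
    base[both] <- cc$base
    qual[both] <- cc$qual
  }
  read_record(r1$id, paste(base, collapse = ""), qual)
}
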