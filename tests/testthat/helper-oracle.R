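## Independent brute-force oracles: direct probability products in plain
## (non-log) probability space, nested loops, no shared code with the
## package internals. Only usable for short reads (products underflow
## for long ones) -- which is exactly where they serve as ground truth.

NUC4 <- c("A", "C", "G", "T")

oracle_pe <- function(q) 10^(-max(q, 2) / 10)

oracle_obs <- function(b, q, n) {
  if (b == "N") return(0.25)
  if (b == n) 1 - oracle_pe(q) else oracle_pe(q) / 3
}

## probability of one read position against the adaptor template
oracle_match <- function(a_base, r_base, q, beyond) {
  if (beyond || a_base == "N" || r_base == "N") return(0.25)
  if (a_base == r_base) 1 - oracle_pe(q) else oracle_pe(q) / 3
}

## probability of one doubly covered molecule position
oracle_overlap <- function(b1, q1, b2, q2) {
  total <- 0
  for (n in NUC4) {
    total <- total + 0.25 * oracle_obs(b1, q1, n) * oracle_obs(b2, q2, n)
  }
  total
}

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

## full posterior in probability space: prob[i+1] for i = 0..l1+l2 plus
## the no-merge hypothesis; prior is a length_prior object but evaluated
## here with plain stats:: calls
oracle_posterior <- function(r1, r2, a1, a2, prior) {
  l1 <- nchar(r1$bases)
  l2 <- nchar(r2$bases)
  L <- l1 + l2
  ch1 <- strsplit(r1$bases, "")[[1]]
  ch2 <- strsplit(r2$bases, "")[[1]]
  chrc <- strsplit(oracle_revcomp(r2$bases), "")[[1]]
  qrc <- rev(r2$quals)
  ach1 <- strsplit(a1, "")[[1]]
  ach2 <- strsplit(a2, "")[[1]]
  pri <- function(i) {
    if (prior$kind == "uniform") 1 / (L + 2)
    else stats::dlnorm(max(i, 0.5), prior$mu, prior$sigma)
  }
  probs <- numeric(L + 1)
  for (i in 0:L) {
    p <- pri(i)
    s1 <- min(i, l1)
    if (s1 < l1) for (k in s1:(l1 - 1)) {        # read-1 adaptor part
      d <- k - s1
      p <- p * oracle_match(if (d < length(ach1)) ach1[d + 1] else "N",
                            ch1[k + 1], r1$quals[k + 1],
                            d >= length(ach1))
    }
    s2 <- min(i, l2)
    if (s2 < l2) for (k in s2:(l2 - 1)) {        # read-2 adaptor part
      d <- k - s2
      p <- p * oracle_match(if (d < length(ach2)) ach2[d + 1] else "N",
                            ch2[k + 1], r2$quals[k + 1],
                            d >= length(ach2))
    }
    if (i > 0) for (m in 0:(i - 1)) {            # molecule positions
      covered1 <- m < l1
      covered2 <- m >= i - l2
      if (covered1 && covered2) {
        j <- m - (i - l2)
        p <- p * oracle_overlap(ch1[m + 1], r1$quals[m + 1],
                                chrc[j + 1], qrc[j + 1])
      } else {
        p <- p * 0.25
      }
    }
    probs[i + 1] <- p
  }
  tail <- if (prior$kind == "uniform") 1 / (L + 2)
          else stats::plnorm(L, prior$mu, prior$sigma, lower.tail = FALSE)
  list(probs = probs, no_merge = tail * 0.25^L)
}

## brute-force consensus: posterior over the four nucleotides and the
## error probability of the winner, straight from the definitions
oracle_consensus <- function(b1, q1, b2, q2) {
  lik <- vapply(NUC4, function(n) {
    oracle_obs(b1, q1, n) * oracle_obs(b2, q2, n)
  }, numeric(1))
  post <- lik * 0.25 / sum(lik * 0.25)
  best <- which.max(lik)
  if (lik[[b1]] == lik[best]) best <- which(NUC4 == b1)  # tie to read 1
  err <- sum(lik[-best]) / sum(lik)
  list(base = NUC4[best], post = post, err = err)
}
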