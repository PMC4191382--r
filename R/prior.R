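#' Fragment-length prior
#'
#' The prior over the (latent) original molecule length used by the merge
#' model. Two kinds are supported:
#'
#' * `"uniform"`: every length hypothesis, including the
#'   molecule-longer-than-both-reads ("no merge") hypothesis, receives the
#'   same mass. For a read pair of lengths `l1`, `l2` there are
#'   `l1 + l2 + 2` hypotheses, so each gets `1 / (l1 + l2 + 2)`. Use this
#'   when nothing is known about the insert-size distribution.
#' * `"lognormal"`: the density `1 / (i * sqrt(2*pi) * sigma) *
#'   exp(-(ln i - mu)^2 / (2 sigma^2))`, the distribution that fits
#'   sequencing-library insert sizes well; degraded (ancient) libraries
#'   have small `mu` and small `sigma`, modern libraries larger ones.
#'   `mu` and `sigma` are on the log-length scale. The density at length 0
#'   (an adaptor dimer) is evaluated at 0.5 as a continuity correction.
#'
#' @param kind `"uniform"` or `"lognormal"`.
#' @param mu Location on the log-length scale (log-normal only).
#' @param sigma Scale on the log-length scale, `> 0` (log-normal only).
#'
#' @return An object of class `length_prior`.
#' @seealso [fit_length_prior()] to estimate `mu`, `sigma` from observed
#'   lengths; [tail_mass()] for the no-merge prior mass.
#' @examples
#' length_prior("uniform")
#' length_prior("lognormal", mu = 3.8, sigma = 0.3)
#' @export
length_prior <- function(kind = c("uniform", "lognormal"),
                         mu = NULL, sigma = NULL) {
  kind <- match.arg(kind)
  if (kind == "lognormal") {
    if (is.null(mu) || is.null(sigma)) {
      stop("a log-normal prior needs both 'mu' and 'sigma'")
    }
    mu <- as.numeric(mu)
    sigma <- as.numeric(sigma)
    if (!is.finite(mu) || !is.finite(sigma) || sigma <= 0) {
      stop("'sigma' must be finite and > 0")
    }
  } else {
    mu <- NULL
    sigma <- NULL
  }
  structure(list(kind = kind, mu = mu, sigma = sigma),
            class = "length_prior")
}

#' @export
print.length_prior <- function(x, ...) {
  if (x$kind == "uniform") {
    cat("<length_prior> uniform over all length hypotheses\n")
  } else {
    cat(sprintf(
      "<length_prior> log-normal, mu = %.4f, sigma = %.4f (log-length scale)\n",
      x$mu, x$sigma))
    cat(sprintf("  median length %.1f bp, mass below 100 bp: %.3f\n",
                exp(x$mu), stats::plnorm(100, x$mu, x$sigma)))
  }
  invisible(x)
}

#' Log density of the log-normal fragment-length prior
#'
#' @param i Length (positive); vectorised.
#' @param mu,sigma Log-normal parameters on the log-length scale,
#'   `sigma > 0`.
#' @return `log` of `1/(i*sqrt(2*pi)*sigma) * exp(-(ln i - mu)^2/(2 sigma^2))`.
#' @examples
#' lognormal_logpdf(exp(3.8), mu = 3.8, sigma = 0.3)
#' @export
lognormal_logpdf <- function(i, mu, sigma) {
  if (any(!is.finite(i)) || any(i <= 0)) {
    stop("'i' must be positive (length 0 is handled upstream by a ",
         "continuity correction)")
  }
  if (sigma <= 0) stop("'sigma' must be > 0")
  stats::dlnorm(i, meanlog = mu, sdlog = sigma, log = TRUE)
}

#' Prior mass on molecules longer than L
#'
#' The prior factor of the no-merge (molecule longer than the combined
#' read length) hypothesis: `1 - cdf(L)` for a log-normal prior. For the
#' uniform prior every hypothesis gets the same per-hypothesis mass
#' `1 / (L + 2)` (the `L + 1` candidate lengths plus the no-merge
#' hypothesis).
#'
#' @param L Combined read length `l1 + l2` (or `l1` for single reads),
#'   `>= 0`.
#' @param prior A [length_prior()].
#' @return A probability.
#' @examples
#' tail_mass(0, length_prior("lognormal", 3.8, 0.3)) # == 1
#' tail_mass(200, length_prior("lognormal", 3.8, 0.3))
#' @export
tail_mass <- function(L, prior) {
  stopifnot(inherits(prior, "length_prior"), L >= 0)
  if (prior$kind == "lognormal") {
    stats::plnorm(L, meanlog = prior$mu, sdlog = prior$sigma,
                  lower.tail = FALSE)
  } else {
    1 / (L + 2)
  }
}

## log prior over candidate lengths i = 0..L (length 0 uses the
## continuity correction) for a pair with combined read length L
.logprior_grid <- function(prior, L) {
  if (prior$kind == "uniform") {
    rep(-log(L + 2), L + 1L)
  } else {
    i <- 0:L
    lognormal_logpdf(pmax(i, 0.5), prior$mu, prior$sigma)
  }
}

## log prior of the no-merge hypothesis
.logprior_no_merge <- function(prior, L) {
  log(tail_mass(L, prior))
}

#' Fit a log-normal fragment-length prior by maximum likelihood
#'
#' Closed-form maximum-likelihood estimates on observed fragment lengths:
#' `mu_hat = mean(log x)` and `sigma_hat = sqrt(mean((log x - mu_hat)^2))`
#' (the 1/n maximum-likelihood variance, not the unbiased 1/(n-1) form).
#' Typical sources of lengths are previously merged reads from the same
#' library or an insert-size histogram.
#'
#' @param lengths Positive numeric vector of observed fragment lengths
#'   (at least 2), or a path to a plain text file with one length per
#'   line.
#' @return A `length_prior` of kind `"lognormal"` with the fitted
#'   parameters and an `n` attribute.
#' @examples
#' set.seed(1)
#' fit_length_prior(round(rlnorm(500, 3.8, 0.3)))
#' @export
fit_length_prior <- function(lengths) {
  if (is.character(lengths) && length(lengths) == 1L) {
    lengths <- scan(lengths, what = numeric(), quiet = TRUE)
  }
  lengths <- as.numeric(lengths)
  if (length(lengths) < 2L) {
    stop("need at least 2 observed lengths to fit a prior")
  }
  if (anyNA(lengths) || any(lengths <= 0)) {
    stop("all lengths must be positive")
  }
  lx <- log(lengths)
  mu <- mean(lx)
  sigma <- sqrt(mean((lx - mu)^2))
  if (sigma == 0) {
    stop("degenerate fit: all lengths identical, sigma would be 0")
  }
  out <- length_prior("lognormal", mu = mu, sigma = sigma)
  attr(out, "n") <- length(lengths)
  out
}
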