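# Ex-Gaussian distribution: the standard parametric family for response
# times (normal component mu/sigma convolved with an exponential of mean tau).

#' Ex-Gaussian density
#'
#' @param x quantiles (ms).
#' @param mu,sigma mean and SD of the Gaussian component (ms), `sigma > 0`.
#' @param tau mean of the exponential component (ms), `tau > 0`.
#' @return density values.
#' @export
dexgauss <- function(x, mu, sigma, tau) {
  stopifnot(sigma > 0, tau > 0)
  z <- (x - mu) / sigma
  # log-scale to avoid overflow of exp(sigma^2/(2 tau^2) - (x-mu)/tau)
  lg <- -log(tau) + sigma^2 / (2 * tau^2) - (x - mu) / tau +
    stats::pnorm(z - sigma / tau, log.p = TRUE)
  exp(lg)
}

#' Ex-Gaussian cumulative distribution function
#'
#' @inheritParams dexgauss
#' @return probabilities in `[0, 1]`.
#' @export
pexgauss <- function(x, mu, sigma, tau) {
  stopifnot(sigma > 0, tau > 0)
  z <- (x - mu) / sigma
  lcorr <- sigma^2 / (2 * tau^2) - (x - mu) / tau +
    stats::pnorm(z - sigma / tau, log.p = TRUE)
  p <- stats::pnorm(z) - exp(lcorr)
  pmin(pmax(p, 0), 1)
}

#' Ex-Gaussian quantile function
#'
#' Numeric inversion of [pexgauss()] by vectorized bisection, run to a relative
#' tolerance of 1e-9 on the quantile.
#'
#' @param p probabilities in `(0, 1)`.
#' @inheritParams dexgauss
#' @return quantiles (ms).
#' @export
qexgauss <- function(p, mu, sigma, tau) {
  stopifnot(sigma > 0, tau > 0, all(p > 0 & p < 1))
  lo <- rep(mu - 10 * sigma, length(p))
  hi <- mu + 10 * sigma + stats::qexp(pmax(p, 0.5), rate = 1 / tau) + 10 * tau
  hi <- rep(max(hi), length(p))
  for (i in seq_len(200L)) {
    mid <- (lo + hi) / 2
    below <- pexgauss(mid, mu, sigma, tau) < p
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
    if (max((hi - lo) / pmax(abs(mid), 1)) < 1e-9) break
  }
  (lo + hi) / 2
}

#' Ex-Gaussian random deviates
#'
#' @param n number of draws.
#' @inheritParams dexgauss
#' @return numeric vector of draws (ms).
#' @export
rexgauss <- function(n, mu, sigma, tau) {
  stopifnot(sigma > 0, tau > 0)
  stats::rnorm(n, mu, sigma) + stats::rexp(n, rate = 1 / tau)
}
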