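#' Zero-truncated negative binomial log-probability
#'
#' Log-pmf of the negative binomial distribution (mean/dispersion
#' parametrization) conditioned on the count being at least 1. This is the
#' low-abundance leaf of the clonal abundance mixture: a present, sampled
#' clone that is neither clonally expanded nor derived from a plasma cell
#' contributes a small number of reads.
#'
#' @param x Integer counts, all >= 1.
#' @param mu Mean of the untruncated negative binomial (> 0).
#' @param size Dispersion parameter (> 0); the variance is
#'   `mu + mu^2 / size`.
#' @return Log-probabilities, same length as `x`.
#' @examples
#' sum(exp(log_pmf_ztnb(1:1000, mu = 2, size = 1))) # ~1
#' @export
log_pmf_ztnb <- function(x, mu, size) {
  if (any(x < 1)) stop("zero-truncated negative binomial requires x >= 1")
  if (mu <= 0 || size <= 0) stop("mu and size must be positive")
  log_p0 <- size * (log(size) - log(size + mu))
  stats::dnbinom(x, size = size, mu = mu, log = TRUE) - log1mexp(log_p0)
}

#' Discretized generalized Pareto log-probability
#'
#' Log-pmf of the integer distribution obtained by differencing the
#' continuous generalized Pareto CDF on unit intervals:
#' `P(X = x) = F(x - u + 1) - F(x - u)` with support `{u, u+1, ...}`.
#' This heavy-tailed distribution is the high-abundance leaf of the clonal
#' abundance mixture, modelling counts from clonally expanded populations or
#' actively secreting plasma cells.
#'
#' @param x Integer counts, all >= `u`.
#' @param xi Shape (tail index), >= 0; `xi = 0` gives a discretized
#'   exponential, `xi > 0` a polynomial (Pareto-type) tail.
#' @param sigma Scale, > 0.
#' @param u Location (minimum attainable count), integer >= 1.
#' @return Log-probabilities, same length as `x`.
#' @examples
#' # xi = 0 reduces to a geometric-like discretized exponential
#' log_pmf_dgpd(3, xi = 0, sigma = 2, u = 1)
#' @export
log_pmf_dgpd <- function(x, xi, sigma, u = 1) {
  if (sigma <= 0) stop("sigma must be positive")
  if (xi < 0) stop("xi must be non-negative (heavy or exponential tail)")
  if (u < 1) stop("u must be >= 1")
  if (any(x < u)) stop("discretized generalized Pareto requires x >= u")
  y0 <- x - u
  # log survival of the continuous GPD at y >= 0
  logS <- function(y) {
    if (xi == 0) -y / sigma else -(1 / xi) * log1p(xi * y / sigma)
  }
  ls0 <- logS(y0)
  ls1 <- logS(y0 + 1)
  ls0 + log1mexp(ls1 - ls0)
}

# Random draws from the zero-truncated negative binomial (inverse CDF).
rztnb <- function(n, mu, size) {
  p0 <- exp(size * (log(size) - log(size + mu)))
  u <- stats::runif(n, min = p0, max = 1)
  stats::qnbinom(pmin(u, 1 - 1e-16), size = size, mu = mu)
}

# Random draws from the discretized generalized Pareto: draw the continuous
# variate and floor onto the integer grid starting at u.
rdgpd <- function(n, xi, sigma, u = 1) {
  w <- stats::runif(n)
  y <- if (xi == 0) -sigma * log1p(-w) else (sigma / xi) * ((1 - w)^(-xi) - 1)
  u + floor(y)
}
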