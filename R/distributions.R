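#' Zero-altered (hurdle) Poisson probability mass function
#'
#' The zero-altered Poisson (ZAP) random variable equals 0 with probability
#' `theta` and, conditional on being positive, follows a zero-truncated
#' Poisson (ZTP) distribution with rate `mu`:
#' \deqn{P(Y=0)=\theta, \qquad
#'       P(Y=y)=(1-\theta)\frac{e^{-\mu}\mu^y}{(1-e^{-\mu})\,y!},\ y\ge 1.}
#'
#' @param y Vector of non-negative integers.
#' @param theta Probability of a structural zero, in `[0, 1]`. Recycled.
#' @param mu Rate of the truncated Poisson part, `> 0`. Recycled.
#' @param log Return log-probabilities?
#' @return Numeric vector of probabilities (computed in log space).
#' @examples
#' dzap(0:5, theta = 0.3, mu = 2)
#' sum(dzap(0:200, theta = 0.3, mu = 2))  # 1
#' @export
dzap <- function(y, theta, mu, log = FALSE) {
  if (any(y < 0) || any(y != floor(y)))
    stop("`y` must contain non-negative integers")
  check_zap_params(theta, mu)
  n <- max(length(y), length(theta), length(mu))
  y <- rep_len(y, n); theta <- rep_len(theta, n); mu <- rep_len(mu, n)
  lp <- ifelse(
    y == 0,
    log(theta),
    log1p(-theta) - mu + y * log(mu) - log(-expm1(-mu)) - lgamma(y + 1)
  )
  if (log) lp else exp(lp)
}

#' @rdname dzap
#' @export
zap_pmf <- dzap

#' Mean and variance of the zero-altered Poisson distribution
#'
#' \deqn{E[Y] = (1-\theta)\frac{\mu}{1-e^{-\mu}}, \qquad
#'       Var(Y) = (1-\theta)\frac{\mu+\mu^2}{1-e^{-\mu}} - E[Y]^2.}
#'
#' @inheritParams dzap
#' @return A list with numeric components `mean` and `variance` (vectorized).
#' @examples
#' zap_moments(theta = 0, mu = 2)$mean  # 2 / (1 - exp(-2))
#' @export
zap_moments <- function(theta, mu) {
  check_zap_params(theta, mu)
  n <- max(length(theta), length(mu))
  theta <- rep_len(theta, n); mu <- rep_len(mu, n)
  em <- -expm1(-mu)                      # 1 - e^{-mu}
  m <- (1 - theta) * mu / em
  v <- (1 - theta) * (mu + mu^2) / em - m^2
  list(mean = m, variance = pmax(v, 0))
}

#' Mean of the zero-truncated Poisson distribution
#'
#' `mu / (1 - exp(-mu))`, the map inverted by [ztp_mle()].
#'
#' @param mu Positive rate(s).
#' @return Numeric vector of ZTP means (all `> 1`).
#' @export
ztp_mean <- function(mu) {
  stopifnot(all(mu > 0))
  mu / (-expm1(-mu))
}

#' Log-likelihood of a zero-truncated Poisson sample
#'
#' For positive counts \eqn{Y_1^+,\dots,Y_{N^+}^+}:
#' \deqn{LL^+ = -N^+\log(1-e^{-\mu}) + \log(\mu)\sum_i Y_i^+
#'              - N^+\mu - \sum_i \log(Y_i^+!).}
#' This is the splitting criterion of the truncated part of the hurdle
#' forest; the final factorial term uses `lgamma`.
#'
#' @param y Vector of integers `>= 1`.
#' @param mu Positive rate.
#' @return The log-likelihood (scalar).
#' @examples
#' ztp_loglik(c(2, 2, 2), ztp_mle(c(2, 2, 2)))
#' @export
ztp_loglik <- function(y, mu) {
  if (length(y) == 0) stop("empty sample")
  if (any(y < 1) || any(y != floor(y)))
    stop("zero-truncated sample must contain integers >= 1")
  if (!is.numeric(mu) || length(mu) != 1 || mu <= 0)
    stop("`mu` must be a positive scalar")
  n <- length(y)
  -n * log(-expm1(-mu)) + log(mu) * sum(y) - n * mu - sum(lgamma(y + 1))
}

#' Maximum-likelihood rate of a zero-truncated Poisson sample
#'
#' Solves the estimating equation
#' \deqn{\bar Y^+ = \mu / (1 - e^{-\mu})}
#' by safeguarded Newton iteration (absolute tolerance 1e-10 on the mean
#' scale). When the sample mean is 1 (all observations equal 1) the MLE has
#' no interior solution and the boundary value `MU_MIN = 1e-8` is returned;
#' the ZTP mean at that value is 1, i.e. the sample mean.
#'
#' @param y Vector of integers `>= 1`.
#' @return The estimated rate `mu` (scalar, `> 0`).
#' @examples
#' ztp_mle(c(2, 2, 2))  # about 1.59362
#' @export
ztp_mle <- function(y) {
  if (length(y) == 0) stop("cannot fit a zero-truncated Poisson to an empty node")
  if (any(y < 1) || any(y != floor(y)))
    stop("zero-truncated sample must contain integers >= 1")
  cpp_ztp_mu_from_mean(mean(y))
}

#' Draw zero-altered Poisson counts
#'
#' Each draw is 0 with probability `theta[i]`; otherwise an exact
#' inverse-CDF draw from ZTP(`mu[i]`) obtained as
#' `qpois(u, mu)` with `u` uniform on `(e^{-mu}, 1)`, so no rejection loop
#' is needed even for tiny `mu`. Uses R's RNG: call `set.seed()` for
#' reproducibility.
#'
#' @param n Number of draws; `theta` and `mu` are recycled to length `n`.
#' @inheritParams dzap
#' @return Integer-valued numeric vector of non-negative counts.
#' @examples
#' set.seed(1)
#' table(rzap(1000, theta = 0.3, mu = 2))
#' @export
rzap <- function(n, theta, mu) {
  check_zap_params(theta, mu)
  theta <- rep_len(theta, n); mu <- rep_len(mu, n)
  zero <- stats::runif(n) < theta
  e0 <- exp(-mu)
  u <- e0 + stats::runif(n) * (1 - e0)  # uniform on (P(Pois=0), 1)
  y <- stats::qpois(u, mu)
  y[y < 1] <- 1  # guards qpois rounding at u ~ e0
  y[zero] <- 0
  y
}

#' @rdname rzap
#' @param theta_vec,mu_vec Parameter vectors of equal length; one draw each.
#' @export
zap_sample <- function(theta_vec, mu_vec) {
  if (length(theta_vec) != length(mu_vec))
    stop("`theta_vec` and `mu_vec` must have equal length")
  rzap(length(theta_vec), theta_vec, mu_vec)
}

check_zap_params <- function(theta, mu) {
  # theta = 1 is admitted as the degenerate point mass at zero: forest
  # zero-probability estimates can hit the boundary exactly
  if (any(theta < 0) || any(theta > 1))
    stop("`theta` must lie in [0, 1]")
  if (any(mu <= 0)) stop("`mu` must be > 0")
  invisible(TRUE)
}

#' Boundary value used for a degenerate truncated-Poisson node
#' @export
MU_MIN <- 1e-8
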