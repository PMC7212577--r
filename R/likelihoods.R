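# Observation models and local variational bounds.
#
# Non-Gaussian likelihoods are handled by per-entry quadratic lower bounds
# with an auxiliary parameter zeta.  Each bound is quadratic in the linear
# predictor x = sum_k z_k w_k, so every non-Gaussian entry can be rewritten
# as a Gaussian pseudo-observation with a pseudo-precision, and the Gaussian
# update machinery is reused unchanged.

sigmoid <- stats::plogis

softplus <- function(x) log1p(exp(-abs(x))) + pmax(x, 0)

# lambda(z) = tanh(z/2)/(4z), continuous at 0 with value 1/8
lambda_jj <- function(z) {
  z <- abs(z)
  out <- ifelse(z < 1e-6, 1 / 8 - z^2 / 96, tanh(z / 2) / (4 * pmax(z, 1e-300)))
  out
}

# Global upper bound on the negative curvature of the Poisson log-likelihood
# y*log(softplus(x)) - softplus(x):  -f''(x) = s'(x) + y * g(x) with
# g(x) = (s(x)^2 - s'(x)*softplus(x)) / softplus(x)^2,  sup s' = 1/4,
# sup g = 0.16710 (attained near x = 0.5), so 1/4 + 0.17*y dominates.
POISSON_CURVATURE <- 0.17

#' Jaakkola-Jordan bound for Bernoulli observations
#'
#' Quadratic lower bound on the expected logistic log-likelihood
#' `E_q[log p(y | sigmoid(x))]` for `y` in `{0,1}`:
#' `log sigmoid(zeta) + (y - 1/2) E[x] - zeta/2 - lambda(zeta) (E[x^2] - zeta^2)`
#' with `lambda(z) = tanh(z/2) / (4 z)`.  The bound is tight when the
#' predictor is concentrated at `x` and `zeta = |x|`; its maximizer over
#' `zeta` is `sqrt(E[x^2])` (see [zeta_bernoulli()]).
#'
#' @param y Binary observation(s).
#' @param x_mean,x_var First moment and variance of the linear predictor
#'   under the variational posterior.
#' @param zeta Positive local variational parameter.
#' @return The bound value (vectorized).
#' @export
bernoulli_bound <- function(y, x_mean, x_var = 0, zeta) {
  ex2 <- x_var + x_mean^2
  log(sigmoid(zeta)) + (y - 0.5) * x_mean - zeta / 2 - lambda_jj(zeta) * (ex2 - zeta^2)
}

#' @rdname bernoulli_bound
#' @param x_sq Second moment `E[x^2]` of the linear predictor.
#' @export
zeta_bernoulli <- function(x_sq) sqrt(pmax(x_sq, 0))

poisson_loglik <- function(y, x) {
  rate <- softplus(x)
  ifelse(y == 0, 0, y * log(rate)) - rate - lgamma(y + 1)
}

poisson_dloglik <- function(y, x) {
  s <- sigmoid(x)
  l <- softplus(x)
  # s/l -> 1 as x -> -Inf; guard the ratio
  r <- ifelse(x < -30, 1, s / pmax(l, 1e-300))
  y * r - s
}

#' Quadratic bound for Poisson observations under a softplus rate
#'
#' Lower bound on `E_q[log p(y | rate = softplus(x))]`, built from the
#' uniform curvature bound `-d2/dx2 log p <= 1/4 + 0.17 y` of the Poisson
#' log-likelihood with softplus rate: a second-order expansion around
#' `zeta` with the curvature replaced by its supremum.  Tight at
#' `x = zeta`; the maximizer over `zeta` is `E[x]` (see [zeta_poisson()]).
#'
#' @inheritParams bernoulli_bound
#' @param y Non-negative integer count(s).
#' @export
poisson_bound <- function(y, x_mean, x_var = 0, zeta) {
  if (any(y < 0) || any(y != round(y))) stop("poisson observations must be non-negative integers")
  L <- 0.25 + POISSON_CURVATURE * y
  ex2 <- x_var + x_mean^2
  poisson_loglik(y, zeta) + poisson_dloglik(y, zeta) * (x_mean - zeta) -
    L / 2 * (ex2 - 2 * zeta * x_mean + zeta^2)
}

#' @rdname poisson_bound
#' @export
zeta_poisson <- function(x_mean) x_mean

#' Expected Gaussian log-likelihood under the variational posterior
#'
#' Exact expectation of the Gaussian log-density summed over observed
#' entries, `sum 0.5 E[log tau_d] - 0.5 log 2 pi -
#' 0.5 E[tau_d] E[(y - x)^2]`, where `E[(y - x)^2] = (y - E[x])^2 + Var[x]`
#' uses the full second moment of the predictor.
#'
#' @param y Data matrix (samples x features).
#' @param mask Logical matrix of observed entries.
#' @param x_mean,x_var Matrices of predictor means and variances.
#' @param tau_mean,tau_logmean Per-feature noise precision expectations
#'   `E[tau]` and `E[log tau]`.
#' @export
gaussian_loglik <- function(y, mask, x_mean, x_var, tau_mean, tau_logmean) {
  if (any(tau_mean <= 0)) stop("noise precision expectations must be positive")
  nobs <- colSums(mask)
  ss <- colSums(mask * ((y - x_mean)^2 + x_var))
  sum(nobs * (0.5 * tau_logmean - 0.5 * log(2 * pi))) - 0.5 * sum(tau_mean * ss)
}
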