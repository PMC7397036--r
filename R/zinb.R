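#' Zero-inflated negative binomial log-density
#'
#' Log probability mass of the ZINB distribution: a point mass at zero with
#' probability `pi` mixed with a negative binomial NB(mu, theta), where
#' `theta` is the inverse-dispersion (variance `mu + mu^2/theta`). All
#' arguments are recycled to a common shape; computation is via log-gamma and
#' log-sum-exp throughout for stability.
#'
#' @param x non-negative integer counts.
#' @param pi dropout (zero-inflation) probability, clamped to
#'   `[1e-6, 1 - 1e-6]`.
#' @param mu NB mean, positive.
#' @param theta NB inverse-dispersion, positive.
#' @return log-pmf values, same shape as the broadcast arguments.
#' @export
zinb_log_pmf <- function(x, pi, mu, theta) {
  eps <- 1e-6
  pi <- pmin(pmax(pi, eps), 1 - eps)
  if (any(x < 0) || any(abs(x - round(x)) > 1e-8)) stop("x must be non-negative integers")
  if (any(mu <= 0) || any(theta <= 0)) stop("mu and theta must be positive")
  nb_ll <- lgamma(x + theta) - lgamma(theta) - lgamma(x + 1) +
    theta * (log(theta) - log(theta + mu)) + x * (log(mu) - log(theta + mu))
  out <- log1p(-pi) + nb_ll
  iz <- x == 0
  if (any(iz)) {
    # log( pi + (1-pi) * NB(0) ) via log-sum-exp
    a <- log(pi)
    b <- log1p(-pi) + theta * (log(theta) - log(theta + mu))
    if (length(a) == 1L) a <- rep(a, length(b))
    if (length(b) == 1L) b <- rep(b, length(a))
    m <- pmax(a, b)
    lse <- m + log(exp(a - m) + exp(b - m))
    # broadcast-safe assignment
    res <- out
    lse_full <- (x * 0) + lse  # recycle to x's shape
    res[iz] <- lse_full[iz]
    out <- res
  }
  out
}

#' ZINB reconstruction loss
#'
#' Negative ZINB log-likelihood averaged over all (cell, gene) entries; the
#' data-reconstruction loss of the autoencoder.
#'
#' @param x_raw count matrix (cells x genes).
#' @param params list with matrices `pi`, `mu`, `theta` of the same shape
#'   (a `ZINBParams` head output).
#' @return scalar mean negative log-likelihood.
#' @export
reconstruction_loss <- function(x_raw, params) {
  if (!all(dim(x_raw) == dim(params$mu))) stop("shape mismatch between x_raw and ZINB parameters")
  -mean(zinb_log_pmf(x_raw, params$pi, params$mu, params$theta))
}

# Gradient of the mean negative ZINB log-likelihood with respect to the three
# pre-activation heads:
#   pi    = sigmoid(a_pi)
#   mu    = clamp(sf * exp(a_mu))
#   theta = clamp(softplus(a_th))
# Returns d(loss)/d(a_pi), d(loss)/d(a_mu), d(loss)/d(a_th) as matrices of the
# input shape. `pi`, `mu`, `theta` are the post-activation (clamped) values;
# `mu_free`/`theta_free` flag entries inside the clamp bounds (gradient is
# stopped at the bounds). Derivations:
#   x > 0:  d logp/d pi = -1/(1-pi)
#           d logp/d mu = x/mu - (x+theta)/(theta+mu)
#           d logp/d th = digamma(x+th) - digamma(th) + log(th/(th+mu))
#                         + 1 - (x+th)/(th+mu)
#   x == 0: with A = (th/(th+mu))^th, D = pi + (1-pi) A:
#           d logp/d pi = (1 - A)/D
#           d logp/d mu = -(1-pi) A th / ((th+mu) D)
#           d logp/d th = (1-pi) A (log(th/(th+mu)) + mu/(th+mu)) / D
zinb_grad_preact <- function(x, pi, mu, theta, a_th, mu_free, theta_free) {
  n <- length(x)
  eps <- 1e-6
  pi <- pmin(pmax(pi, eps), 1 - eps)
  lr <- log(theta) - log(theta + mu)      # log(th/(th+mu))
  iz <- x == 0

  dpi <- dmu <- dth <- numeric(n)
  if (any(!iz)) {
    xs <- x[!iz]; mus <- mu[!iz]; ths <- theta[!iz]; pis <- pi[!iz]
    dpi[!iz] <- -1 / (1 - pis)
    dmu[!iz] <- xs / mus - (xs + ths) / (ths + mus)
    dth[!iz] <- digamma(xs + ths) - digamma(ths) + lr[!iz] + 1 - (xs + ths) / (ths + mus)
  }
  if (any(iz)) {
    muz <- mu[iz]; thz <- theta[iz]; piz <- pi[iz]; lrz <- lr[iz]
    logA <- thz * lrz
    A <- exp(logA)
    D <- piz + (1 - piz) * A
    dpi[iz] <- (1 - A) / D
    dmu[iz] <- -(1 - piz) * A * thz / ((thz + muz) * D)
    dth[iz] <- (1 - piz) * A * (lrz + muz / (thz + muz)) / D
  }
  # chain through activations; loss = -mean(logp) so flip sign and scale
  scale <- -1 / n
  g_pi <- scale * dpi * pi * (1 - pi)
  g_mu <- scale * dmu * mu * mu_free          # d mu/d a_mu = mu (exp activation)
  g_th <- scale * dth * stats::plogis(a_th) * theta_free
  list(pi = g_pi, mu = g_mu, theta = g_th)
}
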