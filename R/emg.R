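#' Exponentially modified Gaussian (EMG) parameters
#'
#' Parameter container for the perceived path-length ratio \eqn{\lambda_p},
#' modeled as the sum of independent normal and exponential random variables:
#' \eqn{\lambda_p = X + Y} with \eqn{X \sim N(\mu, \sigma^2)} and
#' \eqn{Y \sim Exp(\beta)} (\eqn{\beta} is the *scale*, i.e. \eqn{E[Y] = \beta}).
#' The mean is exactly \eqn{\mu + \beta}.
#'
#' @param mu Location of the Gaussian component (dimensionless).
#' @param sigma Standard deviation of the Gaussian component (> 0).
#' @param beta Scale of the exponential component (> 0).
#' @return An object of class `emg_parameters`.
#' @examples
#' emg_parameters(0.77, 0.30, 0.68)
#' @export
emg_parameters <- function(mu, sigma, beta) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu))
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("'sigma' must be a positive finite number")
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
    stop("'beta' must be a positive finite number")
  structure(list(mu = mu, sigma = sigma, beta = beta),
            class = "emg_parameters")
}

#' @export
print.emg_parameters <- function(x, ...) {
  cat(sprintf("EMG parameters: mu = %g, sigma = %g, beta = %g (mean = %g)\n",
              x$mu, x$sigma, x$beta, x$mu + x$beta))
  invisible(x)
}

.check_emg <- function(params) {
  if (!inherits(params, "emg_parameters"))
    params <- emg_parameters(params$mu, params$sigma, params$beta)
  params
}

#' Density of the exponentially modified Gaussian
#'
#' Computed in log space for numerical stability so that the Gaussian limit
#' (`beta` much smaller than `sigma`) is handled without overflow.
#'
#' @param x Quantiles (finite).
#' @param params An [emg_parameters()] object.
#' @param log If `TRUE`, return the log-density.
#' @return Density values, same length as `x`.
#' @export
demg <- function(x, params, log = FALSE) {
  params <- .check_emg(params)
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("'x' must be finite numeric")
  z <- (x - params$mu) / params$sigma
  s <- params$sigma / params$beta
  if (s < 1e3) {
    logf <- -base::log(params$beta) - z * s + s^2 / 2 +
      pnorm(z - s, log.p = TRUE)
  } else {
    # Gaussian limit: exp(s^2/2) and log-Phi(z - s) cancel catastrophically,
    # so use the asymptotic erfcx expansion of the same expression
    u2 <- (s - z)^2 / 2
    logf <- dnorm(z, log = TRUE) - base::log(params$sigma - params$beta * z) +
      log1p(-1 / (2 * u2) + 3 / (4 * u2^2))
  }
  if (log) logf else exp(logf)
}

#' Distribution function of the exponentially modified Gaussian
#'
#' @inheritParams demg
#' @param q Quantiles (finite).
#' @return Cumulative probabilities.
#' @export
pemg <- function(q, params) {
  params <- .check_emg(params)
  if (!is.numeric(q) || any(!is.finite(q)))
    stop("'q' must be finite numeric")
  z <- (q - params$mu) / params$sigma
  s <- params$sigma / params$beta
  p <- pnorm(z) - exp(pnorm(z - s, log.p = TRUE) - s * z + s^2 / 2)
  pmin(pmax(p, 0), 1)
}

#' Sample from the exponentially modified Gaussian
#'
#' Draws are the sum of a normal and an independent exponential variate.
#'
#' @param n Number of draws (>= 1).
#' @param params An [emg_parameters()] object.
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric vector of length `n`.
#' @export
remg <- function(n, params, seed = NULL) {
  params <- .check_emg(params)
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("'n' must be a positive count")
  if (!is.null(seed)) set.seed(seed)
  rnorm(n, params$mu, params$sigma) + rexp(n, rate = 1 / params$beta)
}

#' Sample a strictly positive perceived ratio
#'
#' The EMG support is the whole real line; a perceived length ratio must be
#' positive. Nonpositive draws (negligible probability at the study's
#' parameters) are rejected and resampled. Values in (0, 1) are allowed: the
#' empirical ratio distribution has visible mass below one.
#'
#' @inheritParams remg
#' @param max_tries Resampling rounds before giving up.
#' @return Numeric vector of `n` positive draws.
#' @export
remg_positive <- function(n, params, seed = NULL, max_tries = 100L) {
  if (!is.null(seed)) set.seed(seed)
  out <- remg(n, params)
  for (i in seq_len(max_tries)) {
    bad <- which(out <= 0)
    if (!length(bad)) return(out)
    out[bad] <- remg(length(bad), params)
  }
  stop("could not draw positive EMG variates; parameters place too much mass below 0")
}

#' Moments of the exponentially modified Gaussian
#'
#' `emg_mean()` is exact: \eqn{E[X + Y] = \mu + \beta}.
#'
#' @param params An [emg_parameters()] object.
#' @return A single number.
#' @export
emg_mean <- function(params) {
  params <- .check_emg(params)
  params$mu + params$beta
}

#' @rdname emg_mean
#' @export
emg_variance <- function(params) {
  params <- .check_emg(params)
  params$sigma^2 + params$beta^2
}

#' @rdname emg_mean
#' @export
emg_skewness <- function(params) {
  params <- .check_emg(params)
  2 * params$beta^3 / (params$sigma^2 + params$beta^2)^1.5
}

#' Numerical mode of the exponentially modified Gaussian
#'
#' Argmax of [demg()] found by derivative-free maximization bracketed on
#' \eqn{[\mu - 3\sigma,\ \mu + 3(\sigma + \beta)]}. For `beta` much smaller
#' than `sigma` the distribution degenerates to the Gaussian and the mode
#' approaches `mu`.
#'
#' @param params An [emg_parameters()] object.
#' @param tol Absolute tolerance on the location of the maximum.
#' @return The modal value (single number).
#' @export
emg_mode <- function(params, tol = 1e-8) {
  params <- .check_emg(params)
  lo <- params$mu - 3 * params$sigma
  hi <- params$mu + 3 * (params$sigma + params$beta)
  opt <- optimize(function(x) demg(x, params, log = TRUE),
                  interval = c(lo, hi), maximum = TRUE, tol = tol)
  if (!is.finite(opt$objective))
    stop("mode search failed: non-finite density over the bracket")
  opt$maximum
}

#' Fit an exponentially modified Gaussian by maximum likelihood
#'
#' Maximum-likelihood estimation with moment-based initialization: the EMG
#' moments \eqn{E = \mu + \beta}, \eqn{Var = \sigma^2 + \beta^2} and skewness
#' \eqn{2\beta^3 / (\sigma^2+\beta^2)^{3/2}} are inverted for starting values;
#' the likelihood is then maximized over \eqn{(\mu, \log\sigma, \log\beta)}.
#'
#' @param x Numeric sample (>= 50 finite values, nonzero variance).
#' @return An [emg_parameters()] object with attributes `loglik` and
#'   `convergence`.
#' @export
emg_fit <- function(x) {
  if (!is.numeric(x) || length(x) < 50L)
    stop("need at least 50 samples to fit the EMG")
  if (any(!is.finite(x)))
    stop("samples must be finite")
  m <- mean(x)
  v <- var(x)
  if (v <= .Machine$double.eps * max(1, m^2))
    stop("degenerate sample: zero variance")
  g <- mean((x - m)^3) / v^1.5
  # moment inversion; clamp skewness so the Gaussian start stays valid
  beta0 <- sqrt(v) * (max(g, 1e-3) / 2)^(1 / 3)
  beta0 <- min(beta0, 0.95 * sqrt(v))
  sigma0 <- sqrt(max(v - beta0^2, 1e-4 * v))
  mu0 <- m - beta0
  nll <- function(theta) {
    p <- emg_parameters(theta[1], exp(theta[2]), exp(theta[3]))
    -sum(demg(x, p, log = TRUE))
  }
  fit <- optim(c(mu0, base::log(sigma0), base::log(beta0)), nll,
               method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
  out <- emg_parameters(fit$par[1], exp(fit$par[2]), exp(fit$par[3]))
  attr(out, "loglik") <- -fit$value
  attr(out, "convergence") <- fit$convergence
  out
}

#' Additive velocity noise draws
#'
#' Zero-mean Gaussian perturbations of the individual walking speed around the
#' fundamental-diagram mean (standard deviation `sigma_eps`, in m/s).
#'
#' @param n Number of draws (>= 1).
#' @param sigma_eps Standard deviation in m/s (>= 0); 0 yields exact zeros.
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n`.
#' @export
noise_sample <- function(n, sigma_eps, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("'n' must be a positive count")
  if (!is.numeric(sigma_eps) || length(sigma_eps) != 1L ||
      !is.finite(sigma_eps) || sigma_eps < 0)
    stop("'sigma_eps' must be a nonnegative number")
  if (!is.null(seed)) set.seed(seed)
  rnorm(n, mean = 0, sd = sigma_eps)
}
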