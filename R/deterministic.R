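#' Continuum occupancy of path A in the deterministic limit
#'
#' With no velocity noise and a fixed perceived ratio, the optimal assignment
#' has the closed form
#' \deqn{N_A(N) = \min\{N,\ (\kappa N + v_0(\sqrt{\lambda} - 1)) /
#'   (\kappa(\sqrt{\lambda} + 1))\},}
#' clamped to \eqn{[0, N]}. `lambda` plays the role of the geometric ratio; in
#' the deterministic model variant a fixed perception constant is substituted
#' for it.
#'
#' @param geom A [geometry()].
#' @param fd A [fundamental_diagram()]; requires `kappa > 0`.
#' @param n Global pedestrian count(s).
#' @param lambda Length ratio; defaults to `geom$lambda_g`.
#' @return Real-valued occupancy of path A (same length as `n`).
#' @export
deterministic_split <- function(geom, fd, n, lambda = geom$lambda_g) {
  stopifnot(inherits(geom, "geometry"), inherits(fd, "fundamental_diagram"))
  if (fd$kappa <= 0) stop("closed-form split requires kappa > 0")
  if (any(lambda <= 0)) stop("'lambda' must be positive")
  sl <- sqrt(lambda)
  interior <- (fd$kappa * n + fd$v0 * (sl - 1)) / (fd$kappa * (sl + 1))
  pmin(pmax(pmin(n, interior), 0), n)
}

#' Optical-length residual of a split
#'
#' The deterministic optimum equalizes the "optical lengths" of the two
#' paths: \eqn{L_A / v_A(N_A) = (1/\sqrt{\lambda})\, L_B / v_B(N_B)} with
#' \eqn{L_B = \lambda L_A}, equivalently \eqn{v_B / v_A = \sqrt{\lambda}}.
#' This function returns the left-hand side minus the right-hand side; it
#' vanishes at the interior branch of [deterministic_split()]. Positive
#' residual means path A is overcrowded relative to the optimum. The same
#' identity yields \eqn{\lambda = (v_B/v_A)^2}, the basis of the empirical
#' perceived-ratio statistic (see [lambda_p_series()]).
#'
#' @inheritParams deterministic_split
#' @param n_a Real-valued occupancy of path A.
#' @param n Global count.
#' @return The residual (dimensionless).
#' @export
optical_length_residual <- function(geom, fd, n_a, n, lambda = geom$lambda_g) {
  stopifnot(inherits(geom, "geometry"), inherits(fd, "fundamental_diagram"))
  v_a <- fd$v0 - fd$kappa * n_a
  v_b <- fd$v0 - fd$kappa * (n - n_a)
  if (any(v_a <= 0) || any(v_b <= 0))
    stop("mean velocity nonpositive at this split")
  geom$L_A / v_a - (1 / sqrt(lambda)) * (lambda * geom$L_A) / v_b
}

#' Deterministic activation threshold of the longer path
#'
#' The global count above which the interior branch of
#' [deterministic_split()] drops below \eqn{N}, i.e. the deterministic model
#' starts placing pedestrians on path B:
#' \eqn{N^* = v_0(\sqrt{\lambda} - 1) / (\kappa\sqrt{\lambda})}.
#' Returns 0 for `lambda <= 1` (the detour is no longer and activates
#' immediately).
#'
#' @inheritParams deterministic_split
#' @return Continuum count (single number).
#' @export
activation_threshold_deterministic <- function(geom, fd,
                                               lambda = geom$lambda_g) {
  stopifnot(inherits(geom, "geometry"), inherits(fd, "fundamental_diagram"))
  if (fd$kappa <= 0) stop("threshold requires kappa > 0")
  if (lambda <= 1) return(0)
  sl <- sqrt(lambda)
  fd$v0 * (sl - 1) / (fd$kappa * sl)
}
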