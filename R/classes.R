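#' Linear fundamental diagram
#'
#' Parameters of the linear density-speed law \eqn{\langle v_J(N_J)\rangle =
#' v_0 - \kappa N_J} with additive Gaussian velocity noise of standard
#' deviation `sigma_eps`. `v_min` is a floor applied after adding the noise,
#' preventing nonpositive speeds (and hence sign-flipped travel times) at
#' extreme draws; the study's parameter regime never reaches it.
#'
#' @param v0 Free-stream speed in m/s (> 0).
#' @param kappa Slope in m/s per pedestrian (>= 0).
#' @param sigma_eps Velocity-noise standard deviation in m/s (>= 0).
#' @param v_min Speed floor in m/s (> 0).
#' @return An object of class `fundamental_diagram`.
#' @examples
#' fundamental_diagram(1.012, 0.017, 0.15)
#' @export
fundamental_diagram <- function(v0, kappa, sigma_eps = 0, v_min = 0.1) {
  stopifnot(is.numeric(v0), length(v0) == 1L, is.finite(v0),
            is.numeric(kappa), length(kappa) == 1L, is.finite(kappa))
  if (v0 <= 0) stop("'v0' must be positive")
  if (kappa < 0) stop("'kappa' must be nonnegative")
  if (!is.numeric(sigma_eps) || sigma_eps < 0)
    stop("'sigma_eps' must be nonnegative")
  if (!is.numeric(v_min) || v_min <= 0) stop("'v_min' must be positive")
  structure(list(v0 = v0, kappa = kappa, sigma_eps = sigma_eps,
                 v_min = v_min),
            class = "fundamental_diagram")
}

#' @export
print.fundamental_diagram <- function(x, ...) {
  cat(sprintf(
    "Fundamental diagram: v(n) = %g - %g n  [m/s], noise sd %g, floor %g\n",
    x$v0, x$kappa, x$sigma_eps, x$v_min))
  invisible(x)
}

#' Bifurcation geometry
#'
#' Path A is the short, straight reference path; path B the longer detour.
#' `lambda_g` is the length ratio \eqn{L_B / L_A} (greater than 1 in the
#' studied setup). `L_A` is fixed to 1 by convention: only
#' \eqn{\lambda_p L_A} and \eqn{L_A} enter the perceived travel times, and the
#' optimal assignment is invariant under rescaling `L_A`. `A_ref` is the
#' reference walkable area used to convert counts to densities
#' \eqn{\rho = N / A_{ref}}.
#'
#' @param lambda_g Path-length ratio (> 0).
#' @param L_A Reference length of path A in m (> 0).
#' @param A_ref Reference area in m^2 (> 0).
#' @return An object of class `geometry`.
#' @examples
#' geometry(lambda_g = 1.35)
#' @export
geometry <- function(lambda_g = 1.35, L_A = 1, A_ref = 15.0) {
  stopifnot(is.numeric(lambda_g), length(lambda_g) == 1L)
  if (!is.finite(lambda_g) || lambda_g <= 0) stop("'lambda_g' must be positive")
  if (!is.numeric(L_A) || L_A <= 0) stop("'L_A' must be positive")
  if (!is.numeric(A_ref) || A_ref <= 0) stop("'A_ref' must be positive")
  structure(list(lambda_g = lambda_g, L_A = L_A, A_ref = A_ref),
            class = "geometry")
}

#' @export
print.geometry <- function(x, ...) {
  cat(sprintf("Geometry: lambda_g = %g (L_A = %g m), A_ref = %g m^2\n",
              x$lambda_g, x$L_A, x$A_ref))
  invisible(x)
}

#' Count-to-density conversion
#'
#' @param geom A [geometry()] object.
#' @param n Pedestrian count(s).
#' @return Densities `n / A_ref` in pedestrians per m^2.
#' @export
density_from_count <- function(geom, n) {
  stopifnot(inherits(geom, "geometry"))
  n / geom$A_ref
}
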