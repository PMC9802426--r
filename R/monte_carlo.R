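#' Derive independent stream seeds from a base seed
#'
#' One named stream per Monte Carlo run: a base seed deterministically spawns
#' sub-seeds so that every (variant, N) cell of a sweep has its own
#' reproducible stream. All derived seeds stay below 2^31.
#'
#' @param base_seed Integer base seed.
#' @param k Number of streams.
#' @return Integer vector of `k` seeds.
#' @export
stream_seeds <- function(base_seed, k) {
  stopifnot(length(base_seed) == 1L, is.finite(base_seed), k >= 1)
  set.seed(as.integer(base_seed))
  sample.int(2147483646L, k)
}

.variants <- c("deterministic", "velocity_noise", "full")

#' Monte Carlo ensemble of optimal configurations at one global count
#'
#' Draws, for each realization, the stochastic ingredients prescribed by the
#' model variant, solves the discomfort minimization exactly, and records the
#' occupancy of path B:
#' * `deterministic` - no velocity noise, fixed perceived ratio;
#' * `velocity_noise` - per-pedestrian Gaussian velocity noise, fixed ratio;
#' * `full` - velocity noise and a perceived ratio drawn (positively
#'   truncated) from the EMG, shared by all pedestrians in the realization.
#'
#' The fixed ratio of the first two variants defaults to the EMG mean
#' \eqn{\mu + \beta}: the model's expected perception.
#'
#' @param variant One of `"deterministic"`, `"velocity_noise"`, `"full"`.
#' @param geom A [geometry()].
#' @param fd A [fundamental_diagram()] (its `sigma_eps` drives the noise).
#' @param emg [emg_parameters()] of the perceived ratio.
#' @param n Global pedestrian count (>= 0).
#' @param m Number of realizations (>= 1).
#' @param seed Integer seed for this run's stream.
#' @param lambda_fixed Fixed perceived ratio for the non-`full` variants.
#' @return A list of class `ensemble_run` with `variant`, `n`, `m`, the
#'   integer vector `n_b` of path-B occupancies, the probability vector
#'   `p_nb` over k = 0..n, and `mean_n_b`.
#' @export
run_ensemble <- function(variant, geom, fd, emg, n, m, seed,
                         lambda_fixed = emg_mean(emg)) {
  variant <- match.arg(variant, .variants)
  if (m < 1) stop("'m' must be >= 1")
  if (n < 0) stop("'n' must be >= 0")
  set.seed(as.integer(seed))
  n_b <- integer(m)
  if (variant == "deterministic") {
    nb1 <- n - .best_split(geom, fd, rep(0, n), lambda_fixed)[1]
    n_b[] <- as.integer(nb1)
  } else {
    for (r in seq_len(m)) {
      eps <- rnorm(n, 0, fd$sigma_eps)
      lp <- if (variant == "full") remg_positive(1L, emg) else lambda_fixed
      n_b[r] <- n - as.integer(.best_split(geom, fd, eps, lp)[1])
    }
  }
  p_nb <- tabulate(n_b + 1L, nbins = n + 1L) / m
  structure(list(variant = variant, n = n, m = m, n_b = n_b,
                 p_nb = p_nb, mean_n_b = mean(n_b)),
            class = "ensemble_run")
}

#' Sweep the ensemble over a range of global counts
#'
#' Aggregates [run_ensemble()] across counts into the conditional occupancy
#' statistics compared against tracking data: mean occupancies
#' \eqn{\langle N_A(N)\rangle}, \eqn{\langle N_B(N)\rangle}, the conditional
#' law \eqn{P(N_B = k \mid N)} and the herding probability
#' \eqn{P(N_B = 0 \mid N)}. One independent seed stream is spawned per
#' (variant, N) cell, so tables are bit-reproducible given `seed`.
#'
#' @inheritParams run_ensemble
#' @param n_range Nonempty vector of global counts.
#' @return A list of class `ensemble_statistics` with fields `variant`,
#'   `n_values`, `mean_n_a`, `mean_n_b`, `p_empty_b`, `n_realizations`,
#'   `seed`, and the long-format `p_nb` `data.table` (columns `variant`,
#'   `n`, `k`, `prob`).
#' @export
sweep_counts <- function(variant, geom, fd, emg, n_range, m, seed,
                         lambda_fixed = emg_mean(emg)) {
  variant <- match.arg(variant, .variants)
  if (!length(n_range)) stop("'n_range' must be nonempty")
  vseed <- stream_seeds(seed, length(.variants))[match(variant, .variants)]
  seeds <- stream_seeds(vseed, length(n_range))
  runs <- vector("list", length(n_range))
  for (i in seq_along(n_range)) {
    runs[[i]] <- run_ensemble(variant, geom, fd, emg, n_range[i], m,
                              seeds[i], lambda_fixed)
  }
  mean_n_b <- vapply(runs, `[[`, numeric(1), "mean_n_b")
  p_nb <- data.table::rbindlist(lapply(runs, function(r) {
    data.table::data.table(variant = variant, n = r$n, k = 0:r$n,
                           prob = r$p_nb)
  }))
  structure(list(
    variant = variant,
    n_values = as.integer(n_range),
    mean_n_a = n_range - mean_n_b,
    mean_n_b = mean_n_b,
    p_empty_b = vapply(runs, function(r) r$p_nb[1], numeric(1)),
    p_nb = p_nb,
    n_realizations = as.integer(m),
    seed = as.integer(seed)
  ), class = "ensemble_statistics")
}

#' @export
print.ensemble_statistics <- function(x, ...) {
  cat(sprintf("Ensemble statistics (%s variant): N = %d..%d, %d realizations/N\n",
              x$variant, min(x$n_values), max(x$n_values), x$n_realizations))
  invisible(x)
}

#' Activation threshold from ensemble statistics
#'
#' The smallest global count at which the mean occupancy of path B reaches at
#' least one pedestrian.
#'
#' @param stats An `ensemble_statistics` object from [sweep_counts()].
#' @return Integer count.
#' @export
estimate_activation_threshold <- function(stats) {
  stopifnot(inherits(stats, "ensemble_statistics"))
  idx <- which(stats$mean_n_b >= 1)
  if (!length(idx))
    stop("mean N_B never reaches 1 in the swept range; extend 'n_range'")
  stats$n_values[min(idx)]
}

#' Long-format export of ensemble statistics
#'
#' @param x An `ensemble_statistics` object.
#' @param ... Unused.
#' @return A `data.frame` with one row per (N, k): columns `variant`, `n`,
#'   `k`, `prob`.
#' @export
as.data.frame.ensemble_statistics <- function(x, ...) {
  as.data.frame(x$p_nb)
}
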