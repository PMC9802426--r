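#' Per-frame summaries of a frame-record dataset
#'
#' One row per frame: global count `N`, occupancies `n_a`/`n_b`, mean speed
#' per path (`NA` when the path is empty) and the instantaneous flow (sum of
#' all speeds in the frame).
#'
#' @param records Frame-record table (see [read_frames()]).
#' @return A `data.table` keyed by `frame_id`.
#' @export
frame_summaries <- function(records) {
  dt <- data.table::as.data.table(records)
  dt[, .(
    N = .N,
    n_a = sum(path == "A"),
    n_b = sum(path == "B"),
    v_a = if (any(path == "A")) mean(speed[path == "A"]) else NA_real_,
    v_b = if (any(path == "B")) mean(speed[path == "B"]) else NA_real_,
    flow = sum(speed)
  ), by = frame_id]
}

#' Conditional occupancy statistics
#'
#' Mean occupancies of the two paths and the conditional law
#' \eqn{P(N_B = k \mid N)}, conditioning on the per-frame global count (integer
#' bins, no smoothing). Conservation `mean_n_a + mean_n_b = N` holds by
#' construction in every bin.
#'
#' @param records Frame-record table (nonempty).
#' @return A list of class `occupancy_statistics`: `table` (`N`, `n_frames`,
#'   `mean_n_a`, `mean_n_b`), long-format `p_nb` (`N`, `k`, `prob`), and
#'   `activation` (smallest observed `N` with mean `N_B >= 1`; `NA` if never
#'   reached).
#' @export
occupancy_statistics <- function(records) {
  if (!nrow(records)) stop("insufficient data: no records")
  fs <- frame_summaries(records)
  tab <- fs[, .(n_frames = .N, mean_n_a = mean(n_a), mean_n_b = mean(n_b)),
            keyby = N]
  p_nb <- fs[, .(prob = as.numeric(.N)), by = .(N, k = n_b)]
  p_nb[, prob := prob / sum(prob), by = N]
  data.table::setkey(p_nb, N, k)
  act <- tab[mean_n_b >= 1, N]
  structure(list(table = tab, p_nb = p_nb,
                 activation = if (length(act)) min(act) else NA_integer_),
            class = "occupancy_statistics")
}

#' @export
print.occupancy_statistics <- function(x, ...) {
  cat(sprintf("Occupancy statistics over %d frames, N in %d..%d; activation N* = %s\n",
              sum(x$table$n_frames), min(x$table$N), max(x$table$N),
              ifelse(is.na(x$activation), "not reached", x$activation)))
  invisible(x)
}

#' Fit the local fundamental diagram by ordinary least squares
#'
#' Regresses each pedestrian's recorded speed on the occupancy of its own
#' path, pooled across paths A and B (the same diagram is assumed to hold on
#' both; `per_path` carries the independent per-path fits used to verify
#' that). The residual standard deviation estimates the combined behavioral
#' and measurement speed noise.
#'
#' @param records Frame-record table with at least two distinct local-count
#'   levels.
#' @return A list of class `diagram_fit`: `v0_hat`, `kappa_hat`, `r_squared`,
#'   `resid_sd`, `n_points`, the 95% `ci` matrix (rows `v0`, `kappa`), the
#'   underlying `lm` object, and `per_path`.
#' @export
fit_local_diagram <- function(records) {
  if (!nrow(records)) stop("insufficient data: no records")
  dt <- data.table::as.data.table(records)
  dt[, n_j := .N, by = .(frame_id, path)]
  if (length(unique(dt$n_j)) < 2L)
    stop("rank-deficient design: need at least 2 distinct local-count levels")
  .one <- function(d) {
    fit <- lm(speed ~ n_j, data = d)
    ci <- confint(fit)
    list(v0_hat = unname(coef(fit)[1]), kappa_hat = -unname(coef(fit)[2]),
         r_squared = summary(fit)$r.squared,
         resid_sd = summary(fit)$sigma, n_points = nrow(d),
         ci = rbind(v0 = ci[1, ], kappa = -rev(ci[2, ])),
         fit = fit)
  }
  pooled <- .one(dt)
  per_path <- lapply(split(dt, dt$path), function(d) {
    if (length(unique(d$n_j)) < 2L) NULL else .one(d)
  })
  structure(c(pooled, list(per_path = per_path)), class = "diagram_fit")
}

#' @export
print.diagram_fit <- function(x, ...) {
  cat(sprintf(
    "Local fundamental diagram fit: v0 = %.4f m/s, kappa = %.4f m/s/ped (R^2 = %.3f, resid sd = %.3f, n = %d)\n",
    x$v0_hat, x$kappa_hat, x$r_squared, x$resid_sd, x$n_points))
  invisible(x)
}

#' Global fundamental diagrams and their reconstruction from the local one
#'
#' Mean walking speed per path conditioned on the *global* count `N` (speeds
#' pooled over pedestrians), together with a finite-difference check that the
#' global slope satisfies
#' \eqn{\partial_N \langle v_J(N)\rangle \approx -\kappa\, \partial_N N_J(N)}:
#' the change of the global diagram is the local slope times the change of the
#' path's mean occupancy. Central differences over `+/- window` counts are
#' used to tame bin noise.
#'
#' @param records Frame-record table.
#' @param kappa Local diagram slope used on the model side of the check
#'   (e.g. `fit_local_diagram(records)$kappa_hat`).
#' @param window Half-width (in counts) of the central difference.
#' @return A `data.table` with one row per (N, path): `v_mean`, `n_obs`,
#'   `mean_occ`, finite differences `dv_dN` and `model_slope`
#'   (\eqn{-\kappa\,\Delta N_J/\Delta N}), their relative residual
#'   `rel_resid`, and the per-N indicator `b_faster` for
#'   \eqn{\langle v_B(N)\rangle > \langle v_A(N)\rangle}.
#' @export
global_diagram <- function(records, kappa, window = 2L) {
  if (!nrow(records)) stop("insufficient data: no records")
  dt <- data.table::as.data.table(records)
  fs <- frame_summaries(records)
  dt <- merge(dt, fs[, .(frame_id, N)], by = "frame_id")
  g <- dt[, .(v_mean = mean(speed), n_obs = .N), keyby = .(path, N)]
  occ <- fs[, .(A = mean(n_a), B = mean(n_b)), keyby = N]
  occ_long <- data.table::melt(occ, id.vars = "N", variable.name = "path",
                               value.name = "mean_occ",
                               variable.factor = FALSE)
  g <- merge(g, occ_long, by = c("path", "N"))
  cdiff <- function(nv, yv, n0) {
    i1 <- which(nv == n0 - window); i2 <- which(nv == n0 + window)
    if (!length(i1) || !length(i2)) return(NA_real_)
    (yv[i2] - yv[i1]) / (2 * window)
  }
  g[, dv_dN := vapply(N, function(n0) cdiff(N, v_mean, n0), numeric(1)),
    by = path]
  g[, model_slope := vapply(N, function(n0) {
    -kappa * cdiff(N, mean_occ, n0)
  }, numeric(1)), by = path]
  g[, rel_resid := abs(dv_dN - model_slope) / pmax(abs(model_slope), 1e-12)]
  vw <- data.table::dcast(g, N ~ path, value.var = "v_mean")
  if (!"B" %in% names(vw)) vw[, B := NA_real_]
  vw[, b_faster := !is.na(B) & !is.na(A) & B > A]
  merge(g, vw[, .(N, b_faster)], by = "N")[]
}

#' Per-frame perceived path-length ratio series
#'
#' The instantaneous statistic \eqn{\lambda_p = (\hat v_B / \hat v_A)^2},
#' the squared ratio of the frame's mean speeds on the two paths, computed for
#' every frame with both paths occupied (other frames are skipped and
#' counted).
#'
#' @param records Frame-record table.
#' @return Numeric vector of per-frame ratios with attributes `n_skipped`
#'   (frames failing the both-occupied restriction) and `frames_used`.
#' @export
lambda_p_series <- function(records) {
  fs <- frame_summaries(records)
  ok <- fs$n_a > 0 & fs$n_b > 0
  out <- (fs$v_b[ok] / fs$v_a[ok])^2
  attr(out, "n_skipped") <- sum(!ok)
  attr(out, "frames_used") <- sum(ok)
  out
}

#' Fit the perceived-ratio distribution
#'
#' Delegates to [emg_fit()] and reports the series' empirical mode (kernel
#' density argmax).
#'
#' @param series Numeric vector from [lambda_p_series()] (>= 100 values).
#' @return A list with `params` ([emg_parameters()]), `empirical_mode`, and
#'   `n`.
#' @export
fit_lambda_p <- function(series) {
  if (length(series) < 100L)
    stop("need at least 100 perceived-ratio values to fit")
  params <- emg_fit(as.numeric(series))
  d <- density(as.numeric(series))
  list(params = params, empirical_mode = d$x[which.max(d$y)],
       n = length(series))
}

#' Analytic throughput bounds from the fundamental diagram
#'
#' The balanced split \eqn{N_A = N/2} maximizes the total flow,
#' \eqn{\phi_{ideal}(N) = (v_0 - \kappa N/2)\,N}; the fully unbalanced
#' assignment \eqn{N_A = N} gives the lower bound
#' \eqn{\phi_{unbal}(N) = (v_0 - \kappa N)\,N}. Assumes both paths have equal
#' cross-section. `rel_gap` is \eqn{(\phi_{ideal} - \phi_{unbal}) /
#' \phi_{ideal}}.
#'
#' @param v0,kappa Fundamental-diagram parameters.
#' @param n Vector of global counts.
#' @return A `data.table` with `N`, `phi_ideal`, `phi_unbalanced`, `rel_gap`.
#' @export
flow_bounds <- function(v0, kappa, n) {
  ideal <- (v0 - kappa * n / 2) * n
  unbal <- (v0 - kappa * n) * n
  data.table::data.table(
    N = n, phi_ideal = ideal, phi_unbalanced = unbal,
    rel_gap = ifelse(n == 0, 0, (ideal - unbal) / ideal))
}

#' Observed flow versus the analytic bounds
#'
#' Per global count: the mean observed flow (sum of recorded speeds per
#' frame, averaged over frames) next to the ideal and unbalanced bounds
#' evaluated at the fitted diagram. The equal-cross-section assumption behind
#' the bounds is flagged in the result.
#'
#' @param records Frame-record table.
#' @param fit A `diagram_fit` from [fit_local_diagram()] with `kappa_hat > 0`.
#' @param n_range Counts over which the maximum relative gap is reported
#'   (default 1..19, where the closed-form gap stays below one fifth at the
#'   study's fitted diagram).
#' @return A list of class `flow_table`: `table` (per-N observed flow and
#'   bounds), `max_rel_gap` over `n_range`, and `equal_sections_assumed`.
#' @export
flow_analysis <- function(records, fit, n_range = 1:19) {
  stopifnot(inherits(fit, "diagram_fit"))
  if (fit$kappa_hat <= 0) stop("flow bounds require kappa_hat > 0")
  fs <- frame_summaries(records)
  obs <- fs[, .(phi_obs = mean(flow), n_frames = .N), keyby = N]
  tab <- merge(obs, flow_bounds(fit$v0_hat, fit$kappa_hat, obs$N), by = "N")
  gap <- flow_bounds(fit$v0_hat, fit$kappa_hat, n_range)
  structure(list(table = tab, max_rel_gap = max(gap$rel_gap),
                 n_range = n_range, equal_sections_assumed = TRUE),
            class = "flow_table")
}

#' Wilson score interval for a binomial proportion
#'
#' @param k Successes.
#' @param n Trials.
#' @param conf Confidence level.
#' @return A two-column matrix `lower`, `upper`.
#' @export
wilson_interval <- function(k, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  # the score interval contains the point estimate; enforce this against
  # floating-point rounding at p = 0 or 1
  cbind(lower = pmin(pmax(ctr - hw, 0), p),
        upper = pmax(pmin(ctr + hw, 1), p))
}

#' Herding probability from data
#'
#' The per-N fraction of frames in which path B is empty,
#' \eqn{P(N_B = 0 \mid N)}, with Wilson-interval uncertainty.
#'
#' @param records Frame-record table (nonempty).
#' @param conf Confidence level of the interval.
#' @return A `data.table` with `N`, `n_frames`, `p_empty_b`, `lower`, `upper`.
#' @export
herding_probability <- function(records, conf = 0.95) {
  if (!nrow(records)) stop("insufficient data: no records")
  fs <- frame_summaries(records)
  tab <- fs[, .(n_frames = .N, k_empty = sum(n_b == 0)), keyby = N]
  ci <- wilson_interval(tab$k_empty, tab$n_frames, conf)
  tab[, p_empty_b := k_empty / n_frames]
  tab[, `:=`(lower = ci[, "lower"], upper = ci[, "upper"], k_empty = NULL)]
  tab[]
}

#' Ten-bin summary of a per-N table
#'
#' Coarse summary used for error bars: the N range is cut into `bins`
#' equal-width bins and a value column is averaged per bin, reporting the
#' min/max of the per-N means inside each bin.
#'
#' @param tab A `data.table` with a column `N` and the column `value_col`.
#' @param value_col Name of the column to summarize.
#' @param bins Number of bins.
#' @return A `data.table` with `bin`, `N_mid`, `mean`, `min`, `max`.
#' @export
binned_summary <- function(tab, value_col, bins = 10L) {
  dt <- data.table::as.data.table(tab)
  v <- dt[[value_col]]
  br <- seq(min(dt$N) - 0.5, max(dt$N) + 0.5, length.out = bins + 1L)
  b <- cut(dt$N, br, labels = FALSE, include.lowest = TRUE)
  data.table::data.table(bin = b, N = dt$N, value = v)[
    , .(N_mid = mean(N), mean = mean(value), min = min(value),
        max = max(value)), keyby = bin]
}
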