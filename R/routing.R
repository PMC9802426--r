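#' Mean walking speed at a given local count
#'
#' The linear fundamental diagram \eqn{\langle v_J(N_J)\rangle = v_0 - \kappa
#' N_J}, floored at `fd$v_min`.
#'
#' @param fd A [fundamental_diagram()].
#' @param n_j Local pedestrian count(s) on the path (>= 0).
#' @return Speed(s) in m/s.
#' @export
local_mean_velocity <- function(fd, n_j) {
  stopifnot(inherits(fd, "fundamental_diagram"))
  if (any(n_j < 0)) stop("'n_j' must be nonnegative")
  pmax(fd$v0 - fd$kappa * n_j, fd$v_min)
}

#' Individual walking speed with additive noise
#'
#' \eqn{v^{(i)}(N_J) = v_0 - \kappa N_J + \epsilon^{(i)}}, floored at
#' `fd$v_min` after adding the perturbation. The pedestrian's own presence is
#' included in `n_j` (the path's total occupancy), so `n_j >= 1`.
#'
#' @param fd A [fundamental_diagram()].
#' @param n_j Occupancy of the pedestrian's path, including the pedestrian.
#' @param eps Per-pedestrian velocity perturbation(s) in m/s.
#' @return Speed(s) in m/s, strictly positive.
#' @export
individual_velocity <- function(fd, n_j, eps) {
  stopifnot(inherits(fd, "fundamental_diagram"))
  if (any(n_j < 1)) stop("'n_j' must be >= 1 (the pedestrian counts itself)")
  pmax(fd$v0 - fd$kappa * n_j + eps, fd$v_min)
}

#' Perceived travel time on one path
#'
#' Path A is perceived at face value, \eqn{\tau_A = L_A / v}; path B is
#' rescaled by the shared perceived-length ratio, \eqn{\tau_B = \lambda_p L_A /
#' v}. The geometric ratio \eqn{\lambda_g} cancels out of the perceived time
#' (the perception map divides it away), which is why only `L_A` and
#' `lambda_p` appear.
#'
#' @param geom A [geometry()].
#' @param fd A [fundamental_diagram()].
#' @param path `"A"` or `"B"`.
#' @param n_j Occupancy of `path`, including the pedestrian (>= 1).
#' @param eps The pedestrian's velocity perturbation (m/s).
#' @param lambda_p Shared perceived-length ratio (> 0).
#' @return Perceived travel time in seconds.
#' @export
perceived_time <- function(geom, fd, path, n_j, eps, lambda_p) {
  stopifnot(inherits(geom, "geometry"))
  if (!all(path %in% c("A", "B"))) stop("'path' must be \"A\" or \"B\"")
  if (any(lambda_p <= 0)) stop("'lambda_p' must be positive")
  v <- individual_velocity(fd, n_j, eps)
  ifelse(path == "A", geom$L_A / v, lambda_p * geom$L_A / v)
}

#' Crowd-level discomfort of a configuration
#'
#' The discomfort functional is the sum of all pedestrians' perceived travel
#' times, each evaluated at the total occupancy of the path assigned to that
#' pedestrian under the configuration.
#'
#' @param geom A [geometry()].
#' @param fd A [fundamental_diagram()].
#' @param eps Vector of N per-pedestrian velocity perturbations (m/s).
#' @param lambda_p Shared perceived-length ratio for this realization (> 0).
#' @param labels Character vector of N path labels (`"A"`/`"B"`).
#' @return Total discomfort in seconds (0 for an empty crowd).
#' @export
total_discomfort <- function(geom, fd, eps, lambda_p, labels) {
  if (length(eps) != length(labels))
    stop("'eps' and 'labels' must have the same length")
  n <- length(labels)
  if (n == 0L) return(0)
  if (!all(labels %in% c("A", "B"))) stop("labels must be \"A\" or \"B\"")
  n_a <- sum(labels == "A")
  n_b <- n - n_a
  n_j <- ifelse(labels == "A", n_a, n_b)
  sum(perceived_time(geom, fd, labels, n_j, eps, lambda_p))
}

# Cost matrices at every possible occupancy level 0..N. Row k+1 holds each
# pedestrian's cost when its path carries k pedestrians.
.cost_matrices <- function(geom, fd, eps, lambda_p) {
  n <- length(eps)
  counts <- 0:n
  v <- pmax(matrix(fd$v0 - fd$kappa * counts, n + 1L, n) +
              matrix(eps, n + 1L, n, byrow = TRUE), fd$v_min)
  list(a = geom$L_A / v, b = lambda_p * geom$L_A / v)
}

# Minimal cost over assignments, returning c(n_a, cost). For each split size
# the optimal membership puts on B the pedestrians with the smallest
# cost difference at that split's fixed speeds; splits are scanned from
# n_a = N downward so ties resolve to the larger N_A.
.best_split <- function(geom, fd, eps, lambda_p) {
  n <- length(eps)
  if (n == 0L) return(c(0, 0))
  cm <- .cost_matrices(geom, fd, eps, lambda_p)
  best_cost <- Inf
  best_na <- n
  for (na in n:0) {
    nb <- n - na
    cost <- if (nb == 0L) {
      sum(cm$a[na + 1L, ])
    } else if (na == 0L) {
      sum(cm$b[nb + 1L, ])
    } else {
      d <- cm$b[nb + 1L, ] - cm$a[na + 1L, ]
      sum(cm$a[na + 1L, ]) + sum(sort(d, partial = nb)[seq_len(nb)])
    }
    if (cost < best_cost) {
      best_cost <- cost
      best_na <- na
    }
  }
  c(best_na, best_cost)
}

#' Exact polynomial-time minimizer of the discomfort functional
#'
#' For each split size \eqn{N_A \in \{0..N\}} the path speeds are fixed by the
#' counts, so the optimal membership assigns to B the \eqn{N_B} pedestrians
#' with the smallest cost difference (B-cost minus A-cost); scanning all
#' split sizes then yields the global optimum over all \eqn{2^N}
#' configurations in \eqn{O(N^2 \log N)}. The cost equals
#' [minimize_bruteforce()]'s exactly. Ties between split sizes resolve to the
#' larger \eqn{N_A}; ties between pedestrians put B at the latest indices,
#' giving the lexicographically smallest label vector.
#'
#' @inheritParams total_discomfort
#' @return A list with `labels`, `n_a`, `n_b` and `cost`.
#' @export
minimize_exact <- function(geom, fd, eps, lambda_p) {
  n <- length(eps)
  if (n == 0L)
    return(list(labels = character(0), n_a = 0L, n_b = 0L, cost = 0))
  bs <- .best_split(geom, fd, eps, lambda_p)
  na <- as.integer(bs[1])
  nb <- n - na
  labels <- rep("A", n)
  if (nb == n) {
    labels[] <- "B"
  } else if (nb > 0L) {
    cm <- .cost_matrices(geom, fd, eps, lambda_p)
    d <- cm$b[nb + 1L, ] - cm$a[na + 1L, ]
    sel <- order(d, -seq_len(n))[seq_len(nb)]
    labels[sel] <- "B"
  }
  list(labels = labels, n_a = na, n_b = as.integer(nb), cost = bs[2])
}

#' Brute-force minimizer over all 2^N configurations
#'
#' Exhaustive enumeration of the full configuration set; the reference oracle
#' for [minimize_exact()]. Guarded at N <= 20. Among equal-cost
#' configurations the one with the larger \eqn{N_A} wins, then the
#' lexicographically smallest label vector (A before B, pedestrian 1 most
#' significant).
#'
#' @inheritParams total_discomfort
#' @return A list with `labels`, `n_a`, `n_b` and `cost`.
#' @export
minimize_bruteforce <- function(geom, fd, eps, lambda_p) {
  n <- length(eps)
  if (n > 20L) stop("brute force is guarded at N <= 20")
  if (n == 0L)
    return(list(labels = character(0), n_a = 0L, n_b = 0L, cost = 0))
  pows <- 2^(0:(n - 1L))
  lexw <- 2^(n - seq_len(n))  # pedestrian 1 most significant
  total <- 2^n
  best <- list(cost = Inf, na = -1L, key = Inf, bits = NULL)
  chunk <- 65536L
  for (start in seq(0L, total - 1L, by = chunk)) {
    masks <- start:min(start + chunk - 1L, total - 1L)
    bits <- outer(masks, pows, function(m, p) (m %/% p) %% 2 == 1)
    nb <- rowSums(bits)
    na <- n - nb
    va <- pmax(outer(fd$v0 - fd$kappa * na, eps, "+"), fd$v_min)
    vb <- pmax(outer(fd$v0 - fd$kappa * nb, eps, "+"), fd$v_min)
    cost <- rowSums(ifelse(bits, lambda_p * geom$L_A / vb, geom$L_A / va))
    cmin <- min(cost)
    if (cmin <= best$cost) {
      idx <- which(cost == cmin)
      na_max <- max(na[idx])
      idx <- idx[na[idx] == na_max]
      key <- as.vector(bits[idx, , drop = FALSE] %*% lexw)
      j <- idx[which.min(key)]
      cand <- list(cost = cmin, na = as.integer(na[j]),
                   key = min(key), bits = bits[j, ])
      if (cmin < best$cost ||
          cand$na > best$na ||
          (cand$na == best$na && cand$key < best$key)) {
        best <- cand
      }
    }
  }
  labels <- ifelse(best$bits, "B", "A")
  list(labels = labels, n_a = best$na, n_b = as.integer(n - best$na),
       cost = best$cost)
}
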