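test_that("velocities follow the linear diagram with floor", {
  fd <- study_fd()
  expect_equal(local_mean_velocity(fd, 0), 1.012)
  expect_equal(local_mean_velocity(fd, 10), 0.842)
  fd0 <- fundamental_diagram(1.0, 0)
  expect_equal(local_mean_velocity(fd0, c(0, 5, 50)), rep(1, 3))

  expect_equal(individual_velocity(fd, 5, 0), local_mean_velocity(fd, 5))
  expect_equal(individual_velocity(fd, 5, 0.15), 1.077)
  expect_equal(individual_velocity(fd, 3, -10), fd$v_min)
  expect_error(individual_velocity(fd, 0, 0), ">= 1")
})

test_that("perceived time rescales path B by the shared ratio", {
  geom <- study_geom()
  fd <- fundamental_diagram(0.8, 0)  # v = 0.8 regardless of count
  expect_equal(perceived_time(geom, fd, "A", 1, 0, 1.45), 1.25)
  expect_equal(perceived_time(geom, fd, "B", 1, 0, 1),
               perceived_time(geom, fd, "A", 1, 0, 1))
  fd1 <- fundamental_diagram(1.0, 0)
  expect_equal(perceived_time(geom, fd1, "B", 1, 0, 1.45), 1.45)
  expect_error(perceived_time(geom, fd, "C", 1, 0, 1), "path")
  expect_error(perceived_time(geom, fd, "B", 1, 0, -1), "positive")
})

test_that("total discomfort sums perceived times at configuration occupancies", {
  geom <- study_geom()
  fd <- fundamental_diagram(1, 0.3)
  expect_identical(total_discomfort(geom, fd, numeric(0), 1, character(0)), 0)
  expect_equal(total_discomfort(geom, fd, c(0, 0), 1, c("A", "A")), 5.0)
  expect_equal(total_discomfort(geom, fd, c(0, 0), 1, c("A", "B")), 2 / 0.7)
  expect_error(total_discomfort(geom, fd, 0, 1, c("A", "B")), "same length")
})

test_that("brute-force minimizer finds known optima with deterministic tie-breaks", {
  geom <- study_geom()
  fd <- fundamental_diagram(1, 0.3)
  s <- minimize_bruteforce(geom, fd, c(0, 0), 1)
  expect_equal(s$cost, 2 / 0.7)
  expect_equal(sort(s$labels), c("A", "B"))

  # a single pedestrian takes the shorter-perceived path
  s1 <- minimize_bruteforce(geom, study_fd(), 0, 1.4)
  expect_identical(s1$labels, "A")

  # no congestion penalty and lambda_p > 1: everyone on A
  fd0 <- fundamental_diagram(1, 0)
  for (n in c(3, 6)) {
    s <- minimize_bruteforce(geom, fd0, rep(0, n), 1.2)
    expect_identical(s$labels, rep("A", n))
  }

  # full degeneracy (flat diagram, lambda_p = 1): ties resolve to all-A
  s <- minimize_bruteforce(geom, fd0, rep(0, 4), 1)
  expect_identical(s$labels, rep("A", 4))
  expect_identical(minimize_exact(geom, fd0, rep(0, 4), 1)$labels,
                   rep("A", 4))
})

test_that("exact polynomial minimizer matches brute force and beats random configurations", {
  geom <- study_geom()
  fd <- study_fd()
  set.seed(515)
  for (i in 1:60) {
    n <- sample(1:10, 1)
    inst <- random_instance(n)
    a <- minimize_exact(geom, fd, inst$eps, inst$lambda_p)
    b <- minimize_bruteforce(geom, fd, inst$eps, inst$lambda_p)
    expect_equal(a$cost, b$cost, tolerance = 1e-10)
    expect_equal(a$cost,
                 total_discomfort(geom, fd, inst$eps, inst$lambda_p, a$labels))
    # returned minimizer is no worse than random configurations
    rand_costs <- replicate(20, total_discomfort(
      geom, fd, inst$eps, inst$lambda_p,
      sample(c("A", "B"), n, replace = TRUE)))
    expect_true(all(a$cost <= rand_costs + 1e-12))
  }
  expect_identical(minimize_exact(geom, fd, numeric(0), 1.2)$n_a, 0L)
  expect_error(minimize_bruteforce(geom, fd, rep(0, 21), 1.2), "N <= 20")
})

test_that("scaling the reference length scales costs and preserves the argmin", {
  fd <- study_fd()
  set.seed(99)
  inst <- random_instance(8)
  g1 <- geometry(1.35, L_A = 1)
  g3 <- geometry(1.35, L_A = 3.7)
  a1 <- minimize_exact(g1, fd, inst$eps, inst$lambda_p)
  a3 <- minimize_exact(g3, fd, inst$eps, inst$lambda_p)
  expect_identical(a1$labels, a3$labels)
  expect_equal(a3$cost, 3.7 * a1$cost, tolerance = 1e-12)
})

test_that("symmetric instances split evenly", {
  geom <- geometry(1.0)
  fd <- fundamental_diagram(1.2, 0.05)
  for (n in c(4, 7, 10)) {
    s <- minimize_exact(geom, fd, rep(0, n), 1)
    expect_lte(abs(s$n_a - s$n_b), 1)
  }
})

test_that("deterministic instances keep path B empty below threshold and use it above", {
  geom <- study_geom()
  fd <- study_fd()
  lam <- emg_mean(emg_tuned())  # fixed perception ratio 1.48
  nstar <- activation_threshold_deterministic(geom, fd, lambda = lam)
  for (n in 1:floor(nstar))
    expect_identical(minimize_exact(geom, fd, rep(0, n), lam)$n_b, 0L)
  for (n in seq(ceiling(nstar) + 4, 24, by = 4))
    expect_gte(minimize_exact(geom, fd, rep(0, n), lam)$n_b, 1L)
})
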