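test_that("deterministic variant is a point mass; m = 1 gives point-mass conditionals", {
  geom <- study_geom(); fd <- study_fd(); emg <- emg_tuned()
  r <- run_ensemble("deterministic", geom, fd, emg, 15, 200, seed = 1)
  expect_identical(length(unique(r$n_b)), 1L)
  expect_equal(sum(r$p_nb == 1), 1)

  st <- sweep_counts("full", geom, fd, emg, 3:5, 1, seed = 2)
  expect_true(all(st$p_nb[, max(prob), by = n]$V1 == 1))
  expect_error(run_ensemble("bogus", geom, fd, emg, 5, 10, seed = 1))
})

test_that("ensemble statistics normalize and conserve pedestrians", {
  geom <- study_geom(); fd <- study_fd(); emg <- emg_tuned()
  st <- sweep_counts("full", geom, fd, emg, 1:8, 300, seed = 33)
  sums <- st$p_nb[, sum(prob), by = n]$V1
  expect_equal(sums, rep(1, 8), tolerance = 1e-9)
  expect_equal(st$mean_n_a + st$mean_n_b, as.numeric(1:8))
  expect_true(all(st$p_empty_b >= 0 & st$p_empty_b <= 1))
  # p_empty_b equals the k = 0 entry of the conditional law
  expect_equal(st$p_empty_b, st$p_nb[k == 0][order(n), prob])
})

test_that("sweeps are reproducible by seed and stable across seeds", {
  geom <- study_geom(); fd <- study_fd(); emg <- emg_tuned()
  a <- sweep_counts("full", geom, fd, emg, 5, 10000, seed = 7)
  b <- sweep_counts("full", geom, fd, emg, 5, 10000, seed = 7)
  expect_identical(a$p_nb, b$p_nb)
  c <- sweep_counts("full", geom, fd, emg, 5, 10000, seed = 8)
  tv <- 0.5 * sum(abs(a$p_nb$prob - c$p_nb$prob))
  expect_lt(tv, 0.05)
})

test_that("velocity fluctuations activate path B earlier than the deterministic model", {
  geom <- study_geom(); fd <- study_fd(); emg <- emg_tuned()
  det <- sweep_counts("deterministic", geom, fd, emg, 1:8, 1, seed = 5)
  full <- sweep_counts("full", geom, fd, emg, 1:8, 2000, seed = 5)
  expect_true(all(full$mean_n_b >= det$mean_n_b))
  expect_gt(sum(full$mean_n_b), 0)
})

test_that("doubling the realization count moves the herding probability by less than 3 SE", {
  geom <- study_geom(); fd <- study_fd(); emg <- emg_tuned()
  a <- run_ensemble("full", geom, fd, emg, 6, 2000, seed = 11)
  b <- run_ensemble("full", geom, fd, emg, 6, 4000, seed = 12)
  p <- (2000 * a$p_nb[1] + 4000 * b$p_nb[1]) / 6000
  se <- sqrt(p * (1 - p) * (1 / 2000 + 1 / 4000))
  expect_lt(abs(a$p_nb[1] - b$p_nb[1]), 3 * se)
})

test_that("activation threshold estimation agrees with the closed form and errors without a crossing", {
  geom <- study_geom(); fd <- study_fd(); emg <- emg_tuned()
  det <- sweep_counts("deterministic", geom, fd, emg, 1:25, 1, seed = 3)
  est <- estimate_activation_threshold(det)
  # discrete crossing of mean N_B = 1: continuum crossing, computed from the
  # closed-form split, within one pedestrian
  cont <- uniroot(function(n)
    n - deterministic_split(geom, fd, n, lambda = emg_mean(emg)) - 1,
    c(1, 25))$root
  expect_lte(abs(est - ceiling(cont)), 1)

  low <- sweep_counts("deterministic", geom, fd, emg, 1:5, 1, seed = 3)
  expect_error(estimate_activation_threshold(low), "never reaches")
})
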