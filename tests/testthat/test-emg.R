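test_that("EMG density normalizes, matches the convolution oracle, and has a Gaussian limit", {
  for (p in list(emg_data_fit(), emg_tuned(), emg_parameters(0, 1, 2))) {
    expect_equal(integrate(function(x) demg(x, p), -10, 10 + 10 * p$beta,
                           rel.tol = 1e-10)$value, 1, tolerance = 1e-6)
  }

  # independent oracle: numerical convolution of normal and exponential
  p <- emg_data_fit()
  for (x0 in c(0.2, 0.77, 1.2, 2.5)) {
    oracle <- integrate(function(y) dnorm(x0 - y, p$mu, p$sigma) *
                          dexp(y, rate = 1 / p$beta),
                        0, Inf, rel.tol = 1e-12)$value
    expect_equal(demg(x0, p), oracle, tolerance = 1e-6)
  }

  # beta -> 0 degenerates to the pure Gaussian
  p0 <- emg_parameters(0.77, 0.30, 1e-8)
  xs <- seq(-0.5, 2, by = 0.1)
  expect_equal(demg(xs, p0), dnorm(xs, 0.77, 0.30), tolerance = 1e-6)

  expect_error(demg(NA_real_, p), "finite")
  expect_error(demg(Inf, p), "finite")
})

test_that("EMG distribution function integrates the density", {
  p <- emg_tuned()
  for (q in c(0.8, 1.2, 1.8)) {
    expect_equal(pemg(q, p),
                 integrate(function(x) demg(x, p), -10, q,
                           rel.tol = 1e-10)$value,
                 tolerance = 1e-8)
  }
})

test_that("EMG sampling is reproducible, has the right mean, and passes a KS check", {
  p <- emg_data_fit()
  x <- remg(1e5, p, seed = 101)
  expect_identical(x, remg(1e5, p, seed = 101))
  # E[X + Y] = mu + beta = 1.45; sample mean within 3 standard errors
  se <- sqrt(emg_variance(p) / 1e5)
  expect_lt(abs(mean(x) - 1.45), 3 * se)

  # near-degenerate parameters collapse to a point mass at mu
  pd <- emg_parameters(1.3, 1e-8, 1e-8)
  expect_equal(remg(100, pd, seed = 1), rep(1.3, 100), tolerance = 1e-6)

  # KS distance below the 1% critical value at n = 1e4
  x4 <- remg(1e4, p, seed = 202)
  ks <- suppressWarnings(stats::ks.test(x4, function(q) pemg(q, p)))
  expect_lt(unname(ks$statistic), 1.63 / sqrt(1e4))

  expect_error(remg(0, p), "positive count")

  # positivity-truncated sampler never returns nonpositive draws
  xp <- remg_positive(1e4, emg_parameters(0.1, 0.3, 0.2), seed = 7)
  expect_true(all(xp > 0))
})

test_that("EMG mean is exact and the mode matches a dense-grid argmax", {
  expect_equal(emg_mean(emg_data_fit()), 1.45)
  expect_equal(emg_mean(emg_tuned()), 1.48)
  expect_equal(emg_mean(emg_parameters(0.9, 0.2, 1e-9)), 0.9)

  # Gaussian limit: mode at mu
  expect_equal(emg_mode(emg_parameters(1.3, 0.25, 1e-9)), 1.3,
               tolerance = 1e-5)

  # dense-grid oracle
  for (p in list(emg_data_fit(), emg_tuned())) {
    grid <- seq(p$mu - 3 * p$sigma, p$mu + 3 * (p$sigma + p$beta), by = 1e-4)
    expect_equal(emg_mode(p), grid[which.max(demg(grid, p))],
                 tolerance = 2e-4)
  }

  # translation equivariance and right skew (mean >= mode)
  p <- emg_data_fit()
  shifted <- emg_parameters(p$mu + 0.8, p$sigma, p$beta)
  expect_equal(emg_mode(shifted), emg_mode(p) + 0.8, tolerance = 1e-5)
  for (p in list(emg_data_fit(), emg_tuned(), emg_parameters(0, 0.5, 0.1)))
    expect_gte(emg_mean(p) - emg_mode(p), 0)
})

test_that("maximum-likelihood EMG fitting recovers generating parameters", {
  for (truth in list(emg_data_fit(), emg_tuned())) {
    x <- remg(1e5, truth, seed = 303)
    f <- emg_fit(x)
    expect_lt(abs(f$mu - truth$mu) / truth$mu, 0.05)
    expect_lt(abs(f$sigma - truth$sigma) / truth$sigma, 0.05)
    expect_lt(abs(f$beta - truth$beta) / truth$beta, 0.05)
  }

  # pure Gaussian data: the exponential component collapses
  g <- rnorm(2e4, 1.2, 0.3)
  set.seed(404)
  fg <- emg_fit(g)
  expect_lt(fg$beta, 0.2 * fg$sigma)

  expect_error(emg_fit(rep(1, 100)), "zero variance")
  expect_error(emg_fit(rnorm(10)), "at least 50")
})

test_that("velocity noise draws are zero-mean Gaussian with the configured sd", {
  expect_identical(noise_sample(50, 0), rep(0, 50))
  x <- noise_sample(1e5, 0.15, seed = 11)
  expect_identical(x, noise_sample(1e5, 0.15, seed = 11))
  expect_lt(abs(sd(x) - 0.15) / 0.15, 0.02)
  expect_lt(abs(mean(x)), 3 * 0.15 / sqrt(1e5))
  expect_error(noise_sample(0, 0.15), "positive count")
  expect_error(noise_sample(10, -1), "nonnegative")
})
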