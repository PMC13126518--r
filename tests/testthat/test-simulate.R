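test_that("log-Gaussian components integrate to their nominal areas", {
  grid <- make_t_grid(1, 10000, 200, "ms")
  one <- make_log_gaussian_distribution(
    data.frame(center = 100, width = 0.08, area = 1.7), grid)
  expect_equal(sum(one), 1.7, tolerance = 1e-12)

  two <- make_log_gaussian_distribution(
    data.frame(center = c(100, 500), width = 0.08, area = 1), grid)
  expect_equal(sum(two), 2, tolerance = 0.01 * 2)

  # moment check by direct summation: mean of log10 T equals the center
  comp <- make_log_gaussian_distribution(
    data.frame(center = 100, width = 0.08, area = 1), grid)
  m1 <- sum(comp * log10(grid$values)) / sum(comp)
  expect_lt(abs(m1 - log10(100)), 1e-3)
})

test_that("a vanishing width concentrates all mass at the nearest grid point", {
  grid <- make_t_grid(1, 10000, 50, "ms")
  g <- make_log_gaussian_distribution(
    data.frame(center = 123, width = 1e-4, area = 1), grid)
  i_near <- which.min(abs(log10(grid$values) - log10(123)))
  expect_gt(g[i_near], 0.999)
})

test_that("component centers must lie inside the grid window", {
  grid <- make_t_grid(1, 1000, 10, "ms")
  expect_error(make_log_gaussian_distribution(
    data.frame(center = 1000, width = 0.1, area = 1), grid), "inside")
  expect_error(make_log_gaussian_distribution(
    data.frame(center = 100, width = -1, area = 1), grid), "positive")
})

test_that("synthesized delta distributions give the closed-form curves", {
  grid <- make_t_grid(1, 10000, 100, "ms")
  i0 <- 60
  T0 <- grid$values[i0]
  A <- 2.5
  dist <- numeric(100); dist[i0] <- A
  tt <- seq(0.5, 5000, by = 2.5)
  expect_equal(synthesize_signal(dist, grid, "cpmg", tt),
               A * exp(-tt / T0), tolerance = 1e-12)
  expect_equal(synthesize_signal(dist, grid, "ir", tt),
               A * (1 - 2 * exp(-tt / T0)), tolerance = 1e-12)
  expect_equal(synthesize_signal(dist, grid, "sr", tt),
               A * (1 - exp(-tt / T0)), tolerance = 1e-12)
})

test_that("synthesize_signal is linear in the distribution", {
  set.seed(21)
  grid <- make_t_grid(1, 1000, 30, "ms")
  tt <- seq(1, 800, by = 4)
  for (rep in 1:5) {
    d1 <- runif(30); d2 <- runif(30)
    a <- rnorm(1); b <- rnorm(1)
    lhs <- synthesize_signal(a * d1 + b * d2, grid, "cpmg", tt)
    rhs <- a * synthesize_signal(d1, grid, "cpmg", tt) +
      b * synthesize_signal(d2, grid, "cpmg", tt)
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
  expect_error(synthesize_signal(runif(10), grid, "cpmg", tt), "length")
})

test_that("noise injection is seeded, scaled, and zero at 0%", {
  sig <- exp(-seq(0.1, 10, length.out = 10000))
  expect_identical(add_gaussian_noise(sig, 0, 1), sig)
  n1 <- add_gaussian_noise(sig, 1, 42)
  n2 <- add_gaussian_noise(sig, 1, 42)
  expect_identical(n1, n2)
  n3 <- add_gaussian_noise(sig, 1, 43)
  expect_false(identical(n1, n3))
  # rms 1% of max|signal| within 3% (law of large numbers at n = 10000)
  expect_lt(abs(sd(n1 - sig) / (0.01 * max(abs(sig))) - 1), 0.03)
  expect_error(add_gaussian_noise(sig, -1, 1), "non-negative")
})

test_that("the two-peak validation fixture is reproducible and decays", {
  fx <- simulate_two_peak_signal(noise_percent = 0, seed = 5)
  expect_true(all(diff(fx$signal$amplitude) <= 0))
  expect_identical(fx$signal$time[1], 0.2)
  expect_identical(nrow(fx$signal), 15000L)
  fx2 <- simulate_two_peak_signal(noise_percent = 2, seed = 5)
  fx3 <- simulate_two_peak_signal(noise_percent = 2, seed = 5)
  expect_identical(fx2$signal$amplitude, fx3$signal$amplitude)
  expect_equal(sum(fx$truth), 2, tolerance = 0.02)
})

test_that("noiseless fixtures are fit to numerical precision at tiny alpha", {
  fx <- simulate_two_peak_signal(noise_percent = 0, seed = 1)
  res <- suppressWarnings(run_ilt(fx$signal, "cpmg", fx$grid, alpha = 1e-4))
  expect_lt(res$chi2, 1e-6 * sum(fx$signal$amplitude^2))
})
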