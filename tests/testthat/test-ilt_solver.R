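test_that("svd_compress keeps full rank on well-posed systems", {
  c3 <- c(2, -1, 5)
  comp <- svd_compress(diag(3), c3, rel_tol = 1e-12)
  expect_identical(comp$rank_kept, 3L)
  # projected system is an orthogonal rotation: same LS solution
  x_full <- qr.solve(diag(3), c3)
  x_proj <- qr.solve(comp$design, comp$target)
  expect_equal(x_proj, x_full, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("a zero row adds no singular direction", {
  set.seed(11)
  K <- matrix(rnorm(12), 4, 3)
  r1 <- svd_compress(K, rnorm(4))$rank_kept
  K2 <- rbind(K, 0)
  r2 <- svd_compress(K2, rnorm(5))$rank_kept
  expect_identical(r1, r2)
})

test_that("svd_compress validates its inputs", {
  expect_error(svd_compress(matrix(numeric(0), 0, 0), numeric(0)),
               "non-empty")
  expect_error(svd_compress(diag(2), 1:3), "nrow")
  expect_error(svd_compress(diag(2), 1:2, rel_tol = 2), "rel_tol")
})

test_that("compressed and uncompressed NNLS solutions agree", {
  set.seed(42)
  grid <- make_t_grid(1, 1000, 20, "ms")
  tt <- sort(runif(40, 0.5, 2500))
  K <- build_kernel("cpmg", tt, grid)
  g_true <- runif(20) * rbinom(20, 1, 0.3)
  b <- drop(unclass(K) %*% g_true) + rnorm(40, 0, 0.01)

  comp <- svd_compress(K, b, rel_tol = 1e-12)
  x_comp <- solve_nnls(assemble_regularized_system(comp$design, comp$target,
                                                   0.05, "identity"))
  x_full <- solve_nnls(assemble_regularized_system(unclass(K), b,
                                                   0.05, "identity"))
  expect_lt(max(abs(x_comp - x_full)), 1e-6)
})

test_that("regularized stacking realizes the penalized objective", {
  d <- matrix(rnorm(12), 4, 3)
  tg <- rnorm(4)
  s0 <- assemble_regularized_system(d, tg, 0, "identity")
  expect_identical(dim(s0$design), c(4L, 3L))
  expect_identical(s0$target, tg)

  s4 <- assemble_regularized_system(d, tg, 4, "identity")
  expect_equal(s4$design[5:7, ], 2 * diag(3), ignore_attr = TRUE)
  expect_identical(s4$target[5:7], c(0, 0, 0))

  sd2 <- assemble_regularized_system(matrix(rnorm(8), 2, 4), rnorm(2), 1,
                                     "second_difference")
  expect_equal(sd2$design[3, ], c(1, -2, 1, 0), ignore_attr = TRUE)
  expect_equal(sd2$design[4, ], c(0, 1, -2, 1), ignore_attr = TRUE)

  expect_error(assemble_regularized_system(d, tg, -1), "non-negative")
})

test_that("solve_nnls clamps to the non-negative orthant", {
  s <- assemble_regularized_system(diag(2), c(1, -1), 0)
  expect_equal(as.numeric(solve_nnls(s)), c(1, 0))
  s2 <- assemble_regularized_system(diag(2), c(1, 1), 0)
  expect_equal(as.numeric(solve_nnls(s2)), c(1, 1))
})

test_that("solve_nnls matches exhaustive active-set enumeration", {
  set.seed(7)
  for (rep in 1:40) {
    A <- matrix(rnorm(24), 6, 4)
    b <- rnorm(6)
    x <- solve_nnls(list(design = A, target = b))
    expect_true(all(x >= 0))
    obj <- sum((A %*% as.numeric(x) - b)^2)
    expect_equal(obj, brute_force_nnls_objective(A, b), tolerance = 1e-8)
  }
})

test_that("solve_nnls satisfies the KKT conditions", {
  set.seed(8)
  for (rep in 1:20) {
    A <- matrix(rnorm(60), 10, 6)
    b <- rnorm(10)
    x <- as.numeric(solve_nnls(list(design = A, target = b)))
    grad <- drop(crossprod(A, A %*% x - b))
    expect_true(all(grad[x == 0] >= -1e-8))
    expect_true(all(abs(grad[x > 0]) <= 1e-8))
  }
})

test_that("solve_nnls agrees with an independent NNLS implementation", {
  skip_if_not_installed("pracma")
  set.seed(9)
  for (rep in 1:10) {
    A <- matrix(rnorm(80), 16, 5)
    b <- rnorm(16)
    x <- as.numeric(solve_nnls(list(design = A, target = b)))
    ref <- pracma::lsqnonneg(A, b)$x
    expect_equal(x, ref, tolerance = 1e-8)
  }
})

test_that("chi_squared is the summed squared residual", {
  expect_identical(chi_squared(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_identical(chi_squared(c(1, 0), c(0, 0)), 1)
  set.seed(3)
  a <- rnorm(50); b <- rnorm(50)
  acc <- 0
  for (i in 1:50) acc <- acc + (a[i] - b[i])^2
  expect_equal(chi_squared(a, b), acc, tolerance = 1e-12)
  expect_error(chi_squared(1:3, 1:2), "mismatch")
})

test_that("run_ilt recovers a single exponential at its relaxation time", {
  grid <- make_t_grid(1, 10000, 200, "ms")
  sig <- small_cpmg_signal(T2 = 100, n = 600, t_max = 2000)
  res <- suppressWarnings(run_ilt(sig, "cpmg", grid, alpha = 0.1))
  expect_true(all(res$g >= 0))
  pk <- find_peaks(res$g, grid)
  expect_one_grid_step(pk$center[which.max(pk$height)], 100, grid)
  # fit and chi2 are consistent with the distribution
  K <- build_kernel("cpmg", sig$time, grid)
  expect_equal(res$fit, drop(unclass(K) %*% res$g), tolerance = 1e-10)
  expect_equal(res$chi2, sum(res$residuals^2), tolerance = 1e-10)
})

test_that("an all-zero signal inverts to the zero distribution", {
  grid <- make_t_grid(1, 1000, 30, "ms")
  tt <- seq(1, 500, by = 1)
  sig <- relaxation_signal(data.frame(t = tt, a = 0 * tt), "ms")
  res <- run_ilt(sig, "cpmg", grid, alpha = 1)
  expect_identical(res$g, rep(0, 30))
  expect_identical(res$chi2, 0)
})

test_that("misfit grows monotonically along an increasing alpha ladder", {
  sig <- small_cpmg_signal(T2 = c(50, 400), amp = c(1, 1),
                           n = 500, t_max = 2500)
  grid <- make_t_grid(1, 10000, 80, "ms")
  chi2s <- vapply(c(0.01, 0.1, 1, 10), function(a) {
    suppressWarnings(run_ilt(sig, "cpmg", grid, alpha = a))$chi2
  }, numeric(1))
  expect_true(all(diff(chi2s) >= -1e-10 * (1 + chi2s[-4])))
})

test_that("with the identity operator a huge alpha shrinks g to zero", {
  sig <- small_cpmg_signal(T2 = 100, n = 300, t_max = 1500)
  grid <- make_t_grid(1, 10000, 50, "ms")
  K <- build_kernel("cpmg", sig$time, grid)
  smax <- svd(unclass(K))$d[1]
  res <- suppressWarnings(
    run_ilt(sig, "cpmg", grid, alpha = 1e8 * smax^2,
            reg_operator = "identity")
  )
  expect_lt(sqrt(sum(res$g^2)), 1e-6)
})

test_that("run_ilt enforces timescale agreement and column selection", {
  sig <- small_cpmg_signal()
  expect_error(run_ilt(sig, "cpmg", make_t_grid(1, 100, 10, "s"), 1),
               "timescale")
  expect_error(run_ilt(sig, "cpmg", make_t_grid(1, 100, 10, "ms"), 1,
                       column = "nope"), "no signal column")
})
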