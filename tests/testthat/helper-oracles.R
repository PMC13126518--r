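# Independent oracles used against the implementation paths.

# Exhaustive active-set NNLS: solve the unconstrained least-squares
# problem on every subset of columns, keep the feasible (non-negative)
# candidates, return the best objective value. Exponential in N; only
# for tiny systems.
brute_force_nnls_objective <- function(A, b) {
  N <- ncol(A)
  best <- sum(b^2) # empty active set: x = 0
  for (mask in seq_len(2^N - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(N) - 1)) > 0)
    coef <- qr.coef(qr(A[, S, drop = FALSE]), b)
    coef[is.na(coef)] <- 0
    if (any(coef < 0)) next
    x <- numeric(N)
    x[S] <- coef
    best <- min(best, sum((A %*% x - b)^2))
  }
  best
}

# Element-by-element kernel evaluation with scalar arithmetic (no
# vectorization shared with the implementation).
elementwise_kernel <- function(kind, times, Ts) {
  out <- matrix(NA_real_, length(times), length(Ts))
  for (j in seq_along(times)) {
    for (i in seq_along(Ts)) {
      e <- exp(-times[j] / Ts[i])
      out[j, i] <- switch(kind, cpmg = e, ir = 1 - 2 * e, sr = 1 - e)
    }
  }
  out
}

# Small, fast CPMG test signal: one or two exponential components on a
# short record. Keeps unit tests well under a second each.
small_cpmg_signal <- function(T2 = 100, amp = 1, n = 400, t_max = 1200,
                              timescale = "ms") {
  tt <- seq(t_max / n, t_max, length.out = n)
  y <- rowSums(sapply(seq_along(T2), function(i) amp[min(i, length(amp))] *
                        exp(-tt / T2[i])))
  relaxation_signal(data.frame(time = tt, signal_1 = y),
                    timescale = timescale)
}

expect_one_grid_step <- function(center, truth, grid) {
  step <- (log10(grid$t_end) - log10(grid$t_start)) / (grid$n_points - 1)
  expect_lt(abs(log10(center / truth)), step * (1 + 1e-9))
}
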