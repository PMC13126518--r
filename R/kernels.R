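#' Relaxation kernel functions
#'
#' Model response of a unit-amplitude component with relaxation time `T`
#' at acquisition time `t`, for the three supported pulse sequences:
#'
#' * CPMG (transverse relaxation, T2): `exp(-t/T)` — a monotone decay
#'   from 1 to 0;
#' * inversion recovery (longitudinal, T1): `1 - 2 exp(-t/T)` — grows
#'   from -1 to +1;
#' * saturation recovery (longitudinal, T1): `1 - exp(-t/T)` — grows
#'   from 0 to 1.
#'
#' @param kind Kernel tag: `"cpmg"`, `"ir"` or `"sr"` (case-insensitive).
#' @param t Acquisition time(s), non-negative, same unit as `T`.
#' @param T Relaxation time(s), strictly positive.
#' @return Kernel values, vectorized over `t` and `T`.
#' @examples
#' kernel_value("cpmg", t = 0.1, T = 0.1) # exp(-1)
#' kernel_value("ir", t = 0, T = 1)       # -1
#' @export
kernel_value <- function(kind, t, T) {
  kind <- normalize_kernel_kind(kind)
  if (any(!is.finite(t)) || any(t < 0)) {
    abort("`t` must be finite and non-negative.")
  }
  if (any(!is.finite(T)) || any(T <= 0)) {
    abort("`T` must be finite and strictly positive.")
  }
  e <- exp(-t / T)
  switch(kind,
    cpmg = e,
    ir = 1 - 2 * e,
    sr = 1 - e
  )
}

#' Discretized kernel matrix
#'
#' Evaluates the chosen kernel over the outer product of the experimental
#' time axis and the relaxation-time grid, giving the n x N design matrix
#' `K` of the discrete forward model `c(t_n) = sum_i g(T_i) K(t_n, T_i)`.
#' Row j corresponds to `times[j]`, column i to `grid$values[i]`.
#'
#' @param kind Kernel tag: `"cpmg"`, `"ir"` or `"sr"`.
#' @param times Experimental time axis: non-empty, non-negative, strictly
#'   increasing, in the same timescale as `grid`. A leading `t = 0` is
#'   allowed (inversion-recovery signals legitimately start at -c0).
#' @param grid A [make_t_grid()] grid.
#' @return A `kernel_matrix` object: the numeric matrix with attributes
#'   `kind`, `times` and `grid`.
#' @export
build_kernel <- function(kind, times, grid) {
  kind <- normalize_kernel_kind(kind)
  assert_t_grid(grid)
  if (length(times) == 0 || any(!is.finite(times))) {
    abort("`times` must be non-empty and finite.")
  }
  if (any(times < 0)) {
    abort("`times` must be non-negative; negative acquisition times found.")
  }
  if (length(times) > 1 && any(diff(times) <= 0)) {
    bad <- which(diff(times) <= 0)[1] + 1
    abort(sprintf(
      "`times` must be strictly increasing (violated at position %d).", bad
    ))
  }
  K <- outer(times, grid$values, function(t, T) kernel_value(kind, t, T))
  structure(K, kind = kind, times = times, grid = grid,
            class = c("kernel_matrix", class(K)))
}

#' @export
print.kernel_matrix <- function(x, ...) {
  g <- attr(x, "grid")
  cat(sprintf("<kernel_matrix> %s, %d times x %d relaxation times (%s)\n",
              toupper(attr(x, "kind")), nrow(x), ncol(x), g$timescale))
  invisible(x)
}
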