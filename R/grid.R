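#' Log-spaced relaxation-time grid
#'
#' Builds the candidate relaxation-time axis of the inversion: `n_points`
#' values uniformly spaced in log10 between `t_start` and `t_end`, both
#' endpoints included. This is the discretization of the distribution
#' `g(T)` — the window should bracket every relaxation time expected in
#' the sample (for biological samples, typically 0.001 to 10 s).
#'
#' @param t_start Smallest candidate relaxation time, in `timescale` units.
#'   Must be positive.
#' @param t_end Largest candidate relaxation time; must exceed `t_start`.
#' @param n_points Number of grid points (at least 2). Typical values are
#'   100 or 200.
#' @param timescale Unit tag carried with the grid: `"seconds"`,
#'   `"milliseconds"` or `"microseconds"` (short forms `"s"`, `"ms"`,
#'   `"us"` accepted). No conversion is performed; the distribution axis
#'   inherits this unit.
#' @return A `t_grid` object: a list with fields `t_start`, `t_end`,
#'   `n_points`, `timescale` and `values` (the grid itself).
#' @examples
#' make_t_grid(0.001, 10, 5, "seconds")$values # the four decades
#' @export
make_t_grid <- function(t_start, t_end, n_points, timescale = "seconds") {
  timescale <- normalize_timescale(timescale)
  if (!is.numeric(t_start) || length(t_start) != 1 || !is.finite(t_start) ||
      t_start <= 0) {
    abort("`t_start` must be a single positive number.")
  }
  if (!is.numeric(t_end) || length(t_end) != 1 || !is.finite(t_end) ||
      t_end <= t_start) {
    abort("`t_end` must be a single number greater than `t_start`.")
  }
  if (!is.numeric(n_points) || length(n_points) != 1 ||
      n_points != round(n_points) || n_points < 2) {
    abort("`n_points` must be an integer of at least 2.")
  }
  n_points <- as.integer(n_points)
  values <- 10^seq(log10(t_start), log10(t_end), length.out = n_points)
  # pin the endpoints exactly despite floating-point seq()
  values[1] <- t_start
  values[n_points] <- t_end
  structure(
    list(t_start = t_start, t_end = t_end, n_points = n_points,
         timescale = timescale, values = values),
    class = "t_grid"
  )
}

#' @export
print.t_grid <- function(x, ...) {
  cat(sprintf(
    "<t_grid> %d log10-uniform points, %g to %g %s\n",
    x$n_points, x$t_start, x$t_end, x$timescale
  ))
  invisible(x)
}

#' @export
format.t_grid <- function(x, ...) {
  sprintf("t_grid(%g, %g, %d, %s)", x$t_start, x$t_end, x$n_points,
          x$timescale)
}

#' @rdname make_t_grid
#' @param x Object to test or print.
#' @export
is_t_grid <- function(x) inherits(x, "t_grid")

assert_t_grid <- function(grid) {
  if (!is_t_grid(grid)) abort("`grid` must be a `t_grid` (see make_t_grid()).")
  grid
}

# Width of one grid step in decades of log10(T).
grid_log_step <- function(grid) {
  assert_t_grid(grid)
  (log10(grid$t_end) - log10(grid$t_start)) / (grid$n_points - 1)
}

#' @method as_tibble t_grid
#' @export
as_tibble.t_grid <- function(x, ...) {
  tibble(T = x$values)
}
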