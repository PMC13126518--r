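#' Detect peaks in a relaxation-time distribution
#'
#' Finds the local maxima of a non-negative distribution `g` over a log
#' grid, keeping those at least `min_height_frac` of the global maximum.
#' Each peak's extent runs between the local minima that surround it (or
#' the grid boundaries); plateau maxima are resolved to their smallest
#' index; width is the full width at half maximum measured in decades of
#' log10(T), by linear interpolation in log10(T) at half height.
#'
#' @param g Non-negative amplitude vector over `grid`.
#' @param grid The [make_t_grid()] grid `g` lives on.
#' @param min_height_frac Detection threshold as a fraction of `max(g)`,
#'   in (0, 1); default 0.05.
#' @return A tibble with one row per peak: `center` (grid T at the
#'   maximum), `height`, `fwhm_log` (decades), `area` (sum of `g` over
#'   the extent), `idx_lo`, `idx_hi`.
#' @export
find_peaks <- function(g, grid, min_height_frac = 0.05) {
  assert_t_grid(grid)
  if (length(g) != grid$n_points) {
    abort("`g` must have one value per grid point.")
  }
  if (any(!is.finite(g)) || any(g < 0)) {
    abort("`g` must be finite and non-negative.")
  }
  if (!is.numeric(min_height_frac) || length(min_height_frac) != 1 ||
      min_height_frac <= 0 || min_height_frac >= 1) {
    abort("`min_height_frac` must be in (0, 1).")
  }
  empty <- tibble(center = numeric(), height = numeric(),
                  fwhm_log = numeric(), area = numeric(),
                  idx_lo = integer(), idx_hi = integer())
  if (max(g) <= 0) return(empty)

  n <- length(g)
  maxima <- local_maxima(g)
  maxima <- maxima[g[maxima] >= min_height_frac * max(g)]
  if (length(maxima) == 0) return(empty)

  minima <- local_minima(g)
  logT <- log10(grid$values)
  rows <- lapply(maxima, function(p) {
    lo <- max(c(1L, minima[minima < p]))
    hi <- min(c(n, minima[minima > p]))
    half <- g[p] / 2
    list(center = grid$values[p], height = g[p],
         fwhm_log = fwhm_at(g, logT, p, half),
         area = sum(g[lo:hi]), idx_lo = lo, idx_hi = hi)
  })
  dplyr::bind_rows(rows)
}

# Indices of local maxima, plateaus resolved to their smallest index.
local_maxima <- function(g) {
  n <- length(g)
  runs <- rle(g)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  k <- length(runs$values)
  keep <- vapply(seq_len(k), function(i) {
    left_up <- i == 1 || runs$values[i - 1] < runs$values[i]
    right_down <- i == k || runs$values[i + 1] < runs$values[i]
    left_up && right_down
  }, logical(1))
  starts[keep]
}

# Indices of (plateau-resolved) local minima, used to delimit peak extents.
local_minima <- function(g) {
  local_maxima(-g)
}

# Full width at half maximum in log10(T), walking outward from peak `p`
# and interpolating the half-height crossings; clipped at the grid edges
# when the distribution never falls below half height there.
fwhm_at <- function(g, logT, p, half) {
  n <- length(g)
  left <- logT[1]
  for (i in seq(p, 1)) {
    if (g[i] < half) {
      frac <- (half - g[i]) / (g[i + 1] - g[i])
      left <- logT[i] + frac * (logT[i + 1] - logT[i])
      break
    }
  }
  right <- logT[n]
  for (i in seq(p, n)) {
    if (g[i] < half) {
      frac <- (half - g[i]) / (g[i - 1] - g[i])
      right <- logT[i] - frac * (logT[i] - logT[i - 1])
      break
    }
  }
  right - left
}

#' Total spectral area of a distribution
#'
#' `g` is a discrete amplitude per grid point (the summation form of the
#' forward model), so the total area is a plain sum — the quantity the
#' regularization trade-off preserves while peak shapes change.
#'
#' @param g Non-negative amplitude vector.
#' @return `sum(g)`.
#' @export
total_area <- function(g) {
  if (any(!is.finite(g)) || any(g < 0)) {
    abort("`g` must be finite and non-negative.")
  }
  sum(g)
}

#' Compare a recovered distribution with its ground truth
#'
#' Detects peaks in both distributions, matches recovered peaks to truth
#' peaks greedily by proximity in log10(T), and reports per-peak relative
#' center deviations (%), the number of unmatched ("spurious") recovered
#' peaks, and the L2 distance between the sum-normalized distributions.
#' The metric set used to validate inversions against simulated inputs.
#'
#' @param recovered,truth Non-negative amplitude vectors over `grid`.
#' @param grid Their common [make_t_grid()] grid.
#' @param min_height_frac Peak threshold passed to [find_peaks()].
#' @return An `ilt_comparison`: list with `peaks` (tibble: one row per
#'   truth peak, with matched recovered center and `deviation_pct`),
#'   `n_spurious`, and `l2_distance`.
#' @export
compare_to_truth <- function(recovered, truth, grid, min_height_frac = 0.05) {
  assert_t_grid(grid)
  if (length(recovered) != length(truth)) {
    abort("`recovered` and `truth` must have equal length.")
  }
  truth_peaks <- find_peaks(truth, grid, min_height_frac)
  if (nrow(truth_peaks) == 0) {
    abort("`truth` has no peaks above threshold; nothing to compare against.")
  }
  rec_peaks <- find_peaks(recovered, grid, min_height_frac)

  matches <- greedy_match(log10(rec_peaks$center), log10(truth_peaks$center))
  peaks <- dplyr::mutate(
    dplyr::rename(truth_peaks, true_center = "center",
                  true_height = "height"),
    recovered_center = rec_peaks$center[matches],
    recovered_height = rec_peaks$height[matches],
    deviation_pct = 100 * (.data$recovered_center / .data$true_center - 1)
  )
  peaks <- dplyr::select(peaks, "true_center", "recovered_center",
                         "deviation_pct", "true_height", "recovered_height")

  norm2 <- function(v) if (sum(v) > 0) v / sum(v) else v
  structure(
    list(
      peaks = peaks,
      n_spurious = nrow(rec_peaks) - sum(!is.na(matches)),
      l2_distance = sqrt(sum((norm2(recovered) - norm2(truth))^2))
    ),
    class = "ilt_comparison"
  )
}

# Greedily pair recovered positions to truth positions by smallest
# |log10 T| gap; each side used at most once. Returns, for each truth
# position, the index of the matched recovered position (NA if none).
greedy_match <- function(recovered_log, truth_log) {
  match_idx <- rep(NA_integer_, length(truth_log))
  if (length(recovered_log) == 0) return(match_idx)
  d <- abs(outer(truth_log, recovered_log, "-"))
  for (k in seq_len(min(dim(d)))) {
    ij <- arrayInd(which.min(d), dim(d))
    if (!is.finite(d[ij])) break
    match_idx[ij[1]] <- ij[2]
    d[ij[1], ] <- Inf
    d[, ij[2]] <- Inf
  }
  match_idx
}

#' @export
print.ilt_comparison <- function(x, ...) {
  cat("<ilt_comparison>\n")
  print(x$peaks)
  cat(sprintf("spurious recovered peaks: %d;  L2 distance (normalized): %.4g\n",
              x$n_spurious, x$l2_distance))
  invisible(x)
}

#' @method tidy ilt_comparison
#' @export
tidy.ilt_comparison <- function(x, ...) x$peaks

#' @method glance ilt_comparison
#' @export
glance.ilt_comparison <- function(x, ...) {
  tibble(
    n_truth_peaks = nrow(x$peaks),
    n_matched = sum(!is.na(x$peaks$recovered_center)),
    n_spurious = x$n_spurious,
    mean_abs_deviation_pct = mean(abs(x$peaks$deviation_pct), na.rm = TRUE),
    l2_distance = x$l2_distance
  )
}
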