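#' Drop initial data points
#'
#' Removes the first `k` rows of a relaxation signal (time axis and every
#' amplitude column). Used to discard points corrupted by spectrometer
#' dead-time or other spurious early samples, which otherwise inject
#' artificial peaks into the inverted distribution.
#'
#' @param signal A [relaxation_signal()].
#' @param k Number of leading points to drop; `0 <= k < nrow(signal)`.
#' @return The trimmed `relaxation_signal`.
#' @export
remove_start_points <- function(signal, k) {
  assert_signal(signal)
  n <- nrow(signal)
  if (!is.numeric(k) || length(k) != 1 || k != round(k) || k < 0) {
    abort("`k` must be a single non-negative integer.")
  }
  if (k >= n) {
    abort(sprintf(
      "cannot remove %d start points from a signal of %d rows (nothing would remain).",
      k, n
    ))
  }
  if (k == 0) return(signal)
  rewrap_signal(signal[-seq_len(k), , drop = FALSE], signal)
}

#' Correct a constant baseline offset
#'
#' Estimates and subtracts a constant amplitude offset from every signal
#' column. A displaced baseline violates the asymptotes of the relaxation
#' model and shows up as spurious slow components in the distribution, so
#' the estimate is anchored to the region where each model's asymptote is
#' known:
#'
#' * CPMG decays to zero — the mean of the last `m` points is subtracted
#'   (tail forced to zero);
#' * inversion recovery runs from -A to +A — the midpoint of the first-`m`
#'   and last-`m` means is subtracted (curve centered);
#' * saturation recovery starts at zero — the mean of the first `m`
#'   points is subtracted (head forced to zero).
#'
#' @param signal A [relaxation_signal()].
#' @param kind Kernel tag of the experiment (`"cpmg"`, `"ir"`, `"sr"`);
#'   selects the offset rule.
#' @param m Number of points averaged at each anchor; defaults to
#'   `max(5, 2%)` of the record and must satisfy `1 <= m <= n/4`.
#' @return The offset-corrected `relaxation_signal`.
#' @export
correct_offset <- function(signal, kind, m = NULL) {
  assert_signal(signal)
  kind <- normalize_kernel_kind(kind)
  n <- nrow(signal)
  if (is.null(m)) m <- max(5, ceiling(0.02 * n))
  if (!is.numeric(m) || length(m) != 1 || m != round(m) || m < 1 || m > n / 4) {
    abort(sprintf("`m` must be an integer in [1, n/4] = [1, %d].",
                  floor(n / 4)))
  }
  out <- signal
  for (lab in signal_labels(signal)) {
    y <- signal[[lab]]
    head_mean <- mean(y[seq_len(m)])
    tail_mean <- mean(y[seq.int(n - m + 1, n)])
    offset <- switch(kind,
      cpmg = tail_mean,
      ir = (head_mean + tail_mean) / 2,
      sr = head_mean
    )
    out[[lab]] <- y - offset
  }
  rewrap_signal(out, signal)
}

#' Normalize each column by its first value
#'
#' Divides every amplitude column by its own first entry, so all columns
#' start at exactly 1 (or, for inversion recovery starting negative, at 1
#' with flipped sign). Useful for comparing signals of different absolute
#' amplitude on one scale.
#'
#' Saturation-recovery data start near zero, so the first value is not a
#' usable scale; such columns are rejected — disable normalization or
#' remove the leading points first.
#'
#' @param signal A [relaxation_signal()].
#' @return The normalized `relaxation_signal`.
#' @export
normalize_first_value <- function(signal) {
  assert_signal(signal)
  out <- signal
  for (lab in signal_labels(signal)) {
    y <- signal[[lab]]
    if (abs(y[1]) <= 1e-12 * max(abs(y))) {
      abort(paste0(
        "column `", lab, "` starts at (near) zero, so first-value ",
        "normalization is undefined (typical of saturation-recovery data). ",
        "Disable normalization or remove the leading points first."
      ))
    }
    out[[lab]] <- y / y[1]
  }
  rewrap_signal(out, signal)
}

#' Apply the standard preprocessing pipeline
#'
#' Convenience composition applied before inversion, in the fixed order:
#' [remove_start_points()], then [correct_offset()], then
#' [normalize_first_value()]. The order is not user-configurable so that
#' batch runs over compared signals are always processed identically.
#'
#' @param signal A [relaxation_signal()].
#' @param kind Kernel tag (used by the offset rule).
#' @param remove_start Leading points to drop (default 0).
#' @param offset_mode `"auto"` to apply the kernel-matched offset
#'   correction, `"off"` to skip it.
#' @param normalize Logical: divide each column by its first value?
#' @param offset_points `m` passed to [correct_offset()] (default
#'   `max(5, 2%)` of the record).
#' @return The preprocessed `relaxation_signal`.
#' @export
preprocess_signal <- function(signal, kind,
                              remove_start = 0,
                              offset_mode = c("off", "auto"),
                              normalize = FALSE,
                              offset_points = NULL) {
  offset_mode <- match.arg(offset_mode)
  signal <- remove_start_points(signal, remove_start)
  if (offset_mode == "auto") {
    signal <- correct_offset(signal, kind, offset_points)
  }
  if (isTRUE(normalize)) signal <- normalize_first_value(signal)
  signal
}
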