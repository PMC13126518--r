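#' Relaxation signal table
#'
#' A relaxation signal is a tibble whose first column (`time`) is the
#' experimental acquisition axis and whose remaining columns are one or
#' more amplitude series sharing that axis — the same layout as the
#' plain-text input tables ([read_signal_table()]). A `timescale`
#' attribute records the time unit; no conversion is ever applied.
#'
#' @param data A data frame: column 1 the time axis, columns 2+ amplitude
#'   series. Times must be finite, non-negative and strictly increasing;
#'   amplitudes finite.
#' @param timescale Time unit tag (`"seconds"`, `"milliseconds"`,
#'   `"microseconds"`, or short forms `"s"`, `"ms"`, `"us"`).
#' @param labels Optional character vector of column names for the
#'   amplitude series; defaults to existing names or `signal_1`,
#'   `signal_2`, ...
#' @return A tibble of class `relaxation_signal`.
#' @examples
#' sig <- relaxation_signal(
#'   data.frame(t = c(1, 2, 3, 4), a = exp(-c(1, 2, 3, 4) / 2)),
#'   timescale = "ms"
#' )
#' signal_timescale(sig)
#' @export
relaxation_signal <- function(data, timescale = "seconds", labels = NULL) {
  timescale <- normalize_timescale(timescale)
  if (!is.data.frame(data) || ncol(data) < 2) {
    abort("`data` must be a data frame with a time column and at least one amplitude column.")
  }
  times <- as.numeric(data[[1]])
  if (any(!is.finite(times))) {
    abort(sprintf("non-finite time value at row %d.",
                  which(!is.finite(times))[1]))
  }
  if (any(times < 0)) {
    abort(sprintf("negative time value at row %d.", which(times < 0)[1]))
  }
  if (length(times) > 1 && any(diff(times) <= 0)) {
    abort(sprintf("times must be strictly increasing; violated at row %d.",
                  which(diff(times) <= 0)[1] + 1))
  }
  cols <- lapply(data[-1], as.numeric)
  for (j in seq_along(cols)) {
    if (any(!is.finite(cols[[j]]))) {
      abort(sprintf("non-finite amplitude at row %d, column %d.",
                    which(!is.finite(cols[[j]]))[1], j + 1))
    }
  }
  if (is.null(labels)) {
    labels <- names(data)[-1]
    if (is.null(labels) || any(labels == "") ||
        all(grepl("^V[0-9]+$", labels))) {
      labels <- paste0("signal_", seq_along(cols))
    }
  }
  if (length(labels) != length(cols)) {
    abort("`labels` must name every amplitude column.")
  }
  out <- tibble::new_tibble(
    c(list(time = times), setNames(cols, labels)),
    nrow = length(times),
    class = "relaxation_signal",
    timescale = timescale
  )
  out
}

#' @rdname relaxation_signal
#' @param x A `relaxation_signal`.
#' @export
signal_timescale <- function(x) {
  assert_signal(x)
  attr(x, "timescale")
}

#' @rdname relaxation_signal
#' @export
signal_labels <- function(x) {
  assert_signal(x)
  setdiff(names(x), "time")
}

#' @rdname relaxation_signal
#' @export
is_relaxation_signal <- function(x) inherits(x, "relaxation_signal")

assert_signal <- function(x) {
  if (!is_relaxation_signal(x)) {
    abort("expected a `relaxation_signal` (see relaxation_signal() or read_signal_table()).")
  }
  x
}

# Rebuild the class/attributes after a transformation of the columns.
rewrap_signal <- function(data, template) {
  tibble::new_tibble(
    as.list(data), nrow = nrow(data),
    class = "relaxation_signal",
    timescale = attr(template, "timescale")
  )
}

#' @export
print.relaxation_signal <- function(x, ...) {
  cat(sprintf("<relaxation_signal> %d points, %d signal(s), time in %s\n",
              nrow(x), ncol(x) - 1L, attr(x, "timescale")))
  NextMethod()
}
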