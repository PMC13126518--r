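#' Read a plain-text signal table
#'
#' Reads the standard relaxometry exchange format: a `.txt`/`.dat`/`.csv`
#' table whose first column is the time axis and whose remaining columns
#' are amplitude signals sharing that axis. The delimiter is sniffed
#' among tab, comma, semicolon and whitespace (in that order); if the
#' first row does not parse as numbers it is taken as column labels.
#'
#' @param path Path to the file.
#' @param timescale Unit of the time axis (`"s"`, `"ms"`, `"us"` or long
#'   forms); recorded on the returned signal, never converted.
#' @return A [relaxation_signal()].
#' @export
read_signal_table <- function(path, timescale = "seconds") {
  timescale <- normalize_timescale(timescale)
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 4) {
    abort(sprintf("%s: need at least 4 data rows, found %d non-empty lines.",
                  path, length(lines)))
  }
  # sniff the delimiter on the last line (never a header)
  probe <- lines[length(lines)]
  sep <- if (grepl("\t", probe)) "\t"
         else if (grepl(",", probe)) ","
         else if (grepl(";", probe)) ";"
         else ""

  split_row <- function(line) {
    if (sep == "") strsplit(trimws(line), "[[:space:]]+")[[1]]
    else trimws(strsplit(line, sep, fixed = TRUE)[[1]])
  }
  first <- suppressWarnings(as.numeric(split_row(lines[1])))
  has_header <- any(is.na(first))

  tab <- tryCatch(
    read.table(text = paste(lines, collapse = "\n"), sep = sep,
               header = has_header, check.names = FALSE,
               colClasses = "character", comment.char = ""),
    error = function(e) abort(sprintf("%s: malformed table (%s).",
                                      path, conditionMessage(e)))
  )
  if (ncol(tab) < 2) {
    abort(sprintf("%s: need at least 2 columns (time + amplitude), found %d.",
                  path, ncol(tab)))
  }
  if (nrow(tab) < 4) {
    abort(sprintf("%s: need at least 4 numeric rows, found %d.",
                  path, nrow(tab)))
  }
  header_off <- if (has_header) 1L else 0L
  num <- lapply(seq_len(ncol(tab)), function(j) {
    v <- suppressWarnings(as.numeric(tab[[j]]))
    if (any(is.na(v))) {
      abort(sprintf("%s: non-numeric value at row %d, column %d.",
                    path, which(is.na(v))[1] + header_off, j))
    }
    v
  })
  times <- num[[1]]
  if (length(times) > 1 && any(diff(times) <= 0)) {
    abort(sprintf("%s: time axis not strictly increasing at row %d.",
                  path, which(diff(times) <= 0)[1] + 1 + header_off))
  }
  labels <- if (has_header) names(tab)[-1] else NULL
  df <- data.frame(num, check.names = FALSE)
  names(df) <- c("time", labels %||% paste0("signal_", seq_len(ncol(tab) - 1)))
  relaxation_signal(df, timescale = timescale, labels = names(df)[-1])
}

#' Write a signal table
#'
#' Writes a [relaxation_signal()] in the plain-text exchange format read
#' by [read_signal_table()]: a header row of labels, then tab-separated
#' numeric rows (time first).
#'
#' @param signal A [relaxation_signal()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_table <- function(signal, path) {
  assert_signal(signal)
  readr::write_tsv(as.data.frame(signal), path)
  invisible(path)
}

#' Write inversion results as CSV tables
#'
#' Emits the result bundle of one or more inversions sharing a grid:
#' `distribution.csv` (T axis + one distribution column per signal),
#' `fit.csv` and `residuals.csv` (time axis + one column per signal),
#' `peaks.csv` (detected peaks, one row each) and `run_config.json`
#' (every parameter needed to reproduce the run).
#'
#' @param results An `ilt_result` or `ilt_result_set`.
#' @param out_dir Output directory (created if missing).
#' @param peak_threshold `min_height_frac` used for `peaks.csv`.
#' @param run_config Optional named list persisted as `run_config.json`
#'   alongside the parameters recorded from the results themselves.
#' @return Tibble manifest of written files (`file`, `path`).
#' @export
write_results <- function(results, out_dir, peak_threshold = 0.05,
                          run_config = list()) {
  if (inherits(results, "ilt_result")) {
    results <- structure(setNames(list(results), results$label),
                         class = "ilt_result_set")
  }
  if (!inherits(results, "ilt_result_set") || length(results) == 0) {
    abort("`results` must hold at least one inversion result.")
  }
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    abort(sprintf("cannot create output directory %s.", out_dir))
  }
  first <- results[[1]]
  labs <- vapply(results, function(r) r$label, character(1))

  dist_tab <- as.data.frame(
    c(list(T = first$grid$values), lapply(results, function(r) r$g)),
    check.names = FALSE
  )
  fit_tab <- as.data.frame(
    c(list(time = first$times), lapply(results, function(r) r$fit)),
    check.names = FALSE
  )
  res_tab <- as.data.frame(
    c(list(time = first$times), lapply(results, function(r) r$residuals)),
    check.names = FALSE
  )
  peaks_tab <- dplyr::bind_rows(lapply(results, function(r) {
    pk <- find_peaks(r$g, r$grid, peak_threshold)
    if (nrow(pk)) dplyr::mutate(pk, signal = r$label, .before = 1) else NULL
  }))
  if (nrow(peaks_tab) == 0) {
    peaks_tab <- tibble(signal = character(), center = numeric(),
                        height = numeric(), fwhm_log = numeric(),
                        area = numeric(), idx_lo = integer(),
                        idx_hi = integer())
  }

  config <- c(
    list(
      kernel = first$kind, alpha = first$alpha,
      reg_operator = first$operator,
      t_start = first$grid$t_start, t_end = first$grid$t_end,
      n_points = first$grid$n_points, timescale = first$grid$timescale,
      peak_threshold = peak_threshold, signals = unname(labs),
      chi2 = unname(vapply(results, function(r) r$chi2, numeric(1))),
      rank_kept = unname(vapply(results, function(r) r$rank_kept,
                                numeric(1)))
    ),
    run_config
  )

  paths <- c(
    distribution = file.path(out_dir, "distribution.csv"),
    fit = file.path(out_dir, "fit.csv"),
    residuals = file.path(out_dir, "residuals.csv"),
    peaks = file.path(out_dir, "peaks.csv"),
    run_config = file.path(out_dir, "run_config.json")
  )
  readr::write_csv(dist_tab, paths[["distribution"]])
  readr::write_csv(fit_tab, paths[["fit"]])
  readr::write_csv(res_tab, paths[["residuals"]])
  readr::write_csv(peaks_tab, paths[["peaks"]])
  jsonlite::write_json(config, paths[["run_config"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  tibble(file = names(paths), path = unname(paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
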