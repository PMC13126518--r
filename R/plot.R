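#' Plot an inversion result
#'
#' `type = "distribution"` draws the relaxation-time distribution
#' (relaxogram) on a log T axis; `"fit"` overlays the fitted model on
#' the measured signal; `"residuals"` shows the time-domain residuals.
#'
#' @param object An `ilt_result` or `ilt_result_set`.
#' @param type One of `"distribution"`, `"fit"`, `"residuals"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ilt_result
#' @export
autoplot.ilt_result <- function(object,
                                type = c("distribution", "fit", "residuals"),
                                ...) {
  type <- match.arg(type)
  ts <- object$grid$timescale
  switch(type,
    distribution = ggplot2::ggplot(tidy(object),
                                   ggplot2::aes(x = .data$T, y = .data$g)) +
      ggplot2::geom_line() +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = sprintf("relaxation time T (%s)", ts),
                    y = "amplitude g(T)",
                    title = sprintf("%s distribution, alpha = %g",
                                    toupper(object$kind), object$alpha)),
    fit = ggplot2::ggplot(augment(object), ggplot2::aes(x = .data$time)) +
      ggplot2::geom_point(ggplot2::aes(y = .data$observed),
                          size = 0.4, alpha = 0.4) +
      ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
      ggplot2::labs(x = sprintf("time (%s)", ts), y = "amplitude",
                    title = "signal and regularized fit"),
    residuals = ggplot2::ggplot(augment(object),
                                ggplot2::aes(x = .data$time,
                                             y = .data$residual)) +
      ggplot2::geom_line() +
      ggplot2::geom_hline(yintercept = 0, linetype = 2) +
      ggplot2::labs(x = sprintf("time (%s)", ts), y = "residual")
  )
}

#' @rdname autoplot.ilt_result
#' @method autoplot ilt_result_set
#' @export
autoplot.ilt_result_set <- function(object,
                                    type = c("distribution", "fit",
                                             "residuals"),
                                    ...) {
  type <- match.arg(type)
  ts <- object[[1]]$grid$timescale
  if (type == "distribution") {
    ggplot2::ggplot(tidy(object),
                    ggplot2::aes(x = .data$T, y = .data$g,
                                 colour = .data$signal)) +
      ggplot2::geom_line() +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = sprintf("relaxation time T (%s)", ts),
                    y = "amplitude g(T)")
  } else {
    col <- if (type == "fit") "fitted" else "residual"
    ggplot2::ggplot(augment(object),
                    ggplot2::aes(x = .data$time, y = .data[[col]],
                                 colour = .data$signal)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = sprintf("time (%s)", ts), y = col)
  }
}

#' Quick relaxogram for a distribution vector
#'
#' @param g Amplitude vector over `grid`.
#' @param grid A [make_t_grid()] grid.
#' @return A ggplot object.
#' @export
plot_distribution <- function(g, grid) {
  assert_t_grid(grid)
  ggplot2::ggplot(tibble(T = grid$values, g = g),
                  ggplot2::aes(x = .data$T, y = .data$g)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = sprintf("relaxation time T (%s)", grid$timescale),
                  y = "amplitude g(T)")
}
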