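#' Raster plot of a spike record
#'
#' @param object A \code{spike_record}.
#' @param types Cell types to show (default: all LIF populations present).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spike_record <- function(object,
                                  types = setdiff(unique(object$cell_type),
                                                  c("MF", "IO")),
                                  ...) {
  df <- object[object$cell_type %in% types, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data$id)) +
    ggplot2::geom_point(shape = ".", alpha = 0.6) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$cell_type),
                        scales = "free_y") +
    ggplot2::labs(x = "time (ms)", y = "neuron id") +
    ggplot2::theme_minimal()
}

#' Population rates of a burst run
#'
#' @param object A \code{burst_result}.
#' @param ... Unused.
#' @return A ggplot of mean rates (error bars: SD across neurons and
#'   repetitions) per population and period.
#' @export
autoplot.burst_result <- function(object, ...) {
  ggplot2::ggplot(object$rates,
                  ggplot2::aes(x = .data$cell_type, y = .data$mean_hz,
                               fill = .data$period)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$mean_hz - .data$sd_hz, 0),
                   ymax = .data$mean_hz + .data$sd_hz),
      position = ggplot2::position_dodge(width = 0.9), width = 0.3) +
    ggplot2::labs(x = NULL, y = "firing rate (Hz)") +
    ggplot2::theme_minimal()
}

#' Learning curves of an OKR run
#'
#' @param object An \code{okr_result}.
#' @param what \code{"learning"} (fitted min/max per trial) or
#'   \code{"trials"} (binned rates with cosine fits for selected trials).
#' @param trials Trials shown when \code{what = "trials"}.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.okr_result <- function(object, what = c("learning", "trials"),
                                trials = NULL, ...) {
  what <- match.arg(what)
  if (what == "learning") {
    df <- tidyr::pivot_longer(object$fits, c("min", "max"),
                              names_to = "bound", values_to = "rate")
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$trial, y = .data$rate,
                                       colour = .data$bound)) +
        ggplot2::geom_line() +
        ggplot2::facet_wrap(ggplot2::vars(.data$cell_type), scales = "free_y") +
        ggplot2::labs(x = "trial", y = "cosine-fit rate (Hz)") +
        ggplot2::theme_minimal()
    )
  }
  if (is.null(trials)) {
    trials <- unique(round(seq(1, max(object$curves$trial), length.out = 4)))
  }
  df <- object$curves[object$curves$trial %in% trials, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_mid, y = .data$rate,
                                   colour = factor(.data$trial))) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm",
                         formula = y ~ cos(2 * pi * x / 2000) +
                           sin(2 * pi * x / 2000), se = FALSE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$cell_type), scales = "free_y") +
    ggplot2::labs(x = "time in trial (ms)", y = "rate (Hz)",
                  colour = "trial") +
    ggplot2::theme_minimal()
}

#' Data and fitted curve of a cosine fit
#' @param object A \code{cosine_fit}.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cosine_fit <- function(object, ...) {
  df <- object$data
  df$fitted <- object$fitted
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$rate)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "steelblue") +
    ggplot2::labs(x = "time (ms)", y = "rate (Hz)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
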