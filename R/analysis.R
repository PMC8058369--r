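#' Mean population firing rate in a window
#'
#' Total spike count of the given cells inside \code{[from, to)} divided by
#' the number of cells and the window length in seconds.
#'
#' @param rec A spike record.
#' @param ids Integer vector of global neuron ids (must be non-empty).
#' @param window Numeric \code{c(from, to)} in ms.
#' @return Rate in Hz.
#' @export
#' @examples
#' # 1 neuron with 5 spikes in 1000 ms -> 5 Hz
mean_firing_rate <- function(rec, ids, window) {
  if (length(ids) == 0) stop("empty id set", call. = FALSE)
  if (diff(window) <= 0) stop("window must be non-empty", call. = FALSE)
  n <- sum(rec$id %in% ids & rec$time_ms >= window[1] & rec$time_ms < window[2])
  n / (length(ids) * diff(window) / 1000)
}

#' Binned population rate
#'
#' @param rec A spike record.
#' @param cell_type Population to bin.
#' @param bin Bin width in ms.
#' @param window Optional \code{c(from, to)} ms; defaults to
#'   \code{[0, max spike time]} rounded up to a bin.
#' @return Tibble with \code{t_mid} (bin centre, ms) and \code{rate} (Hz,
#'   per-neuron population mean).
#' @export
bin_population_rates <- function(rec, cell_type, bin = 100, window = NULL) {
  n_cells <- attr(rec, "n_cells")[[cell_type]]
  if (is.null(n_cells) || n_cells == 0) stop("no cells of type ", cell_type,
                                             call. = FALSE)
  sub <- rec[rec$cell_type == cell_type, ]
  if (is.null(window)) {
    hi <- if (nrow(rec)) ceiling(max(rec$time_ms) / bin) * bin else bin
    window <- c(0, hi)
  }
  breaks <- seq(window[1], window[2], by = bin)
  tt <- sub$time_ms[sub$time_ms >= window[1] & sub$time_ms < window[2]]
  counts <- tabulate(findInterval(tt, breaks), nbins = length(breaks) - 1L)
  tibble::tibble(
    t_mid = breaks[-length(breaks)] + bin / 2,
    rate = counts / (n_cells * bin / 1000)
  )
}

#' Least-squares cosine fit of a binned rate curve
#'
#' Fits \eqn{r(t) = a + b \cos(2\pi (t - \phi)/T)} by linear least squares
#' in the basis \eqn{\{1, \cos, \sin\}}. The fitted minimum is
#' \eqn{a - |b|} and the maximum \eqn{a + |b|}.
#'
#' @param t Bin centres (ms).
#' @param rate Rates (Hz).
#' @param period Period T in ms.
#' @return Object of class \code{cosine_fit}: list with \code{offset},
#'   \code{amplitude} (>= 0), \code{phase} (ms, in \code{[0, T)}; NA when
#'   the amplitude is 0), \code{min}, \code{max}, \code{period},
#'   \code{fitted}, \code{data}.
#' @export
#' @examples
#' t <- seq(50, 1950, by = 100)
#' fit <- cosine_fit(t, 50 + 20 * cos(2 * pi * t / 2000), period = 2000)
#' glance(fit)
cosine_fit <- function(t, rate, period) {
  if (length(t) < 3) stop("need at least 3 bins", call. = FALSE)
  X <- cbind(1, cos(2 * pi * t / period), sin(2 * pi * t / period))
  cf <- stats::lm.fit(X, rate)$coefficients
  a <- cf[[1]]; A <- cf[[2]]; B <- cf[[3]]
  b <- sqrt(A^2 + B^2)
  phase <- if (b < 1e-12) NA_real_ else (atan2(B, A) * period / (2 * pi)) %% period
  structure(
    list(offset = a, amplitude = b, phase = phase,
         min = a - b, max = a + b, period = period,
         fitted = as.numeric(X %*% cf),
         data = tibble::tibble(t = t, rate = rate)),
    class = "cosine_fit"
  )
}

#' @export
print.cosine_fit <- function(x, ...) {
  cat(sprintf("<cosine_fit> offset %.2f, amplitude %.2f Hz, phase %s ms (T = %g ms)\n",
              x$offset, x$amplitude,
              if (is.na(x$phase)) "NA" else sprintf("%.1f", x$phase),
              x$period))
  invisible(x)
}

#' Tidy a cosine fit
#' @param x A \code{cosine_fit}.
#' @param ... Unused.
#' @return One row per parameter (term, estimate).
#' @export
tidy.cosine_fit <- function(x, ...) {
  tibble::tibble(
    term = c("offset", "amplitude", "phase"),
    estimate = c(x$offset, x$amplitude, x$phase)
  )
}

#' One-row summary of a cosine fit
#' @param x A \code{cosine_fit}.
#' @param ... Unused.
#' @return Tibble with offset, amplitude, phase, min, max, rmse.
#' @export
glance.cosine_fit <- function(x, ...) {
  tibble::tibble(
    offset = x$offset, amplitude = x$amplitude, phase = x$phase,
    min = x$min, max = x$max,
    rmse = sqrt(mean((x$data$rate - x$fitted)^2))
  )
}

#' Turn a fitted object into a tidy tibble
#' @param x Object.
#' @param ... Method arguments.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row model summary
#' @param x Object.
#' @param ... Method arguments.
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Phase difference between two cosine fits
#'
#' Signed circular difference in radians, in \code{(-pi, pi]}.
#' @param fit_a,fit_b \code{cosine_fit} objects sharing a period.
#' @return Radians.
#' @export
phase_difference <- function(fit_a, fit_b) {
  d <- (fit_a$phase - fit_b$phase) / fit_a$period * 2 * pi
  ((d + pi) %% (2 * pi)) - pi
}
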