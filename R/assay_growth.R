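#' Fit sliding-window growth rates to an OD time series
#'
#' An ordinary least-squares line is fitted to log(OD) against time in every
#' contiguous window of `window` datapoints (default 20, matching 10-min
#' plate-reader sampling over ~3 h); the steepest slope is the maximal growth
#' rate. Ties are broken in favour of the earliest window.
#'
#' @param curve A data frame with columns `time` (hours, strictly increasing)
#'   and `od` (optical density, > 0).
#' @param window Window length in datapoints (>= 3).
#' @return An object of class `growth_fit`; see [max_growth_rate()],
#'   [generics::tidy()] and [generics::glance()] methods.
#' @examples
#' curve <- tibble::tibble(time = seq(0, 5, by = 1/6),
#'                         od = 0.01 * exp(0.5 * seq(0, 5, by = 1/6)))
#' max_growth_rate(curve)
#' @export
fit_growth_rate <- function(curve, window = 20) {
  stopifnot(all(c("time", "od") %in% names(curve)), window >= 3)
  if (nrow(curve) < window) {
    stop("curve shorter than the sliding window (", nrow(curve), " < ",
         window, " points)", call. = FALSE)
  }
  if (any(curve$od <= 0)) stop("non-positive OD values", call. = FALSE)
  if (any(diff(curve$time) <= 0)) {
    stop("timepoints must be strictly increasing", call. = FALSE)
  }
  t <- curve$time
  y <- log(curve$od)
  nw <- nrow(curve) - window + 1L
  # rolling OLS slope via cumulative sums: slope = (n*Sxy - Sx*Sy) / (n*Sxx - Sx^2)
  cs <- function(z) c(0, cumsum(z))
  win_sum <- function(z) {
    c_ <- cs(z)
    c_[(window + 1):(nrow(curve) + 1)] - c_[1:nw]
  }
  sx <- win_sum(t); sy <- win_sum(y)
  sxx <- win_sum(t * t); sxy <- win_sum(t * y)
  slope <- (window * sxy - sx * sy) / (window * sxx - sx^2)
  best <- which.max(slope)  # which.max returns the earliest maximum
  structure(
    list(slopes = tibble::tibble(window_start = seq_len(nw),
                                 t_start = t[seq_len(nw)],
                                 t_end = t[seq_len(nw) + window - 1L],
                                 slope = slope),
         window = as.integer(window),
         max_rate = slope[best], best_window = best,
         n_points = nrow(curve)),
    class = "growth_fit"
  )
}

#' Maximal growth rate of an OD time series
#'
#' @inheritParams fit_growth_rate
#' @return The steepest sliding-window slope of log(OD) vs time (per hour).
#' @export
max_growth_rate <- function(curve, window = 20) {
  fit_growth_rate(curve, window)$max_rate
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> %d points, window %d: max rate %.4f/h (window starting t = %.2f h)\n",
              x$n_points, x$window, x$max_rate,
              x$slopes$t_start[x$best_window]))
  invisible(x)
}

#' Tidy the per-window slopes of a growth fit
#'
#' @param x A `growth_fit`.
#' @param ... Unused.
#' @return A tibble with one row per sliding window: `window_start`,
#'   `t_start`, `t_end`, `slope`.
#' @exportS3Method generics::tidy
#' @export
tidy.growth_fit <- function(x, ...) x$slopes

#' One-row summary of a growth fit
#'
#' @param x A `growth_fit`.
#' @param ... Unused.
#' @return A tibble with `max_rate`, `best_window`, `window`, `n_points`.
#' @exportS3Method generics::glance
#' @export
glance.growth_fit <- function(x, ...) {
  tibble::tibble(max_rate = x$max_rate, best_window = x$best_window,
                 window = x$window, n_points = x$n_points)
}
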