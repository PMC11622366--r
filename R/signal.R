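#' Resample traces onto a uniform time grid
#'
#' Linearly interpolates each trace onto an evenly spaced grid spanning its
#' own time range; no extrapolation beyond the raw span. With
#' `dt = "auto"` the step is the median raw inter-scan interval of the
#' trace (when processing an analyte/PCIS pair, pass the PCIS trace's
#' median step explicitly so both land on one shared grid).
#'
#' @param traces A trace tibble.
#' @param dt Grid step in minutes, or `"auto"`.
#' @return A trace tibble on the uniform grid.
#' @export
#' @examples
#' tr <- trace_tbl(c(0, 1, 2), c(0, 10, 20), label = "x")
#' resample_uniform(tr, dt = 0.5)
resample_uniform <- function(traces, dt = "auto") {
  if (!identical(dt, "auto") && (!is.numeric(dt) || dt <= 0)) {
    abort("dt must be a positive number of minutes or \"auto\"",
          class = "pcisr_validation_error")
  }
  traces <- validate_traces(traces)
  purrr::map_dfr(trace_split(traces), function(tr) {
    step <- if (identical(dt, "auto")) median(diff(tr$time_min)) else dt
    grid <- seq(tr$time_min[1], tr$time_min[nrow(tr)], by = step)
    out <- tr[rep(1, length(grid)), ]
    out$time_min <- grid
    out$intensity <- approx(tr$time_min, tr$intensity, xout = grid)$y
    out
  })
}

# Median raw inter-scan interval of a single trace (the "auto" grid step).
median_scan_interval <- function(trace) {
  trace <- single_trace(trace)
  median(diff(trace$time_min))
}

#' Centered moving-average smoothing
#'
#' Applies a centered moving average of odd width to each trace. At the
#' edges the window truncates to the available points, so a window of 1 is
#' the identity and constants are preserved exactly.
#'
#' @param traces A trace tibble (conventionally already on a uniform grid).
#' @param window Odd window width in points (default 3).
#' @return The smoothed trace tibble.
#' @export
smooth_traces <- function(traces, window = 3) {
  traces <- validate_traces(traces)
  purrr::map_dfr(trace_split(traces), function(tr) {
    tr$intensity <- moving_average(tr$intensity, window)
    tr
  })
}

#' @rdname smooth_traces
#' @param x Numeric vector.
#' @export
moving_average <- function(x, window = 3) {
  if (window < 1 || window %% 2 != 1) {
    abort("smoothing window must be an odd integer >= 1",
          class = "pcisr_validation_error")
  }
  if (window > length(x)) {
    abort("smoothing window longer than the trace",
          class = "pcisr_validation_error")
  }
  if (window == 1) return(x)
  half <- (window - 1) / 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half)
    hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Restrict traces to a half-open time window
#'
#' Keeps points with `t_start <= time < t_end`. All windows in this package
#' are half-open so adjacent windows never double-count a boundary scan.
#'
#' @param traces A trace tibble.
#' @param t_start,t_end Window bounds in minutes, `t_start < t_end`.
#' @return The restricted trace tibble.
#' @export
window_traces <- function(traces, t_start, t_end) {
  if (t_start >= t_end) {
    abort("t_start must be < t_end", class = "pcisr_validation_error")
  }
  out <- dplyr::filter(traces, .data$time_min >= t_start,
                       .data$time_min < t_end)
  if (nrow(out) == 0) {
    abort(sprintf("empty window [%g, %g) on trace", t_start, t_end),
          class = "pcisr_window_error")
  }
  out
}

#' Pearson correlation of two signals
#'
#' The standard product-moment coefficient, with the degenerate cases a
#' chromatography user hits in practice turned into clear errors.
#'
#' @param a,b Equal-length numeric vectors (>= 3 points, non-constant).
#' @return A single coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b)) {
    abort("signals must have equal length", class = "pcisr_validation_error")
  }
  if (length(a) < 3) {
    abort("need at least 3 points for a correlation",
          class = "pcisr_validation_error")
  }
  if (sd(a) == 0 || sd(b) == 0) {
    abort("constant signal: correlation undefined",
          class = "pcisr_constant_signal_error")
  }
  cor(a, b, method = "pearson")
}
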