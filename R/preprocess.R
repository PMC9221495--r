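#' Block moving-average preprocessing configuration
#'
#' The temporal downsampling applied before distance computation: a strided
#' moving average with window `window_s` and stride `stride_s` seconds. With
#' the defaults (5 s window, 5 s stride) the windows tile the recording
#' without overlap, so a 150-sample recording at 1 frame per second becomes
#' a 30-sample series. Both must be positive integer multiples of the
#' series' sampling interval. Trailing samples that do not fill a window are
#' dropped.
#'
#' @param window_s Averaging window in seconds (> 0).
#' @param stride_s Stride between window starts in seconds (> 0).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(window_s = 5, stride_s = 5) {
  check_number(window_s, "window_s", 0, strict = TRUE)
  check_number(stride_s, "stride_s", 0, strict = TRUE)
  structure(list(window_s = window_s, stride_s = stride_s),
            class = "preprocess_config")
}

#' @export
print.preprocess_config <- function(x, ...) {
  cat(sprintf("Block moving average: %g s window, %g s stride\n",
              x$window_s, x$stride_s))
  invisible(x)
}

samples_of <- function(seconds, interval, what) {
  n <- seconds / interval
  if (abs(n - round(n)) > 1e-9)
    stop_invalid("%s (%g s) is not an integer multiple of the sampling interval (%g s)",
                 what, seconds, interval)
  as.integer(round(n))
}

#' Strided moving-average downsampling of a colour time series
#'
#' Output sample `j` (0-based) of each channel is the arithmetic mean of
#' input samples `[j*s, j*s + w)` where `w` and `s` are the window and
#' stride in samples; the output has `floor((T - w)/s) + 1` samples and
#' sampling interval `stride_s`. All channels are treated independently and
#' identically.
#'
#' @param series A `color_ts` (or `color_ts_list`, processed elementwise).
#' @param config A [preprocess_config()].
#' @return The downsampled `color_ts` (or `color_ts_list`).
#' @examples
#' s <- color_ts(matrix(1:10, nrow = 1), 1)
#' block_average(s, preprocess_config(window_s = 2, stride_s = 2))$values
#' @export
block_average <- function(series, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  if (inherits(series, "color_ts_list") ||
      (is.list(series) && !inherits(series, "color_ts")))
    return(new_color_ts_list(lapply(series, block_average, config = config)))
  stopifnot(inherits(series, "color_ts"))
  w <- samples_of(config$window_s, series$sampling_interval_s, "window_s")
  s <- samples_of(config$stride_s, series$sampling_interval_s, "stride_s")
  n_t <- ncol(series$values)
  if (n_t < w)
    stop_invalid("tube '%s': series length %d shorter than window (%d samples)",
                 series$tube_id, n_t, w)
  n_out <- (n_t - w) %/% s + 1L
  starts <- (seq_len(n_out) - 1L) * s
  out <- vapply(starts, function(st)
    rowMeans(series$values[, (st + 1L):(st + w), drop = FALSE]),
    numeric(nrow(series$values)))
  out <- matrix(out, nrow = nrow(series$values))
  color_ts(out, config$stride_s, tube_id = series$tube_id,
           true_concentration = series$true_concentration,
           channel_names = series$channel_names)
}
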