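#' A multichannel colour time series for one tube
#'
#' Container for one tube's recorded (or simulated) colour trace: a
#' channels-by-timepoints intensity matrix with sampling interval and an
#' optional known concentration.
#'
#' @param values Numeric matrix, channels x timepoints, finite, nominally in
#'   \[0, 1\]. Row names, if present, are taken as channel names.
#' @param sampling_interval_s Seconds between consecutive samples (> 0).
#' @param tube_id Identifier string.
#' @param true_concentration Known concentration, or `NA` if unknown.
#' @param channel_names Channel labels; defaults to `rownames(values)` or
#'   `ch1..chK`.
#' @return An object of class `color_ts`.
#' @export
color_ts <- function(values, sampling_interval_s, tube_id = "tube",
                     true_concentration = NA_real_, channel_names = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values) || any(!is.finite(values)))
    stop_invalid("tube '%s': intensity values must be finite numeric", tube_id)
  if (ncol(values) < 1L || nrow(values) < 1L)
    stop_invalid("tube '%s': needs >= 1 channel and >= 1 timepoint", tube_id)
  check_number(sampling_interval_s, "sampling_interval_s", 0, strict = TRUE)
  if (is.null(channel_names))
    channel_names <- rownames(values)
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(nrow(values)))
  if (length(channel_names) != nrow(values))
    stop_invalid("tube '%s': %d channel names for %d channels", tube_id,
                 length(channel_names), nrow(values))
  rownames(values) <- channel_names
  if (!is.na(true_concentration))
    check_number(true_concentration, "true_concentration", 0)
  structure(
    list(tube_id = as.character(tube_id),
         channel_names = as.character(channel_names),
         values = values,
         sampling_interval_s = sampling_interval_s,
         true_concentration = as.numeric(true_concentration)),
    class = "color_ts")
}

#' @export
print.color_ts <- function(x, ...) {
  conc <- if (is.na(x$true_concentration)) "unknown"
          else format(x$true_concentration)
  cat(sprintf("<color_ts> %s: %d channels (%s) x %d samples @ %g s, concentration %s\n",
              x$tube_id, nrow(x$values),
              paste(x$channel_names, collapse = ","),
              ncol(x$values), x$sampling_interval_s, conc))
  invisible(x)
}

new_color_ts_list <- function(x) {
  structure(x, class = "color_ts_list")
}

#' @export
print.color_ts_list <- function(x, ...) {
  concs <- vapply(x, function(s) s$true_concentration, numeric(1))
  cat(sprintf("<color_ts_list> %d series", length(x)))
  if (!all(is.na(concs))) {
    tab <- table(concs)
    cat(sprintf("; levels: %s",
                paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                      collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

#' @export
`[.color_ts_list` <- function(x, i) {
  new_color_ts_list(unclass(x)[i])
}

concentrations_of <- function(series_list) {
  vapply(series_list, function(s) s$true_concentration, numeric(1))
}

check_common_channels <- function(a, b) {
  if (!identical(a$channel_names, b$channel_names))
    stop_invalid("channel mismatch between '%s' (%s) and '%s' (%s)",
                 a$tube_id, paste(a$channel_names, collapse = ","),
                 b$tube_id, paste(b$channel_names, collapse = ","))
  invisible(TRUE)
}
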