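#' Read and write colour time series as tidy CSV
#'
#' The on-disk format is one row per (tube, channel, timepoint) with columns
#' `tube_id, concentration, time_s, channel, intensity`. Intensities are
#' written with 15 significant digits so a write/read round trip is lossless
#' to double precision for all practical purposes.
#'
#' @param series A `color_ts_list` (or a single `color_ts`).
#' @param path CSV file path.
#' @return `read_series_csv()` returns a `color_ts_list`;
#'   `write_series_csv()` returns `path` invisibly.
#' @export
write_series_csv <- function(series, path) {
  if (inherits(series, "color_ts")) series <- new_color_ts_list(list(series))
  stopifnot(inherits(series, "color_ts_list") || is.list(series))
  rows <- lapply(series, function(s) {
    n_t <- ncol(s$values)
    t_s <- seq(0, by = s$sampling_interval_s, length.out = n_t)
    data.frame(
      tube_id = s$tube_id,
      concentration = s$true_concentration,
      time_s = rep(t_s, each = nrow(s$values)),
      channel = rep(s$channel_names, times = n_t),
      intensity = as.vector(s$values),
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df$time_s <- format(df$time_s, digits = 15, trim = TRUE, scientific = FALSE)
  df$intensity <- format(df$intensity, digits = 15, trim = TRUE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  if (!file.exists(path))
    stop_invalid("file not found: %s", path)
  if (file.size(path) == 0)
    stop_invalid("empty input file: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0)
    stop_invalid("no data rows in %s", path)
  need <- c("tube_id", "concentration", "time_s", "channel", "intensity")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop_invalid("missing columns in %s: %s", path,
                 paste(missing_cols, collapse = ", "))
  if (!is.numeric(df$intensity) || any(!is.finite(df$intensity)))
    stop_invalid("non-numeric or non-finite intensities in %s", path)
  if (!is.numeric(df$time_s))
    stop_invalid("non-numeric time_s in %s", path)

  tube_ids <- unique(df$tube_id)  # order of first appearance
  out <- lapply(tube_ids, function(id) {
    sub <- df[df$tube_id == id, , drop = FALSE]
    channels <- unique(sub$channel)
    times <- sort(unique(sub$time_s))
    per_ch <- split(sub, factor(sub$channel, levels = channels))
    n_per <- vapply(per_ch, nrow, integer(1))
    if (length(unique(n_per)) != 1L || n_per[1] != length(times))
      stop_invalid("tube '%s': ragged channels (counts %s over %d timepoints)",
                   id, paste(n_per, collapse = "/"), length(times))
    vals <- vapply(per_ch, function(ch) {
      ch <- ch[order(ch$time_s), , drop = FALSE]
      if (!isTRUE(all.equal(ch$time_s, times)))
        stop_invalid("tube '%s': channels sampled on different time grids", id)
      ch$intensity
    }, numeric(length(times)))
    dt <- if (length(times) > 1) times[2] - times[1] else 1
    conc <- unique(sub$concentration)
    if (length(conc) != 1L)
      stop_invalid("tube '%s': conflicting concentration labels", id)
    color_ts(t(vals), dt, tube_id = id, true_concentration = conc,
             channel_names = channels)
  })
  new_color_ts_list(out)
}
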