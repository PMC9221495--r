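#' Dynamic time warping configuration
#'
#' Settings for the DTW distance: the local cost between aligned samples
#' (absolute or squared difference), an optional Sakoe-Chiba band width, and
#' the aggregation of per-channel distances for multichannel series
#' (arithmetic mean). The step pattern is the basic symmetric one —
#' insertion, deletion and diagonal steps all with weight 1 — and no
#' path-length normalisation is applied.
#'
#' @param local_cost `"absolute"` (default) or `"squared"`.
#' @param window_constraint Non-negative integer band half-width, or `NULL`
#'   for unconstrained warping (the default; the series compared here are
#'   short, so the full O(nm) table is cheap).
#' @return An object of class `dtw_config`.
#' @export
dtw_config <- function(local_cost = c("absolute", "squared"),
                       window_constraint = NULL) {
  local_cost <- match.arg(local_cost)
  if (!is.null(window_constraint)) {
    check_number(window_constraint, "window_constraint", 0)
    if (window_constraint != round(window_constraint))
      stop_invalid("'window_constraint' must be an integer")
    window_constraint <- as.integer(window_constraint)
  }
  structure(list(local_cost = local_cost,
                 window_constraint = window_constraint),
            class = "dtw_config")
}

#' @export
print.dtw_config <- function(x, ...) {
  cat(sprintf("DTW: %s local cost, symmetric steps, %s band, channel mean\n",
              x$local_cost,
              if (is.null(x$window_constraint)) "no"
              else sprintf("+/-%d", x$window_constraint)))
  invisible(x)
}

#' Dynamic time warping distance between two sequences
#'
#' Minimum cumulative local cost over all monotone, contiguous,
#' boundary-anchored warping paths between `x` and `y`, computed by dynamic
#' programming. Symmetric and non-negative, with `dtw_distance(x, x) == 0`;
#' note DTW is not a metric (no triangle inequality).
#'
#' @param x,y Non-empty finite numeric vectors.
#' @param config A [dtw_config()].
#' @return Non-negative scalar distance.
#' @examples
#' dtw_distance(c(1, 2, 3), c(1, 2, 2, 3))  # 0: the 2 is duplicated for free
#' @export
dtw_distance <- function(x, y, config = dtw_config()) {
  stopifnot(inherits(config, "dtw_config"))
  if (length(x) == 0 || length(y) == 0)
    stop_invalid("DTW requires non-empty sequences")
  if (!is.numeric(x) || !is.numeric(y) || any(!is.finite(x)) ||
      any(!is.finite(y)))
    stop_invalid("DTW requires finite numeric sequences")
  w <- config$window_constraint
  if (!is.null(w) && w < abs(length(x) - length(y)))
    stop_invalid("window constraint %d infeasible for lengths %d and %d",
                 w, length(x), length(y))
  dtw_dp(as.numeric(x), as.numeric(y), config$local_cost == "squared",
         if (is.null(w)) -1L else w)
}

#' Channel-averaged DTW distance between two multichannel series
#'
#' Arithmetic mean over channels of the univariate DTW distances between
#' corresponding channel pairs; each channel is warped independently.
#'
#' @param a,b `color_ts` objects with identical channel names.
#' @param config A [dtw_config()].
#' @return Non-negative scalar distance.
#' @export
multichannel_distance <- function(a, b, config = dtw_config()) {
  stopifnot(inherits(a, "color_ts"), inherits(b, "color_ts"))
  check_common_channels(a, b)
  d <- vapply(seq_along(a$channel_names), function(ch)
    dtw_distance(a$values[ch, ], b$values[ch, ], config), numeric(1))
  mean(d)
}

#' All-pairs channel-averaged DTW distance matrix
#'
#' @param dataset A `color_ts_list` with at least 2 series sharing channels.
#' @param config A [dtw_config()].
#' @return A symmetric matrix with zero diagonal, dimnames set to tube ids.
#' @export
distance_matrix <- function(dataset, config = dtw_config()) {
  n <- length(dataset)
  if (n < 2)
    stop_invalid("distance matrix needs >= 2 series")
  ids <- vapply(dataset, function(s) s$tube_id, character(1))
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      M[i, j] <- M[j, i] <- multichannel_distance(dataset[[i]], dataset[[j]],
                                                  config)
    }
  }
  M
}
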