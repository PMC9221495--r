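#' Experimental design of a kinetic recording campaign
#'
#' Describes which concentration levels are recorded, how many replicate
#' tubes each level gets, and the temporal sampling of each recording.
#'
#' @param levels Strictly increasing vector of non-negative concentrations.
#' @param replicates Positive integer vector of tube counts, recycled to
#'   `length(levels)`.
#' @param duration_s Recording duration in seconds (> 0).
#' @param frame_rate_hz Frames per second (> 0); `duration_s * frame_rate_hz`
#'   must be a positive integer (the number of time points).
#' @param channel_names Ordered channel labels.
#' @return An object of class `dataset_design`.
#' @seealso [default_design()] for the 62-tube reference design.
#' @export
dataset_design <- function(levels, replicates,
                           duration_s = 150, frame_rate_hz = 1,
                           channel_names = c("R", "G", "B")) {
  if (!is.numeric(levels) || length(levels) < 1L || any(!is.finite(levels)))
    stop_invalid("'levels' must be a non-empty finite numeric vector")
  if (any(levels < 0))
    stop_invalid("concentration levels must be non-negative")
  if (any(diff(levels) <= 0))
    stop_invalid("concentration levels must be strictly increasing")
  replicates <- rep_len(as.integer(replicates), length(levels))
  if (any(is.na(replicates)) || any(replicates < 1L))
    stop_invalid("replicate counts must be integers >= 1")
  check_number(duration_s, "duration_s", 0, strict = TRUE)
  check_number(frame_rate_hz, "frame_rate_hz", 0, strict = TRUE)
  n_t <- duration_s * frame_rate_hz
  if (abs(n_t - round(n_t)) > 1e-9 || round(n_t) < 1)
    stop_invalid("duration_s * frame_rate_hz must be a positive integer")
  if (!is.character(channel_names) || length(channel_names) < 1L ||
      anyDuplicated(channel_names))
    stop_invalid("'channel_names' must be distinct labels")
  structure(
    list(levels = as.numeric(levels),
         replicates = replicates,
         duration_s = duration_s,
         frame_rate_hz = frame_rate_hz,
         channel_names = channel_names),
    class = "dataset_design")
}

#' The 62-tube reference design
#'
#' The design used throughout: seven low levels (1.5, 3, 6.5, 17, 33, 45,
#' 65) totalling 22 tubes — three replicates per level plus one extra at 33 —
#' and four replicates at each of 100, 200, 350, 500, 600, 700, 900, 1000,
#' 1100 and 1200 (40 tubes), recorded for 150 s at 1 frame per second in
#' three colour channels. Concentrations are unit-agnostic labels (nominally
#' ppb).
#'
#' @return A [dataset_design()] with 62 tubes.
#' @export
default_design <- function() {
  low <- c(1.5, 3, 6.5, 17, 33, 45, 65)
  high <- c(100, 200, 350, 500, 600, 700, 900, 1000, 1100, 1200)
  reps <- c(ifelse(low == 33, 4L, 3L), rep(4L, length(high)))
  dataset_design(levels = c(low, high), replicates = reps)
}

#' @export
print.dataset_design <- function(x, ...) {
  cat(sprintf("Dataset design: %d tubes over %d levels\n",
              sum(x$replicates), length(x$levels)))
  cat(sprintf("  levels: %s\n", paste(x$levels, collapse = ", ")))
  cat(sprintf("  replicates: %s\n", paste(x$replicates, collapse = ", ")))
  cat(sprintf("  %g s at %g frames/s (%d time points), channels %s\n",
              x$duration_s, x$frame_rate_hz,
              as.integer(round(x$duration_s * x$frame_rate_hz)),
              paste(x$channel_names, collapse = "/")))
  invisible(x)
}

n_timepoints <- function(design) {
  as.integer(round(design$duration_s * design$frame_rate_hz))
}
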