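#' Rectangular region of interest
#'
#' Half-open pixel rectangle `[x0, x1) x [y0, y1)` in 0-based image
#' coordinates (x across columns, y down rows), matching the convention of
#' most imaging toolkits.
#'
#' @param x0,y0 Top-left corner (inclusive, 0-based).
#' @param x1,y1 Bottom-right corner (exclusive).
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(x0, y0, x1, y1) {
  for (v in list(x0, y0, x1, y1))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) ||
        v != round(v) || v < 0)
      stop_invalid("ROI coordinates must be non-negative integers")
  if (x0 >= x1 || y0 >= y1)
    stop_invalid("ROI must satisfy x0 < x1 and y0 < y1")
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0),
                 x1 = as.integer(x1), y1 = as.integer(y1)),
            class = "roi_spec")
}

check_roi_bounds <- function(roi, width, height) {
  if (roi$x1 > width || roi$y1 > height)
    stop_invalid("ROI [%d,%d)x[%d,%d) exceeds image bounds %dx%d",
                 roi$x0, roi$x1, roi$y0, roi$y1, width, height)
  invisible(TRUE)
}

#' Render a colour time series as PNG image frames
#'
#' Writes one RGB frame per timepoint: pixels inside the tube ROI carry the
#' series' channel intensities at that timepoint (plus optional pixel
#' noise), the background is a constant grey. A sidecar `frames.json`
#' records the frame rate, ROI and tube metadata. Intensities are quantised
#' to 8 bits by the PNG encoder, so a render/extract round trip is exact to
#' within half a quantisation step.
#'
#' @param series A `color_ts` with 3 channels.
#' @param dir Output directory (created if needed).
#' @param width,height Frame size in pixels.
#' @param roi A [roi_spec()] inside the frame.
#' @param background Background grey level in \[0, 1\].
#' @param pixel_noise_sd Per-pixel additive Gaussian noise sd (default 0).
#' @param seed Optional seed used when `pixel_noise_sd > 0`.
#' @return The directory path, invisibly.
#' @seealso [extract_series_from_frames()]
#' @export
render_frames <- function(series, dir, width = 64, height = 48,
                          roi = roi_spec(16, 12, 48, 36),
                          background = 0.5, pixel_noise_sd = 0, seed = NULL) {
  stopifnot(inherits(series, "color_ts"), inherits(roi, "roi_spec"))
  if (nrow(series$values) != 3L)
    stop_invalid("frame rendering needs a 3-channel (RGB) series")
  check_roi_bounds(roi, width, height)
  check_number(pixel_noise_sd, "pixel_noise_sd", 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- (roi$y0 + 1L):roi$y1
  cols <- (roi$x0 + 1L):roi$x1
  n_t <- ncol(series$values)
  for (ti in seq_len(n_t)) {
    img <- array(background, dim = c(height, width, 3L))
    for (ch in 1:3) {
      patch <- matrix(series$values[ch, ti], length(rows), length(cols))
      if (pixel_noise_sd > 0)
        patch <- patch + rnorm(length(patch), 0, pixel_noise_sd)
      img[rows, cols, ch] <- patch
    }
    img <- pmin(pmax(img, 0), 1)
    png::writePNG(img, file.path(dir, sprintf("frame_%05d.png", ti)))
  }
  meta <- list(frame_rate_hz = 1 / series$sampling_interval_s,
               roi = unclass(roi),
               tube_id = series$tube_id,
               true_concentration = series$true_concentration,
               channel_names = series$channel_names)
  jsonlite::write_json(meta, file.path(dir, "frames.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Extract a colour time series from a directory of image frames
#'
#' Frames are taken in lexicographic filename order (one timepoint per
#' frame); each channel value is the arithmetic mean of that channel over
#' the ROI pixels. PNG (via the png package) and TIFF (via the tiff
#' package, if installed) frames are supported; 8- and 16-bit images are
#' rescaled to \[0, 1\] by their decoders.
#'
#' @param frame_dir Directory containing the frames.
#' @param roi A [roi_spec()]; if `NULL`, read from a `frames.json` sidecar.
#' @param frame_rate_hz Frames per second; if `NULL`, read from the sidecar.
#' @return A `color_ts` with one timepoint per frame.
#' @export
extract_series_from_frames <- function(frame_dir, roi = NULL,
                                       frame_rate_hz = NULL) {
  if (!dir.exists(frame_dir))
    stop_invalid("frame directory not found: %s", frame_dir)
  sidecar <- file.path(frame_dir, "frames.json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else NULL
  if (is.null(roi)) {
    if (is.null(meta))
      stop_invalid("no ROI given and no frames.json sidecar in %s", frame_dir)
    roi <- roi_spec(meta$roi$x0, meta$roi$y0, meta$roi$x1, meta$roi$y1)
  }
  if (is.null(frame_rate_hz)) {
    if (is.null(meta))
      stop_invalid("no frame rate given and no frames.json sidecar in %s",
                   frame_dir)
    frame_rate_hz <- meta$frame_rate_hz
  }
  check_number(frame_rate_hz, "frame_rate_hz", 0, strict = TRUE)
  files <- list.files(frame_dir, pattern = "\\.(png|tif|tiff)$",
                      ignore.case = TRUE)
  if (length(files) == 0)
    stop_invalid("no readable image frames in %s", frame_dir)
  files <- sort(files)  # lexicographic order defines time
  dims <- NULL
  vals <- matrix(NA_real_, 3L, length(files))
  for (fi in seq_along(files)) {
    f <- file.path(frame_dir, files[fi])
    img <- tryCatch(read_frame(f), error = function(e)
      stop_invalid("cannot read frame '%s': %s", files[fi], conditionMessage(e)))
    if (length(dim(img)) == 2L)  # greyscale: replicate to 3 channels
      img <- array(img, dim = c(dim(img), 3L))
    if (is.null(dims)) {
      dims <- dim(img)
      check_roi_bounds(roi, width = dims[2], height = dims[1])
    } else if (!identical(dim(img)[1:2], dims[1:2])) {
      stop_invalid("frame '%s' has dimensions %dx%d, expected %dx%d",
                   files[fi], dim(img)[1], dim(img)[2], dims[1], dims[2])
    }
    rows <- (roi$y0 + 1L):roi$y1
    cols <- (roi$x0 + 1L):roi$x1
    for (ch in 1:3)
      vals[ch, fi] <- mean(img[rows, cols, min(ch, dim(img)[3])])
  }
  conc <- if (!is.null(meta$true_concentration) &&
              !is.null(unlist(meta$true_concentration)))
    as.numeric(meta$true_concentration) else NA_real_
  id <- if (!is.null(meta$tube_id)) as.character(meta$tube_id) else
    basename(frame_dir)
  color_ts(vals, 1 / frame_rate_hz, tube_id = id,
           true_concentration = conc, channel_names = c("R", "G", "B"))
}

read_frame <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE))
    return(png::readPNG(path))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required to read TIFF frames")
    return(tiff::readTIFF(path))
  }
  stop("unsupported image format")
}
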