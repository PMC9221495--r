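#' Generate a synthetic kinetic colour-trace dataset
#'
#' Simulates one multichannel recording per tube of the design. Each tube
#' draws a single lognormal amplitude factor (mean 1, coefficient of
#' variation `params$replicate_amplitude_cv`) that scales its noise-free
#' absorbance curve; channel intensities then receive independent additive
#' Gaussian noise of standard deviation `params$noise_sd` per sample and are
#' clipped to \[0, 1\]. Identical `(design, params, seed)` give bit-identical
#' output.
#'
#' @param design A [dataset_design()].
#' @param params A [kinetic_params()].
#' @param seed Integer seed (mandatory, for reproducibility).
#' @return A `color_ts_list` with `sum(design$replicates)` series, each with
#'   `duration_s * frame_rate_hz` timepoints per channel. Tube ids encode the
#'   level and replicate index.
#' @examples
#' ds <- generate_dataset(default_design(), kinetic_params(), seed = 1)
#' length(ds)  # 62
#' @export
generate_dataset <- function(design, params = kinetic_params(), seed) {
  stopifnot(inherits(design, "dataset_design"),
            inherits(params, "kinetic_params"))
  if (missing(seed))
    stop_invalid("'seed' is required for reproducible generation")
  check_number(seed, "seed")
  if (length(design$channel_names) != 3L)
    stop_invalid("the kinetic model renders 3 (RGB) channels; design has %d",
                 length(design$channel_names))

  n_t <- n_timepoints(design)
  dt <- 1 / design$frame_rate_hz
  time_grid <- seq(0, by = dt, length.out = n_t)
  cv <- params$replicate_amplitude_cv
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- -sdlog^2 / 2  # lognormal with mean exactly 1

  set.seed(as.integer(seed))
  out <- vector("list", sum(design$replicates))
  idx <- 0L
  for (li in seq_along(design$levels)) {
    conc <- design$levels[li]
    base_a <- kinetic_curve(conc, time_grid, params)
    for (ri in seq_len(design$replicates[li])) {
      m <- if (cv > 0) stats::rlnorm(1, meanlog, sdlog) else 1
      ch <- absorbance_to_channels(base_a * m, params)
      if (params$noise_sd > 0)
        ch <- ch + matrix(rnorm(length(ch), 0, params$noise_sd), nrow = 3L)
      ch <- pmin(pmax(ch, 0), 1)
      idx <- idx + 1L
      rownames(ch) <- design$channel_names
      out[[idx]] <- color_ts(ch, dt,
                             tube_id = sprintf("tube%02d_c%s_r%d", idx,
                                               format(conc), ri),
                             true_concentration = conc,
                             channel_names = design$channel_names)
    }
  }
  new_color_ts_list(out)
}
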