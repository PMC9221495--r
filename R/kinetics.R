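#' Kinetic model parameters for synthetic colour development
#'
#' Parameter set for the synthetic generator's model of nanozyme-catalysed
#' chromogenic colour development. The analyte (e.g. cisplatin converted to
#' catalytic platinum nanoparticles) drives oxidation of a chromogenic
#' substrate whose blue product absorbs red light, so the red camera channel
#' drops fastest as colour develops. The model has a saturating amplitude in
#' concentration and first-order development in time:
#'
#' \deqn{A(c, t) = A_{max} \frac{c}{c + c_{1/2}} (1 - e^{-k(c) t}),
#'       \quad k(c) = k_0 (c / c_{ref})^{\gamma}}
#'
#' Channel intensities follow a Beer-Lambert response,
#' \eqn{I_i = B_i \, 10^{-\epsilon_i A}}, with per-channel effective
#' extinction coefficients ordered red >= green >= blue.
#'
#' @param max_amplitude Absorbance ceiling \eqn{A_{max}} (dimensionless, > 0).
#' @param half_saturation_conc Concentration at which the plateau amplitude
#'   reaches half the ceiling (> 0, same units as the design grid).
#' @param rate_base First-order rate constant \eqn{k_0} (per second, > 0) at
#'   the reference concentration.
#' @param rate_conc_exponent Exponent \eqn{\gamma \ge 0} coupling the rate to
#'   concentration; 0 makes development speed concentration-independent.
#' @param conc_ref Reference concentration \eqn{c_{ref}} for the rate law
#'   (> 0); defaults to the largest concentration of the default design.
#' @param baseline_rgb Length-3 vector of channel intensities in \[0, 1\] for
#'   the analyte-free (transparent) solution.
#' @param channel_extinction Length-3 vector of per-channel effective
#'   extinction coefficients (>= 0), ordered red >= green >= blue.
#' @param noise_sd Standard deviation of per-sample additive Gaussian
#'   intensity noise (>= 0).
#' @param replicate_amplitude_cv Coefficient of variation of the lognormal
#'   tube-to-tube amplitude factor (>= 0).
#'
#' @return An object of class `kinetic_params`.
#' @seealso [kinetic_curve()], [absorbance_to_channels()],
#'   [generate_dataset()]
#' @examples
#' p <- kinetic_params()
#' kinetic_curve(100, 0:10, p)
#' @export
kinetic_params <- function(max_amplitude = 1.2,
                           half_saturation_conc = 150,
                           rate_base = 0.02,
                           rate_conc_exponent = 0.5,
                           conc_ref = 1200,
                           baseline_rgb = c(0.95, 0.96, 0.97),
                           channel_extinction = c(0.85, 0.45, 0.12),
                           noise_sd = 0.002,
                           replicate_amplitude_cv = 0.006) {
  check_number(max_amplitude, "max_amplitude", 0, strict = TRUE)
  check_number(half_saturation_conc, "half_saturation_conc", 0, strict = TRUE)
  check_number(rate_base, "rate_base", 0, strict = TRUE)
  check_number(rate_conc_exponent, "rate_conc_exponent", 0)
  check_number(conc_ref, "conc_ref", 0, strict = TRUE)
  check_number(noise_sd, "noise_sd", 0)
  check_number(replicate_amplitude_cv, "replicate_amplitude_cv", 0)
  if (length(baseline_rgb) != 3L || !is.numeric(baseline_rgb) ||
      any(!is.finite(baseline_rgb)) ||
      any(baseline_rgb < 0) || any(baseline_rgb > 1))
    stop_invalid("'baseline_rgb' must be 3 intensities in [0, 1]")
  if (length(channel_extinction) != 3L || !is.numeric(channel_extinction) ||
      any(!is.finite(channel_extinction)) || any(channel_extinction < 0))
    stop_invalid("'channel_extinction' must be 3 non-negative coefficients")
  if (is.unsorted(rev(channel_extinction)))
    stop_invalid(paste0("'channel_extinction' must be ordered red >= green ",
                        ">= blue (the oxidised product absorbs red light)"))
  structure(
    list(max_amplitude = max_amplitude,
         half_saturation_conc = half_saturation_conc,
         rate_base = rate_base,
         rate_conc_exponent = rate_conc_exponent,
         conc_ref = conc_ref,
         baseline_rgb = as.numeric(baseline_rgb),
         channel_extinction = as.numeric(channel_extinction),
         noise_sd = noise_sd,
         replicate_amplitude_cv = replicate_amplitude_cv),
    class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic model parameters\n")
  cat(sprintf("  amplitude: %.3g x c/(c + %.3g), rate k0 = %.3g /s, exponent %.3g (c_ref %.4g)\n",
              x$max_amplitude, x$half_saturation_conc, x$rate_base,
              x$rate_conc_exponent, x$conc_ref))
  cat(sprintf("  baseline RGB: (%.3g, %.3g, %.3g); extinction: (%.3g, %.3g, %.3g)\n",
              x$baseline_rgb[1], x$baseline_rgb[2], x$baseline_rgb[3],
              x$channel_extinction[1], x$channel_extinction[2],
              x$channel_extinction[3]))
  cat(sprintf("  noise sd %.3g, replicate amplitude CV %.3g\n",
              x$noise_sd, x$replicate_amplitude_cv))
  invisible(x)
}

#' Noise-free colour-development absorbance curve
#'
#' Evaluates the saturating-growth absorbance model
#' \eqn{A(c,t) = A_{max}\, c/(c + c_{1/2})\, (1 - e^{-k(c)t})} with
#' \eqn{k(c) = k_0 (c/c_{ref})^\gamma}. The curve is non-decreasing in time
#' and in concentration, and identically zero at zero concentration (no
#' catalyst, no colour).
#'
#' @param concentration Analyte concentration (>= 0, scalar).
#' @param time_grid Non-negative, non-decreasing vector of times (seconds).
#' @param params A [kinetic_params()] object.
#' @return Numeric vector of absorbances, one per time point.
#' @export
kinetic_curve <- function(concentration, time_grid, params = kinetic_params()) {
  stopifnot(inherits(params, "kinetic_params"))
  check_number(concentration, "concentration", 0)
  if (!is.numeric(time_grid) || length(time_grid) < 1L ||
      any(!is.finite(time_grid)))
    stop_invalid("'time_grid' must be a non-empty finite numeric vector")
  if (any(time_grid < 0))
    stop_invalid("'time_grid' must be non-negative")
  if (is.unsorted(time_grid))
    stop_invalid("'time_grid' must be non-decreasing")
  if (concentration == 0)
    return(numeric(length(time_grid)))
  amp <- params$max_amplitude * concentration /
    (concentration + params$half_saturation_conc)
  k <- params$rate_base * (concentration / params$conc_ref)^params$rate_conc_exponent
  amp * (1 - exp(-k * time_grid))
}

#' Map absorbance to RGB channel intensities
#'
#' Beer-Lambert response of each camera channel to the developed colour:
#' \eqn{I_i = B_i \, 10^{-\epsilon_i A}}. With the default extinction profile
#' the red channel falls fastest (the blue oxidation product absorbs around
#' 652 nm) and the blue channel barely moves.
#'
#' @param absorbance Non-negative absorbance vector.
#' @param params A [kinetic_params()] object.
#' @return A matrix with 3 rows (R, G, B) and one column per absorbance
#'   value; for a single absorbance, a named length-3 vector.
#' @export
absorbance_to_channels <- function(absorbance, params = kinetic_params()) {
  stopifnot(inherits(params, "kinetic_params"))
  if (!is.numeric(absorbance) || any(!is.finite(absorbance)))
    stop_invalid("'absorbance' must be finite numeric")
  if (any(absorbance < 0))
    stop_invalid("'absorbance' must be non-negative")
  out <- outer(params$channel_extinction, absorbance,
               function(e, a) 10^(-e * a))
  out <- out * params$baseline_rgb
  rownames(out) <- c("R", "G", "B")
  if (length(absorbance) == 1L) setNames(drop(out), c("R", "G", "B")) else out
}
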