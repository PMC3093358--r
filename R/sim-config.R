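#' Simulation configuration for synthetic worm locomotion
#'
#' Parameterizes the synthetic undulatory-locomotion generator: a sinusoidal
#' body wave travelling head-to-tail during forward movement (tail-to-head
#' during reversals), interrupted by scripted omega turns in which the head
#' curls back to within one body width of the posterior body and the heading
#' reorients by 120-180 degrees. Omega-turn and reversal onsets are
#' independent Poisson processes.
#'
#' Kinematic defaults are typical adult C. elegans crawling values: 1.0 mm
#' body, 0.6 rad wave amplitude, 0.9 body-length wavelength, 0.5 Hz wave
#' frequency, 0.15 mm/s forward speed.
#'
#' @param duration_s recording duration (seconds).
#' @param frame_rate_hz sampling rate (frames/s), default 30.
#' @param body_length_mm worm body length (mm).
#' @param n_midline_points number of midline points K (>= 10), default 50.
#' @param wave_amplitude_rad amplitude of the tangent-angle wave (radians).
#' @param wave_wavelength_bodylengths wavelength in body lengths.
#' @param wave_frequency_hz undulation frequency (Hz).
#' @param forward_speed_mm_s crawling speed (mm/s).
#' @param omega_rate_per_s Poisson rate of omega-turn onsets (events/s).
#' @param omega_duration_s scripted omega-turn duration (seconds).
#' @param reversal_rate_per_s Poisson rate of reversal onsets (events/s).
#' @param reversal_duration_s reversal bout duration (seconds).
#' @param rng_seed integer seed; identical config + seed gives bit-identical
#'   output.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(duration_s = 10, omega_rate_per_s = 0)
#' @export
sim_config <- function(duration_s = 60,
                       frame_rate_hz = 30,
                       body_length_mm = 1.0,
                       n_midline_points = 50L,
                       wave_amplitude_rad = 0.6,
                       wave_wavelength_bodylengths = 0.9,
                       wave_frequency_hz = 0.5,
                       forward_speed_mm_s = 0.15,
                       omega_rate_per_s = 0.03,
                       omega_duration_s = 1.5,
                       reversal_rate_per_s = 0.02,
                       reversal_duration_s = 3,
                       rng_seed = 1L) {
  stop_if_not_scalar_number(duration_s, "duration_s", allow_zero = FALSE)
  stop_if_not_scalar_number(frame_rate_hz, "frame_rate_hz", allow_zero = FALSE)
  stop_if_not_scalar_number(body_length_mm, "body_length_mm",
                            allow_zero = FALSE)
  stop_if_not_scalar_number(wave_amplitude_rad, "wave_amplitude_rad")
  stop_if_not_scalar_number(wave_wavelength_bodylengths,
                            "wave_wavelength_bodylengths", allow_zero = FALSE)
  stop_if_not_scalar_number(wave_frequency_hz, "wave_frequency_hz")
  stop_if_not_scalar_number(forward_speed_mm_s, "forward_speed_mm_s")
  stop_if_not_scalar_number(omega_rate_per_s, "omega_rate_per_s")
  stop_if_not_scalar_number(omega_duration_s, "omega_duration_s",
                            allow_zero = FALSE)
  stop_if_not_scalar_number(reversal_rate_per_s, "reversal_rate_per_s")
  stop_if_not_scalar_number(reversal_duration_s, "reversal_duration_s",
                            allow_zero = FALSE)
  if (!is.numeric(n_midline_points) || length(n_midline_points) != 1L ||
      is.na(n_midline_points) || n_midline_points < 10) {
    stop("'n_midline_points' must be a single integer >= 10", call. = FALSE)
  }
  if (!is.numeric(rng_seed) || length(rng_seed) != 1L || is.na(rng_seed)) {
    stop("'rng_seed' must be a single integer", call. = FALSE)
  }
  structure(list(duration_s = duration_s,
                 frame_rate_hz = frame_rate_hz,
                 body_length_mm = body_length_mm,
                 n_midline_points = as.integer(n_midline_points),
                 wave_amplitude_rad = wave_amplitude_rad,
                 wave_wavelength_bodylengths = wave_wavelength_bodylengths,
                 wave_frequency_hz = wave_frequency_hz,
                 forward_speed_mm_s = forward_speed_mm_s,
                 omega_rate_per_s = omega_rate_per_s,
                 omega_duration_s = omega_duration_s,
                 reversal_rate_per_s = reversal_rate_per_s,
                 reversal_duration_s = reversal_duration_s,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Worm simulation config:", x$duration_s, "s at", x$frame_rate_hz,
      "fps;", x$n_midline_points, "midline points\n")
  cat("  body", x$body_length_mm, "mm; wave A =", x$wave_amplitude_rad,
      "rad, lambda =", x$wave_wavelength_bodylengths, "BL, f =",
      x$wave_frequency_hz, "Hz; speed", x$forward_speed_mm_s, "mm/s\n")
  cat("  omega rate", x$omega_rate_per_s, "/s (", x$omega_duration_s,
      "s ); reversal rate", x$reversal_rate_per_s, "/s (",
      x$reversal_duration_s, "s ); seed", x$rng_seed, "\n")
  invisible(x)
}
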