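#' Simulate a ground-truth-labeled worm posture sequence
#'
#' Generates per-frame midlines (head to tail, mm) for a single worm crawling
#' with a sinusoidal body wave, interrupted by Poisson-timed reversals (the
#' wave direction flips tail-to-head) and scripted omega turns (a large
#' transient body bend that brings the head to within one body width of the
#' posterior body and reorients the heading by 120-180 degrees). Every frame
#' carries a ground-truth state label.
#'
#' The body tangent angle is \eqn{\theta(s,t) = heading(t) + \pi +
#' (1-B(t)) A \sin(2\pi(s/\lambda - \phi(t))) - B(t)\,\Phi\,(s - 1/2)} where
#' \eqn{s \in [0,1]} is the body coordinate (0 = head), \eqn{\phi} advances
#' at +f during forward movement and -f during reversals, and \eqn{B(t)} is
#' a trapezoidal omega-bend envelope (0 outside omega turns). Midline points
#' are obtained by integrating the tangent at K-1 equal arc-length steps, so
#' arc length is conserved exactly.
#'
#' Omega and reversal onsets are drawn as independent Poisson processes; the
#' raw onset lists are stored in the result (`omega_onsets_s`,
#' `reversal_onsets_s`), so inter-onset intervals are exactly exponential
#' with means `1/omega_rate_per_s` and `1/reversal_rate_per_s`. In the frame
#' labels, overlapping events merge and omega turns take precedence over
#' (truncate) reversals.
#'
#' @param config a [sim_config()] object.
#' @param compute_midlines if `FALSE`, skip midline construction and return
#'   only times, labels and onsets (cheap, for event-statistics studies).
#' @return An object of class `posture_sequence`: a list with `times`
#'   (seconds), `midlines` (list of K x 2 matrices, mm, head first),
#'   `true_state` (character, FORWARD/BACKWARD/OMEGA), `omega_onsets_s`,
#'   `reversal_onsets_s`, `heading_rad`, and `config`.
#' @examples
#' ps <- simulate_posture_sequence(sim_config(duration_s = 5,
#'                                            omega_rate_per_s = 0,
#'                                            reversal_rate_per_s = 0))
#' range(ps$times)
#' @export
simulate_posture_sequence <- function(config, compute_midlines = TRUE) {
  if (!inherits(config, "sim_config")) {
    stop("'config' must be a sim_config object", call. = FALSE)
  }
  fps <- config$frame_rate_hz
  n <- max(1L, as.integer(round(config$duration_s * fps)))
  times <- (seq_len(n) - 1) / fps
  dt <- 1 / fps
  K <- config$n_midline_points

  sim <- with_seed(config$rng_seed, {
    om <- poisson_onsets(config$omega_rate_per_s, config$duration_s)
    rev <- poisson_onsets(config$reversal_rate_per_s, config$duration_s)
    h0 <- stats::runif(1, 0, 2 * pi)
    dh <- if (length(om)) {
      sample(c(-1, 1), length(om), replace = TRUE) *
        stats::runif(length(om), 120, 180) * pi / 180
    } else numeric(0)
    list(om = om, rev = rev, h0 = h0, dh = dh)
  })

  # per-frame labels: FORWARD baseline; reversals; omega overrides
  state <- rep("FORWARD", n)
  for (on in sim$rev) {
    idx <- which(times >= on & times < on + config$reversal_duration_s)
    state[idx] <- "BACKWARD"
  }
  omega_frame <- rep(FALSE, n)
  p <- rep(0, n)            # progress through the current omega event
  for (on in sim$om) {
    idx <- which(times >= on & times < on + config$omega_duration_s)
    omega_frame[idx] <- TRUE
    p[idx] <- (times[idx] - on) / config$omega_duration_s
  }
  state[omega_frame] <- "OMEGA"

  # trapezoidal bend envelope: 15% rise, 70% plateau, 15% fall
  B <- rep(0, n)
  B[omega_frame] <- pmin(1, pmin(p[omega_frame], 1 - p[omega_frame]) / 0.15)

  # heading: baseline + per-event linear reorientation ramps
  heading <- rep(sim$h0, n)
  if (length(sim$om)) {
    for (e in seq_along(sim$om)) {
      ramp <- pmin(1, pmax(0, (times - sim$om[e]) / config$omega_duration_s))
      heading <- heading + sim$dh[e] * ramp
    }
  }

  # wave phase: advances forward, retreats during reversals, keeps advancing
  # through omega turns (the residual wave is suppressed by B anyway)
  dir <- ifelse(state == "BACKWARD", -1, 1)
  phase <- cumsum(dir * config$wave_frequency_hz * dt) -
    dir[1] * config$wave_frequency_hz * dt

  # centroid path: forward speed, reversed during backward bouts, scaled
  # down by the bend envelope during omega turns
  speed <- config$forward_speed_mm_s * dir * (1 - B)
  cx <- cumsum(c(0, (speed * cos(heading) * dt)[-n]))
  cy <- cumsum(c(0, (speed * sin(heading) * dt)[-n]))

  midlines <- NULL
  if (compute_midlines) {
    L <- config$body_length_mm
    ds <- 1 / (K - 1)
    m_mid <- (seq_len(K - 1) - 0.5) * ds      # segment midpoint body coords
    A <- config$wave_amplitude_rad
    lambda <- config$wave_wavelength_bodylengths
    Phi <- 1.05 * 2 * pi                      # total omega bend (rad)
    # n x (K-1) tangent angles
    theta <- (heading + pi) +
      (1 - B) * A * sin(2 * pi * (outer(rep(1, n), m_mid) / lambda -
                                    phase)) -
      B * Phi * outer(rep(1, n), m_mid - 0.5)
    segx <- L * ds * cos(theta)
    segy <- L * ds * sin(theta)
    X <- matrix(0, n, K)
    Y <- matrix(0, n, K)
    for (j in seq_len(K - 1)) {
      X[, j + 1] <- X[, j] + segx[, j]
      Y[, j + 1] <- Y[, j] + segy[, j]
    }
    X <- X - rowMeans(X) + cx
    Y <- Y - rowMeans(Y) + cy
    midlines <- lapply(seq_len(n), function(i) cbind(x = X[i, ], y = Y[i, ]))
  }

  structure(list(times = times,
                 midlines = midlines,
                 true_state = state,
                 omega_onsets_s = sim$om,
                 reversal_onsets_s = sim$rev,
                 heading_rad = heading,
                 config = config),
            class = "posture_sequence")
}

#' @export
print.posture_sequence <- function(x, ...) {
  cat("Posture sequence:", length(x$times), "frames (",
      round(max(x$times), 1), "s at", x$config$frame_rate_hz, "fps)\n")
  tab <- table(x$true_state)
  cat("  states:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  omega onsets:", length(x$omega_onsets_s),
      " reversal onsets:", length(x$reversal_onsets_s), "\n")
  invisible(x)
}

#' Restrict a posture sequence to a subset of frames
#'
#' Used to process long recordings in blocks (e.g. rasterize and analyze a
#' window at a time) without materializing the full frame stack.
#'
#' @param posture a `posture_sequence`.
#' @param idx integer frame indices (increasing).
#' @return A `posture_sequence` covering only the selected frames; onset
#'   lists are kept unchanged.
#' @export
posture_subset <- function(posture, idx) {
  stopifnot(inherits(posture, "posture_sequence"))
  out <- posture
  out$times <- posture$times[idx]
  if (!is.null(posture$midlines)) out$midlines <- posture$midlines[idx]
  out$true_state <- posture$true_state[idx]
  out$heading_rad <- posture$heading_rad[idx]
  out
}
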