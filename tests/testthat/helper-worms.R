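# Shared fixtures and small oracles, all built in code.

# Wrap ground-truth simulator midlines as valid wk_midline objects.
as_wk_midlines <- function(posture) {
  out <- lapply(posture$midlines, function(p) {
    structure(list(points = p, valid = TRUE, failure_reason = "none",
                   length_mm = sum(sqrt(rowSums(diff(p)^2)))),
              class = "wk_midline")
  })
  attr(out, "times") <- posture$times
  out
}

# Event-level matching of detected onsets to true onsets at a time
# tolerance; returns precision, recall, F1.
event_f1 <- function(true_onsets, det_onsets, tol_s = 0.5) {
  used <- rep(FALSE, length(det_onsets))
  matched <- 0L
  for (o in true_onsets) {
    j <- which(!used & abs(det_onsets - o) <= tol_s)
    if (length(j)) {
      matched <- matched + 1L
      used[j[1]] <- TRUE
    }
  }
  precision <- if (length(det_onsets)) matched / length(det_onsets) else 0
  recall <- if (length(true_onsets)) matched / length(true_onsets) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(precision = precision, recall = recall, f1 = f1)
}

# Monte-Carlo oracle: sampling distribution of the mean of `n_gaps`
# exponential gaps with the given mean. Returns the 95% interval.
mc_mean_gap_ci <- function(mean_gap, n_gaps, reps = 4000, seed = 99) {
  withr::with_seed(seed, {
    means <- replicate(reps, mean(rexp(n_gaps, 1 / mean_gap)))
  })
  stats::quantile(means, c(0.025, 0.975))
}

# Monte-Carlo oracle: 95% interval of the grand mean of per-animal mean
# inter-onset gaps for `n_animals` Poisson processes (direct simulation of
# exponential gaps, vectorized: onset_k = sum of k gaps).
mc_grand_mean_ci <- function(rate, window_s, n_animals, reps = 10000,
                             seed = 77) {
  withr::with_seed(seed, {
    n <- reps * n_animals
    max_ev <- stats::qpois(1 - 1e-9, rate * window_s) + 10L
    gaps <- matrix(rexp(n * max_ev, rate), n, max_ev)
    onsets <- gaps %*% upper.tri(diag(max_ev), diag = TRUE)
    inside <- onsets <= window_s
    k <- rowSums(inside)
    first <- onsets[, 1]
    last <- onsets[cbind(seq_len(n), pmax(k, 1L))]
    animal_mean <- ifelse(k >= 2L, (last - first) / (k - 1L), NA_real_)
    gm <- rowMeans(matrix(animal_mean, reps, n_animals), na.rm = TRUE)
    stats::quantile(gm, c(0.025, 0.975))
  })
}

# Analytic curvature field (degrees per segment) of the simulator's sine
# gait, evaluated at the interior junctions, given the per-frame phase.
analytic_sine_map <- function(cfg, phase) {
  K <- cfg$n_midline_points
  ds <- 1 / (K - 1)
  s_j <- (1:(K - 2)) / (K - 1)
  A <- cfg$wave_amplitude_rad
  lam <- cfg$wave_wavelength_bodylengths
  vals <- sapply(s_j, function(s) {
    A * 2 * pi * ds / lam * cos(2 * pi * (s / lam - phase))
  })
  vals * 180 / pi
}

# Forward-gait phase sequence matching the simulator (phase starts at 0).
forward_phase <- function(cfg, n_frames) {
  f <- cfg$wave_frequency_hz
  dt <- 1 / cfg$frame_rate_hz
  cumsum(rep(f * dt, n_frames)) - f * dt
}

# Frames within tol_s of any ground-truth state boundary.
near_boundaries <- function(true_state, times, tol_s = 0.5) {
  r <- rle(true_state)
  bnd <- cumsum(r$lengths)
  bnd <- bnd[-length(bnd)]
  near <- rep(FALSE, length(true_state))
  dt <- stats::median(diff(times))
  w <- round(tol_s / dt)
  for (b in bnd) {
    near[max(1, b - w):min(length(true_state), b + w)] <- TRUE
  }
  near
}
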