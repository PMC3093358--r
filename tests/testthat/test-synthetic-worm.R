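test_that("config validation rejects bad kinematic parameters", {
  expect_error(sim_config(duration_s = -1), "duration_s")
  expect_error(sim_config(frame_rate_hz = 0), "frame_rate_hz")
  expect_error(sim_config(omega_rate_per_s = -0.1), "omega_rate_per_s")
  expect_error(sim_config(wave_amplitude_rad = NaN), "wave_amplitude_rad")
  expect_error(sim_config(n_midline_points = 5), "n_midline_points")
})

test_that("event-free simulation is pure forward crawling with net motion", {
  cfg <- sim_config(duration_s = 60, omega_rate_per_s = 0,
                    reversal_rate_per_s = 0, rng_seed = 1)
  ps <- simulate_posture_sequence(cfg)
  expect_true(all(ps$true_state == "FORWARD"))
  d0 <- colMeans(ps$midlines[[1]])
  d1 <- colMeans(ps$midlines[[length(ps$midlines)]])
  disp <- sqrt(sum((d1 - d0)^2))
  expect_gt(disp, 0)
  expect_equal(disp, cfg$forward_speed_mm_s * cfg$duration_s,
               tolerance = 0.05)
})

test_that("midlines have exact arc length and equal point spacing", {
  cfg <- sim_config(duration_s = 20, rng_seed = 3)
  ps <- simulate_posture_sequence(cfg)
  lens <- vapply(ps$midlines, function(p)
    sum(sqrt(rowSums(diff(p)^2))), 0)
  # inextensible worm: arc length conserved (well under the 1% contract)
  expect_lt(diff(range(lens)) / mean(lens), 1e-9)
  expect_equal(mean(lens), cfg$body_length_mm, tolerance = 1e-12)
  sp <- sqrt(rowSums(diff(ps$midlines[[7]])^2))
  expect_lt((max(sp) - min(sp)) / mean(sp), 1e-6)
  expect_true(all(vapply(ps$midlines, nrow, 0L) == cfg$n_midline_points))
})

test_that("identical config and seed reproduce the sequence bit-exactly", {
  cfg <- sim_config(duration_s = 30, rng_seed = 7)
  a <- simulate_posture_sequence(cfg)
  b <- simulate_posture_sequence(cfg)
  expect_identical(a$midlines, b$midlines)
  expect_identical(a$true_state, b$true_state)
  expect_identical(a$omega_onsets_s, b$omega_onsets_s)
})

test_that("omega onsets follow the configured Poisson process", {
  # empirical mean inter-onset interval within the 95% CI of an
  # exponential-sampling oracle at the same n
  cfg <- sim_config(duration_s = 1000, omega_rate_per_s = 0.03,
                    reversal_rate_per_s = 0, rng_seed = 1)
  ps <- simulate_posture_sequence(cfg, compute_midlines = FALSE)
  gaps <- diff(ps$omega_onsets_s)
  expect_gt(length(gaps), 5)
  ci <- mc_mean_gap_ci(1 / 0.03, length(gaps))
  expect_gt(mean(gaps), ci[1])
  expect_lt(mean(gaps), ci[2])

  # Poisson event-count bound over several seeds
  for (seed in 1:4) {
    cfg2 <- sim_config(duration_s = 500, omega_rate_per_s = 0.04,
                       rng_seed = seed)
    n_ev <- length(simulate_posture_sequence(
      cfg2, compute_midlines = FALSE)$omega_onsets_s)
    expect_lt(abs(n_ev - 0.04 * 500), 3 * sqrt(0.04 * 500) + 1)
  }
})

test_that("the scripted omega pose brings the head to the posterior body", {
  cfg <- sim_config(duration_s = 120, omega_rate_per_s = 0.05,
                    reversal_rate_per_s = 0, rng_seed = 5)
  ps <- simulate_posture_sequence(cfg)
  bw <- cfg$body_length_mm / 12
  for (on in ps$omega_onsets_s[1:2]) {
    mid <- which.min(abs(ps$times - (on + cfg$omega_duration_s / 2)))
    p <- ps$midlines[[mid]]
    head_pt <- p[1, ]
    posterior <- p[round(nrow(p) * 0.4):nrow(p), ]
    d <- min(sqrt(rowSums(sweep(posterior, 2, head_pt)^2)))
    expect_lt(d, bw)
    # heading reorientation of 120-180 degrees across the event
    pre <- which.min(abs(ps$times - (on - 0.1)))
    post <- which.min(abs(ps$times - (on + cfg$omega_duration_s + 0.1)))
    dh <- abs(wormkymo:::wrap_angle(ps$heading_rad[post] -
                                      ps$heading_rad[pre]))
    expect_gte(dh, 119 * pi / 180)
    expect_lte(dh, 181 * pi / 180)
  }
})

test_that("rasterized frames draw a worm-sized tube with stable area", {
  cfg <- sim_config(duration_s = 2, wave_amplitude_rad = 0,
                    omega_rate_per_s = 0, reversal_rate_per_s = 0,
                    rng_seed = 2)
  ps <- simulate_posture_sequence(cfg)
  px <- 0.02
  fs <- rasterize(ps, pixel_size_mm = px, image_shape = c(96, 96))
  f <- fs$frames[[1]]
  expect_true(all(f >= 0 & f <= 1))
  # straight worm: major-axis extent close to body length in pixels
  fg <- which(f > 0.5, arr.ind = TRUE)
  ext <- max(stats::dist(fg))
  expect_lt(abs(ext - cfg$body_length_mm / px), 2)

  # areas of binarized frames stable and near the analytic tube area
  areas <- vapply(fs$frames, function(fr) sum(fr > 0.5), 0)
  expect_lt((max(areas) - min(areas)) / mean(areas), 0.05)
  w_max <- cfg$body_length_mm / 12
  analytic <- w_max * cfg$body_length_mm * (0.4 + 0.6 * 2 / pi) / px^2
  expect_lt(abs(mean(areas) - analytic) / analytic, 0.05)
})

test_that("rasterize rejects empty input and out-of-frame worms", {
  cfg <- sim_config(duration_s = 5, omega_rate_per_s = 0,
                    reversal_rate_per_s = 0, rng_seed = 1)
  ps <- simulate_posture_sequence(cfg)
  expect_error(rasterize(ps, frames = integer(0)), "no frames")
  expect_error(rasterize(ps, pixel_size_mm = 0), "pixel_size_mm")
  # without re-centering the worm eventually leaves a small frame
  cfg2 <- sim_config(duration_s = 60, omega_rate_per_s = 0,
                     reversal_rate_per_s = 0, rng_seed = 1)
  ps2 <- simulate_posture_sequence(cfg2)
  expect_error(rasterize(ps2, image_shape = c(128, 128), center = FALSE),
               "frame [0-9]+")
})

test_that("plate-track archetypes behave as designed", {
  tr <- simulate_plate_track("thermotaxis",
                             list(archetype = "stay-center"), seed = 3)
  r <- sqrt(tr$x_mm^2 + tr$y_mm^2)
  zone17_r <- 1.5 / 8 * tr$plate_radius_mm
  expect_gte(mean(r < zone17_r), 0.9)

  still <- simulate_plate_track("thermotaxis",
                                list(archetype = "stay-center",
                                     speed_mm_s = 0, duration_s = 100),
                                seed = 1)
  expect_true(all(still$x_mm == still$x_mm[1]))
  expect_true(all(still$y_mm == still$y_mm[1]))

  a <- simulate_plate_track("nacl", list(archetype = "wander-both"),
                            seed = 9)
  b <- simulate_plate_track("nacl", list(archetype = "wander-both"),
                            seed = 9)
  expect_identical(a$x_mm, b$x_mm)
  expect_error(simulate_plate_track("thermotaxis",
                                    list(archetype = "moonwalk"), seed = 1),
               "unknown archetype")
  expect_true(all(sqrt(a$x_mm^2 + a$y_mm^2) <= a$plate_radius_mm + 1e-9))
})

test_that("ratio-trace generator injects exact, seeded responses", {
  flat <- simulate_ratio_traces(1, response_percent = 0, noise_snr = Inf,
                                seed = 1)[[1]]
  expect_equal(diff(range(flat$f535 / flat$f480)), 0)
  expect_identical(attr(flat, "true_peak_pct"), 0)

  tr <- simulate_ratio_traces(1, response_percent = 20, noise_snr = Inf,
                              seed = 1)[[1]]
  rc <- ratio_change(tr)
  expect_equal(max(rc$ratio_change_pct), 20)

  a <- simulate_ratio_traces(3, 17, noise_snr = 20, seed = 4)
  b <- simulate_ratio_traces(3, 17, noise_snr = 20, seed = 4)
  expect_identical(a[[2]]$f535, b[[2]]$f535)
  expect_error(simulate_ratio_traces(2, 17, noise_snr = -1), "noise_snr")
  expect_error(simulate_ratio_traces(2, 17, bleach_rate = -1),
               "bleach_rate")
})
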