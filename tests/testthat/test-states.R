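invalid_ml <- function() {
  structure(list(points = NULL, valid = FALSE,
                 failure_reason = "self_contact", length_mm = NA_real_),
            class = "wk_midline")
}

forward_midlines <- function(duration_s = 4, seed = 1) {
  cfg <- sim_config(duration_s = duration_s, omega_rate_per_s = 0,
                    reversal_rate_per_s = 0, rng_seed = seed)
  ps <- simulate_posture_sequence(cfg)
  list(ps = ps, mls = as_wk_midlines(ps))
}

test_that("omega detection honors merge and minimum-duration contracts", {
  w <- forward_midlines()
  n <- length(w$mls)
  expect_false(any(detect_omega(w$mls, times = w$ps$times)))

  # a single pose held 1 s is exactly one event
  held <- w$mls
  for (i in 31:60) held[[i]] <- invalid_ml()
  om <- detect_omega(held, times = w$ps$times)
  expect_identical(nrow(attr(om, "events")), 1L)
  expect_equal(attr(om, "events")$onset_s, w$ps$times[31])

  # two candidate runs separated by < 0.3 s merge into one event
  gappy <- w$mls
  for (i in c(31:40, 46:55)) gappy[[i]] <- invalid_ml()
  expect_identical(nrow(attr(detect_omega(gappy, w$ps$times), "events")),
                   1L)

  # a blip shorter than 0.2 s is discarded
  blip <- w$mls
  for (i in 31:34) blip[[i]] <- invalid_ml()
  expect_identical(nrow(attr(detect_omega(blip, w$ps$times), "events")),
                   0L)
})

test_that("direction classification reads the wave propagation sign", {
  w <- forward_midlines(duration_s = 10, seed = 2)
  map <- build_map(w$mls, times = w$ps$times)
  lab <- classify_direction(map)
  inner <- seq(16, length(lab) - 15)
  expect_gte(mean(lab[inner] == "FORWARD"), 0.95)

  # time-reversed recording swaps FORWARD and BACKWARD
  map_rev <- build_map(rev(w$mls), times = w$ps$times)
  lab_rev <- classify_direction(map_rev)
  expect_gte(mean(lab_rev[inner] == "BACKWARD"), 0.95)

  # a frozen (zero-wave) posture is unclassifiable
  frozen <- w$mls
  for (i in seq_along(frozen)) frozen[[i]] <- frozen[[1]]
  lab0 <- classify_direction(build_map(frozen, times = w$ps$times))
  expect_true(all(lab0 == "UNKNOWN"))

  expect_error(classify_direction(map, window_s = 0.01), "window")
})

test_that("short direction blips are absorbed, never emitted as intervals", {
  labels <- rep("FORWARD", 120)
  labels[50:54] <- "BACKWARD"   # 5 frames < 15-frame persistence at 30 fps
  out <- wormkymo:::absorb_short_runs(labels, min_len = 15L)
  expect_true(all(out == "FORWARD"))
  labels[70:100] <- "BACKWARD"  # a real reversal survives
  out2 <- wormkymo:::absorb_short_runs(labels, min_len = 15L)
  expect_true(all(out2[70:100] == "BACKWARD"))
  expect_true(all(out2[1:49] == "FORWARD"))
})

test_that("state labels partition frames and agree with the map mask", {
  cfg <- sim_config(duration_s = 60, omega_rate_per_s = 0.05,
                    reversal_rate_per_s = 0.03, rng_seed = 4)
  ps <- simulate_posture_sequence(cfg)
  st <- segment_states(ps)
  expect_length(st$labels, length(ps$times))
  expect_true(all(st$labels %in%
                    c("FORWARD", "BACKWARD", "OMEGA", "UNKNOWN")))
  # intervals partition the recording
  iv <- st$intervals
  expect_equal(sum(vapply(seq_len(nrow(iv)), function(i) {
    sum(st$times >= iv$start_s[i] & st$times < iv$end_s[i])
  }, 0)), length(st$labels))
  # OMEGA frames coincide exactly with the curvature-map mask
  expect_identical(st$labels == "OMEGA", unname(st$map$mask[, 1]))
})

test_that("inter-omega durations are onset-to-onset within the window", {
  ts <- turn_statistics(c(100, 300, 600))
  expect_equal(ts$inter_omega_durations_s, c(200, 300))
  expect_equal(ts$mean_s, 250)

  # onsets beyond the analysis window are excluded
  ts2 <- turn_statistics(c(100, 300, 600, 1400), window_s = 1000)
  expect_identical(ts2$n_events, 3L)

  none <- turn_statistics(numeric(0))
  expect_length(none$inter_omega_durations_s, 0)
  expect_true(is.na(none$mean_s))
  one <- turn_statistics(c(42))
  expect_true(is.na(one$mean_s))
  expect_length(one$inter_omega_durations_s, 0)
})

test_that("group turn statistics average per-animal means", {
  stats_list <- list(turn_statistics(c(0, 100, 200)),     # mean 100
                     turn_statistics(c(0, 300)),          # mean 300
                     turn_statistics(c(500)))             # undefined
  g <- turn_statistics_group(stats_list)
  expect_identical(g$n_animals, 2L)
  expect_equal(g$grand_mean_s, 200)
  expect_equal(g$sem_s, stats::sd(c(100, 300)) / sqrt(2))
})

test_that("simulated Poisson turning reproduces the configured mean gap", {
  stats_list <- lapply(1:8, function(seed) {
    cfg <- sim_config(duration_s = 1000, omega_rate_per_s = 0.03,
                      reversal_rate_per_s = 0, rng_seed = 100 + seed)
    ps <- simulate_posture_sequence(cfg, compute_midlines = FALSE)
    turn_statistics(ps$omega_onsets_s, window_s = 1000)
  })
  g <- turn_statistics_group(stats_list)
  ci <- mc_grand_mean_ci(0.03, 1000, 8, reps = 3000)
  expect_gt(g$grand_mean_s, ci[1])
  expect_lt(g$grand_mean_s, ci[2])
})
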