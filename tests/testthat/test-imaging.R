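test_that("ratio change is zero-mean over baseline and exact by design", {
  tr <- simulate_ratio_traces(1, response_percent = 17, seed = 1)[[1]]
  rc <- ratio_change(tr)
  bw <- attr(rc, "baseline_window_s")
  bl <- rc$time_s >= bw[1] & rc$time_s < bw[2]
  expect_equal(mean(rc$ratio_change_pct[bl]), 0, tolerance = 1e-12)
  expect_equal(max_ratio_change(rc), 17)
  # constant channels: identically zero
  const <- structure(list(time_s = 0:60, f535 = rep(3, 61),
                          f480 = rep(2, 61)), class = "ratio_trace")
  expect_true(all(ratio_change(const)$ratio_change_pct == 0))
})

test_that("a common multiplicative factor cancels exactly in the ratio", {
  tr <- simulate_ratio_traces(1, response_percent = 23, seed = 2)[[1]]
  rc <- ratio_change(tr)
  bleach <- exp(-0.013 * tr$time_s) * 1.7
  scaled <- structure(list(time_s = tr$time_s, f535 = tr$f535 * bleach,
                           f480 = tr$f480 * bleach,
                           temperature_c = tr$temperature_c),
                      class = "ratio_trace",
                      onset_s = attr(tr, "onset_s"))
  rc2 <- ratio_change(scaled)
  expect_equal(rc2$ratio_change_pct, rc$ratio_change_pct,
               tolerance = 1e-12)
  # bleach detrending also leaves the noiseless response intact
  rc3 <- ratio_change(scaled, detrend = TRUE)
  expect_equal(max_ratio_change(rc3), 23, tolerance = 0.2)
})

test_that("ratio-change guards reject degenerate inputs", {
  tr <- simulate_ratio_traces(1, seed = 1)[[1]]
  expect_error(ratio_change(tr, baseline_window_s = c(500, 510)), "empty")
  bad <- tr
  bad$f480[3] <- -1
  expect_error(ratio_change(bad, baseline_window_s = c(0, 5)),
               "non-positive")
})

test_that("extrema support excitatory, inhibitory and absolute modes", {
  inh <- simulate_ratio_traces(1, response_percent = -12, seed = 3)[[1]]
  rc <- ratio_change(inh)
  expect_equal(max_ratio_change(rc, direction = "min"), -12)
  expect_equal(max_ratio_change(rc, direction = "abs"), -12)
  expect_lt(max_ratio_change(rc), abs(-12))
})

test_that("group summaries give pointwise SEM and per-animal maxima", {
  traces <- c(simulate_ratio_traces(1, 10, seed = 1),
              simulate_ratio_traces(1, 30, seed = 1))
  gs <- group_summary(traces)
  expect_equal(gs$max_mean, 20)
  expect_equal(gs$max_sem, 10)

  same <- simulate_ratio_traces(1, 17, seed = 5)
  gs2 <- group_summary(c(same, same, same))
  expect_true(all(gs2$sem_pct == 0))

  noisy <- lapply(simulate_ratio_traces(10, 17, noise_snr = 10, seed = 6),
                  ratio_change)
  gs3 <- group_summary(noisy)
  M <- vapply(noisy, function(tr) tr$ratio_change_pct,
              numeric(length(noisy[[1]]$time_s)))
  expect_equal(gs3$sem_pct, apply(M, 1, stats::sd) / sqrt(10))
  expect_error(group_summary(list()), "no traces")
})

test_that("noisy peak recovery scatters as a resimulation oracle predicts", {
  trs <- lapply(simulate_ratio_traces(10, 17, noise_snr = 20, seed = 3),
                ratio_change)
  got <- vapply(trs, max_ratio_change, 0, smooth_s = 3)
  # oracle: resimulate many traces at the same SNR and settings
  oracle <- vapply(1:40, function(r) {
    tr <- simulate_ratio_traces(10, 17, noise_snr = 20,
                                seed = 5000 + r)
    mean(vapply(lapply(tr, ratio_change), max_ratio_change, 0,
                smooth_s = 3))
  }, 0)
  expect_gt(mean(got), stats::quantile(oracle, 0.005))
  expect_lt(mean(got), stats::quantile(oracle, 0.995))
  expect_lt(stats::sd(got), 4 * stats::sd(unlist(oracle)) * sqrt(10))

  # flat traces with noise only: small positive extremum bias matching
  # the oracle at the same SNR
  flat <- vapply(1:30, function(r) {
    tr <- simulate_ratio_traces(1, 0, noise_snr = 10,
                                seed = 7000 + r)[[1]]
    max_ratio_change(ratio_change(tr), smooth_s = 3)
  }, 0)
  expect_gt(mean(flat), 0)
  expect_lt(mean(flat), 5)
})

test_that("misaligned traces are rejected and resampling aligns them", {
  a <- simulate_ratio_traces(1, 17, seed = 1)[[1]]
  b <- simulate_ratio_traces(1, 17, seed = 1, sample_rate_hz = 4)[[1]]
  expect_error(group_summary(list(a, b)), "aligned")
  ab <- resample_traces(list(a, b), times = a$time_s)
  expect_no_error(group_summary(ab))
})

test_that("puncta combs are binned into the sixteen-class histogram", {
  pos <- seq(0, 50, by = 0.1)
  teeth <- seq(4, 46, by = 2)
  comb <- vapply(pos, function(x)
    sum(exp(-(x - teeth)^2 / (2 * 0.3^2))), 0)
  pp <- puncta_spacing(comb, positions_um = pos, min_prominence = 0.3)
  expect_length(pp$positions_um, length(teeth))
  expect_length(pp$spacings_um, length(teeth) - 1)
  expect_equal(unname(mean(pp$spacings_um)), 2, tolerance = 0.02)
  expect_identical(sum(pp$histogram > 0), 1L)
  expect_length(pp$histogram, 16L)
  expect_equal(sum(pp$histogram), 1)

  # one missing tooth doubles one spacing: two occupied classes
  teeth2 <- setdiff(teeth, 24)
  comb2 <- vapply(pos, function(x)
    sum(exp(-(x - teeth2)^2 / (2 * 0.3^2))), 0)
  pp2 <- puncta_spacing(comb2, positions_um = pos, min_prominence = 0.3)
  expect_identical(sum(pp2$histogram > 0), 2L)
  expect_equal(max(pp2$spacings_um), 4, tolerance = 0.02)

  # noisy comb: recovered mean spacing within 5% of truth
  noisy <- comb + withr::with_seed(8, rnorm(length(pos), 0, 0.05))
  pp3 <- puncta_spacing(noisy, positions_um = pos, min_prominence = 0.3)
  expect_lt(abs(mean(pp3$spacings_um) - 2) / 2, 0.05)

  # fewer than two puncta: empty spacings, not an error
  lone <- exp(-(pos - 25)^2 / 0.2)
  expect_length(puncta_spacing(lone, positions_um = pos,
                               min_prominence = 0.3)$spacings_um, 0)
})
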