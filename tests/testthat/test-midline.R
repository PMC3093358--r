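make_frames <- function(duration_s = 2, seed = 1, omega_rate = 0, ...) {
  cfg <- sim_config(duration_s = duration_s, omega_rate_per_s = omega_rate,
                    reversal_rate_per_s = 0, rng_seed = seed, ...)
  ps <- simulate_posture_sequence(cfg)
  list(ps = ps, fs = rasterize(ps))
}

test_that("segmentation recovers the worm area and flags empty frames", {
  w <- make_frames()
  mask <- segment_worm(w$fs$frames[[1]])
  w_max <- 1 / 12
  analytic <- w_max * (0.4 + 0.6 * 2 / pi) / 0.01^2
  expect_lt(abs(sum(mask) - analytic) / analytic, 0.05)
  expect_false(attr(mask, "no_worm"))

  empty <- segment_worm(matrix(0, 32, 32))
  expect_true(attr(empty, "no_worm"))
  expect_false(any(empty))
  expect_error(segment_worm(matrix(c(NA, 1), 2, 2)), "finite")
})

test_that("a speck near the worm is removed by the largest-component rule", {
  w <- make_frames()
  f <- w$fs$frames[[1]]
  f[2:3, 2:3] <- 1            # bright speck far from the worm
  mask <- segment_worm(f)
  expect_false(mask[2, 2])
  expect_gt(sum(mask), 100)
})

test_that("extracted midlines match the true posture to sub-pixel accuracy", {
  w <- make_frames(duration_s = 1, seed = 4)
  mls <- extract_midlines(w$fs, orient = FALSE)
  px <- w$fs$pixel_size_mm
  for (i in seq_along(mls)) {
    m <- mls[[i]]
    expect_true(m$valid)
    expect_equal(m$length_mm, 1, tolerance = 0.03)
    # point-to-curve distance against the ground truth (both centered)
    truth <- sweep(w$ps$midlines[[i]], 2, colMeans(w$ps$midlines[[i]]))
    dense <- wormkymo:::resample_polyline(truth, 800)
    est <- sweep(m$points, 2, colMeans(m$points))
    d <- vapply(seq_len(nrow(est)), function(j)
      min(sqrt(colSums((t(dense) - est[j, ])^2))), 0)
    expect_lt(mean(d) / px, 2)
    # resampled spacings equal within contract
    sp <- sqrt(rowSums(diff(m$points)^2))
    expect_lt((max(sp) - min(sp)) / mean(sp), 1e-3)
  }
})

test_that("resampling preserves arc length within 1%", {
  th <- seq(0, 3, length.out = 400)
  wiggly <- cbind(th, 0.3 * sin(3 * th))
  rs <- wormkymo:::resample_polyline(wiggly, 50)
  l0 <- sum(sqrt(rowSums(diff(wiggly)^2)))
  l1 <- sum(sqrt(rowSums(diff(rs)^2)))
  expect_lt(abs(l1 - l0) / l0, 0.01)
})

test_that("the omega pose defeats extraction with a self-contact flag", {
  cfg <- sim_config(duration_s = 30, omega_rate_per_s = 0.2,
                    reversal_rate_per_s = 0, rng_seed = 6)
  ps <- simulate_posture_sequence(cfg)
  on <- ps$omega_onsets_s[1]
  peak <- which.min(abs(ps$times - (on + cfg$omega_duration_s / 2)))
  fs <- rasterize(ps, frames = peak)
  ml <- extract_midline(segment_worm(fs$frames[[1]]), fs$pixel_size_mm)
  expect_false(ml$valid)
  expect_true(ml$failure_reason %in%
                c("self_contact", "skeleton_branch", "too_short"))
})

test_that("degenerate masks fail with informative reasons", {
  empty <- structure(matrix(FALSE, 16, 16), no_worm = TRUE)
  expect_identical(extract_midline(empty, 0.01)$failure_reason, "no_worm")
  dot <- matrix(FALSE, 16, 16)
  dot[8, 8] <- TRUE
  expect_false(extract_midline(dot, 0.01)$valid)
  expect_error(extract_midline(dot, 0.01, K = 2), "K")
})

test_that("orientation recovers the true head on ground-truth sequences", {
  cfg <- sim_config(duration_s = 60, omega_rate_per_s = 0.04,
                    reversal_rate_per_s = 0.02, rng_seed = 8)
  ps <- simulate_posture_sequence(cfg)
  mls <- orient_and_track(as_wk_midlines(ps))
  expect_identical(attr(mls, "polarity_method"), "displacement")
  head_first <- vapply(seq_along(mls), function(i) {
    p <- mls[[i]]$points
    truth <- ps$midlines[[i]]
    sum((p[1, ] - truth[1, ])^2) < sum((p[1, ] - truth[nrow(truth), ])^2)
  }, TRUE)
  expect_gte(mean(head_first), 0.99)
})

test_that("orientation is invariant to scrambled input point order", {
  cfg <- sim_config(duration_s = 20, omega_rate_per_s = 0,
                    reversal_rate_per_s = 0, rng_seed = 9)
  ps <- simulate_posture_sequence(cfg)
  straight <- orient_and_track(as_wk_midlines(ps))
  scrambled <- as_wk_midlines(ps)
  flip_idx <- seq(1, length(scrambled), by = 2)
  for (i in flip_idx) {
    scrambled[[i]]$points <-
      scrambled[[i]]$points[rev(seq_len(nrow(scrambled[[i]]$points))), ]
  }
  rescued <- orient_and_track(scrambled)
  for (i in seq_along(straight)) {
    expect_equal(rescued[[i]]$points, straight[[i]]$points)
  }
  expect_error(orient_and_track(list(structure(
    list(points = NULL, valid = FALSE, failure_reason = "no_worm",
         length_mm = NA_real_), class = "wk_midline"))), "no valid")
})

test_that("invalid-frame fraction tracks the true omega time fraction", {
  cfg <- sim_config(duration_s = 120, omega_rate_per_s = 0.03,
                    reversal_rate_per_s = 0, rng_seed = 2)
  ps <- simulate_posture_sequence(cfg)
  fs <- rasterize(ps)
  mls <- extract_midlines(fs, orient = FALSE)
  invalid_frac <- mean(!vapply(mls, function(m) m$valid, TRUE))
  true_frac <- mean(ps$true_state == "OMEGA")
  expect_lt(abs(invalid_frac - true_frac), 0.02)
})

test_that("midline CSV round-trips frames and failure reasons", {
  w <- make_frames(duration_s = 0.2)
  mls <- extract_midlines(w$fs, orient = FALSE)
  mls[[2]] <- structure(list(points = NULL, valid = FALSE,
                             failure_reason = "self_contact",
                             length_mm = NA_real_), class = "wk_midline")
  path <- tempfile(fileext = ".csv")
  write_midlines_csv(mls, path)
  back <- read_midlines_csv(path)
  expect_length(back, length(mls))
  expect_false(back[[2]]$valid)
  expect_identical(back[[2]]$failure_reason, "self_contact")
  expect_equal(back[[1]]$points[, 1], unname(mls[[1]]$points[, 1]))
  unlink(path)
})
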