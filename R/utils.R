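# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so seeded generators never perturb the session stream.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

stop_if_not_scalar_number <- function(x, name, allow_zero = TRUE,
                                      allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (!allow_inf && !is.finite(x))) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (x < 0 || (!allow_zero && x == 0)) {
    stop(sprintf("'%s' must be %s", name,
                 if (allow_zero) ">= 0" else "> 0"), call. = FALSE)
  }
  invisible(x)
}

# Onset times of a homogeneous Poisson process on [0, duration).
poisson_onsets <- function(rate, duration) {
  if (rate <= 0) return(numeric(0))
  onsets <- numeric(0)
  t <- 0
  repeat {
    # draw gaps in chunks to limit rexp() call count
    n <- max(16L, ceiling(rate * duration * 0.5))
    gaps <- stats::rexp(n, rate)
    onsets <- c(onsets, t + cumsum(gaps))
    t <- onsets[length(onsets)]
    if (t > duration) break
  }
  onsets[onsets < duration]
}

# Wrap angles (radians) to (-pi, pi].
wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

# Arc length of a polyline given as an n x 2 matrix.
polyline_length <- function(p) {
  if (nrow(p) < 2L) return(0)
  sum(sqrt(rowSums(diff(p)^2)))
}

# Resample a polyline to K points at equal arc length (linear
# interpolation along the cumulative chord length), followed by a few
# fixed-point iterations that equalize the consecutive chord distances of
# the output (plain arc-length placement leaves chords unequal wherever
# the path curves or jitters).
resample_polyline <- function(p, K) {
  if (K < 3L) stop("K must be >= 3", call. = FALSE)
  seg <- sqrt(rowSums(diff(p)^2))
  keep <- c(TRUE, seg > 0)
  p <- p[keep, , drop = FALSE]
  if (nrow(p) < 2L) stop("degenerate polyline", call. = FALSE)
  s <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
  at <- function(si) cbind(stats::approx(s, p[, 1], xout = si)$y,
                           stats::approx(s, p[, 2], xout = si)$y)
  si <- seq(0, s[length(s)], length.out = K)
  q <- at(si)
  for (it in 1:6) {
    ch <- c(0, cumsum(sqrt(rowSums(diff(q)^2))))
    d <- diff(ch)
    if ((max(d) - min(d)) / mean(d) < 1e-7) break
    si <- stats::approx(ch, si,
                        xout = seq(0, ch[K], length.out = K))$y
    q <- at(si)
  }
  q
}

# Centered moving-average smoothing of a numeric vector, window w (odd);
# endpoints are kept fixed.
smooth_open_curve <- function(x, w = 3L) {
  if (w < 3L || length(x) < w) return(x)
  sm <- stats::filter(x, rep(1 / w, w), sides = 2)
  out <- ifelse(is.na(sm), x, sm)
  out[1] <- x[1]
  out[length(x)] <- x[length(x)]
  as.numeric(out)
}

# Run-length intervals of a label vector with frame times; returns a
# data.frame(state, start_s, end_s, start_frame, end_frame). The end time of
# a run is the start time of the next run (last run ends at the final
# timestamp plus one frame period).
label_intervals <- function(labels, times) {
  r <- rle(as.character(labels))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  dt <- if (length(times) > 1L) stats::median(diff(times)) else 1
  end_s <- c(times[starts[-1]], times[length(times)] + dt)
  data.frame(state = r$values,
             start_s = times[starts],
             end_s = end_s,
             start_frame = starts,
             end_frame = ends,
             stringsAsFactors = FALSE)
}

# Merge TRUE-runs separated by gaps shorter than merge_gap frames, then drop
# runs shorter than min_len frames.
clean_bool_runs <- function(x, merge_gap, min_len) {
  r <- rle(x)
  # fill short FALSE gaps flanked by TRUE runs
  if (length(r$lengths) > 2L) {
    for (i in seq_along(r$values)[-c(1, length(r$values))]) {
      if (!r$values[i] && r$lengths[i] < merge_gap &&
          r$values[i - 1] && r$values[i + 1]) {
        r$values[i] <- TRUE
      }
    }
  }
  x <- inverse.rle(r)
  r <- rle(x)
  r$values[r$values & r$lengths < min_len] <- FALSE
  inverse.rle(r)
}
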