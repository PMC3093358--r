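#' Simulate dual-channel cameleon ratio traces
#'
#' Generates YFP (F535) and CFP (F480) time series with a
#' temperature-stimulus-locked ratio response, optional photobleaching
#' common to both channels, and per-channel multiplicative Gaussian noise.
#' The response kernel \eqn{k(t) = (1 - e^{-(t-t_0)/\tau_r}) e^{-(t-t_0)/\tau_d}}
#' is normalized so its sampled maximum is exactly 1, so the ground-truth
#' peak percent ratio change equals `response_percent` by construction.
#'
#' `noise_snr` follows the convention usual for evoked-response imaging:
#' it is the ratio of the peak response amplitude to the per-sample noise
#' SD of the ratio-change trace (so SNR 10 on a 17% response means 1.7
#' percentage points of ratio noise per sample). The noise is realized as
#' independent multiplicative Gaussian noise on both channels. For null
#' responses (`response_percent = 0`) the reference amplitude falls back
#' to 10%, a typical wild-type response magnitude, so "noise only" traces
#' still carry a defined noise floor. Use `Inf` for noiseless traces.
#'
#' @param n_traces number of traces (animals), >= 1.
#' @param response_percent peak ratio change from baseline (percent; may be
#'   negative for inhibitory responses).
#' @param onset_s stimulus onset time (s), default 30.
#' @param kinetics list with `rise_s` and `decay_s` time constants.
#' @param noise_snr response-amplitude-referenced SNR (Inf = noiseless);
#'   must be >= 0.
#' @param bleach_rate common exponential bleaching rate (1/s), >= 0.
#' @param seed RNG seed.
#' @param duration_s trace duration (s), default 90.
#' @param sample_rate_hz sampling rate (Hz), default 5 (200 ms exposures).
#' @param baseline_ratio baseline YFP/CFP ratio R0, default 1.5.
#' @param f480_baseline baseline CFP intensity (a.u.), default 1000.
#' @return List of `ratio_trace` objects (class `ratio_traces`), each a
#'   data.frame-like list with `time_s`, `f535`, `f480`, `temperature_c`
#'   and attribute `true_peak_pct`.
#' @export
simulate_ratio_traces <- function(n_traces, response_percent = 17,
                                  onset_s = 30,
                                  kinetics = list(rise_s = 5, decay_s = 15),
                                  noise_snr = Inf, bleach_rate = 0,
                                  seed = 1L, duration_s = 90,
                                  sample_rate_hz = 5,
                                  baseline_ratio = 1.5,
                                  f480_baseline = 1000) {
  if (n_traces < 1L) stop("'n_traces' must be >= 1", call. = FALSE)
  stop_if_not_scalar_number(noise_snr, "noise_snr", allow_inf = TRUE)
  stop_if_not_scalar_number(bleach_rate, "bleach_rate")
  t <- seq(0, duration_s, by = 1 / sample_rate_hz)
  kern <- rep(0, length(t))
  post <- t >= onset_s
  tt <- t[post] - onset_s
  k <- (1 - exp(-tt / kinetics$rise_s)) * exp(-tt / kinetics$decay_s)
  if (max(k) > 0) k <- k / max(k)
  kern[post] <- k
  # temperature program: hold, then ramp up 3 degC over 20 s at onset
  temperature <- 20 + 3 * pmin(1, pmax(0, (t - onset_s) / 20))

  bleach <- exp(-bleach_rate * t)
  ref_amp <- max(abs(response_percent), 10)
  rel_sd <- if (is.finite(noise_snr) && noise_snr > 0) {
    # split the target ratio-change noise SD evenly across both channels
    (ref_amp / 100) / (noise_snr * sqrt(2))
  } else 0

  traces <- with_seed(as.integer(seed), {
    lapply(seq_len(n_traces), function(i) {
      e480 <- if (rel_sd > 0) stats::rnorm(length(t), 0, rel_sd) else 0
      e535 <- if (rel_sd > 0) stats::rnorm(length(t), 0, rel_sd) else 0
      f480 <- f480_baseline * bleach * (1 + e480)
      f535 <- f480_baseline * bleach * baseline_ratio *
        (1 + response_percent / 100 * kern) * (1 + e535)
      structure(list(time_s = t, f535 = f535, f480 = f480,
                     temperature_c = temperature),
                class = "ratio_trace",
                true_peak_pct = response_percent,
                onset_s = onset_s)
    })
  })
  structure(traces, class = "ratio_traces")
}

#' @export
print.ratio_traces <- function(x, ...) {
  cat("Ratio traces:", length(x), "traces of", length(x[[1]]$time_s),
      "samples\n")
  invisible(x)
}

#' Compute the YFP/CFP ratio-change time course
#'
#' The ratio R = F535/F480 is referenced to its mean R0 over a baseline
#' window, yielding the percent ratio change 100 (R - R0)/R0 per sample.
#' The default baseline is the 10 s ending at stimulus onset (detected from
#' the temperature channel when present, otherwise the first 10 s).
#' Optional exponential bleach detrending fits a log-linear decay to the
#' reference (CFP) channel and divides both channels by it; it is off by
#' default because ratioing already cancels bleaching common to both
#' channels.
#'
#' @param trace a `ratio_trace` or data.frame with `time_s`, `f535`,
#'   `f480`, optionally `temperature_c`.
#' @param baseline_window_s numeric c(start, end) in seconds, or NULL for
#'   the default rule.
#' @param detrend apply exponential bleach detrending (default FALSE).
#' @return The completed `ratio_trace` with `ratio`, `ratio_change_pct`,
#'   and attributes `baseline_window_s` and `r0`.
#' @export
ratio_change <- function(trace, baseline_window_s = NULL, detrend = FALSE) {
  tr <- unclass(trace)
  t <- tr$time_s
  if (is.null(t) || is.null(tr$f535) || is.null(tr$f480)) {
    stop("trace needs time_s, f535 and f480", call. = FALSE)
  }
  if (is.null(baseline_window_s)) {
    onset <- attr(trace, "onset_s")
    if (is.null(onset) && !is.null(tr$temperature_c)) {
      moved <- which(abs(tr$temperature_c - tr$temperature_c[1]) > 0.2)
      onset <- if (length(moved)) t[moved[1]] else NA
    }
    baseline_window_s <- if (!is.null(onset) && is.finite(onset) &&
                             onset > t[1]) {
      c(max(t[1], onset - 10), onset)
    } else {
      c(t[1], t[1] + 10)
    }
  }
  bl <- t >= baseline_window_s[1] & t < baseline_window_s[2]
  if (!any(bl)) stop("empty baseline window", call. = FALSE)
  if (any(tr$f480[bl] <= 0)) {
    stop("non-positive F480 in the baseline window", call. = FALSE)
  }
  f535 <- tr$f535
  f480 <- tr$f480
  if (detrend) {
    ok <- f480 > 0
    fit <- stats::lm(log(f480[ok]) ~ t[ok])
    decay <- exp(stats::predict(fit, newdata = list(t = t)))
    decay <- decay / decay[1]
    f535 <- f535 / decay
    f480 <- f480 / decay
  }
  ratio <- f535 / f480
  r0 <- mean(ratio[bl])
  out <- structure(list(time_s = t, f535 = f535, f480 = f480,
                        temperature_c = tr$temperature_c,
                        ratio = ratio,
                        ratio_change_pct = 100 * (ratio - r0) / r0),
                   class = "ratio_trace",
                   baseline_window_s = baseline_window_s,
                   r0 = r0,
                   true_peak_pct = attr(trace, "true_peak_pct"),
                   onset_s = attr(trace, "onset_s"))
  out
}

#' Maximum ratio change from baseline
#'
#' Signed extremum of the percent ratio change over the post-baseline
#' window: the maximum by default, the minimum for inhibitory responses
#' (`direction = "min"`), or the extremum of largest magnitude
#' (`direction = "abs"`). With `smooth_s > 0` the ratio-change trace is
#' boxcar-smoothed before the extremum is taken; the default 0 reports the
#' raw sample extremum (exact on noiseless data), while a window of about
#' the response rise time (e.g. 3 s) is recommended for noisy recordings
#' because a raw extremum of a noisy trace is biased upward.
#'
#' @param trace a completed `ratio_trace` (see [ratio_change()]); an
#'   unprocessed trace is completed with default settings first.
#' @param direction "max", "min" or "abs".
#' @param window_s optional c(start, end) search window (s); default is
#'   from the end of the baseline window to the end of the trace.
#' @param smooth_s boxcar smoothing width (s) applied before the extremum.
#' @return Scalar percent ratio change.
#' @export
max_ratio_change <- function(trace, direction = c("max", "min", "abs"),
                             window_s = NULL, smooth_s = 0) {
  direction <- match.arg(direction)
  if (is.null(trace$ratio_change_pct)) trace <- ratio_change(trace)
  t <- trace$time_s
  bw <- attr(trace, "baseline_window_s")
  if (is.null(window_s)) window_s <- c(bw[2], t[length(t)])
  if (window_s[1] >= t[length(t)]) {
    stop("trace ends before the search window", call. = FALSE)
  }
  x <- trace$ratio_change_pct
  if (smooth_s > 0) {
    dt <- stats::median(diff(t))
    w <- max(1L, round(smooth_s / dt))
    if (w %% 2L == 0L) w <- w + 1L
    if (w >= 3L && length(x) >= w) {
      sm <- stats::filter(x, rep(1 / w, w), sides = 2)
      x <- ifelse(is.na(sm), x, as.numeric(sm))
    }
  }
  sel <- t >= window_s[1] & t <= window_s[2]
  xs <- x[sel]
  switch(direction,
         max = max(xs),
         min = min(xs),
         abs = xs[which.max(abs(xs))])
}

#' Group summary of ratio traces
#'
#' Pointwise mean and SEM of the percent ratio change across equal-length,
#' time-aligned traces, plus the mean +/- SEM of the per-animal maximum
#' ratio change (the scalar summary reported alongside published mean
#' traces). Use [resample_traces()] first if the traces are not aligned.
#'
#' @param traces list of `ratio_trace` objects (completed or raw).
#' @param ... passed to [max_ratio_change()] (e.g. `direction`,
#'   `smooth_s`).
#' @return List with `time_s`, `mean_pct`, `sem_pct`, `max_mean`,
#'   `max_sem`, `max_per_trace`, `n`.
#' @export
group_summary <- function(traces, ...) {
  if (length(traces) == 0L) stop("no traces", call. = FALSE)
  traces <- lapply(traces, function(tr)
    if (is.null(tr$ratio_change_pct)) ratio_change(tr) else tr)
  t0 <- traces[[1]]$time_s
  same <- vapply(traces, function(tr) {
    length(tr$time_s) == length(t0) &&
      all(abs(tr$time_s - t0) < 1e-9 * max(1, max(abs(t0))))
  }, TRUE)
  if (!all(same)) {
    stop("traces are not time-aligned; see resample_traces()", call. = FALSE)
  }
  M <- vapply(traces, function(tr) tr$ratio_change_pct,
              numeric(length(t0)))
  n <- length(traces)
  mean_pct <- rowMeans(M)
  sem_pct <- if (n > 1L) apply(M, 1, stats::sd) / sqrt(n) else
    rep(0, length(t0))
  mx <- vapply(traces, max_ratio_change, 0, ...)
  list(time_s = t0,
       mean_pct = mean_pct,
       sem_pct = sem_pct,
       max_mean = mean(mx),
       max_sem = if (n > 1L) stats::sd(mx) / sqrt(n) else NA_real_,
       max_per_trace = mx,
       n = n)
}

#' Resample traces onto a common time grid
#'
#' Linear interpolation of both channels (and temperature) onto `times`.
#'
#' @param traces list of `ratio_trace` objects.
#' @param times target time grid; defaults to the first trace's times.
#' @return List of resampled `ratio_trace` objects.
#' @export
resample_traces <- function(traces, times = NULL) {
  if (is.null(times)) times <- traces[[1]]$time_s
  lapply(traces, function(tr) {
    out <- list(time_s = times,
                f535 = stats::approx(tr$time_s, tr$f535, times, rule = 2)$y,
                f480 = stats::approx(tr$time_s, tr$f480, times, rule = 2)$y,
                temperature_c = if (!is.null(tr$temperature_c)) {
                  stats::approx(tr$time_s, tr$temperature_c, times,
                                rule = 2)$y
                })
    attributes(out) <- c(attributes(out),
                         attributes(tr)[c("true_peak_pct", "onset_s")])
    class(out) <- "ratio_trace"
    out
  })
}

#' Adjacent-puncta spacing histogram along a neurite
#'
#' Detects fluorescence puncta as local maxima of prominence at least
#' `min_prominence` after rolling-median baseline subtraction, refines peak
#' centers by 3-point parabolic interpolation, and bins the adjacent-center
#' spacings into `n_classes` equal-width classes over `range_um` (spacings
#' outside the range are clamped into the end classes so the fractions
#' always sum to 1). Fewer than two puncta yield empty spacings, not an
#' error.
#'
#' @param intensity_profile numeric 1-D fluorescence profile.
#' @param positions_um positions of the samples (micrometers); or supply
#'   `pixel_size_um`.
#' @param pixel_size_um spacing between samples (used when `positions_um`
#'   is NULL).
#' @param min_prominence minimum peak prominence (a.u. of the
#'   baseline-subtracted profile).
#' @param n_classes number of histogram classes, default 16.
#' @param range_um histogram range, default c(0, 8).
#' @param baseline_window_um rolling-median window for baseline removal,
#'   default 3.
#' @return An object of class `puncta_profile`: list with `positions_um`,
#'   `spacings_um`, `histogram` (fractions), `class_edges_um`,
#'   `class_mids_um`.
#' @export
puncta_spacing <- function(intensity_profile, positions_um = NULL,
                           pixel_size_um = 0.1, min_prominence = 0.1,
                           n_classes = 16L, range_um = c(0, 8),
                           baseline_window_um = 3) {
  y <- as.numeric(intensity_profile)
  n <- length(y)
  pos <- if (is.null(positions_um)) (seq_len(n) - 1) * pixel_size_um else
    as.numeric(positions_um)
  dx <- stats::median(diff(pos))
  k <- max(3L, round(baseline_window_um / dx))
  if (k %% 2L == 0L) k <- k + 1L
  base <- if (n > k) stats::runmed(y, k) else rep(stats::median(y), n)
  z <- y - base

  is_peak <- which(diff(sign(diff(z))) < 0) + 1L
  keep <- vapply(is_peak, function(i) peak_prominence(z, i) >=
                   min_prominence, TRUE)
  pk <- is_peak[keep]
  centers <- vapply(pk, function(i) {
    if (i <= 1L || i >= n) return(pos[i])
    a <- z[i - 1L]; b <- z[i]; c <- z[i + 1L]
    den <- a - 2 * b + c
    if (den >= 0) return(pos[i])
    pos[i] + 0.5 * (a - c) / den * dx
  }, 0)
  centers <- sort(centers)

  spac <- if (length(centers) >= 2L) diff(centers) else numeric(0)
  edges <- seq(range_um[1], range_um[2], length.out = n_classes + 1L)
  hist_frac <- rep(0, n_classes)
  if (length(spac)) {
    clamped <- pmin(pmax(spac, range_um[1]), range_um[2])
    cls <- pmin(n_classes, pmax(1L, findInterval(clamped, edges,
                                                 rightmost.closed = TRUE)))
    hist_frac <- tabulate(cls, n_classes) / length(spac)
  }
  structure(list(positions_um = centers,
                 spacings_um = spac,
                 histogram = hist_frac,
                 class_edges_um = edges,
                 class_mids_um = (edges[-1] + edges[-length(edges)]) / 2),
            class = "puncta_profile")
}

# Prominence of local maximum at index i: height above the higher of the
# two valley minima reached before a taller sample on each side.
peak_prominence <- function(z, i) {
  n <- length(z)
  left <- z[seq_len(i - 1)]
  right <- z[seq(i + 1, n)]
  lmin <- if (length(left)) {
    taller <- which(left > z[i])
    if (length(taller)) min(left[(max(taller) + 1):(i - 1)]) else min(left)
  } else z[i]
  rmin <- if (length(right)) {
    taller <- which(right > z[i])
    if (length(taller)) min(right[seq_len(min(taller) - 1)]) else min(right)
  } else z[i]
  lmin <- if (is.finite(lmin)) lmin else z[i]
  rmin <- if (is.finite(rmin)) rmin else z[i]
  z[i] - max(lmin, rmin)
}

#' Write ratio traces to a long-format CSV
#'
#' Columns: trace, time_s, f535, f480, temperature_c.
#'
#' @param traces list of `ratio_trace` objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(traces, path) {
  rows <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    data.frame(trace = i, time_s = tr$time_s, f535 = tr$f535,
               f480 = tr$f480,
               temperature_c = if (is.null(tr$temperature_c)) NA_real_
               else tr$temperature_c)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read ratio traces written by [write_traces_csv()]
#'
#' @param path CSV path.
#' @return List of `ratio_trace` objects (class `ratio_traces`).
#' @export
read_traces_csv <- function(path) {
  df <- utils::read.csv(path)
  out <- lapply(split(df, df$trace), function(d) {
    structure(list(time_s = d$time_s, f535 = d$f535, f480 = d$f480,
                   temperature_c = if (all(is.na(d$temperature_c))) NULL
                   else d$temperature_c),
              class = "ratio_trace")
  })
  names(out) <- NULL
  structure(out, class = "ratio_traces")
}
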