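#' Detect omega-turn frames from midlines
#'
#' A frame is an omega candidate if midline extraction failed
#' (self-contact, skeleton branch, too-short) or if the minimum distance
#' between midline points separated by more than `min_sep_frac` of the body
#' arc length falls below one body width. Candidate runs separated by gaps
#' shorter than `merge_gap_s` are merged; runs shorter than
#' `min_duration_s` are discarded.
#'
#' @param midlines list of `wk_midline` objects (oriented or not; the
#'   criterion is symmetric), or a `posture_sequence`.
#' @param times frame times (seconds); defaults to the midlines' `times`
#'   attribute.
#' @param body_width_mm self-contact distance threshold; defaults to the
#'   median valid body length / 12.
#' @param min_sep_frac minimum separation along the body (fraction of arc
#'   length) for the self-distance test, default 0.25.
#' @param merge_gap_s merge gap (s), default 0.3.
#' @param min_duration_s minimum event duration (s), default 0.2.
#' @return Logical per-frame vector with attribute `events`, a
#'   data.frame(onset_s, end_s).
#' @export
detect_omega <- function(midlines, times = NULL, body_width_mm = NULL,
                         min_sep_frac = 0.25, merge_gap_s = 0.3,
                         min_duration_s = 0.2) {
  if (inherits(midlines, "posture_sequence")) {
    times <- midlines$times
    midlines <- lapply(midlines$midlines, function(p) {
      structure(list(points = p, valid = TRUE, failure_reason = "none",
                     length_mm = polyline_length(p)), class = "wk_midline")
    })
  }
  if (is.null(times)) times <- attr(midlines, "times")
  n <- length(midlines)
  if (is.null(times)) times <- seq_len(n) - 1
  dt <- if (n > 1L) stats::median(diff(times)) else 1

  lens <- vapply(midlines, function(m)
    if (isTRUE(m$valid)) m$length_mm else NA_real_, 0)
  if (is.null(body_width_mm)) {
    body_width_mm <- stats::median(lens, na.rm = TRUE) / 12
  }
  cand <- vapply(seq_len(n), function(i) {
    m <- midlines[[i]]
    if (!isTRUE(m$valid)) return(TRUE)
    K <- nrow(m$points)
    min_self_distance(m$points, as.integer(ceiling(min_sep_frac * (K - 1)))) <
      body_width_mm
  }, TRUE)

  merged <- clean_bool_runs(cand,
                            merge_gap = max(1L, round(merge_gap_s / dt)),
                            min_len = max(1L, round(min_duration_s / dt)))
  iv <- label_intervals(merged, times)
  ev <- iv[iv$state == "TRUE", c("start_s", "end_s")]
  names(ev) <- c("onset_s", "end_s")
  rownames(ev) <- NULL
  structure(merged, events = ev)
}

#' Classify forward/backward movement from wave propagation
#'
#' Within a sliding window (default 1 s) the body shift maximizing the mean
#' correlation between curvature profiles `frame_step_s` apart is found
#' (searching -`max_shift`..`max_shift` positions). A shift toward the tail
#' means the undulatory wave travels head to tail, i.e. FORWARD; toward the
#' head means BACKWARD. The comparison step defaults to 0.1 s so that the
#' wave travels at least one body position between the compared frames;
#' this makes the shift sign robust to pixelation noise, which is strongly
#' correlated between adjacent frames. Frames whose peak mean correlation
#' is below
#' `cor_floor`, or whose best shift is 0, are UNKNOWN, as are masked
#' (omega) frames. Direction runs shorter than `min_persist_s` are absorbed
#' into the surrounding state, mirroring how modest direction changes are
#' not reflected in the published curvature maps.
#'
#' @param map a `curvature_map` (omega frames already masked).
#' @param window_s sliding window (s), default 1; must span >= 2 frames.
#' @param max_shift maximum body shift searched (positions), default 10.
#' @param cor_floor minimum peak correlation, default 0.5.
#' @param min_persist_s minimum persistence of a direction (s), default 0.5.
#' @param frame_step_s separation of the compared profiles (s), default
#'   0.1.
#' @return Character per-frame vector of FORWARD/BACKWARD/UNKNOWN (masked
#'   frames are UNKNOWN here; [segment_states()] overwrites them as OMEGA).
#' @export
classify_direction <- function(map, window_s = 1, max_shift = 10L,
                               cor_floor = 0.5, min_persist_s = 0.5,
                               frame_step_s = 0.1) {
  stopifnot(inherits(map, "curvature_map"))
  n <- nrow(map$values)
  times <- map$times
  dt <- if (n > 1L) stats::median(diff(times)) else 1
  if (round(window_s / dt) < 2) stop("window shorter than 2 frames",
                                     call. = FALSE)
  win <- max(1L, round(window_s / dt))
  if (n < 2L) return(rep("UNKNOWN", n))
  step <- max(1L, min(n - 1L, round(frame_step_s / dt)))

  cc <- shift_correlations(map$values, max_shift, step = step)
  # mean correlation curve over the centered window, per frame pair
  kernel <- rep(1, win)
  csum <- apply(cc, 2, function(col) {
    v <- col
    v[is.na(v)] <- 0
    cnt <- as.numeric(!is.na(col))
    s <- stats::filter(v, kernel, sides = 2)
    w <- stats::filter(cnt, kernel, sides = 2)
    # filter() leaves NAs at the edges; fall back to the raw values there
    s <- ifelse(is.na(s), v, s)
    w <- ifelse(is.na(w), cnt, w)
    ifelse(w > 0, s / w, NA_real_)
  })
  if (is.null(dim(csum))) csum <- matrix(csum, nrow = 1L)

  shifts <- -max_shift:max_shift
  lab_pair <- apply(csum, 1, function(z) {
    if (all(is.na(z))) return("UNKNOWN")
    k <- which.max(z)
    if (z[k] < cor_floor || shifts[k] == 0L) return("UNKNOWN")
    if (shifts[k] > 0L) "FORWARD" else "BACKWARD"
  })
  labels <- c(lab_pair, rep(lab_pair[length(lab_pair)], step))
  labels[map$mask[, 1]] <- "UNKNOWN"

  absorb_short_runs(labels, min_len = max(1L, round(min_persist_s / dt)),
                    protected = map$mask[, 1])
}

# Absorb FORWARD/BACKWARD runs shorter than min_len frames into their
# surroundings; frames marked protected (omega/masked) are never altered.
absorb_short_runs <- function(labels, min_len, protected = NULL) {
  if (is.null(protected)) protected <- rep(FALSE, length(labels))
  repeat {
    r <- rle(labels)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    short <- which(r$lengths < min_len &
                     r$values %in% c("FORWARD", "BACKWARD"))
    short <- short[!vapply(short, function(i)
      any(protected[starts[i]:ends[i]]), TRUE)]
    if (!length(short)) break
    i <- short[which.min(r$lengths[short])]
    left <- if (i > 1L) r$values[i - 1L] else NA_character_
    right <- if (i < length(r$values)) r$values[i + 1L] else NA_character_
    fill <- if (!is.na(left) && !is.na(right)) {
      if (left == right) left
      else if (i > 1L && r$lengths[i - 1L] >= r$lengths[i + 1L]) left
      else right
    } else if (!is.na(left)) left else if (!is.na(right)) right
    else break
    labels[starts[i]:ends[i]] <- fill
  }
  labels
}

#' Segment a recording into FORWARD/BACKWARD/OMEGA/UNKNOWN states
#'
#' Runs [detect_omega()] on the midlines, builds the curvature map with
#' omega frames masked, classifies direction on the remaining frames, and
#' assembles the per-frame labels and maximal intervals. OMEGA intervals
#' coincide exactly with the curvature-map mask.
#'
#' @param midlines oriented `wk_midline` list (or `posture_sequence`).
#' @param times frame times (seconds).
#' @param ... tuning parameters passed to [detect_omega()] and
#'   [classify_direction()] (`body_width_mm`, `merge_gap_s`,
#'   `min_duration_s`, `window_s`, `max_shift`, `cor_floor`,
#'   `min_persist_s`).
#' @return An object of class `state_track`: list with `labels`, `times`,
#'   `intervals` (data.frame state/start_s/end_s), `map` (the masked
#'   `curvature_map`), `omega_events`.
#' @export
segment_states <- function(midlines, times = NULL, ...) {
  dots <- list(...)
  pick <- function(names) dots[intersect(names, names(dots))]
  om_args <- pick(c("body_width_mm", "min_sep_frac", "merge_gap_s",
                    "min_duration_s"))
  dir_args <- pick(c("window_s", "max_shift", "cor_floor", "min_persist_s",
                     "frame_step_s"))

  if (inherits(midlines, "posture_sequence")) {
    times <- midlines$times
  } else if (is.null(times)) {
    times <- attr(midlines, "times")
  }
  omega <- do.call(detect_omega,
                   c(list(midlines = midlines, times = times), om_args))
  map <- build_map(midlines, times = times, smooth = TRUE,
                   extra_mask = as.logical(omega))
  labels <- do.call(classify_direction, c(list(map = map), dir_args))
  labels[as.logical(omega)] <- "OMEGA"
  iv <- label_intervals(labels, map$times)
  structure(list(labels = labels,
                 times = map$times,
                 intervals = iv[, c("state", "start_s", "end_s")],
                 map = map,
                 omega_events = attr(omega, "events")),
            class = "state_track")
}

#' @export
print.state_track <- function(x, ...) {
  tab <- table(x$labels)
  cat("State track:", length(x$labels), "frames;",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  omega events:", nrow(x$omega_events), "\n")
  invisible(x)
}

#' Inter-omega-turn duration statistics
#'
#' Omega onsets within the first `window_s` seconds of the recording are
#' collected; inter-omega durations are successive onset-to-onset
#' differences. With fewer than two onsets the duration list is empty and
#' the mean is reported as missing (NA), never 0.
#'
#' @param states a `state_track`, or a numeric vector of omega onset times.
#' @param window_s analysis window (s), default 1000.
#' @return An object of class `turn_stats`: list with `omega_onsets_s`,
#'   `inter_omega_durations_s`, `mean_s`, `sem_s`, `n_events`,
#'   `analysis_window_s`.
#' @examples
#' turn_statistics(c(100, 300, 600))$mean_s  # 250
#' @export
turn_statistics <- function(states, window_s = 1000) {
  onsets <- if (inherits(states, "state_track")) {
    states$omega_events$onset_s
  } else {
    as.numeric(states)
  }
  onsets <- sort(onsets[onsets < window_s])
  durations <- diff(onsets)
  mean_s <- if (length(durations)) mean(durations) else NA_real_
  sem_s <- if (length(durations) > 1L) {
    stats::sd(durations) / sqrt(length(durations))
  } else NA_real_
  structure(list(omega_onsets_s = onsets,
                 inter_omega_durations_s = durations,
                 mean_s = mean_s, sem_s = sem_s,
                 n_events = length(onsets),
                 analysis_window_s = window_s),
            class = "turn_stats")
}

#' @export
print.turn_stats <- function(x, ...) {
  cat("Turn statistics over first", x$analysis_window_s, "s:",
      x$n_events, "omega onsets\n")
  if (is.na(x$mean_s)) {
    cat("  mean inter-omega duration: (undefined, < 2 onsets)\n")
  } else {
    cat("  mean inter-omega duration:", round(x$mean_s, 2), "+/-",
        round(x$sem_s, 2), "s (SEM)\n")
  }
  invisible(x)
}

#' Per-group aggregation of turn statistics
#'
#' Mean of per-animal mean inter-omega durations, with SEM across animals
#' (matching per-animal n in published duration summaries). Animals with an
#' undefined mean (fewer than two onsets) are excluded.
#'
#' @param stats_list list of `turn_stats` objects (one per animal).
#' @return List with `grand_mean_s`, `sem_s`, `n_animals`,
#'   `per_animal_mean_s`.
#' @export
turn_statistics_group <- function(stats_list) {
  means <- vapply(stats_list, function(s) s$mean_s, 0)
  means <- means[!is.na(means)]
  list(grand_mean_s = if (length(means)) mean(means) else NA_real_,
       sem_s = if (length(means) > 1L) stats::sd(means) / sqrt(length(means))
       else NA_real_,
       n_animals = length(means),
       per_animal_mean_s = means)
}

#' Write a state track to CSV files
#'
#' @param states a `state_track`.
#' @param labels_path CSV path for (frame, time_s, label).
#' @param intervals_path optional CSV path for the intervals table.
#' @return `labels_path`, invisibly.
#' @export
write_states_csv <- function(states, labels_path, intervals_path = NULL) {
  utils::write.csv(data.frame(frame = seq_along(states$labels),
                              time_s = states$times,
                              label = states$labels),
                   labels_path, row.names = FALSE)
  if (!is.null(intervals_path)) {
    utils::write.csv(states$intervals, intervals_path, row.names = FALSE)
  }
  invisible(labels_path)
}
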