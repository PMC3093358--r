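#' Simulate an animal track on an assay plate
#'
#' Run-and-tumble biased random walk confined to a circular plate:
#' persistent heading with angular noise, Poisson-timed tumbles
#' (reorientation to a random heading), and optional drift toward a target
#' radius or point. Behavioral archetypes select the drift program:
#'
#' \describe{
#'   \item{stay-center}{drift to the plate center (the cold region on a
#'     radial thermal gradient).}
#'   \item{stay-periphery}{drift to the outer rim (the warm region).}
#'   \item{stay-ring}{drift to the intermediate ring (the cultivation
#'     temperature zone).}
#'   \item{wander-both}{alternate between center and periphery targets.}
#'   \item{approach-peak-k-times}{for NaCl/odorant plates: approach the
#'     concentration peak `k` times with excursions in between
#'     (`k = 0` wanders while avoiding the peak; `k = 1` makes a single
#'     brief visit).}
#' }
#'
#' @param kind assay type: "thermotaxis", "nacl" or "chemotaxis".
#' @param behavior_params list: `archetype` (above), plus optional
#'   `duration_s` (3600), `dt_s` (1), `speed_mm_s` (0.15),
#'   `plate_radius_mm` (45), `ang_sd` (0.25 rad/sqrt(s)), `drift_gain`
#'   (0.8), `tumble_rate` (0.02/s), `k` (peak approaches, 3),
#'   `dwell_s` (60), `excursion_s` (180), `peak` (list(x, y, radius_mm)).
#' @param seed RNG seed.
#' @return An object of class `plate_track`: list with `time_s`, `x_mm`,
#'   `y_mm` (plate-center origin), `plate_radius_mm`, `gradient` (for
#'   thermotaxis: list(t_center = 17, t_edge = 25)), `peak` (for nacl and
#'   chemotaxis), `kind`, `archetype`.
#' @examples
#' tr <- simulate_plate_track("thermotaxis",
#'                            list(archetype = "stay-center",
#'                                 duration_s = 600), seed = 1)
#' @export
simulate_plate_track <- function(kind = c("thermotaxis", "nacl",
                                          "chemotaxis"),
                                 behavior_params = list(), seed = 1L) {
  kind <- match.arg(kind)
  p <- utils::modifyList(list(archetype = "stay-center",
                              duration_s = 3600, dt_s = 1,
                              speed_mm_s = 0.15, plate_radius_mm = 45,
                              ang_sd = 0.25, drift_gain = 0.8,
                              tumble_rate = 0.02, k = 3L,
                              dwell_s = 60, excursion_s = 180,
                              switch_mean_s = 900,
                              peak = NULL),
                         behavior_params)
  R <- p$plate_radius_mm
  if (R <= 0) stop("plate radius must be > 0", call. = FALSE)
  arch <- p$archetype
  known <- c("stay-center", "stay-periphery", "stay-ring", "wander-both",
             "approach-peak-k-times")
  if (!arch %in% known) {
    stop("unknown archetype: ", arch, call. = FALSE)
  }
  peak <- p$peak
  if (kind != "thermotaxis" && is.null(peak)) {
    peak <- list(x = R / 2, y = 0, radius_mm = 5)
  }

  n <- as.integer(ceiling(p$duration_s / p$dt_s)) + 1L
  dt <- p$dt_s
  xs <- numeric(n); ys <- numeric(n)

  with_seed(as.integer(seed), {
    pos <- if (is.null(peak)) {
      c(R / 2 * cos(stats::runif(1, 0, 2 * pi)),
        R / 2 * sin(stats::runif(1, 0, 2 * pi)))
    } else {
      # peak assays start on the far side of the plate, as animals are
      # placed away from the spotted gradient
      -c(peak$x, peak$y) / sqrt(peak$x^2 + peak$y^2) * R / 2
    }
    h <- stats::runif(1, 0, 2 * pi)
    target_r <- switch(arch,
                       "stay-center" = 0,
                       "stay-periphery" = R - 4,
                       "stay-ring" = 3 * R / 8,
                       "wander-both" = 0,
                       NA_real_)
    next_switch <- if (arch == "wander-both") p$switch_mean_s else Inf
    # peak-approach state machine
    phase <- "approach"
    entries_done <- 0L
    timer <- 0
    xs[1] <- pos[1]; ys[1] <- pos[2]
    for (i in 2:n) {
      tnow <- (i - 2L) * dt
      # choose the desired bearing
      bearing <- NA_real_
      if (arch == "approach-peak-k-times") {
        dpk <- c(peak$x, peak$y) - pos
        dist_pk <- sqrt(sum(dpk^2))
        if (p$k < 1L) {                       # avoid the peak entirely
          bearing <- if (dist_pk < peak$radius_mm + 12)
            atan2(-dpk[2], -dpk[1]) else NA_real_
        } else if (phase == "approach") {
          bearing <- atan2(dpk[2], dpk[1])
          if (dist_pk <= peak$radius_mm * 0.6) {
            phase <- "dwell"; timer <- p$dwell_s
          }
        } else if (phase == "dwell") {
          bearing <- atan2(dpk[2], dpk[1])
          timer <- timer - dt
          if (timer <= 0) {
            entries_done <- entries_done + 1L
            phase <- "leave"; timer <- p$excursion_s
          }
        } else {                              # leave
          bearing <- atan2(-dpk[2], -dpk[1])
          timer <- timer - dt
          if (timer <= 0 && entries_done < p$k) phase <- "approach"
        }
      } else if (!is.na(target_r)) {
        if (tnow >= next_switch) {  # scheduled center/periphery alternation
          target_r <- if (target_r == 0) R - 4 else 0
          next_switch <- next_switch + p$switch_mean_s
        }
        r <- sqrt(sum(pos^2))
        if (abs(r - target_r) > 1) {
          phi <- atan2(pos[2], pos[1])
          bearing <- if (r > target_r) phi + pi else phi
        }
      }
      # heading update: drift toward bearing, angular noise, tumbles
      if (!is.na(bearing)) {
        h <- h + p$drift_gain * wrap_angle(bearing - h) * min(1, dt)
      }
      h <- h + stats::rnorm(1, 0, p$ang_sd * sqrt(dt))
      # tumbles are suppressed while actively steering away from a peak,
      # so avoidance archetypes cannot stumble into the region by chance
      tumbling_ok <- !(arch == "approach-peak-k-times" && p$k < 1L &&
                         !is.na(bearing))
      if (stats::runif(1) < 1 - exp(-p$tumble_rate * dt) && tumbling_ok) {
        h <- stats::runif(1, 0, 2 * pi)
      }
      pos <- pos + p$speed_mm_s * dt * c(cos(h), sin(h))
      r <- sqrt(sum(pos^2))
      if (r > R) {                            # reflect at the plate wall
        pos <- pos * (2 * R - r) / r
        phi <- atan2(pos[2], pos[1])
        h <- pi + 2 * phi - h
      }
      xs[i] <- pos[1]; ys[i] <- pos[2]
    }
  })

  structure(list(time_s = (seq_len(n) - 1L) * dt,
                 x_mm = xs, y_mm = ys,
                 plate_radius_mm = R,
                 gradient = if (kind == "thermotaxis")
                   list(t_center = 17, t_edge = 25) else NULL,
                 peak = peak,
                 kind = kind,
                 archetype = arch),
            class = "plate_track")
}

#' @export
print.plate_track <- function(x, ...) {
  cat("Plate track (", x$kind, ", ", x$archetype, "): ",
      length(x$time_s), " samples over ", max(x$time_s), " s on a ",
      2 * x$plate_radius_mm / 10, " cm plate\n", sep = "")
  invisible(x)
}

#' Write a plate track to CSV with a JSON sidecar
#'
#' @param track a `plate_track`.
#' @param path CSV path (time_s, x_mm, y_mm); plate geometry goes to
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_track_csv <- function(track, path) {
  utils::write.csv(data.frame(time_s = track$time_s, x_mm = track$x_mm,
                              y_mm = track$y_mm),
                   path, row.names = FALSE)
  jsonlite::write_json(list(plate_radius_mm = track$plate_radius_mm,
                            gradient = track$gradient,
                            peak = track$peak,
                            kind = track$kind,
                            archetype = track$archetype),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a plate track written by [write_track_csv()]
#'
#' @param path CSV path; `<path>.json` must exist.
#' @return A `plate_track`.
#' @export
read_track_csv <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(time_s = df$time_s, x_mm = df$x_mm, y_mm = df$y_mm,
                 plate_radius_mm = meta$plate_radius_mm,
                 gradient = meta$gradient,
                 peak = meta$peak,
                 kind = meta$kind,
                 archetype = meta$archetype),
            class = "plate_track")
}
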