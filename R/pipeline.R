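#' Analyze a worm video into a kymograph and behavioral states
#'
#' Convenience wrapper chaining [extract_midlines()], [detect_omega()],
#' [build_map()] and [classify_direction()] via [segment_states()], plus
#' [turn_statistics()].
#'
#' @param stack a `frame_stack` or a TIFF path readable by
#'   [read_frame_stack()].
#' @param K midline points per frame.
#' @param turn_window_s analysis window for [turn_statistics()].
#' @param ... tuning parameters forwarded to [segment_states()].
#' @return List with `midlines`, `states` (a `state_track`, whose `map` is
#'   the omega-masked `curvature_map`), `turn_stats`.
#' @export
analyze_video <- function(stack, K = 50L, turn_window_s = 1000, ...) {
  if (is.character(stack)) stack <- read_frame_stack(stack)
  midlines <- extract_midlines(stack, K = K)
  states <- segment_states(midlines, times = stack$timestamps, ...)
  list(midlines = midlines,
       states = states,
       turn_stats = turn_statistics(states, window_s = turn_window_s))
}

#' Run a reproducible multi-stage pipeline from a configuration
#'
#' Executes the requested stages (simulate, analyze_video,
#' analyze_calcium, score_behavior) and writes all outputs plus a manifest
#' (`manifest.json`) recording the configuration, seed, package version,
#' output files with MD5 checksums, and a manifest hash. Re-running the
#' same configuration and seed reproduces the outputs bit-exactly.
#'
#' The configuration is a named list (or a JSON file path) with optional
#' sections:
#' \describe{
#'   \item{simulate}{sublists `video` (sim_config fields plus
#'     `pixel_size_mm`, `image_shape`, `noise_sd`), `traces`
#'     (arguments of [simulate_ratio_traces()]), `track` (`kind` plus
#'     [simulate_plate_track()] behavior parameters).}
#'   \item{analyze_video}{`input` TIFF path, or omitted to consume the
#'     simulated video; optional tuning parameters of [segment_states()].}
#'   \item{analyze_calcium}{`input` traces CSV, or omitted for the
#'     simulated traces; optional `baseline_window_s`, `smooth_s`.}
#'   \item{score_behavior}{`input` track CSV, or omitted; `assay` is
#'     "ttx" or "nacl".}
#' }
#'
#' @param config named list or JSON path.
#' @param out output directory (created if missing); overrides
#'   `config$out`.
#' @param seed integer seed; overrides `config$seed`.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out = NULL, seed = NULL) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.null(out)) config$out <- out
  if (!is.null(seed)) config$seed <- seed
  if (is.null(config$out)) stop("no output directory given", call. = FALSE)
  if (is.null(config$seed)) config$seed <- 1L
  config$seed <- as.integer(config$seed)

  # validate every stage's configuration before any compute
  sim_cfgs <- validate_pipeline_config(config)

  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(name) file.path(config$out, name)
  written <- character(0)
  note <- function(path) written <<- c(written, path)

  sim <- config$simulate
  if (!is.null(sim$video)) {
    posture <- simulate_posture_sequence(sim_cfgs$video)
    fs <- rasterize(posture,
                    pixel_size_mm = sim$video$pixel_size_mm %||% 0.01,
                    image_shape = sim$video$image_shape %||% c(128L, 128L),
                    noise_sd = sim$video$noise_sd %||% 0,
                    rng_seed = config$seed + 1L)
    write_frame_stack(fs, outfile("video.tif"))
    note(outfile("video.tif")); note(outfile("video.tif.json"))
    utils::write.csv(data.frame(frame = seq_along(posture$times),
                                time_s = posture$times,
                                true_state = posture$true_state),
                     outfile("video_true_states.csv"), row.names = FALSE)
    note(outfile("video_true_states.csv"))
    gt <- do.call(rbind, lapply(seq_along(posture$midlines), function(i) {
      p <- posture$midlines[[i]]
      data.frame(frame = i, time_s = posture$times[i],
                 point_index = seq_len(nrow(p)),
                 x_mm = p[, 1], y_mm = p[, 2])
    }))
    utils::write.csv(gt, outfile("video_true_midlines.csv"),
                     row.names = FALSE)
    note(outfile("video_true_midlines.csv"))
  }
  if (!is.null(sim$traces)) {
    args <- sim$traces
    args$seed <- args$seed %||% (config$seed + 2L)
    traces <- do.call(simulate_ratio_traces, args)
    write_traces_csv(traces, outfile("traces.csv"))
    note(outfile("traces.csv"))
  }
  if (!is.null(sim$track)) {
    args <- sim$track
    kind <- args$kind %||% "thermotaxis"
    args$kind <- NULL
    track <- simulate_plate_track(kind, args,
                                  seed = args$seed %||% (config$seed + 3L))
    write_track_csv(track, outfile("track.csv"))
    note(outfile("track.csv")); note(outfile("track.csv.json"))
  }

  if (!is.null(config$analyze_video)) {
    av <- config$analyze_video
    input <- av$input %||% outfile("video.tif")
    if (!file.exists(input)) {
      stop("analyze_video input not found: ", input, call. = FALSE)
    }
    tune <- av[intersect(names(av),
                         c("body_width_mm", "min_sep_frac", "merge_gap_s",
                           "min_duration_s", "window_s", "max_shift",
                           "cor_floor", "min_persist_s"))]
    res <- do.call(analyze_video,
                   c(list(stack = input, K = av$K %||% 50L), tune))
    write_midlines_csv(res$midlines, outfile("midlines.csv"))
    note(outfile("midlines.csv"))
    write_map_csv(res$states$map, outfile("curvature_map.csv"))
    note(outfile("curvature_map.csv"))
    note(outfile("curvature_map.csv.json"))
    write_states_csv(res$states, outfile("states.csv"),
                     outfile("state_intervals.csv"))
    note(outfile("states.csv")); note(outfile("state_intervals.csv"))
    ts <- res$turn_stats
    jsonlite::write_json(list(n_events = ts$n_events,
                              mean_s = ts$mean_s, sem_s = ts$sem_s,
                              analysis_window_s = ts$analysis_window_s,
                              omega_onsets_s = ts$omega_onsets_s),
                         outfile("turn_statistics.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    note(outfile("turn_statistics.json"))
    render_map(res$states$map, res$states, file = outfile("kymograph.png"))
  }

  if (!is.null(config$analyze_calcium)) {
    ac <- config$analyze_calcium
    input <- ac$input %||% outfile("traces.csv")
    if (!file.exists(input)) {
      stop("analyze_calcium input not found: ", input, call. = FALSE)
    }
    traces <- read_traces_csv(input)
    done <- lapply(traces, ratio_change,
                   baseline_window_s = ac$baseline_window_s)
    gs <- group_summary(done, smooth_s = ac$smooth_s %||% 0)
    utils::write.csv(data.frame(time_s = gs$time_s,
                                mean_pct = gs$mean_pct,
                                sem_pct = gs$sem_pct),
                     outfile("ratio_change_mean.csv"), row.names = FALSE)
    note(outfile("ratio_change_mean.csv"))
    jsonlite::write_json(list(max_ratio_change_mean = gs$max_mean,
                              max_ratio_change_sem = gs$max_sem,
                              max_per_trace = gs$max_per_trace,
                              n = gs$n),
                         outfile("ratio_summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    note(outfile("ratio_summary.json"))
  }

  if (!is.null(config$score_behavior)) {
    sb <- config$score_behavior
    input <- sb$input %||% outfile("track.csv")
    if (!file.exists(input)) {
      stop("score_behavior input not found: ", input, call. = FALSE)
    }
    track <- read_track_csv(input)
    assay <- sb$assay %||%
      (if (identical(track$kind, "nacl")) "nacl" else "ttx")
    score <- if (assay == "ttx") {
      s <- classify_thermotaxis(track,
                                visit_frac = sb$visit_frac %||% 0.10)
      c(list(assay = "ttx"), s)
    } else {
      s <- classify_nacl(track)
      c(list(assay = "nacl"), s)
    }
    jsonlite::write_json(score, outfile("behavior_score.json"),
                         auto_unbox = TRUE, digits = NA)
    note(outfile("behavior_score.json"))
  }

  manifest <- list(
    package = "wormkymo",
    version = as.character(utils::packageVersion("wormkymo")),
    seed = config$seed,
    config = config[setdiff(names(config), "out")],
    outputs = lapply(sort(unique(written)), function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  manifest$manifest_hash <- manifest_hash(manifest)
  jsonlite::write_json(manifest, outfile("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic hash of a manifest: MD5 of its canonical JSON text
# (excluding the hash field itself and any absolute paths).
manifest_hash <- function(manifest) {
  manifest$manifest_hash <- NULL
  txt <- jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(txt, tf)
  unname(tools::md5sum(tf))
}

# Schema validation: build every sim_config up front so malformed
# parameters (negative frame rates etc.) fail before any compute.
validate_pipeline_config <- function(config) {
  out <- list()
  if (!is.null(config$simulate$video)) {
    v <- config$simulate$video
    fields <- intersect(names(v), names(formals(sim_config)))
    v <- v[fields]
    if (is.null(v$rng_seed)) v$rng_seed <- config$seed
    out$video <- do.call(sim_config, v)
  }
  if (!is.null(config$simulate$traces)) {
    tr <- config$simulate$traces
    if (!is.null(tr$noise_snr) && tr$noise_snr < 0) {
      stop("'noise_snr' must be >= 0", call. = FALSE)
    }
    if (!is.null(tr$bleach_rate) && tr$bleach_rate < 0) {
      stop("'bleach_rate' must be >= 0", call. = FALSE)
    }
  }
  if (!is.null(config$simulate$track)) {
    tk <- config$simulate$track
    if (!is.null(tk$plate_radius_mm) && tk$plate_radius_mm <= 0) {
      stop("'plate_radius_mm' must be > 0", call. = FALSE)
    }
  }
  out
}
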