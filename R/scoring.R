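#' Classify a track on a radial thermotaxis plate
#'
#' Assigns one of the four radial-gradient categories — '17' (moved to the
#' cold center), '20' (intermediate cultivation-temperature ring), '25'
#' (warm periphery) or '17/25' (moved around both cold and warm regions) —
#' from zone occupancies. A zone counts as visited when the track spends at
#' least `visit_frac` of its time there. '17/25' requires both the 17- and
#' 25-zones to be visited; otherwise the visited zone with the largest
#' occupancy wins. Tracks visiting no zone are labeled by the zone with the
#' largest (sub-threshold) occupancy, or by the zone nearest the track's
#' mean temperature, and flagged low-confidence.
#'
#' The default gradient is linear, 17 degC at the plate center to 25 degC
#' at the periphery; supply `temperature_fn` for measured (non-linear)
#' plate gradients.
#'
#' @param track a `plate_track` with a gradient.
#' @param zones named list of temperature intervals; default
#'   list('17' = c(-Inf, 18.5), '20' = c(19, 21), '25' = c(23.5, Inf)).
#' @param visit_frac occupancy threshold for "visited", default 0.10.
#' @param temperature_fn optional function radius_mm -> degC overriding the
#'   linear gradient.
#' @return List with `category`, `occupancies` (named, in [0,1]),
#'   `low_confidence`.
#' @export
classify_thermotaxis <- function(track, zones = NULL, visit_frac = 0.10,
                                 temperature_fn = NULL) {
  stopifnot(inherits(track, "plate_track"))
  if (is.null(track$gradient) && is.null(temperature_fn)) {
    stop("track has no temperature gradient", call. = FALSE)
  }
  if (is.null(zones)) {
    zones <- list("17" = c(-Inf, 18.5), "20" = c(19, 21),
                  "25" = c(23.5, Inf))
  }
  r <- sqrt(track$x_mm^2 + track$y_mm^2)
  temp <- if (!is.null(temperature_fn)) {
    temperature_fn(r)
  } else {
    g <- track$gradient
    g$t_center + (g$t_edge - g$t_center) * r / track$plate_radius_mm
  }
  occ <- vapply(zones, function(z) mean(temp >= z[1] & temp <= z[2]), 0)
  visited <- occ >= visit_frac

  low_conf <- FALSE
  category <- if (visited["17"] && visited["25"]) {
    "17/25"
  } else if (any(visited)) {
    names(which.max(occ[visited]))
  } else if (any(occ > 0)) {
    low_conf <- TRUE
    names(which.max(occ))
  } else {
    low_conf <- TRUE
    mid <- vapply(zones, function(z) {
      z[!is.finite(z)] <- NA
      mean(z, na.rm = TRUE)
    }, 0)
    names(which.min(abs(mid - mean(temp))))
  }
  list(category = category, occupancies = occ, low_confidence = low_conf)
}

#' Chemotaxis index
#'
#' CI = (animals at the odorant spot - animals at the control spot) /
#' total animals, in [-1, 1].
#'
#' @param n_at_odorant count at the attractant region.
#' @param n_at_control count at the control region.
#' @param n_total total animals on the plate (> 0).
#' @return The chemotaxis index.
#' @examples
#' chemotaxis_index(55, 20, 100)  # 0.35
#' @export
chemotaxis_index <- function(n_at_odorant, n_at_control, n_total) {
  if (any(c(n_at_odorant, n_at_control, n_total) < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (n_total <= 0) stop("'n_total' must be > 0", call. = FALSE)
  if (n_at_odorant + n_at_control > n_total) {
    stop("region counts exceed the total", call. = FALSE)
  }
  (n_at_odorant - n_at_control) / n_total
}

#' Classify a track on an NaCl gradient plate
#'
#' Counts distinct entries into the concentration-peak region (entries
#' separated by at least `min_excursion_s` outside) and total dwell there.
#' 'normal': migrated repeatedly to the peak (>= 2 entries) or remained
#' there (dwell >= `long_dwell_frac` of the assay). 'partial': a single
#' entry with shorter dwell. 'defective': never reached the peak.
#'
#' @param track a `plate_track` with a peak region.
#' @param peak optional override: list(x, y, radius_mm), default the
#'   track's peak (radius 5 mm).
#' @param min_excursion_s minimum time outside the peak for a re-entry to
#'   count as distinct, default 30.
#' @param long_dwell_frac dwell fraction counting as "remained at the
#'   peak", default 0.5.
#' @return List with `category` ("normal"/"partial"/"defective"),
#'   `n_entries`, `dwell_frac`.
#' @export
classify_nacl <- function(track, peak = NULL, min_excursion_s = 30,
                          long_dwell_frac = 0.5) {
  stopifnot(inherits(track, "plate_track"))
  if (is.null(peak)) peak <- track$peak
  if (is.null(peak)) stop("no peak region defined", call. = FALSE)
  if (sqrt(peak$x^2 + peak$y^2) > track$plate_radius_mm) {
    stop("peak lies outside the plate", call. = FALSE)
  }
  radius <- if (is.null(peak$radius_mm)) 5 else peak$radius_mm
  inside <- sqrt((track$x_mm - peak$x)^2 + (track$y_mm - peak$y)^2) <=
    radius
  dt <- stats::median(diff(track$time_s))
  dwell_frac <- mean(inside)

  r <- rle(inside)
  n_entries <- 0L
  outside_run <- Inf                       # time outside before first entry
  for (i in seq_along(r$values)) {
    if (r$values[i]) {
      if (outside_run * dt >= min_excursion_s || n_entries == 0L) {
        n_entries <- n_entries + 1L
      }
      outside_run <- 0
    } else {
      outside_run <- outside_run + r$lengths[i]
    }
  }
  category <- if (n_entries >= 2L || dwell_frac >= long_dwell_frac) {
    "normal"
  } else if (n_entries == 1L) {
    "partial"
  } else {
    "defective"
  }
  list(category = category, n_entries = n_entries, dwell_frac = dwell_frac)
}

#' Per-category fraction summary across assays
#'
#' Computes, for each category, the fraction of animals per assay, then the
#' mean and SEM of those fractions across assays — the summary format used
#' for published per-genotype behavioral tables (e.g. mean fraction
#' 'normal' +/- SEM). With a single assay the SEM is reported as missing.
#'
#' @param assays a list of character vectors, one per assay, each giving
#'   the per-animal categories; or a single character vector (one assay).
#' @param categories category levels to report; defaults to the union
#'   observed.
#' @return data.frame(category, mean_fraction, sem, n_assays).
#' @examples
#' fraction_summary(list(rep(c("normal", "defective"), c(4, 1)),
#'                       rep("normal", 5)))
#' @export
fraction_summary <- function(assays, categories = NULL) {
  if (!is.list(assays)) assays <- list(assays)
  if (length(assays) == 0L || any(!lengths(assays))) {
    stop("each assay needs at least one animal", call. = FALSE)
  }
  if (is.null(categories)) {
    categories <- sort(unique(unlist(assays)))
  }
  frac <- vapply(assays, function(a) {
    vapply(categories, function(cc) mean(a == cc), 0)
  }, numeric(length(categories)))
  frac <- matrix(frac, nrow = length(categories))
  n <- length(assays)
  data.frame(category = categories,
             mean_fraction = rowMeans(frac),
             sem = if (n > 1L) apply(frac, 1, stats::sd) / sqrt(n) else
               NA_real_,
             n_assays = n,
             row.names = NULL)
}
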