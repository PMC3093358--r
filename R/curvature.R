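#' Signed per-segment curvature profile of a midline
#'
#' The tangent angle of each of the K-1 segments is taken from the segment
#' vector; curvature at interior junction i is the wrapped difference of
#' consecutive tangent angles, in degrees per body segment, positive for
#' counter-clockwise tangent rotation in the mm frame (head to tail).
#'
#' @param midline a `wk_midline` or a K x 2 point matrix (head first).
#' @return Numeric vector of K-2 signed curvatures (degrees), wrapped to
#'   (-180, 180].
#' @examples
#' arc <- cbind(cos(seq(0, 1, length.out = 50)),
#'              sin(seq(0, 1, length.out = 50)))
#' curvature_profile(arc)[1]
#' @export
curvature_profile <- function(midline) {
  p <- if (inherits(midline, "wk_midline")) {
    if (!isTRUE(midline$valid)) {
      stop("cannot compute curvature of an invalid midline", call. = FALSE)
    }
    midline$points
  } else {
    as.matrix(midline)
  }
  if (nrow(p) < 3L) stop("midline needs at least 3 points", call. = FALSE)
  seg <- diff(p)
  theta <- atan2(seg[, 2], seg[, 1])
  wrap_angle(diff(theta)) * 180 / pi
}

#' Build a spatio-temporal curvature map (kymograph matrix)
#'
#' Rows are frames, columns the K-2 interior body positions. Invalid frames
#' (and any frames in `extra_mask`, e.g. detected omega turns) are fully
#' masked; masking happens before smoothing. Smoothing is a 3 x 3 mean
#' filter in which masked entries are excluded and edge/partial
#' neighborhoods are renormalized over the available neighbors, so constant
#' maps are preserved exactly.
#'
#' @param midlines list of `wk_midline` objects (or `posture_sequence`
#'   midline matrices).
#' @param times frame times (seconds); defaults to the `times` attribute or
#'   frame index.
#' @param smooth apply the 3 x 3 mean filter (default TRUE).
#' @param extra_mask optional logical per-frame vector of additional frames
#'   to mask (e.g. omega candidates).
#' @return An object of class `curvature_map`: list with `values` (frames x
#'   positions, degrees; NA where masked), `mask` (TRUE = invalid/omega),
#'   `times`, `body_coords` (interior s in (0,1)), `display_range`
#'   c(-30, 30).
#' @export
build_map <- function(midlines, times = NULL, smooth = TRUE,
                      extra_mask = NULL) {
  if (inherits(midlines, "posture_sequence")) {
    times <- midlines$times
    midlines <- midlines$midlines
  }
  n <- length(midlines)
  if (n < 1L) stop("need at least one frame", call. = FALSE)
  if (is.null(times)) times <- attr(midlines, "times")
  if (is.null(times)) times <- seq_len(n) - 1

  get_pts <- function(m) {
    if (inherits(m, "wk_midline")) {
      if (isTRUE(m$valid)) m$points else NULL
    } else m
  }
  K <- NULL
  for (m in midlines) {
    p <- get_pts(m)
    if (!is.null(p)) { K <- nrow(p); break }
  }
  if (is.null(K)) stop("no valid frames", call. = FALSE)

  values <- matrix(NA_real_, n, K - 2L)
  maskv <- rep(TRUE, n)
  for (i in seq_len(n)) {
    p <- get_pts(midlines[[i]])
    if (!is.null(p)) {
      values[i, ] <- curvature_profile(p)
      maskv[i] <- FALSE
    }
  }
  if (!is.null(extra_mask)) {
    stopifnot(length(extra_mask) == n)
    maskv <- maskv | extra_mask
    values[maskv, ] <- NA_real_
  }
  mask <- matrix(maskv, n, K - 2L)
  if (smooth) values <- smooth_map_3x3(values)
  structure(list(values = values, mask = mask, times = times,
                 body_coords = seq_len(K - 2L) / (K - 1L),
                 display_range = c(-30, 30)),
            class = "curvature_map")
}

# Masked 3x3 mean filter with renormalization over available neighbors.
smooth_map_3x3 <- function(v) {
  n <- nrow(v); m <- ncol(v)
  acc <- matrix(0, n, m)
  wt <- matrix(0, n, m)
  vz <- v
  vz[is.na(vz)] <- 0
  ok <- !is.na(v)
  for (dr in -1:1) {
    rs <- seq_len(n) + dr
    rok <- rs >= 1 & rs <= n
    for (dc in -1:1) {
      cs <- seq_len(m) + dc
      cok <- cs >= 1 & cs <= m
      acc[rok, cok] <- acc[rok, cok] + vz[rs[rok], cs[cok]]
      wt[rok, cok] <- wt[rok, cok] + ok[rs[rok], cs[cok]]
    }
  }
  out <- acc / wt
  out[!ok] <- NA_real_   # smoothing never unmasks
  out[ok & wt == 0] <- v[ok & wt == 0]
  out
}

#' @export
print.curvature_map <- function(x, ...) {
  cat("Curvature map:", nrow(x$values), "frames x", ncol(x$values),
      "body positions;", sum(x$mask[, 1]), "masked frames\n")
  invisible(x)
}

# Row-wise Pearson correlations between curvature profiles `step` frames
# apart at body shifts -max_shift..max_shift. Returns (n-step) x
# (2*max_shift+1); row t compares frames t and t+step.
# Each column's temporal mean (over unmasked rows) is removed first: static
# per-position components (extraction artifacts, mean posture) correlate
# fully at zero shift and would otherwise swamp the travel of the
# undulatory wave. `step` should be large enough that the wave moves at
# least one body position between the compared frames.
shift_correlations <- function(prof, max_shift = 10L, step = 1L) {
  cm <- colMeans(prof, na.rm = TRUE)
  cm[!is.finite(cm)] <- 0
  prof <- sweep(prof, 2, cm)
  n <- nrow(prof); M <- ncol(prof)
  step <- min(step, n - 1L)
  shifts <- -max_shift:max_shift
  out <- matrix(NA_real_, n - step, length(shifts))
  A_all <- prof[seq_len(n - step), , drop = FALSE]
  B_all <- prof[seq_len(n - step) + step, , drop = FALSE]
  for (k in seq_along(shifts)) {
    d <- shifts[k]
    i0 <- max(1L, 1L - d); i1 <- min(M, M - d)
    if (i1 - i0 + 1L < 5L) next
    A <- A_all[, i0:i1, drop = FALSE]
    B <- B_all[, (i0 + d):(i1 + d), drop = FALSE]
    mA <- rowMeans(A); mB <- rowMeans(B)
    cv <- rowMeans(A * B) - mA * mB
    sA <- rowMeans(A^2) - mA^2
    sB <- rowMeans(B^2) - mB^2
    den <- sqrt(pmax(sA, 0) * pmax(sB, 0))
    r <- cv / den
    r[!is.finite(r)] <- NA_real_
    out[, k] <- r
  }
  out
}

#' Render a curvature map with state bars
#'
#' Draws the kymograph with a diverging blue-white-red colormap clipped to
#' the display range (default -30..30 degrees per segment), masked (omega)
#' frames as white stripes, a colorbar, and, when a `state_track` is given,
#' black bars above the map for forward intervals and below for backward.
#'
#' @param map a `curvature_map`.
#' @param states optional `state_track` aligned to the map rows.
#' @param file optional PNG output path; if NULL, draws on the current
#'   device.
#' @param width,height PNG size in pixels.
#' @return `file` (or NULL), invisibly.
#' @export
render_map <- function(map, states = NULL, file = NULL,
                       width = 1200, height = 400) {
  stopifnot(inherits(map, "curvature_map"))
  if (!is.null(states) &&
      length(states$labels) != nrow(map$values)) {
    stop("states are not aligned to the map rows", call. = FALSE)
  }
  if (!is.null(file)) {
    grDevices::png(file, width = width, height = height)
  }
  lim <- map$display_range
  z <- map$values
  z[] <- pmin(lim[2], pmax(lim[1], z))
  pal <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(255)
  op <- graphics::par(no.readonly = TRUE)
  on.exit({
    graphics::par(op)
    if (!is.null(file)) grDevices::dev.off()
  })
  graphics::layout(matrix(1:2, 1, 2), widths = c(6, 1))
  graphics::par(mar = c(4, 4, 2, 1))
  graphics::image(x = map$times, y = map$body_coords, z = z,
                  zlim = lim, col = pal, xlab = "time (s)",
                  ylab = "body position (head → tail)",
                  ylim = c(-0.12, 1.12), useRaster = FALSE)
  if (!is.null(states)) {
    iv <- states$intervals
    fw <- iv[iv$state == "FORWARD", , drop = FALSE]
    bw <- iv[iv$state == "BACKWARD", , drop = FALSE]
    if (nrow(fw)) graphics::rect(fw$start_s, 1.04, fw$end_s, 1.10,
                                 col = "black", border = NA)
    if (nrow(bw)) graphics::rect(bw$start_s, -0.10, bw$end_s, -0.04,
                                 col = "black", border = NA)
  }
  graphics::box()
  # colorbar
  graphics::par(mar = c(4, 1, 2, 3))
  graphics::image(x = 1, y = seq(lim[1], lim[2], length.out = 255),
                  z = matrix(seq(lim[1], lim[2], length.out = 255), 1),
                  zlim = lim, col = pal, xaxt = "n", xlab = "", ylab = "")
  graphics::mtext("curvature (deg/segment)", side = 4, line = 1.5,
                  cex = 0.8)
  invisible(file)
}

#' Write a curvature map as CSV plus JSON metadata
#'
#' @param map a `curvature_map`.
#' @param path CSV path for the values matrix; `<path>.json` receives
#'   times, body coordinates and mask.
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(map, path) {
  utils::write.csv(map$values, path, row.names = FALSE)
  jsonlite::write_json(list(times = map$times,
                            body_coords = map$body_coords,
                            masked_frames = which(map$mask[, 1]),
                            display_range = map$display_range),
                       paste0(path, ".json"), auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}
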