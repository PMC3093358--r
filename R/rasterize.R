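#' Rasterize a posture sequence into a synthetic video frame stack
#'
#' Draws the worm in each frame as a filled tube around the midline with a
#' smooth width profile: maximum width `body_length/12` at mid-body,
#' tapering to 40% of that at head and tail
#' (\eqn{w(s) = w_{max}(0.4 + 0.6\sin(\pi s))}). Background is 0, worm
#' foreground approaches 1, with a 1-pixel anti-aliased edge. Frames are
#' re-centered on the worm centroid (emulating a tracking stage that keeps
#' the animal in the field of view); set `center = FALSE` to rasterize in
#' absolute plate coordinates.
#'
#' @param posture a `posture_sequence` with midlines.
#' @param pixel_size_mm size of one pixel (mm); must be > 0.
#' @param image_shape integer c(rows, cols) of each frame.
#' @param noise_sd additive Gaussian intensity noise (0 = none).
#' @param frames optional integer vector of frame indices to rasterize.
#' @param center re-center each frame on the worm centroid (default TRUE).
#' @param rng_seed optional seed for the noise draw.
#' @return An object of class `frame_stack`: list with `frames` (list of
#'   row x col intensity matrices), `pixel_size_mm`, `frame_rate_hz`,
#'   `timestamps`.
#' @examples
#' ps <- simulate_posture_sequence(sim_config(duration_s = 0.2,
#'                                            omega_rate_per_s = 0,
#'                                            reversal_rate_per_s = 0))
#' fs <- rasterize(ps, pixel_size_mm = 0.01, image_shape = c(128, 128))
#' dim(fs$frames[[1]])
#' @export
rasterize <- function(posture, pixel_size_mm = 0.01,
                      image_shape = c(128L, 128L), noise_sd = 0,
                      frames = NULL, center = TRUE, rng_seed = NULL) {
  stopifnot(inherits(posture, "posture_sequence"))
  if (is.null(posture$midlines) || length(posture$midlines) == 0L) {
    stop("posture sequence has no midlines to rasterize", call. = FALSE)
  }
  if (!is.numeric(pixel_size_mm) || pixel_size_mm <= 0) {
    stop("'pixel_size_mm' must be > 0", call. = FALSE)
  }
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  nr <- as.integer(image_shape[1])
  nc <- as.integer(image_shape[2])
  if (is.null(frames)) frames <- seq_along(posture$midlines)
  if (length(frames) == 0L) stop("no frames to rasterize", call. = FALSE)

  L <- posture$config$body_length_mm
  K <- posture$config$n_midline_points
  s <- seq(0, 1, length.out = K)
  halfw_mm <- (L / 12) * (0.4 + 0.6 * sin(pi * s)) / 2
  halfw_px <- halfw_mm / pixel_size_mm

  draw <- function(i) {
    p <- posture$midlines[[i]]
    if (center) p <- sweep(p, 2, colMeans(p))
    px <- p[, 1] / pixel_size_mm + (nc + 1) / 2
    py <- (nr + 1) / 2 - p[, 2] / pixel_size_mm   # y up -> row down
    if (any(px - halfw_px < 0.5) || any(px + halfw_px > nc + 0.5) ||
        any(py - halfw_px < 0.5) || any(py + halfw_px > nr + 0.5)) {
      stop(sprintf("worm out of frame at frame %d", i), call. = FALSE)
    }
    raster_tube(cbind(px, py), halfw_px, nr, nc)
  }

  imgs <- lapply(frames, draw)
  if (noise_sd > 0) {
    add_noise <- function() {
      lapply(imgs, function(f) f + matrix(stats::rnorm(nr * nc, 0, noise_sd),
                                          nr, nc))
    }
    imgs <- if (is.null(rng_seed)) add_noise() else
      with_seed(rng_seed, add_noise())
  }

  structure(list(frames = imgs,
                 pixel_size_mm = pixel_size_mm,
                 frame_rate_hz = posture$config$frame_rate_hz,
                 timestamps = posture$times[frames]),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat("Frame stack:", length(x$frames), "frames of", d[1], "x", d[2],
      "px;", x$pixel_size_mm, "mm/px at", x$frame_rate_hz, "fps\n")
  invisible(x)
}

#' Write a frame stack as a multi-page TIFF with a JSON sidecar
#'
#' Intensities are clamped to [0, 1] for TIFF storage. The sidecar
#' (`<path>.json`) records `pixel_size_mm`, `frame_rate_hz` and timestamps.
#'
#' @param stack a `frame_stack`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  imgs <- lapply(stack$frames, function(f) {
    f[] <- pmin(1, pmax(0, f))
    f
  })
  tiff::writeTIFF(imgs, path, bits.per.sample = 16L)
  meta <- list(pixel_size_mm = stack$pixel_size_mm,
               frame_rate_hz = stack$frame_rate_hz,
               timestamps = stack$timestamps)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a frame stack written by [write_frame_stack()]
#'
#' @param path TIFF path; the `<path>.json` sidecar must exist.
#' @return A `frame_stack`.
#' @export
read_frame_stack <- function(path) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(imgs)) imgs <- list(imgs)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(frames = imgs,
                 pixel_size_mm = meta$pixel_size_mm,
                 frame_rate_hz = meta$frame_rate_hz,
                 timestamps = as.numeric(meta$timestamps)),
            class = "frame_stack")
}
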