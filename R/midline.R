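#' Segment the worm from a video frame
#'
#' Thresholds the frame (Otsu by default, or a fixed numeric threshold) and
#' keeps the largest connected foreground component, removing specks. An
#' empty mask is a flagged result, not an error.
#'
#' @param frame numeric intensity matrix.
#' @param threshold_policy `"otsu"` or a single numeric threshold.
#' @return Logical mask matrix with attribute `no_worm` (TRUE if empty).
#' @export
segment_worm <- function(frame, threshold_policy = "otsu") {
  if (!all(is.finite(frame))) {
    stop("frame must be finite-valued", call. = FALSE)
  }
  thr <- if (identical(threshold_policy, "otsu")) {
    rng <- range(frame)
    if (diff(rng) <= 0) Inf else
      EBImage::otsu(EBImage::Image(frame), range = rng)
  } else if (is.numeric(threshold_policy) &&
             length(threshold_policy) == 1L) {
    threshold_policy
  } else {
    stop("'threshold_policy' must be \"otsu\" or a number", call. = FALSE)
  }
  bw <- frame > thr
  if (!any(bw)) {
    return(structure(bw, no_worm = TRUE))
  }
  lab <- EBImage::bwlabel(bw)
  tab <- tabulate(as.integer(lab[lab > 0]))
  mask <- matrix(as.integer(lab) == which.max(tab), nrow(frame), ncol(frame))
  structure(mask, no_worm = FALSE)
}

# --- skeleton graph helpers (internal) --------------------------------------

# 8-neighbor offsets
.noff <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
               dc = c(-1, 0, 1, -1, 1, -1, 0, 1))

# Adjacency list for skeleton pixels using m-adjacency: orthogonal
# neighbors always connect; diagonal neighbors connect only when they do
# not already share an orthogonal skeleton neighbor (suppresses redundant
# staircase edges that would inflate pixel degrees). `coords` is n x 2
# (row, col).
skel_graph <- function(coords, nr, nc) {
  n <- nrow(coords)
  id <- matrix(0L, nr, nc)
  id[coords] <- seq_len(n)
  has <- function(rr, cc) {
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    out <- rep(FALSE, length(rr))
    out[ok] <- id[cbind(rr[ok], cc[ok])] > 0L
    out
  }
  adj <- vector("list", n)
  for (k in 1:8) {
    dr <- .noff[k, 1]; dc <- .noff[k, 2]
    rr <- coords[, 1] + dr
    cc <- coords[, 2] + dc
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    nb <- integer(n)
    nb[ok] <- id[cbind(rr[ok], cc[ok])]
    use <- nb > 0L
    if (dr != 0L && dc != 0L) {
      bridge <- has(coords[, 1], coords[, 2] + dc) |
        has(coords[, 1] + dr, coords[, 2])
      use <- use & !bridge
    }
    for (i in which(use)) adj[[i]] <- c(adj[[i]], nb[i])
  }
  adj
}

# BFS distances and predecessors from `start` over adjacency list.
skel_bfs <- function(adj, start) {
  n <- length(adj)
  dist <- rep(NA_integer_, n)
  pred <- rep(0L, n)
  dist[start] <- 0L
  queue <- start
  head <- 1L
  while (head <= length(queue)) {
    v <- queue[head]; head <- head + 1L
    for (w in adj[[v]]) {
      if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        pred[w] <- v
        queue <- c(queue, w)
      }
    }
  }
  list(dist = dist, pred = pred)
}

# Iteratively remove endpoint spurs shorter than `prune_len` pixels that end
# at a junction (degree > 2). Returns the surviving pixel indices.
prune_spurs <- function(adj, prune_len) {
  n <- length(adj)
  alive <- rep(TRUE, n)
  deg <- vapply(adj, length, 1L)
  repeat {
    ends <- which(alive & deg == 1L)
    removed_any <- FALSE
    for (e in ends) {
      if (!alive[e] || deg[e] != 1L) next
      # walk from the endpoint until a junction or a dead end
      path <- e
      prev <- 0L
      v <- e
      repeat {
        nbrs <- adj[[v]]
        nbrs <- nbrs[alive[nbrs] & nbrs != prev]
        if (length(nbrs) == 0L || length(path) > prune_len) break
        if (deg[nbrs[1]] > 2L) {     # reached a junction: spur confirmed
          if (length(path) <= prune_len) {
            alive[path] <- FALSE
            for (pxl in path) {
              for (w in adj[[pxl]]) deg[w] <- deg[w] - 1L
            }
            removed_any <- TRUE
          }
          break
        }
        prev <- v
        v <- nbrs[1]
        path <- c(path, v)
      }
    }
    if (!removed_any) break
  }
  which(alive)
}

#' Extract an ordered midline from a binary worm mask
#'
#' Thins the mask to a topological skeleton (Zhang-Suen), prunes spurs
#' shorter than one body width, and, if the pruned skeleton is a simple
#' endpoint-to-endpoint path, extends it into the mask tips, smooths it and
#' resamples it to `K` points at equal arc length. Frames where the worm
#' touches itself (omega turns) fail with `failure_reason` `self_contact`
#' or `skeleton_branch`; a path shorter than 70% of `expected_length_mm`
#' fails as `too_short`.
#'
#' Coordinates are mm with y increasing upward; index 1 is one body end
#' (head/tail identity is resolved later by [orient_and_track()]).
#'
#' @param mask logical matrix from [segment_worm()].
#' @param pixel_size_mm mm per pixel.
#' @param K number of midline points (>= 3), default 50.
#' @param expected_length_mm optional reference body length for the
#'   too-short rule (e.g. a running median over the video).
#' @param smooth_window moving-average window (skeleton pixels) applied
#'   before resampling, default 3.
#' @return An object of class `wk_midline`: list with `points` (K x 2 mm
#'   matrix or NULL), `valid`, `failure_reason` (one of none, self_contact,
#'   skeleton_branch, too_short, no_worm), `length_mm`.
#' @export
extract_midline <- function(mask, pixel_size_mm, K = 50L,
                            expected_length_mm = NULL, smooth_window = 3L) {
  if (K < 3L) stop("K must be >= 3", call. = FALSE)
  fail <- function(reason) {
    structure(list(points = NULL, valid = FALSE, failure_reason = reason,
                   length_mm = NA_real_), class = "wk_midline")
  }
  if (isTRUE(attr(mask, "no_worm")) || !any(mask)) return(fail("no_worm"))

  nr <- nrow(mask); nc <- ncol(mask)
  dmap <- EBImage::distmap(EBImage::Image(mask))
  body_width_px <- 2 * max(dmap)
  skel <- thin_mask(mask)
  coords <- which(skel, arr.ind = TRUE)
  if (nrow(coords) < 3L) return(fail("too_short"))

  adj <- skel_graph(coords, nr, nc)
  keep <- prune_spurs(adj, prune_len = max(3L, ceiling(body_width_px)))
  if (length(keep) < 3L) return(fail("too_short"))
  coords <- coords[keep, , drop = FALSE]
  adj <- skel_graph(coords, nr, nc)
  deg <- vapply(adj, length, 1L)
  ends <- which(deg == 1L)

  if (length(ends) == 0L) return(fail("self_contact"))
  if (length(ends) == 1L) return(fail("self_contact"))
  if (length(ends) > 2L) return(fail("skeleton_branch"))

  # path between the two farthest endpoints (double BFS)
  b1 <- skel_bfs(adj, ends[1])
  e1 <- ends[which.max(b1$dist[ends])]
  b2 <- skel_bfs(adj, e1)
  e2 <- ends[which.max(b2$dist[ends])]
  if (is.na(b2$dist[e2])) return(fail("self_contact"))
  path <- e2
  while (path[1] != e1) path <- c(b2$pred[path[1]], path)

  # pixels off the main path beyond staircase crumbs indicate an attached
  # loop (self contact) that survived pruning
  if (length(adj) - length(path) > max(3L, ceiling(body_width_px))) {
    return(fail("self_contact"))
  }

  pr <- coords[path, 1]
  pc <- coords[path, 2]

  # extend both ends into the tube tips: walk outward from the skeleton
  # endpoint following the ridge of the distance transform (steering a few
  # degrees per step toward the locally deepest pixel, which tracks curved
  # tails), stop at the mask boundary, and pull back by the endpoint's
  # medial radius to land on the centerline tip
  dval <- function(r, c) {
    ri <- round(r); ci <- round(c)
    if (ri < 1 || ri > nr || ci < 1 || ci > nc || !mask[ri, ci]) return(-1)
    dmap[ri, ci]
  }
  extend_end <- function(rr, cc, back_r, back_c, radius) {
    v <- c(rr - back_r, cc - back_c)
    nv <- sqrt(sum(v^2))
    if (nv == 0) return(NULL)
    v <- v / nv
    step <- 0.5
    max_len <- 2 * body_width_px
    pos <- c(rr, cc)
    pts <- NULL
    len <- 0
    rot <- function(u, a) c(cos(a) * u[1] - sin(a) * u[2],
                            sin(a) * u[1] + cos(a) * u[2])
    while (len < max_len) {
      cand <- list(v, rot(v, 0.35), rot(v, -0.35))
      sc <- vapply(cand, function(u)
        dval(pos[1] + u[1] * step, pos[2] + u[2] * step), 0)
      if (max(sc) < 0) break
      k <- which.max(sc - c(0, 1e-6, 1e-6))   # prefer straight on ties
      v <- cand[[k]]
      pos <- pos + v * step
      len <- len + step
      pts <- rbind(pts, pos)
    }
    keep <- len - radius
    if (keep <= 0) return(NULL)
    pts[seq_len(floor(keep / step)), , drop = FALSE]
  }
  nb <- min(4L, length(path) - 1L)
  head_ext <- extend_end(pr[1], pc[1], pr[1 + nb], pc[1 + nb],
                         dmap[pr[1], pc[1]])
  np <- length(path)
  tail_ext <- extend_end(pr[np], pc[np], pr[np - nb], pc[np - nb],
                         dmap[pr[np], pc[np]])
  if (!is.null(head_ext)) {
    pr <- c(rev(head_ext[, 1]), pr)
    pc <- c(rev(head_ext[, 2]), pc)
  }
  if (!is.null(tail_ext)) {
    pr <- c(pr, tail_ext[, 1])
    pc <- c(pc, tail_ext[, 2])
  }

  # pixel (row, col) -> mm (x right, y up)
  x <- (pc - 0.5) * pixel_size_mm
  y <- (nr - pr + 0.5) * pixel_size_mm
  x <- smooth_open_curve(x, smooth_window)
  y <- smooth_open_curve(y, smooth_window)
  pathlen <- polyline_length(cbind(x, y))

  if (!is.null(expected_length_mm) && is.finite(expected_length_mm) &&
      pathlen < 0.7 * expected_length_mm) {
    return(fail("too_short"))
  }
  pts <- resample_polyline(cbind(x, y), K)
  colnames(pts) <- c("x", "y")
  structure(list(points = pts, valid = TRUE, failure_reason = "none",
                 length_mm = pathlen),
            class = "wk_midline")
}

#' @export
print.wk_midline <- function(x, ...) {
  if (x$valid) {
    cat("Midline:", nrow(x$points), "points,", round(x$length_mm, 3), "mm\n")
  } else {
    cat("Midline: invalid (", x$failure_reason, ")\n")
  }
  invisible(x)
}

#' Extract midlines from every frame of a video
#'
#' Runs [segment_worm()] and [extract_midline()] per frame, maintaining a
#' running median of valid body lengths for the too-short rule, then
#' resolves head/tail identity with [orient_and_track()].
#'
#' @param stack a `frame_stack` (or list of frames with `pixel_size_mm`
#'   passed explicitly).
#' @param K midline points per frame.
#' @param threshold_policy passed to [segment_worm()].
#' @param orient resolve head/tail identity (default TRUE).
#' @return List of `wk_midline` objects with attributes `times` and
#'   `pixel_size_mm`.
#' @export
extract_midlines <- function(stack, K = 50L, threshold_policy = "otsu",
                             orient = TRUE) {
  stopifnot(inherits(stack, "frame_stack"))
  lengths_seen <- numeric(0)
  out <- vector("list", length(stack$frames))
  for (i in seq_along(stack$frames)) {
    mask <- segment_worm(stack$frames[[i]], threshold_policy)
    expected <- if (length(lengths_seen)) stats::median(lengths_seen) else NULL
    ml <- extract_midline(mask, stack$pixel_size_mm, K = K,
                          expected_length_mm = expected)
    if (ml$valid) {
      lengths_seen <- c(lengths_seen, ml$length_mm)
      if (length(lengths_seen) > 100L) {
        lengths_seen <- lengths_seen[-1]
      }
    }
    out[[i]] <- ml
  }
  attr(out, "times") <- stack$timestamps
  attr(out, "pixel_size_mm") <- stack$pixel_size_mm
  if (orient) out <- orient_and_track(out)
  out
}

#' Resolve consistent head-to-tail orientation across frames
#'
#' Per-frame orientation is chosen by nearest-endpoint matching against the
#' previous valid frame (re-matching across invalid omega gaps uses the last
#' valid frame). Global polarity is then fixed so that, during the longest
#' run of consistent wave propagation, the designated head end leads the net
#' centroid displacement. If the recording carries no usable net
#' displacement (e.g. stage-centered video, where the centroid is pinned to
#' the field center), polarity falls back to the mostly-forward assumption
#' — the dominant wave direction is head to tail — applied independently to
#' each contiguous run of valid frames, because nearest-endpoint matching
#' cannot be trusted across omega gaps (the posture reorganizes
#' completely); the result is flagged `low_confidence`.
#'
#' @param midlines list of `wk_midline` objects (attribute `times` optional).
#' @return The midline list, consistently oriented, with attributes
#'   `polarity_method` ("displacement" or "wave_majority") and
#'   `low_confidence`.
#' @export
orient_and_track <- function(midlines) {
  valid <- which(vapply(midlines, function(m) isTRUE(m$valid), TRUE))
  if (length(valid) == 0L) {
    stop("no valid midlines to orient", call. = FALSE)
  }
  flip <- function(m) { m$points <- m$points[rev(seq_len(nrow(m$points))), ]; m }

  # sequential nearest-endpoint alignment
  for (k in seq_along(valid)[-1]) {
    prev <- midlines[[valid[k - 1]]]$points
    cur <- midlines[[valid[k]]]$points
    d_same <- sum((cur - prev)^2)
    d_flip <- sum((cur[rev(seq_len(nrow(cur))), ] - prev)^2)
    if (d_flip < d_same) {
      midlines[[valid[k]]] <- flip(midlines[[valid[k]]])
    }
  }

  if (length(valid) < 3L) {
    attr(midlines, "polarity_method") <- "single_frame"
    attr(midlines, "low_confidence") <- TRUE
    return(midlines)
  }

  K <- nrow(midlines[[valid[1]]]$points)
  prof <- t(vapply(valid, function(i) curvature_profile(midlines[[i]]),
                   numeric(K - 2L)))
  sgn <- wave_shift_sign(prof)
  runs <- rle(sgn)
  usable <- which(runs$values != 0 & !is.na(runs$values))
  if (!length(usable)) {
    attr(midlines, "polarity_method") <- "undetermined"
    attr(midlines, "low_confidence") <- TRUE
    return(midlines)
  }

  # longest run of consistent wave propagation = candidate forward run
  best <- usable[which.max(runs$lengths[usable])]
  hi <- cumsum(runs$lengths)[best]
  lo <- hi - runs$lengths[best] + 1L
  fr <- valid[lo:hi]
  cent <- t(vapply(fr, function(i) colMeans(midlines[[i]]$points),
                   numeric(2)))
  D <- cent[nrow(cent), ] - cent[1, ]
  L <- stats::median(vapply(fr, function(i)
    polyline_length(midlines[[i]]$points), 0))

  if (sqrt(sum(D^2)) > 0.05 * L) {
    # the candidate forward run is taken as FORWARD, so the head is the
    # end that leads the net displacement; flip if that end is last
    Dh <- D / sqrt(sum(D^2))
    proj_first <- mean(vapply(fr, function(i) {
      p <- midlines[[i]]$points
      sum((p[1, ] - colMeans(p)) * Dh)
    }, 0))
    proj_last <- mean(vapply(fr, function(i) {
      p <- midlines[[i]]$points
      sum((p[nrow(p), ] - colMeans(p)) * Dh)
    }, 0))
    if (proj_first < proj_last) {
      midlines <- lapply(midlines, function(m) if (isTRUE(m$valid))
        flip(m) else m)
    }
    attr(midlines, "polarity_method") <- "displacement"
    attr(midlines, "low_confidence") <- FALSE
    return(midlines)
  }

  # stage-centered recording: per-segment mostly-forward polarity
  seg_id <- cumsum(c(1L, diff(valid) > 1L))
  for (sid in unique(seg_id)) {
    rows <- which(seg_id == sid)
    if (length(rows) < 2L) next
    seg_sgn <- wave_shift_sign(prof[rows, , drop = FALSE])
    if (sum(seg_sgn > 0, na.rm = TRUE) < sum(seg_sgn < 0, na.rm = TRUE)) {
      for (i in valid[rows]) midlines[[i]] <- flip(midlines[[i]])
    }
  }
  attr(midlines, "polarity_method") <- "wave_majority"
  attr(midlines, "low_confidence") <- TRUE
  midlines
}

# Per-frame sign of the dominant body-wave shift between profile rows a
# few frames apart: +1 = wave moves toward higher indices (toward the tail
# under correct polarity), -1 = toward lower, 0 = ambiguous.
wave_shift_sign <- function(prof, max_shift = 5L, step = 3L) {
  n <- nrow(prof)
  if (n < 2L) return(rep(0L, n))
  step <- min(step, n - 1L)
  cc <- shift_correlations(prof, max_shift, step = step)
  best <- apply(cc, 1, function(z) {
    if (all(is.na(z))) return(0L)
    as.integer(sign(which.max(z) - (max_shift + 1L)))
  })
  c(best, rep(best[length(best)], step))  # pad to n frames
}

#' Write per-frame midlines to CSV
#'
#' Long format: frame, valid, failure_reason, point_index, x_mm, y_mm
#' (invalid frames contribute a single row with empty coordinates).
#'
#' @param midlines list of `wk_midline` objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_midlines_csv <- function(midlines, path) {
  rows <- lapply(seq_along(midlines), function(i) {
    m <- midlines[[i]]
    if (isTRUE(m$valid)) {
      data.frame(frame = i, valid = TRUE, failure_reason = "none",
                 point_index = seq_len(nrow(m$points)),
                 x_mm = m$points[, 1], y_mm = m$points[, 2])
    } else {
      data.frame(frame = i, valid = FALSE, failure_reason = m$failure_reason,
                 point_index = NA_integer_, x_mm = NA_real_, y_mm = NA_real_)
    }
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read midlines written by [write_midlines_csv()]
#'
#' @param path CSV path.
#' @return List of `wk_midline` objects.
#' @export
read_midlines_csv <- function(path) {
  df <- utils::read.csv(path)
  lapply(split(df, df$frame)[as.character(sort(unique(df$frame)))],
         function(d) {
           if (isTRUE(d$valid[1])) {
             pts <- cbind(x = d$x_mm, y = d$y_mm)
             structure(list(points = pts, valid = TRUE,
                            failure_reason = "none",
                            length_mm = polyline_length(pts)),
                       class = "wk_midline")
           } else {
             structure(list(points = NULL, valid = FALSE,
                            failure_reason = d$failure_reason[1],
                            length_mm = NA_real_),
                       class = "wk_midline")
           }
         })
}
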