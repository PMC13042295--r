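# Frame-sequence container and label-mask file I/O.
#
# A label mask is an integer matrix indexed (row, col) with the image
# convention: row 1 is the top of the image, row index increases downward.
# Class codes follow MASK_CLASSES.

#' Create a frame sequence
#'
#' Bundles an ordered list of label masks with its temporal and spatial
#' calibration. All frames must share one shape; timestamps are derived from
#' the frame interval.
#'
#' @param frames List of integer matrices (label masks), one per timepoint.
#' @param dt Frame interval in minutes (default 15).
#' @param scale Spatial calibration in mm per pixel (default 0.04).
#' @return An object of class `frame_sequence` with elements `frames`, `dt`
#'   (minutes), `scale` (mm/px) and `time_h` (hours from start).
#' @export
frame_sequence <- function(frames, dt = 15, scale = 0.04) {
  if (!is.list(frames) || length(frames) == 0L)
    stop("`frames` must be a non-empty list of label matrices")
  if (dt <= 0) stop("`dt` must be positive (minutes)")
  if (scale <= 0) stop("`scale` must be positive (mm/px)")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must have identical dimensions")
  structure(
    list(
      frames = frames,
      dt = dt,
      scale = scale,
      time_h = (seq_along(frames) - 1) * dt / 60
    ),
    class = "frame_sequence"
  )
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "<frame_sequence> %d frames of %dx%d px, dt = %g min, scale = %g mm/px (%.1f h)\n",
    length(x$frames), d[1], d[2], x$dt, x$scale, max(x$time_h)
  ))
  invisible(x)
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

#' Write a mask sequence to disk
#'
#' Frames are stored either as one 8-bit grayscale PNG per frame (pixel value
#' = class code) or as a single multi-page 8-bit TIFF stack.
#'
#' @param seq A `frame_sequence`.
#' @param path Output directory (PNG mode) or `.tif` file path (TIFF mode).
#' @param format `"png"` or `"tiff"`.
#' @return `path`, invisibly.
#' @export
write_mask_sequence <- function(seq, path, format = c("png", "tiff")) {
  format <- match.arg(format)
  if (format == "png") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(seq$frames)) {
      f <- file.path(path, sprintf("frame_%05d.png", i - 1L))
      png::writePNG(seq$frames[[i]] / 255, f)
    }
  } else {
    tiff::writeTIFF(lapply(seq$frames, function(m) m / 255), path,
                    bits.per.sample = 8L)
  }
  invisible(path)
}

#' Read a mask sequence from disk
#'
#' Inverse of [write_mask_sequence()]: reads per-frame grayscale PNGs from a
#' directory (sorted by file name) or a multi-page TIFF stack.
#'
#' @param path Directory of PNGs or a TIFF file.
#' @param dt Frame interval in minutes.
#' @param scale mm per pixel.
#' @return A `frame_sequence`.
#' @export
read_mask_sequence <- function(path, dt = 15, scale = 0.04) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (length(files) == 0L) stop("no PNG frames found in ", path)
    frames <- lapply(files, function(f) {
      m <- png::readPNG(f)
      if (length(dim(m)) == 3L) m <- m[, , 1]
      matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
    })
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    frames <- lapply(pages, function(m) {
      if (length(dim(m)) == 3L) m <- m[, , 1]
      matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
    })
  }
  frame_sequence(frames, dt = dt, scale = scale)
}

# ---- small pixel-geometry helpers shared across modules ----

# Bresenham line between two pixel centres; returns an n x 2 (row, col)
# matrix including both endpoints, 8-connected.
bresenham <- function(r0, c0, r1, c1) {
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- if (r0 < r1) 1L else -1L
  sc <- if (c0 < c1) 1L else -1L
  err <- dc - dr
  n <- max(dr, dc) + 1L
  out <- matrix(0L, n, 2L)
  r <- r0; c <- c0
  for (i in seq_len(n)) {
    out[i, ] <- c(r, c)
    if (r == r1 && c == c1) break
    e2 <- 2L * err
    if (e2 > -dr) { err <- err - dr; c <- c + sc }
    if (e2 < dc)  { err <- err + dc; r <- r + sr }
  }
  out[seq_len(i), , drop = FALSE]
}

# Integer offsets of a Euclidean disk of given radius (centre included).
disk_offsets <- function(radius) {
  v <- -ceiling(radius):ceiling(radius)
  g <- expand.grid(dr = v, dc = v)
  g <- g[g$dr^2 + g$dc^2 <= radius^2 + 1e-9, ]
  as.matrix(g)
}

# Stamp class `value` at pixel set (n x 2 rows/cols) dilated by `offsets`
# into integer matrix `canvas`, never overwriting classes listed in
# `protect`. Returns modified canvas.
stamp_pixels <- function(canvas, px, offsets, value, protect = integer(0)) {
  if (nrow(px) == 0L) return(canvas)
  nr <- nrow(canvas); nc <- ncol(canvas)
  rr <- rep(px[, 1], each = nrow(offsets)) + offsets[, 1]
  cc <- rep(px[, 2], each = nrow(offsets)) + offsets[, 2]
  keep <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
  idx <- unique(rr[keep] + (cc[keep] - 1L) * nr)
  if (length(protect)) idx <- idx[!(canvas[idx] %in% protect)]
  canvas[idx] <- value
  canvas
}

# Geodesic arc length of an ordered pixel path: per-step Euclidean distance
# (1 for axial, sqrt(2) for diagonal 8-neighbour steps; larger jumps, e.g.
# across a junction cluster, count their true distance).
path_arc_px <- function(path) {
  if (is.null(path) || nrow(path) < 2L) return(0)
  d <- diff(path)
  sum(sqrt(d[, 1]^2 + d[, 2]^2))
}

# Cumulative arc length along the path (first entry 0).
path_cum_arc <- function(path) {
  if (nrow(path) < 2L) return(rep(0, nrow(path)))
  d <- diff(path)
  c(0, cumsum(sqrt(d[, 1]^2 + d[, 2]^2)))
}

# Sub-pixel arc length: a centred moving average (window 5) of the pixel
# coordinates estimates the smooth centreline, removing the length
# inflation of raster zigzags (straight runs are unaffected since averages
# of collinear points stay on the line).
path_smooth <- function(path, half = 2L) {
  n <- nrow(path)
  if (n < 2L * half + 1L) return(path)
  sm <- apply(path, 2, function(x) {
    vapply(seq_len(n), function(i)
      mean(x[max(1L, i - half):min(n, i + half)]), numeric(1))
  })
  # keep the true endpoints
  sm[1, ] <- path[1, ]; sm[n, ] <- path[n, ]
  sm
}

path_smooth_arc_px <- function(path) {
  path_arc_px(path_smooth(path))
}
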