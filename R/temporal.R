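# Temporal consistency smoothing of label-mask sequences and per-ROI binary
# refinement.
#
# Root classes are stabilized with a weighted trailing average of the binary
# per-class masks, a^t = s^t + alpha * a^(t-1), thresholded at tau to give the
# smoothed presence. Droplets and other one-frame artifacts then decay away
# while persistent structure is retained.

#' Default trailing-average weight for a frame interval
#'
#' The weight is tied to wall-clock time with a one-hour half-life:
#' `alpha = 0.5^(dt/60)`, so a 15-min cadence gives about 0.841.
#'
#' @param dt Frame interval, minutes.
#' @return Weight in `[0, 1)`.
#' @export
default_alpha <- function(dt) 0.5^(dt / 60)

#' Trailing-average temporal accumulation
#'
#' Applies the recurrence `a^t = s^t + alpha * a^(t-1)` (with `a^1 = s^1`)
#' independently to the binary mask of each listed class and replaces the
#' class presence with `a^t >= tau`. Classes not listed pass through
#' bit-identically. With `tau = 1` every currently-observed pixel is kept and
#' pixels with sufficiently sustained history survive brief dropouts; with
#' `alpha = 0` the sequence is returned unchanged.
#'
#' @param seq A [frame_sequence()].
#' @param alpha Weight in `[0, 1)`; default [default_alpha()] of `seq$dt`.
#' @param classes Class ids to smooth (default main and lateral roots, 1:2).
#' @param tau Presence threshold on the accumulator (default 1).
#' @return A smoothed `frame_sequence` of the same shape and length.
#' @export
accumulate_trailing <- function(seq, alpha = NULL, classes = c(1L, 2L),
                                tau = 1) {
  stopifnot(inherits(seq, "frame_sequence"))
  if (length(seq$frames) == 0L) stop("empty sequence")
  if (is.null(alpha)) alpha <- default_alpha(seq$dt)
  if (alpha < 0 || alpha >= 1) stop("alpha must be in [0, 1)")
  classes <- as.integer(classes)
  acc <- lapply(classes, function(k) (seq$frames[[1]] == k) * 1.0)
  out <- vector("list", length(seq$frames))
  for (t in seq_along(seq$frames)) {
    f <- seq$frames[[t]]
    if (t > 1L) {
      for (j in seq_along(classes))
        acc[[j]] <- (f == classes[j]) + alpha * acc[[j]]
    }
    g <- f
    g[g %in% classes] <- 0L
    for (j in seq_along(classes)) {
      sel <- acc[[j]] >= tau & g == 0L
      g[sel] <- classes[j]
    }
    out[[t]] <- g
  }
  frame_sequence(out, dt = seq$dt, scale = seq$scale)
}

#' Refine the root mask inside a region of interest
#'
#' Crops the ROI, binarizes the root classes (main + lateral), applies a 3x3
#' morphological closing to bridge 1-px gaps, and keeps the single connected
#' component associated with the origin hint (the component containing the
#' hint, else the one nearest to it; ties broken by larger area, then
#' topmost-leftmost centroid). All other components are removed.
#'
#' @param mask Integer label matrix.
#' @param roi `c(r0, c0, r1, c1)`, 1-based inclusive rectangle.
#' @param origin_hint `c(row, col)` in full-frame coordinates (the root
#'   starting position, typically just below the seed).
#' @param root_classes Classes treated as root (default `c(1, 2)`).
#' @return Logical matrix of ROI size with attributes `offset` (`c(r0, c0)`)
#'   and `empty` (TRUE when no root pixels were found — flagged, not an
#'   error).
#' @export
refine_roi_mask <- function(mask, roi, origin_hint,
                            root_classes = c(1L, 2L)) {
  r0 <- roi[1]; c0 <- roi[2]; r1 <- roi[3]; c1 <- roi[4]
  if (r0 < 1 || c0 < 1 || r1 > nrow(mask) || c1 > ncol(mask) || r0 > r1 ||
      c0 > c1)
    stop("ROI outside frame")
  sub <- mask[r0:r1, c0:c1, drop = FALSE]
  bin <- matrix(sub %in% root_classes, nrow(sub), ncol(sub))
  hint <- c(origin_hint[1] - r0 + 1, origin_hint[2] - c0 + 1)
  if (!any(bin)) {
    return(structure(bin, offset = c(r0, c0), empty = TRUE))
  }
  closed <- EBImage::closing(EBImage::Image(bin * 1),
                             EBImage::makeBrush(3, shape = "box"))
  lab <- EBImage::bwlabel(closed)
  labm <- matrix(as.integer(lab), nrow(sub), ncol(sub))
  n_comp <- max(labm)
  if (n_comp == 1L) {
    out <- labm == 1L
    return(structure(out, offset = c(r0, c0), empty = FALSE))
  }
  # distance from hint to each component, plus tie-break keys
  px <- which(labm > 0L, arr.ind = TRUE)
  comp <- labm[labm > 0L]
  d2 <- (px[, 1] - hint[1])^2 + (px[, 2] - hint[2])^2
  stats <- do.call(rbind, lapply(seq_len(n_comp), function(k) {
    sel <- comp == k
    c(k = k, d = min(d2[sel]), area = sum(sel),
      cr = mean(px[sel, 1]), cc = mean(px[sel, 2]))
  }))
  ord <- order(stats[, "d"], -stats[, "area"], stats[, "cr"], stats[, "cc"])
  keep <- stats[ord[1], "k"]
  structure(labm == keep, offset = c(r0, c0), empty = FALSE)
}
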