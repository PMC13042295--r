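# Multi-plant screening: seed detection, SORT-style tracking (constant
# velocity Kalman filter + Hungarian data association), and quality control.

#' Detect seeds in a label mask
#'
#' One detection per connected component of the seed class with area inside
#' `[min_area, max_area]`; the centroid is the pixel mean. Components larger
#' than `max_area` (e.g. two seeds merged into one blob) are excluded and
#' flagged in the `oversized` attribute.
#'
#' @param mask Integer label matrix.
#' @param min_area,max_area Area gates in px^2.
#' @param class_id Class code for seeds (default 3).
#' @return Data frame with columns `id`, `cr`, `cc` (centroid row/col),
#'   `area`, `r0`, `c0`, `r1`, `c1` (bounding box, inclusive); attribute
#'   `oversized` holds excluded too-large components.
#' @export
detect_seeds <- function(mask, min_area = 5, max_area = Inf, class_id = 3L) {
  bin <- mask == class_id
  empty <- data.frame(id = integer(0), cr = numeric(0), cc = numeric(0),
                      area = numeric(0), r0 = integer(0), c0 = integer(0),
                      r1 = integer(0), c1 = integer(0))
  if (!any(bin)) return(structure(empty, oversized = empty))
  lab <- matrix(as.integer(EBImage::bwlabel(EBImage::Image(bin * 1))),
                nrow(mask), ncol(mask))
  px <- which(lab > 0L, arr.ind = TRUE)
  comp <- lab[lab > 0L]
  rows <- lapply(sort(unique(comp)), function(k) {
    sel <- comp == k
    data.frame(id = k, cr = mean(px[sel, 1]), cc = mean(px[sel, 2]),
               area = sum(sel),
               r0 = min(px[sel, 1]), c0 = min(px[sel, 2]),
               r1 = max(px[sel, 1]), c1 = max(px[sel, 2]))
  })
  det <- do.call(rbind, rows)
  oversized <- det[det$area > max_area, , drop = FALSE]
  det <- det[det$area >= min_area & det$area <= max_area, , drop = FALSE]
  rownames(det) <- NULL
  structure(det, oversized = oversized)
}

# ---- constant-velocity Kalman filter on state (x, y, vx, vy) ----
# Time unit is one frame. Velocity is initialized from the first two
# assigned detections (two-point initialization), after which the filter
# runs with the configured process / measurement noise.

kf_new <- function(z, sigma_p = 1, sigma_m = 2) {
  list(
    x = c(z[1], z[2], 0, 0),
    P = diag(c(sigma_m^2, sigma_m^2, 100, 100)),
    F = rbind(c(1, 0, 1, 0), c(0, 1, 0, 1), c(0, 0, 1, 0), c(0, 0, 0, 1)),
    H = rbind(c(1, 0, 0, 0), c(0, 1, 0, 0)),
    Q = diag(c(sigma_p^2 / 4, sigma_p^2 / 4, sigma_p^2, sigma_p^2)),
    R = diag(c(sigma_m^2, sigma_m^2)),
    n_updates = 1L
  )
}

kf_predict <- function(kf) {
  kf$x <- as.numeric(kf$F %*% kf$x)
  kf$P <- kf$F %*% kf$P %*% t(kf$F) + kf$Q
  kf
}

kf_update <- function(kf, z) {
  if (kf$n_updates == 1L) {
    # two-point velocity initialization: v = z2 - z1 (per frame)
    kf$x[3:4] <- z - kf$x[1:2] + kf$x[3:4]
    kf$x[1:2] <- z
    kf$n_updates <- 2L
    return(kf)
  }
  y <- z - as.numeric(kf$H %*% kf$x)
  # tiny jitter keeps the innovation covariance invertible when both noise
  # terms are zero (the noise-free filter is then an exact observer)
  S <- kf$H %*% kf$P %*% t(kf$H) + kf$R + diag(1e-12, 2)
  K <- kf$P %*% t(kf$H) %*% solve(S)
  kf$x <- kf$x + as.numeric(K %*% y)
  kf$P <- (diag(4) - K %*% kf$H) %*% kf$P
  kf$n_updates <- kf$n_updates + 1L
  kf
}

#' Track plants across frames
#'
#' SORT-style multi-object tracking: each track carries a constant-velocity
#' Kalman filter; at every frame predicted positions are associated with
#' detections by the Hungarian algorithm under a Euclidean gate, unassigned
#' detections start new tracks, and tracks unseen for more than `max_misses`
#' frames are marked lost. Track ids are never reused.
#'
#' @param detections List of per-frame detection data frames (as from
#'   [detect_seeds()]); one entry per frame, possibly with zero rows.
#' @param max_dist Association gate, px (default 50).
#' @param max_misses Frames a track may go unobserved before being lost
#'   (default 8, i.e. 2 h at 15-min cadence).
#' @param sigma_p,sigma_m Kalman process and measurement noise, px.
#' @return List of tracks; each has `id`, `status` (`active`/`lost`),
#'   `qc_reason` (`NA` until [qc_filter()]), `history` (data frame `frame`,
#'   `cr`, `cc`, `observed`, `pred_cr`, `pred_cc`) and `seed_bbox` (bbox of
#'   the first assigned detection).
#' @export
track_plants <- function(detections, max_dist = 50, max_misses = 8,
                         sigma_p = 1, sigma_m = 2) {
  tracks <- list()
  live <- integer(0)  # indices of active tracks
  for (t in seq_along(detections)) {
    det <- detections[[t]]
    nd <- if (is.null(det)) 0L else nrow(det)
    # predict
    for (i in live) {
      tracks[[i]]$kf <- kf_predict(tracks[[i]]$kf)
    }
    assigned_det <- rep(FALSE, nd)
    if (length(live) && nd > 0L) {
      preds <- t(vapply(tracks[live], function(tr) tr$kf$x[1:2], numeric(2)))
      cost <- matrix(Inf, length(live), nd)
      for (i in seq_along(live)) {
        d <- sqrt((preds[i, 1] - det$cr)^2 + (preds[i, 2] - det$cc)^2)
        cost[i, d <= max_dist] <- d[d <= max_dist]
      }
      sol <- hungarian_solve(cost)
      for (i in seq_along(live)) {
        j <- sol$assignment[i]
        if (!is.na(j) && is.finite(cost[i, j])) {
          idx <- live[i]
          tracks[[idx]]$kf <- kf_update(tracks[[idx]]$kf, c(det$cr[j], det$cc[j]))
          tracks[[idx]]$misses <- 0L
          tracks[[idx]]$history <- rbind(
            tracks[[idx]]$history,
            data.frame(frame = t, cr = det$cr[j], cc = det$cc[j],
                       observed = TRUE, pred_cr = preds[i, 1],
                       pred_cc = preds[i, 2]))
          assigned_det[j] <- TRUE
        }
      }
    }
    # unobserved live tracks coast on prediction
    for (i in live) {
      h <- tracks[[i]]$history
      if (nrow(h) == 0L || h$frame[nrow(h)] != t) {
        tracks[[i]]$misses <- tracks[[i]]$misses + 1L
        tracks[[i]]$history <- rbind(
          tracks[[i]]$history,
          data.frame(frame = t, cr = tracks[[i]]$kf$x[1],
                     cc = tracks[[i]]$kf$x[2], observed = FALSE,
                     pred_cr = tracks[[i]]$kf$x[1],
                     pred_cc = tracks[[i]]$kf$x[2]))
        if (tracks[[i]]$misses > max_misses) tracks[[i]]$status <- "lost"
      }
    }
    live <- which(vapply(tracks, function(tr) tr$status == "active",
                         logical(1)))
    # new tracks from unassigned detections
    if (nd > 0L) {
      for (j in which(!assigned_det)) {
        tracks[[length(tracks) + 1L]] <- list(
          id = length(tracks) + 1L, status = "active",
          qc_reason = NA_character_, misses = 0L,
          kf = kf_new(c(det$cr[j], det$cc[j]), sigma_p, sigma_m),
          seed_bbox = c(det$r0[j], det$c0[j], det$r1[j], det$c1[j]),
          history = data.frame(frame = t, cr = det$cr[j], cc = det$cc[j],
                               observed = TRUE, pred_cr = det$cr[j],
                               pred_cc = det$cc[j]))
        live <- c(live, length(tracks))
      }
    }
  }
  tracks
}

#' Quality-control filter for tracks
#'
#' Removes plants that touch each other or move abnormally. A track is marked
#' `qc_removed` with reason `"contact"` when its plant pixels share a
#' connected component (8-adjacency, classes 1-6) with another track's plant
#' in any frame, and `"motion"` when the observed frame-to-frame centroid
#' displacement exceeds `motion_thresh`. Surviving tracks keep their ids.
#'
#' @param tracks Output of [track_plants()].
#' @param seq The `frame_sequence` the tracks were computed on.
#' @param motion_thresh Max allowed centroid displacement, px per frame
#'   (default 40).
#' @param check_every Check contact on every k-th frame (default 4) for
#'   speed; displacement is always checked on all frames.
#' @return The track list with `status`/`qc_reason` updated (removed tracks
#'   get `status = "qc_removed"` plus `first_contact` when applicable).
#' @export
qc_filter <- function(tracks, seq, motion_thresh = 40, check_every = 4L) {
  # motion rule
  for (i in seq_along(tracks)) {
    h <- tracks[[i]]$history
    obs <- h[h$observed, , drop = FALSE]
    if (nrow(obs) >= 2L) {
      disp <- sqrt(diff(obs$cr)^2 + diff(obs$cc)^2) /
        pmax(1, diff(obs$frame))
      if (any(disp > motion_thresh)) {
        tracks[[i]]$status <- "qc_removed"
        tracks[[i]]$qc_reason <- "motion"
      }
    }
  }
  # contact rule
  check_frames <- unique(c(seq(1L, length(seq$frames), by = check_every),
                           length(seq$frames)))
  for (t in check_frames) {
    f <- seq$frames[[t]]
    bin <- f >= 1L & f <= 6L
    if (!any(bin)) next
    lab <- matrix(as.integer(EBImage::bwlabel(EBImage::Image(bin * 1))),
                  nrow(f), ncol(f))
    comp_of <- rep(NA_integer_, length(tracks))
    for (i in seq_along(tracks)) {
      if (tracks[[i]]$status == "qc_removed" &&
          tracks[[i]]$qc_reason == "motion") next
      h <- tracks[[i]]$history
      row <- h[h$frame == t, , drop = FALSE]
      if (nrow(row) == 0L) next
      r <- round(row$cr[1]); c <- round(row$cc[1])
      r <- min(max(r, 1L), nrow(f)); c <- min(max(c, 1L), ncol(f))
      if (lab[r, c] > 0L) {
        comp_of[i] <- lab[r, c]
      } else {
        # nearest plant pixel within 10 px of the centroid
        rr <- max(1L, r - 10L):min(nrow(f), r + 10L)
        cc <- max(1L, c - 10L):min(ncol(f), c + 10L)
        sub <- lab[rr, cc, drop = FALSE]
        if (any(sub > 0L)) {
          w <- which(sub > 0L, arr.ind = TRUE)
          d <- (rr[w[, 1]] - row$cr[1])^2 + (cc[w[, 2]] - row$cc[1])^2
          comp_of[i] <- sub[w[which.min(d), , drop = FALSE]]
        }
      }
    }
    dup <- comp_of[!is.na(comp_of)][duplicated(comp_of[!is.na(comp_of)])]
    if (length(dup)) {
      for (i in which(comp_of %in% dup)) {
        if (tracks[[i]]$status != "qc_removed") {
          tracks[[i]]$status <- "qc_removed"
          tracks[[i]]$qc_reason <- "contact"
          tracks[[i]]$first_contact <- t
        }
      }
    }
  }
  tracks
}
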