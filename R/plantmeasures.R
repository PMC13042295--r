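# Per-plant screening measurements: hypocotyl length with physiological
# validation, total plant area, simple root length, seed size.

# Longest geodesic path length (px) through a skeleton, via two sweeps of
# Dijkstra on the pixel adjacency graph (axial step 1, diagonal sqrt(2)).
skeleton_longest_path <- function(skel) {
  px <- which(skel)
  if (length(px) == 0L) return(0)
  if (length(px) == 1L) return(0)
  nr <- nrow(skel); n <- length(skel)
  id_of <- integer(n); id_of[px] <- seq_along(px)
  nbrs <- lapply(px, function(p) {
    nb <- skel_neighbors(p, skel)
    r0 <- (p - 1L) %% nr; c0 <- (p - 1L) %/% nr
    r1 <- (nb - 1L) %% nr; c1 <- (nb - 1L) %/% nr
    w <- ifelse(abs(r1 - r0) + abs(c1 - c0) == 2L, sqrt(2), 1)
    list(id = id_of[nb], w = w)
  })
  dijk <- function(src) {
    dist <- rep(Inf, length(px)); dist[src] <- 0
    done <- rep(FALSE, length(px))
    repeat {
      cand <- which(!done & is.finite(dist))
      if (!length(cand)) break
      v <- cand[which.min(dist[cand])]
      done[v] <- TRUE
      nb <- nbrs[[v]]
      upd <- dist[v] + nb$w < dist[nb$id]
      dist[nb$id[upd]] <- dist[v] + nb$w[upd]
    }
    dist
  }
  d1 <- dijk(1L)
  far <- which.max(ifelse(is.finite(d1), d1, -1))
  d2 <- dijk(far)
  max(d2[is.finite(d2)])
}

# Pixel rows/cols of a track's analysis region: the seed box expanded
# sideways a little and vertically a lot (roots grow down, hypocotyls up).
track_region <- function(track, dims, side = 20L, up = 150L, down = 300L) {
  bb <- track$seed_bbox
  list(rows = max(1L, bb[1] - up):min(dims[1], bb[3] + down),
       cols = max(1L, bb[2] - side):min(dims[2], bb[4] + side))
}

# The plant's own pixels within the track region: the connected component
# (classes 1-6, 8-adjacency) containing / nearest the seed box, so that a
# neighbour growing into the region is never measured as part of this plant.
own_plant_submask <- function(frame, track, reg) {
  sub <- frame[reg$rows, reg$cols, drop = FALSE]
  bin <- sub >= 1L & sub <= 6L
  if (!any(bin)) return(sub * 0L)
  lab <- matrix(as.integer(EBImage::bwlabel(EBImage::Image(bin * 1))),
                nrow(sub), ncol(sub))
  bb <- track$seed_bbox
  sr <- (max(1L, bb[1] - 2L):min(max(reg$rows), bb[3] + 2L)) - reg$rows[1] + 1L
  sc <- (max(1L, bb[2] - 2L):min(max(reg$cols), bb[4] + 2L)) - reg$cols[1] + 1L
  sr <- sr[sr >= 1L & sr <= nrow(lab)]
  sc <- sc[sc >= 1L & sc <= ncol(lab)]
  ids <- lab[sr, sc, drop = FALSE]
  ids <- ids[ids > 0L]
  if (!length(ids)) return(sub * 0L)
  keep <- as.integer(names(which.max(table(ids))))
  out <- sub
  out[lab != keep] <- 0L
  out
}

#' Hypocotyl length series with physiological validation
#'
#' Per frame, the hypocotyl (class 4) pixels in the track's region are
#' skeletonized and the longest skeleton path gives the raw length. Frames
#' whose raw increment exceeds the maximum-rate gate (default 1 mm/h, i.e.
#' `1 * dt/60` mm per frame — contamination from a touching neighbour) are
#' replaced by the previous value, then the monotonic growth constraint is
#' applied. The raw series is preserved alongside the cleaned one.
#'
#' @param track One track from [track_plants()].
#' @param seq The `frame_sequence`.
#' @param max_rate_mm_h Rate gate in mm/h (default 1).
#' @return List with `raw` and `clean` `trait_series` (mm). Both empty if the
#'   plant never shows hypocotyl pixels.
#' @export
hypocotyl_series <- function(track, seq, max_rate_mm_h = 1) {
  dims <- dim(seq$frames[[1]])
  reg <- track_region(track, dims)
  n <- length(seq$frames)
  raw <- numeric(n)
  for (t in seq_len(n)) {
    sub <- own_plant_submask(seq$frames[[t]], track, reg) == 4L
    raw[t] <- if (any(sub)) skeleton_longest_path(skeletonize(sub)) *
      seq$scale else 0
  }
  if (all(raw == 0))
    return(list(raw = trait_series(seq$time_h, raw, track$id,
                                   "hypocotyl_length", "mm"),
                clean = trait_series(seq$time_h, raw, track$id,
                                     "hypocotyl_length", "mm")))
  gate <- max_rate_mm_h * seq$dt / 60
  clean <- raw
  for (t in 2:n) {
    if (clean[t] - clean[t - 1] > gate) clean[t] <- clean[t - 1]
  }
  clean <- cummax(clean)
  list(
    raw = trait_series(seq$time_h, raw, track$id, "hypocotyl_length", "mm"),
    clean = trait_series(seq$time_h, clean, track$id,
                         "hypocotyl_length", "mm")
  )
}

#' Basic plant measures for screening mode
#'
#' Total plant area (all classes 1-6 in the track's region, mm^2), simple
#' root length (longest path of the class-1 skeleton, no graph construction)
#' and seed size (class-3 area at the first frame).
#'
#' @param track One track from [track_plants()].
#' @param seq The `frame_sequence`.
#' @return List with `area` and `root_length` `trait_series` and
#'   `seed_size_mm2`.
#' @export
plant_measures <- function(track, seq) {
  dims <- dim(seq$frames[[1]])
  reg <- track_region(track, dims)
  n <- length(seq$frames)
  area <- numeric(n); rootlen <- numeric(n)
  for (t in seq_len(n)) {
    sub <- own_plant_submask(seq$frames[[t]], track, reg)
    area[t] <- sum(sub >= 1L & sub <= 6L) * seq$scale^2
    rt <- sub == 1L
    rootlen[t] <- if (any(rt)) skeleton_longest_path(skeletonize(rt)) *
      seq$scale else 0
  }
  bb <- track$seed_bbox
  seed_px <- sum(seq$frames[[1]][bb[1]:bb[3], bb[2]:bb[4]] == 3L)
  list(
    area = trait_series(seq$time_h, area, track$id, "plant_area", "mm2"),
    root_length = trait_series(seq$time_h, rootlen, track$id,
                               "simple_root_length", "mm"),
    seed_size_mm2 = seed_px * seq$scale^2
  )
}
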