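# Synthetic seedling renderer with exact ground truth.
#
# Emulates the mask sequences a segmentation network would produce for a
# time-lapse plate assay: germinating seeds, a main root growing downward,
# lateral roots emerging at scheduled times and angles (straight at first,
# then bending toward the vertical — gravitropic "angle decay"), an
# elongating hypocotyl, and transient imaging artifacts (droplets that last
# one frame, occlusions that erase a window for one or two frames).
#
# Frames are 1-based and frame i carries timestamp (i-1)*dt/60 hours.

#' Linear growth function
#'
#' @param rate_mm_h Elongation rate in mm/h.
#' @param delay_h Lag before growth starts, hours.
#' @return A function of hours-since-germination returning length in mm.
#' @export
growth_linear <- function(rate_mm_h, delay_h = 0) {
  force(rate_mm_h); force(delay_h)
  function(h) pmax(0, (h - delay_h)) * rate_mm_h
}

#' Logistic growth function
#'
#' @param max_mm Asymptotic length, mm.
#' @param k Steepness, 1/h.
#' @param t0_h Inflection time, hours.
#' @return A function of hours returning length in mm (shifted to start at 0).
#' @export
growth_logistic <- function(max_mm, k, t0_h) {
  force(max_mm); force(k); force(t0_h)
  function(h) max_mm / (1 + exp(-k * (h - t0_h))) - max_mm / (1 + exp(k * t0_h))
}

#' Specify one synthetic plant
#'
#' @param seed_rc Seed centre, integer `c(row, col)`.
#' @param germination_frame 1-based frame at which the radicle appears.
#' @param main_growth Function of hours since germination returning main-root
#'   length in mm; must be non-decreasing.
#' @param laterals List of lateral specs, each a list with `frame` (emergence
#'   frame, 1-based), `pos_mm` (insertion point measured along the main root
#'   from its base), `angle` (emergence angle in degrees from vertical;
#'   sign selects the side, magnitude is the angle), and `growth` (function of
#'   hours since emergence, mm).
#' @param hypocotyl_growth Function of hours since germination returning
#'   hypocotyl length in mm, or `NULL` for no hypocotyl.
#' @param mr_width,lr_width,hyp_width Organ stroke widths in pixels.
#' @param seed_radius Seed disk radius in pixels (disk diameter 5 by default).
#' @param bend_after_mm Arc length over which a lateral keeps its emergence
#'   angle before bending toward the vertical.
#' @param bend_decay_mm E-folding arc length of the angle decay toward
#'   vertical.
#' @return A `plant_spec` list.
#' @export
plant_spec <- function(seed_rc, germination_frame = 1L,
                       main_growth = growth_linear(0.1),
                       laterals = list(), hypocotyl_growth = NULL,
                       mr_width = 3L, lr_width = 2L, hyp_width = 4L,
                       seed_radius = 2, bend_after_mm = 2,
                       bend_decay_mm = 4) {
  structure(list(
    seed_rc = as.integer(seed_rc), germination_frame = as.integer(germination_frame),
    main_growth = main_growth, laterals = laterals,
    hypocotyl_growth = hypocotyl_growth,
    mr_width = mr_width, lr_width = lr_width, hyp_width = hyp_width,
    seed_radius = seed_radius, bend_after_mm = bend_after_mm,
    bend_decay_mm = bend_decay_mm
  ), class = "plant_spec")
}

#' Configure a synthetic sequence
#'
#' @param canvas `c(height, width)` in pixels.
#' @param n_frames Number of frames.
#' @param plants List of [plant_spec()] objects.
#' @param scale mm per pixel.
#' @param dt Minutes per frame.
#' @param droplet_rate Probability per frame of injecting a one-frame droplet
#'   blob (class 1 disk, radius 2-5 px) near a root.
#' @param occlusion_rate Probability per frame of starting a 10x10 px
#'   occlusion lasting 1-2 frames.
#' @param artifact_attach If `TRUE` droplets are placed overlapping an
#'   existing root so they perturb the skeleton; otherwise uniformly at
#'   random.
#' @param rng_seed Integer seed; identical configs give bit-identical output.
#' @return A `synth_config` list.
#' @export
synth_config <- function(canvas = c(400, 400), n_frames = 10L, plants = list(),
                         scale = 0.04, dt = 15, droplet_rate = 0,
                         occlusion_rate = 0, artifact_attach = TRUE,
                         rng_seed = 1L) {
  stopifnot(scale > 0, dt > 0, n_frames >= 1)
  for (p in plants) {
    if (p$seed_rc[1] < 1 || p$seed_rc[1] > canvas[1] ||
        p$seed_rc[2] < 1 || p$seed_rc[2] > canvas[2])
      stop("seed position outside canvas")
    hh <- seq(0, n_frames * dt / 60, length.out = 32)
    g <- p$main_growth(hh)
    if (any(diff(g) < -1e-9)) stop("main growth function must be non-decreasing")
  }
  structure(list(
    canvas = as.integer(canvas), n_frames = as.integer(n_frames),
    plants = plants, scale = scale, dt = dt,
    droplet_rate = droplet_rate, occlusion_rate = occlusion_rate,
    artifact_attach = artifact_attach, rng_seed = as.integer(rng_seed)
  ), class = "synth_config")
}

# Dense centreline geometry for one plant, in float pixel coordinates.
# Returns polylines sampled every `step` px with cumulative arc in mm.
plant_geometry <- function(spec, config) {
  step <- 0.5
  scale <- config$scale
  total_h <- (config$n_frames - 1) * config$dt / 60
  r0 <- spec$seed_rc[1]; c0 <- spec$seed_rc[2]

  # main root: straight down from just below the seed
  mr_len_mm <- max(spec$main_growth(total_h), 0) + 2 * scale
  n_mr <- max(2L, ceiling(mr_len_mm / scale / step) + 1L)
  mr_start <- c(r0 + spec$seed_radius, c0)
  mr <- cbind(row = mr_start[1] + (0:(n_mr - 1)) * step, col = rep(c0, n_mr))
  mr_arc <- (0:(n_mr - 1)) * step * scale

  lats <- lapply(spec$laterals, function(l) {
    base_i <- which.min(abs(mr_arc - l$pos_mm))
    base <- mr[base_i, ]
    side <- if (l$angle >= 0) 1 else -1
    theta0 <- abs(l$angle)
    lat_h <- total_h  # generous upper bound on growth duration
    len_mm <- max(l$growth(lat_h), 0) + 2 * scale
    n <- max(2L, ceiling(len_mm / scale / step) + 1L)
    pts <- matrix(0, n, 2); pts[1, ] <- base
    arc <- numeric(n)
    pos <- base
    for (i in 2:n) {
      a_mm <- (i - 2) * step * scale
      th <- if (a_mm <= spec$bend_after_mm) theta0 else
        theta0 * exp(-(a_mm - spec$bend_after_mm) / spec$bend_decay_mm)
      thr <- th * pi / 180
      pos <- pos + step * c(cos(thr), side * sin(thr))
      pts[i, ] <- pos
      arc[i] <- arc[i - 1] + step * scale
    }
    list(spec = l, base = base, base_arc_mm = mr_arc[base_i],
         pts = pts, arc = arc, side = side, theta0 = theta0)
  })

  hyp <- NULL
  if (!is.null(spec$hypocotyl_growth)) {
    len_mm <- max(spec$hypocotyl_growth(total_h), 0) + 2 * scale
    n <- max(2L, ceiling(len_mm / scale / step) + 1L)
    start <- c(r0 - spec$seed_radius, c0)
    hyp <- list(
      pts = cbind(row = start[1] - (0:(n - 1)) * step, col = rep(c0, n)),
      arc = (0:(n - 1)) * step * scale
    )
  }
  list(mr = list(pts = mr, arc = mr_arc), laterals = lats, hypocotyl = hyp)
}

# Index of last polyline sample within arc length `len_mm`.
arc_index <- function(arc, len_mm) max(1L, findInterval(len_mm + 1e-12, arc))

# Point on a polyline at a given arc length (linear interpolation).
point_at_arc <- function(pts, arc, len_mm) {
  if (len_mm <= 0) return(pts[1, ])
  if (len_mm >= arc[length(arc)]) return(pts[nrow(pts), ])
  i <- findInterval(len_mm, arc)
  f <- (len_mm - arc[i]) / (arc[i + 1] - arc[i])
  pts[i, ] + f * (pts[i + 1, ] - pts[i, ])
}

# Rasterize polyline samples from index a to b (rounded, Bresenham-filled).
raster_span <- function(pts, a, b) {
  if (b < a) return(matrix(0L, 0L, 2L))
  seg <- round(pts[a:b, , drop = FALSE])
  storage.mode(seg) <- "integer"
  if (nrow(seg) == 1L) return(seg)
  out <- vector("list", nrow(seg) - 1L)
  for (i in seq_len(nrow(seg) - 1L))
    out[[i]] <- bresenham(seg[i, 1], seg[i, 2], seg[i + 1, 1], seg[i + 1, 2])
  unique(do.call(rbind, out))
}

width_offsets <- function(w) {
  if (w <= 1) return(matrix(0L, 1, 2, dimnames = list(NULL, c("dr", "dc"))))
  if (w == 2) as.matrix(expand.grid(dr = 0:1, dc = 0:1))
  else {
    h <- (w - 1) %/% 2
    as.matrix(expand.grid(dr = -h:h, dc = -h:h))
  }
}

#' Generate a synthetic mask sequence with ground truth
#'
#' Renders every plant in the configuration frame by frame onto a persistent
#' canvas (so plant pixel sets are non-shrinking over time), then overlays
#' per-frame transient artifacts. Label priority within a plant is main root
#' > lateral > hypocotyl > seed; pixels already owned by an earlier-listed
#' plant are never overwritten — such collisions are recorded in
#' `$overlaps`. Two plants overlapping already at the first frame are
#' rejected.
#'
#' @param config A [synth_config()].
#' @return A list with `seq` (a [frame_sequence()]), `truth` (a data frame
#'   with one row per plant, frame and structure: columns `plant`, `frame`,
#'   `time_h`, `structure`, `lateral_id`, `length_mm`, `theta_bt`, `theta_e`,
#'   `emergence_frame`, `area_mm2`, `seed_row`, `seed_col`,
#'   `germination_frame`), `artifacts` (droplet/occlusion log) and `overlaps`.
#' @export
generate_sequence <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(config$rng_seed)

  nr <- config$canvas[1]; nc <- config$canvas[2]
  n_plants <- length(config$plants)
  scale <- config$scale; dt_h <- config$dt / 60
  cls <- matrix(0L, nr, nc)
  owner <- matrix(0L, nr, nc)
  geoms <- lapply(config$plants, plant_geometry, config = config)
  # rendered-up-to indices per structure
  state <- lapply(seq_len(n_plants), function(p) list(
    mr_i = 0L, hyp_i = 0L,
    lat_i = rep(0L, length(geoms[[p]]$laterals)),
    root_px = integer(0)  # linear indices of this plant's root pixels
  ))
  counts <- matrix(0L, n_plants, 7L)  # per-plant pixel count per class 0..6
  overlaps <- list(); artifacts <- list()
  occl_active <- list()
  frames <- vector("list", config$n_frames)
  truth <- vector("list", config$n_frames)

  stamp_plant <- function(p, px, offsets, value, protect) {
    if (nrow(px) == 0L) return(invisible())
    rr <- rep(px[, 1], each = nrow(offsets)) + offsets[, 1]
    ccx <- rep(px[, 2], each = nrow(offsets)) + offsets[, 2]
    keep <- rr >= 1L & rr <= nr & ccx >= 1L & ccx <= nc
    idx <- unique(rr[keep] + (ccx[keep] - 1L) * nr)
    other <- owner[idx] != 0L & owner[idx] != p
    if (any(other))
      overlaps[[length(overlaps) + 1L]] <<-
        data.frame(frame = t_cur, plant = p, other = owner[idx][other][1],
                   n_px = sum(other))
    idx <- idx[!other]
    if (length(protect)) idx <- idx[!(cls[idx] %in% protect)]
    if (!length(idx)) return(invisible())
    # keep per-plant class bookkeeping exact
    old <- cls[idx]
    for (k in unique(old)) counts[p, k + 1L] <<- counts[p, k + 1L] - sum(old == k)
    counts[p, value + 1L] <<- counts[p, value + 1L] + length(idx)
    cls[idx] <<- value
    owner[idx] <<- p
    if (value %in% c(1L, 2L))
      state[[p]]$root_px <<- c(state[[p]]$root_px, idx)
    invisible()
  }

  for (t_cur in seq_len(config$n_frames)) {
    th <- (t_cur - 1) * dt_h
    for (p in seq_len(n_plants)) {
      spec <- config$plants[[p]]; g <- geoms[[p]]
      # seed disk, present from frame 1
      if (t_cur == 1L) {
        sd <- disk_offsets(spec$seed_radius)
        stamp_plant(p, matrix(spec$seed_rc, 1), sd, MASK_CLASSES[["seed"]],
                    protect = c(1L, 2L, 4L))
      }
      if (t_cur >= spec$germination_frame) {
        hg <- th - (spec$germination_frame - 1) * dt_h
        mr_mm <- spec$main_growth(hg)
        mi <- arc_index(g$mr$arc, mr_mm)
        if (mi > state[[p]]$mr_i) {
          px <- raster_span(g$mr$pts, max(1L, state[[p]]$mr_i), mi)
          stamp_plant(p, px, width_offsets(spec$mr_width),
                      MASK_CLASSES[["mainroot"]], protect = integer(0))
          state[[p]]$mr_i <- mi
        }
        if (!is.null(g$hypocotyl)) {
          hyp_mm <- spec$hypocotyl_growth(hg)
          hi <- arc_index(g$hypocotyl$arc, hyp_mm)
          if (hi > state[[p]]$hyp_i) {
            px <- raster_span(g$hypocotyl$pts, max(1L, state[[p]]$hyp_i), hi)
            stamp_plant(p, px, width_offsets(spec$hyp_width),
                        MASK_CLASSES[["hypocotyl"]], protect = c(1L, 2L))
            state[[p]]$hyp_i <- hi
          }
        }
        for (li in seq_along(g$laterals)) {
          L <- g$laterals[[li]]
          if (t_cur >= L$spec$frame && mr_mm >= L$base_arc_mm) {
            lh <- th - (L$spec$frame - 1) * dt_h
            lmm <- L$spec$growth(lh)
            ei <- arc_index(L$arc, lmm)
            if (ei > state[[p]]$lat_i[li]) {
              px <- raster_span(L$pts, max(1L, state[[p]]$lat_i[li]), ei)
              stamp_plant(p, px, width_offsets(spec$lr_width),
                          MASK_CLASSES[["lateral"]], protect = 1L)
              state[[p]]$lat_i[li] <- ei
            }
          }
        }
      }
    }
    if (t_cur == 1L && length(overlaps) > 0L)
      stop("plant specs overlap already at frame 1; adjust seed positions")

    frame <- cls  # copy-on-write snapshot
    # droplets: one-frame class-1 disks on/near a root
    if (config$droplet_rate > 0 && runif(1) < config$droplet_rate) {
      rad <- sample(2:5, 1)
      all_root <- unlist(lapply(state, `[[`, "root_px"))
      if (config$artifact_attach && length(all_root) > 0) {
        at <- all_root[sample.int(length(all_root), 1)]
        ar <- (at - 1L) %% nr + 1L; ac <- (at - 1L) %/% nr + 1L
        ang <- runif(1, 0, 2 * pi); dist <- rad + runif(1, 2, 6)
        dr <- as.integer(round(ar + dist * cos(ang)))
        dc <- as.integer(round(ac + dist * sin(ang)))
      } else {
        dr <- sample.int(nr, 1); dc <- sample.int(nc, 1)
      }
      frame <- stamp_pixels(frame, matrix(c(dr, dc), 1), disk_offsets(rad),
                            MASK_CLASSES[["mainroot"]], protect = 1:6)
      artifacts[[length(artifacts) + 1L]] <-
        data.frame(frame = t_cur, type = "droplet", row = dr, col = dc,
                   radius = rad, duration = 1L)
    }
    if (config$occlusion_rate > 0 && runif(1) < config$occlusion_rate) {
      orr <- sample.int(max(1L, nr - 10L), 1); occ <- sample.int(max(1L, nc - 10L), 1)
      dur <- sample(1:2, 1)
      occl_active[[length(occl_active) + 1L]] <-
        list(r = orr, c = occ, until = t_cur + dur - 1L)
      artifacts[[length(artifacts) + 1L]] <-
        data.frame(frame = t_cur, type = "occlusion", row = orr, col = occ,
                   radius = 5L, duration = dur)
    }
    if (length(occl_active)) {
      occl_active <- Filter(function(o) o$until >= t_cur, occl_active)
      for (o in occl_active)
        frame[o$r:min(nr, o$r + 9L), o$c:min(nc, o$c + 9L)] <- 0L
    }
    frames[[t_cur]] <- frame

    # ground truth rows for this frame
    rows <- vector("list", n_plants)
    for (p in seq_len(n_plants)) {
      spec <- config$plants[[p]]; g <- geoms[[p]]
      germinated <- t_cur >= spec$germination_frame
      hg <- if (germinated) th - (spec$germination_frame - 1) * dt_h else NA_real_
      mr_mm <- if (germinated) spec$main_growth(hg) else 0
      rr <- list(data.frame(
        plant = p, frame = t_cur, time_h = th, structure = "main",
        lateral_id = NA_integer_, length_mm = mr_mm,
        theta_bt = NA_real_, theta_e = NA_real_, emergence_frame = NA_integer_,
        area_mm2 = counts[p, 2L] * scale^2,
        seed_row = spec$seed_rc[1], seed_col = spec$seed_rc[2],
        germination_frame = spec$germination_frame
      ))
      if (!is.null(spec$hypocotyl_growth)) {
        hmm <- if (germinated) spec$hypocotyl_growth(hg) else 0
        rr[[length(rr) + 1L]] <- data.frame(
          plant = p, frame = t_cur, time_h = th, structure = "hypocotyl",
          lateral_id = NA_integer_, length_mm = hmm,
          theta_bt = NA_real_, theta_e = NA_real_, emergence_frame = NA_integer_,
          area_mm2 = counts[p, 5L] * scale^2,
          seed_row = spec$seed_rc[1], seed_col = spec$seed_rc[2],
          germination_frame = spec$germination_frame
        )
      }
      for (li in seq_along(g$laterals)) {
        L <- g$laterals[[li]]
        emerged <- germinated && t_cur >= L$spec$frame && mr_mm >= L$base_arc_mm
        if (!emerged) next
        lh <- th - (L$spec$frame - 1) * dt_h
        lmm <- min(L$spec$growth(lh), L$arc[length(L$arc)])
        tip <- point_at_arc(L$pts, L$arc, lmm)
        v <- tip - L$base  # (d_row, d_col) = (dy, dx) with y downward
        tbt <- if (sqrt(sum(v^2)) > 1e-9)
          acos(v[1] / sqrt(sum(v^2))) * 180 / pi else NA_real_
        te <- if (lmm >= 2) {
          pe <- point_at_arc(L$pts, L$arc, 2)
          ve <- pe - L$base
          acos(ve[1] / sqrt(sum(ve^2))) * 180 / pi
        } else NA_real_
        rr[[length(rr) + 1L]] <- data.frame(
          plant = p, frame = t_cur, time_h = th, structure = "lateral",
          lateral_id = li, length_mm = lmm, theta_bt = tbt, theta_e = te,
          emergence_frame = L$spec$frame,
          area_mm2 = NA_real_,
          seed_row = spec$seed_rc[1], seed_col = spec$seed_rc[2],
          germination_frame = spec$germination_frame
        )
      }
      rows[[p]] <- do.call(rbind, rr)
    }
    truth[[t_cur]] <- if (n_plants) do.call(rbind, rows) else NULL
  }

  list(
    seq = frame_sequence(frames, dt = config$dt, scale = scale),
    truth = if (n_plants) do.call(rbind, truth) else
      data.frame(plant = integer(0), frame = integer(0)),
    artifacts = if (length(artifacts)) do.call(rbind, artifacts) else
      data.frame(frame = integer(0), type = character(0)),
    overlaps = if (length(overlaps)) do.call(rbind, overlaps) else
      data.frame(frame = integer(0), plant = integer(0)),
    config = config
  )
}

#' Render a single frame from explicit plant states
#'
#' Low-level rasterizer used by [generate_sequence()]; exposed for fixture
#' construction. Each state is a list with `px` (n x 2 pixel matrix),
#' `class_id` and `width`. Later entries never overwrite earlier ones.
#'
#' @param plant_states List of state lists.
#' @param canvas `c(height, width)`.
#' @return Integer label matrix.
#' @export
render_frame <- function(plant_states, canvas) {
  m <- matrix(0L, canvas[1], canvas[2])
  painted <- matrix(FALSE, canvas[1], canvas[2])
  for (st in plant_states) {
    before <- m
    m2 <- stamp_pixels(m, st$px, width_offsets(st$width %||% 1L), st$class_id,
                       protect = integer(0))
    new_idx <- which(m2 != before & !painted)
    m[new_idx] <- m2[new_idx]
    painted[m != 0L] <- TRUE
  }
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
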