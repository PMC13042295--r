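# End-to-end analysis drivers: Standard (per-ROI root system architecture
# over time) and Screening (multi-plant germination / hypocotyl), plus the
# configuration-file pipeline runner used by the command-line interface.

# Refined main-root length: the graph path length plus (a) the gap between
# the user-marked origin and the first skeleton pixel and (b) the extension
# of the root cap beyond the skeleton tip (thinning erodes roughly half the
# stroke width at each end). Both corrections are read off the refined mask.
main_length_refined <- function(axes, mask, origin) {
  len <- axes$main$length_px
  path <- axes$main$path
  if (is.null(path) || nrow(path) == 0L) return(len)
  d0 <- sqrt(sum((origin - path[1, ])^2))
  if (d0 <= 6) len <- len + d0
  p <- path[nrow(path), ]
  k <- max(1L, nrow(path) - 5L)
  u <- p - path[k, ]
  nu <- sqrt(sum(u^2))
  if (nu > 0) {
    u <- u / nu
    rr <- max(1L, p[1] - 4L):min(nrow(mask), p[1] + 4L)
    cc <- max(1L, p[2] - 4L):min(ncol(mask), p[2] + 4L)
    sub <- which(mask[rr, cc, drop = FALSE], arr.ind = TRUE)
    if (nrow(sub)) {
      q <- cbind(rr[sub[, 1]] - p[1], cc[sub[, 2]] - p[2])
      proj <- q %*% u
      perp <- sqrt(pmax(0, rowSums(q^2) - proj^2))
      ahead <- proj > 0 & perp <= 2
      if (any(ahead)) len <- len + min(max(proj[ahead]), 3)
    }
  }
  len
}

#' Read a ROI definition file
#'
#' CSV with columns `plant_id, x0, y0, x1, y1, origin_x, origin_y` in
#' 0-based, half-open pixel coordinates (x = column, y = row), as produced
#' by external annotation tools. Converted internally to 1-based inclusive
#' (row, col) rectangles.
#'
#' @param path CSV path.
#' @return Data frame `plant_id, r0, c0, r1, c1, origin_r, origin_c`.
#' @export
read_roi_csv <- function(path) {
  d <- read.csv(path)
  need <- c("plant_id", "x0", "y0", "x1", "y1", "origin_x", "origin_y")
  if (!all(need %in% names(d)))
    stop("ROI file must have columns: ", paste(need, collapse = ", "))
  data.frame(plant_id = d$plant_id,
             r0 = d$y0 + 1L, c0 = d$x0 + 1L, r1 = d$y1, c1 = d$x1,
             origin_r = d$origin_y + 1L, origin_c = d$origin_x + 1L)
}

#' Read an experimental-group definition file
#'
#' CSV with columns `group, x0, y0, x1, y1` (0-based half-open rectangles)
#' and optionally `seed_count` (manual seed count for the region).
#'
#' @param path CSV path.
#' @return Data frame with 1-based inclusive `r0, c0, r1, c1`.
#' @export
read_groups_csv <- function(path) {
  d <- read.csv(path)
  need <- c("group", "x0", "y0", "x1", "y1")
  if (!all(need %in% names(d)))
    stop("group file must have columns: ", paste(need, collapse = ", "))
  out <- data.frame(group = d$group,
                    r0 = d$y0 + 1L, c0 = d$x0 + 1L, r1 = d$y1, c1 = d$x1)
  if ("seed_count" %in% names(d)) out$seed_count <- d$seed_count
  out
}

#' Standard-mode analysis of one plant ROI
#'
#' Runs the full per-plant chain on a mask sequence: temporal trailing-average
#' smoothing of the root classes, per-frame ROI mask refinement,
#' skeletonization with 5-px spur pruning, graph construction and main /
#' lateral classification, lateral identity tracking across frames,
#' 6-h persistence validation, monotonic growth enforcement, and the trait,
#' angle and convex-hull catalogue.
#'
#' @param seq A `frame_sequence` (full frames).
#' @param roi One row of a ROI table (see [read_roi_csv()]).
#' @param alpha Trailing-average weight; `NULL` = [default_alpha()].
#' @param tau Accumulator presence threshold.
#' @param min_spur_px Spur-pruning threshold, px.
#' @param min_persist_h Lateral persistence threshold, hours.
#' @param d_mm Emergence-angle distance, mm.
#' @param max_shift Lateral base matching gate, arc px.
#' @param gap_frames Frames over which a lost lateral identity may be
#'   re-attached at the same base position (default 8, i.e. 2 h at 15-min
#'   cadence).
#' @param smooth Apply temporal accumulation (default TRUE).
#' @param detrend_window_h Window for growth-speed detrending, hours.
#' @param spectrum Compute the growth-speed Fourier spectrum (default FALSE;
#'   needs a long uniform series).
#' @return A `plant_result` list: `plant_id`, `series` (list of
#'   `trait_series`), `laterals` (registry with validation flags), `angles`
#'   (per validated lateral per frame), `hulls` (daily convex-hull metrics),
#'   `final_axes`, `spectrum`, `frames_analyzed`.
#' @export
analyze_plant <- function(seq, roi, alpha = NULL, tau = 1,
                          min_spur_px = 5L, min_persist_h = 6,
                          d_mm = 2, max_shift = 15, gap_frames = 8L,
                          smooth = TRUE, detrend_window_h = 12,
                          spectrum = FALSE) {
  scale <- seq$scale
  rows <- roi$r0:roi$r1; cols <- roi$c0:roi$c1
  sub <- lapply(seq$frames, function(f) f[rows, cols, drop = FALSE])
  subseq <- frame_sequence(sub, dt = seq$dt, scale = scale)
  if (smooth) subseq <- accumulate_trailing(subseq, alpha = alpha, tau = tau)
  origin <- c(roi$origin_r - roi$r0 + 1L, roi$origin_c - roi$c0 + 1L)
  nfr <- length(subseq$frames)

  per_frame <- vector("list", nfr)   # scalar metrics
  lat_rows <- vector("list", nfr)    # per-lateral rows with stable ids
  prev_axes <- NULL; prev_ids <- integer(0)
  next_id <- 1L
  registry <- list()                 # stable id -> first/last frame
  final_axes <- NULL
  daily_frames <- unique(c(
    seq(1L, nfr, by = max(1L, round(24 * 60 / seq$dt))), nfr))
  hull_rows <- list()
  root_px_daily <- list()

  for (t in seq_len(nfr)) {
    m <- refine_roi_mask(subseq$frames[[t]],
                         c(1L, 1L, nrow(subseq$frames[[t]]),
                           ncol(subseq$frames[[t]])), origin)
    if (isTRUE(attr(m, "empty"))) {
      per_frame[[t]] <- c(mr = NA_real_, lr = NA_real_)
      prev_axes <- NULL; prev_ids <- integer(0)
      next
    }
    sk <- prune_spurs(skeletonize(m), min_len = min_spur_px)
    if (!any(sk)) {
      per_frame[[t]] <- c(mr = NA_real_, lr = NA_real_)
      prev_axes <- NULL; prev_ids <- integer(0)
      next
    }
    axes <- tryCatch(classify_axes(build_graph(sk, origin)),
                     error = function(e) NULL)
    if (is.null(axes)) {
      per_frame[[t]] <- c(mr = NA_real_, lr = NA_real_)
      prev_axes <- NULL; prev_ids <- integer(0)
      next
    }
    # stable lateral ids
    mp <- match_laterals(if (is.null(prev_axes))
      structure(list(laterals = list()), class = "axis_labeling") else
        prev_axes, axes, max_shift = max_shift)
    ids <- integer(length(axes$laterals))
    for (j in seq_along(axes$laterals)) {
      pj <- mp$prev[mp$cur == j]
      if (length(pj) == 1L && !is.na(pj) && pj <= length(prev_ids)) {
        ids[j] <- prev_ids[pj]
      } else {
        # bridge short identity gaps: re-attach to a recently dormant
        # lateral at the same base position before minting a fresh id
        ba <- axes$laterals[[j]]$base_arc_px
        cand <- Filter(function(k) {
          r <- registry[[k]]
          r$last >= t - gap_frames && !(as.integer(k) %in% ids) &&
            abs(r$base_arc - ba) <= max_shift
        }, names(registry))
        if (length(cand)) {
          d <- vapply(cand, function(k)
            abs(registry[[k]]$base_arc - ba), numeric(1))
          ids[j] <- as.integer(cand[which.min(d)])
        } else {
          ids[j] <- next_id; next_id <- next_id + 1L
        }
      }
      key <- as.character(ids[j])
      if (is.null(registry[[key]])) {
        registry[[key]] <- list(first = t, last = t, n = 1L,
                                base_arc = axes$laterals[[j]]$base_arc_px)
      } else {
        registry[[key]]$last <- t
        registry[[key]]$n <- registry[[key]]$n + 1L
        registry[[key]]$base_arc <- axes$laterals[[j]]$base_arc_px
      }
    }
    mr_mm <- main_length_refined(axes, m, origin) * scale
    per_frame[[t]] <- c(mr = mr_mm, lr = NA_real_)
    if (length(axes$laterals)) {
      ang <- lateral_angles(axes, scale = scale, d_mm = d_mm)
      ang$stable_id <- ids[ang$lateral_id]
      ang$frame <- t
      ang$base_arc_px <- vapply(axes$laterals, `[[`, numeric(1),
                                "base_arc_px")[ang$lateral_id]
      lat_rows[[t]] <- ang
    }
    if (t %in% daily_frames)
      root_px_daily[[as.character(t)]] <- which(m, arr.ind = TRUE)
    prev_axes <- axes; prev_ids <- ids
    if (t == nfr) final_axes <- axes
  }

  # persistence validation of stable lateral ids: contiguous presence runs
  presence <- function(key) {
    reg <- registry[[key]]
    fr <- sort(unique(unlist(lapply(lat_rows, function(d)
      if (!is.null(d)) d$frame[d$stable_id == as.integer(key)] else NULL))))
    v <- rep(FALSE, nfr); v[fr] <- TRUE
    v
  }
  lat_ids <- names(registry)
  validated <- vapply(lat_ids, function(k)
    temporal_validation(presence(k), subseq$dt, min_persist_h), logical(1))
  lat_df <- if (length(lat_ids)) data.frame(
    stable_id = as.integer(lat_ids),
    first_frame = vapply(registry, `[[`, integer(1), "first"),
    last_frame = vapply(registry, `[[`, integer(1), "last"),
    n_frames = vapply(registry, `[[`, integer(1), "n"),
    validated = validated,
    row.names = NULL
  ) else data.frame(stable_id = integer(0), first_frame = integer(0),
                    last_frame = integer(0), n_frames = integer(0),
                    validated = logical(0))

  angles <- do.call(rbind, lat_rows)
  valid_ids <- lat_df$stable_id[lat_df$validated]
  if (!is.null(angles)) {
    angles$validated <- angles$stable_id %in% valid_ids
    angles$time_h <- subseq$time_h[angles$frame]
  }

  # trait series (lengths cleaned with the monotonic constraint)
  mr_raw <- vapply(per_frame, function(x) unname(x["mr"]), numeric(1))
  tvec <- subseq$time_h
  ok <- !is.na(mr_raw)
  series <- list()
  if (any(ok)) {
    mr_raw_ts <- trait_series(tvec[ok], mr_raw[ok], roi$plant_id,
                              "mr_length_raw", "mm")
    mr_ts <- enforce_monotonic(mr_raw_ts)
    mr_ts$trait <- "mr_length"
    lr_per_frame <- vapply(seq_len(nfr), function(t) {
      d <- lat_rows[[t]]
      if (is.null(d)) return(0)
      sum(d$length_mm[d$stable_id %in% valid_ids])
    }, numeric(1))
    lr_ts <- enforce_monotonic(trait_series(tvec[ok], lr_per_frame[ok],
                                            roi$plant_id, "lr_length", "mm"))
    n_lr <- vapply(seq_len(nfr), function(t)
      sum(lat_df$validated & lat_df$first_frame <= t), numeric(1))
    tr <- mr_ts$values + lr_ts$values
    series <- list(
      mr_length_raw = mr_raw_ts,
      mr_length = mr_ts,
      lr_length = lr_ts,
      tr_length = trait_series(tvec[ok], tr, roi$plant_id, "tr_length", "mm"),
      n_lateral = trait_series(tvec[ok], n_lr[ok], roi$plant_id,
                               "n_lateral", "count"),
      lr_density = trait_series(tvec[ok],
                                ifelse(mr_ts$values > 0,
                                       10 * n_lr[ok] / mr_ts$values,
                                       NA_real_),
                                roi$plant_id, "lr_density", "LRs/cm"),
      main_over_total = trait_series(tvec[ok],
                                     ifelse(tr > 0, mr_ts$values / tr,
                                            NA_real_),
                                     roi$plant_id, "main_over_total", "ratio")
    )
    if (length(mr_ts$values) >= 3L)
      series$mr_speed <- growth_speed(mr_ts)
  }

  # daily convex hulls
  for (t in daily_frames) {
    px <- root_px_daily[[as.character(t)]]
    if (is.null(px)) next
    tr_now <- if (length(series)) {
      i <- which.min(abs(series$tr_length$time_h - subseq$time_h[t]))
      series$tr_length$values[i]
    } else NA_real_
    hm <- convex_hull_metrics(px, scale = scale, total_root_length_mm = tr_now)
    hull_rows[[length(hull_rows) + 1L]] <-
      data.frame(frame = t, time_h = subseq$time_h[t],
                 area_mm2 = hm$area_mm2, width_mm = hm$width_mm,
                 height_mm = hm$height_mm, density_mm_mm2 = hm$density_mm_mm2,
                 aspect = hm$aspect)
  }

  spec_df <- NULL
  if (spectrum && !is.null(series$mr_speed) &&
      length(series$mr_speed$values) >= 16L) {
    det <- detrend_series(series$mr_speed, window_h = detrend_window_h)
    spec_df <- fourier_spectrum(det)
  }

  structure(list(
    plant_id = roi$plant_id, series = series, laterals = lat_df,
    angles = angles, hulls = do.call(rbind, hull_rows),
    final_axes = final_axes, spectrum = spec_df,
    frames_analyzed = sum(ok), dt = seq$dt, scale = scale
  ), class = "plant_result")
}

#' Standard-mode analysis of all plants
#'
#' @param seq A `frame_sequence`.
#' @param rois ROI table ([read_roi_csv()] format, 1-based columns).
#' @param ... Passed to [analyze_plant()].
#' @return List of `plant_result`, one per ROI row.
#' @export
analyze_standard <- function(seq, rois, ...) {
  lapply(seq_len(nrow(rois)), function(i)
    analyze_plant(seq, rois[i, ], ...))
}

#' Screening-mode analysis
#'
#' Detects seeds, tracks them with the SORT-style tracker, applies the
#' contact/motion quality control, builds the germination curve and its Hill
#' fit (per group when a group table is supplied), and measures hypocotyl
#' and whole-plant series for each surviving track.
#'
#' @param seq A `frame_sequence`.
#' @param groups Optional group table ([read_groups_csv()] format).
#' @param min_area,max_area Seed area gates, px^2.
#' @param max_dist,max_misses Tracker association gate and patience.
#' @param motion_thresh QC motion threshold, px/frame.
#' @param min_persist_h Germination persistence threshold, hours.
#' @param measure Also compute hypocotyl and plant measures (slower;
#'   default TRUE).
#' @return A `screening_result` list: `tracks`, `germination` (curve +
#'   `fit`), per-group fits, `hypocotyl`, `plant` measures.
#' @export
analyze_screening <- function(seq, groups = NULL, min_area = 5,
                              max_area = 400, max_dist = 50, max_misses = 8,
                              motion_thresh = 40, min_persist_h = 6,
                              measure = TRUE) {
  detections <- lapply(seq$frames, detect_seeds, min_area = min_area,
                       max_area = max_area)
  tracks <- track_plants(detections, max_dist = max_dist,
                         max_misses = max_misses)
  tracks <- qc_filter(tracks, seq, motion_thresh = motion_thresh)
  surviving <- Filter(function(tr) tr$status != "qc_removed", tracks)
  curve <- germination_curve(tracks, seq, min_persist_h = min_persist_h)
  fit <- tryCatch(fit_hill(curve), error = function(e) NULL)

  group_of <- function(tr) {
    if (is.null(groups)) return("all")
    h <- tr$history[1, ]
    hit <- which(groups$r0 <= h$cr & h$cr <= groups$r1 &
                   groups$c0 <= h$cc & h$cc <= groups$c1)
    if (length(hit)) as.character(groups$group[hit[1]]) else NA_character_
  }
  by_group <- NULL
  if (!is.null(groups)) {
    glab <- vapply(surviving, group_of, character(1))
    by_group <- lapply(split(surviving, glab), function(trs) {
      cv <- germination_curve(trs, seq, min_persist_h = min_persist_h)
      list(curve = cv, fit = tryCatch(fit_hill(cv), error = function(e) NULL),
           n = length(trs))
    })
  }

  hyp <- NULL; pm <- NULL
  if (measure) {
    hyp <- lapply(surviving, hypocotyl_series, seq = seq)
    names(hyp) <- vapply(surviving, `[[`, integer(1), "id")
    pm <- lapply(surviving, plant_measures, seq = seq)
    names(pm) <- names(hyp)
  }
  structure(list(
    tracks = tracks, germination = list(curve = curve, fit = fit),
    by_group = by_group, hypocotyl = hyp, plant = pm
  ), class = "screening_result")
}

# ---------------------------------------------------------------------------
# Demo experiments: the package's reference study conditions. Standard mode
# emulates a plate of ten seedlings imaged every 15 min for six days at
# 0.04 mm/px on a 600x600 px canvas, with plants already germinated when
# imaging starts (as in practice, where rigs are started a few days after
# sowing); screening mode emulates a 20-seed germination/etiolation screen.

#' Demo standard-mode experiment (synthetic)
#'
#' Ten seedlings in a 5 x 2 grid, six days at 15-min cadence, 600 x 600 px
#' at 0.04 mm/px. Main roots start at 2.5-3.5 mm and elongate at
#' 0.04-0.05 mm/h; each plant carries 2-4 laterals emerging between day 2
#' and day 4 at 35-55 degrees with gravitropic angle decay.
#'
#' @param n_plants Number of plants (max 10).
#' @param n_frames Number of frames (default 577 = 144 h at 15 min).
#' @param droplet_rate Per-frame droplet artifact probability.
#' @param rng_seed Seed.
#' @return List with `config` (a [synth_config()]) and `rois` (ROI table).
#' @export
demo_standard_experiment <- function(n_plants = 10L, n_frames = 577L,
                                     droplet_rate = 0, rng_seed = 1L) {
  stopifnot(n_plants >= 1L, n_plants <= 10L)
  cols <- rep(c(70L, 190L, 310L, 430L, 550L), 2)[seq_len(n_plants)]
  rows <- rep(c(25L, 325L), each = 5)[seq_len(n_plants)]
  set.seed(rng_seed + 7717L)
  plants <- list(); roi_rows <- list()
  for (i in seq_len(n_plants)) {
    init <- runif(1, 2.5, 3.5)
    rate <- runif(1, 0.04, 0.05)
    n_lat <- sample(2:4, 1)
    pos <- sort(runif(n_lat, 1.2, 3.4))
    while (n_lat > 1 && min(diff(pos)) < 0.7)
      pos <- sort(runif(n_lat, 1.2, 3.4))
    side_pool <- if (cols[i] <= 80L) 1 else if (cols[i] >= 520L) -1 else
      c(-1, 1)
    sides <- sample(rep(side_pool, n_lat), n_lat)
    # on a given side, emergence angles decrease with depth so laterals
    # never cross (crossing-root disambiguation is out of scope)
    angles <- numeric(n_lat)
    for (s in unique(sides)) {
      k <- sum(sides == s)
      draw <- sort(runif(k, 30, 48), decreasing = TRUE)
      while (k > 1L && min(-diff(draw)) < 2)
        draw <- sort(runif(k, 30, 48), decreasing = TRUE)
      angles[sides == s] <- draw
    }
    lats <- lapply(seq_len(n_lat), function(j) {
      list(frame = sample(seq(121L, 193L), 1),   # day 1.25 .. day 2
           pos_mm = pos[j],
           angle = sides[j] * angles[j],
           growth = growth_linear(runif(1, 0.028, 0.034)))
    })
    mg <- local({
      i0 <- init; r0 <- rate
      function(h) i0 + r0 * h
    })
    plants[[i]] <- plant_spec(
      seed_rc = c(rows[i], cols[i]), germination_frame = 1L,
      main_growth = mg,
      laterals = lats,
      hypocotyl_growth = NULL,
      bend_after_mm = 1.5, bend_decay_mm = 2.5
    )
    roi_rows[[i]] <- data.frame(
      plant_id = i,
      r0 = max(1L, rows[i] - 10L), c0 = cols[i] - 60L,
      r1 = min(600L, rows[i] + 290L), c1 = min(600L, cols[i] + 59L),
      origin_r = rows[i] + 2L, origin_c = cols[i]
    )
  }
  list(
    config = synth_config(canvas = c(600L, 600L), n_frames = n_frames,
                          plants = plants, scale = 0.04, dt = 15,
                          droplet_rate = droplet_rate,
                          rng_seed = rng_seed),
    rois = do.call(rbind, roi_rows)
  )
}

#' Demo screening-mode experiment (synthetic)
#'
#' Twenty seeds in a 5 x 4 grid germinating on a Hill-like schedule, each
#' growing a short primary root and an elongating hypocotyl.
#'
#' @param n_seeds Number of seeds (max 20).
#' @param n_frames Number of frames (default 193 = 48 h at 15 min).
#' @param germination_frames Optional explicit 1-based germination frames
#'   (NA = never germinates); default draws times from a Hill(t50 = 20 h,
#'   n = 4) schedule with 10 percent dormant seeds.
#' @param rng_seed Seed.
#' @return List with `config` and `truth_germination_h` (NA = dormant).
#' @export
demo_screening_experiment <- function(n_seeds = 20L, n_frames = 193L,
                                      germination_frames = NULL,
                                      rng_seed = 1L) {
  stopifnot(n_seeds >= 1L, n_seeds <= 20L)
  grid <- expand.grid(row = c(90L, 250L, 410L, 570L),
                      col = c(70L, 190L, 310L, 430L, 550L))
  set.seed(rng_seed + 3391L)
  dt_h <- 0.25
  if (is.null(germination_frames)) {
    u <- runif(n_seeds)
    t50 <- 20; nH <- 4
    germination_frames <- ifelse(
      u > 0.9, NA_integer_,
      # invert the Hill CDF: t = t50 * (p/(1-p))^(1/n), p in (0, 0.9)
      as.integer(round(t50 * ((u / 0.9) / (1 - pmin(u / 0.9, 0.999)))^(1 / nH)
                       / dt_h)) + 1L
    )
  }
  plants <- lapply(seq_len(n_seeds), function(i) {
    g <- germination_frames[i]
    plant_spec(
      seed_rc = c(grid$row[i], grid$col[i]),
      germination_frame = if (is.na(g)) n_frames + 10L else g,
      main_growth = growth_linear(0.06),
      laterals = list(),
      hypocotyl_growth = growth_linear(0.05, delay_h = 2)
    )
  })
  list(
    config = synth_config(canvas = c(700L, 620L), n_frames = n_frames,
                          plants = plants, scale = 0.04, dt = 15,
                          rng_seed = rng_seed),
    truth_germination_h = (germination_frames - 1L) * dt_h
  )
}

#' Run the pipeline from a configuration file
#'
#' YAML configuration with keys `mode` (`standard` or `screening`), input
#' (`masks`: directory/TIFF plus `dt`, `scale`; or `synthetic: demo` to use
#' the built-in demo experiment), `roi`/`groups` CSV paths, `out` directory,
#' `seed` and parameter overrides (`alpha`, `tau`, `min_spur_px`,
#' `min_persist_h`, `d_mm`). Writes tidy CSV reports, RSML, a run manifest
#' (config hash, package version, seed) and a plain-text log, all with
#' byte-stable ordering.
#'
#' @param config_path YAML file path.
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config_path) {
  cfg <- yaml::read_yaml(config_path)
  out <- cfg$out %||% "rhizolapse_out"
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out, "run.log")
  logmsg <- function(...) {
    line <- sprintf("[%s] %s", "run", sprintf(...))
    cat(line, "\n", sep = "", file = logf, append = TRUE)
  }
  seed <- cfg$seed %||% 1L
  mode <- cfg$mode %||% "standard"
  logmsg("mode=%s seed=%d", mode, as.integer(seed))

  rois <- NULL
  if (identical(cfg$synthetic, "demo")) {
    if (mode == "standard") {
      demo <- demo_standard_experiment(
        n_plants = cfg$n_plants %||% 4L,
        n_frames = cfg$n_frames %||% 193L, rng_seed = seed)
      gen <- generate_sequence(demo$config)
      seq <- gen$seq; rois <- demo$rois
    } else {
      demo <- demo_screening_experiment(
        n_seeds = cfg$n_seeds %||% 12L,
        n_frames = cfg$n_frames %||% 145L, rng_seed = seed)
      gen <- generate_sequence(demo$config)
      seq <- gen$seq
    }
  } else {
    if (is.null(cfg$masks)) stop("config needs `masks` or `synthetic: demo`")
    if (!file.exists(cfg$masks)) stop("mask input not found: ", cfg$masks)
    seq <- read_mask_sequence(cfg$masks, dt = cfg$dt %||% 15,
                              scale = cfg$scale %||% 0.04)
  }

  if (mode == "standard") {
    if (is.null(rois)) {
      if (is.null(cfg$roi)) stop("standard mode needs a `roi` CSV")
      rois <- read_roi_csv(cfg$roi)
    }
    res <- analyze_standard(seq, rois,
                            alpha = cfg$alpha, tau = cfg$tau %||% 1,
                            min_spur_px = cfg$min_spur_px %||% 5L,
                            min_persist_h = cfg$min_persist_h %||% 6,
                            d_mm = cfg$d_mm %||% 2)
    write_standard_reports(res, out, seq)
    logmsg("standard: %d plants analyzed", length(res))
  } else {
    groups <- if (!is.null(cfg$groups)) read_groups_csv(cfg$groups) else NULL
    res <- analyze_screening(seq, groups = groups,
                             min_persist_h = cfg$min_persist_h %||% 6)
    write_screening_reports(res, out)
    logmsg("screening: %d tracks", length(res$tracks))
  }
  manifest <- list(
    package = "rhizolapse",
    version = as.character(utils::packageVersion("rhizolapse")),
    mode = mode, seed = as.integer(seed),
    config_md5 = unname(tools::md5sum(config_path)),
    n_frames = length(seq$frames), dt_min = seq$dt, scale_mm_px = seq$scale
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}

write_standard_reports <- function(res, out, seq) {
  traits <- do.call(rbind, lapply(res, function(r)
    do.call(rbind, lapply(r$series, as.data.frame))))
  if (!is.null(traits))
    write.csv(traits[order(traits$plant, traits$trait, traits$time_h), ],
              file.path(out, "traits.csv"), row.names = FALSE)
  ang <- do.call(rbind, lapply(res, function(r) {
    if (is.null(r$angles)) return(NULL)
    cbind(plant_id = r$plant_id, r$angles)
  }))
  if (!is.null(ang))
    write.csv(ang[order(ang$plant_id, ang$stable_id, ang$frame), ],
              file.path(out, "angles.csv"), row.names = FALSE)
  hull <- do.call(rbind, lapply(res, function(r) {
    if (is.null(r$hulls)) return(NULL)
    cbind(plant_id = r$plant_id, r$hulls)
  }))
  if (!is.null(hull))
    write.csv(hull, file.path(out, "hulls.csv"), row.names = FALSE)
  axes <- lapply(res, `[[`, "final_axes")
  keep <- !vapply(axes, is.null, logical(1))
  if (any(keep))
    write_rsml(axes[keep], file.path(out, "scene.rsml"), scale = seq$scale,
               dt = seq$dt,
               plant_ids = vapply(res, `[[`, numeric(1), "plant_id")[keep])
}

write_screening_reports <- function(res, out) {
  trk <- do.call(rbind, lapply(res$tracks, function(tr)
    data.frame(id = tr$id, status = tr$status,
               qc_reason = tr$qc_reason %||% NA_character_,
               n_frames = nrow(tr$history))))
  write.csv(trk, file.path(out, "tracks.csv"), row.names = FALSE)
  cv <- res$germination$curve
  write.csv(data.frame(time_h = cv$time_h, percent = cv$values),
            file.path(out, "germination_curve.csv"), row.names = FALSE)
  f <- res$germination$fit
  if (!is.null(f))
    write.csv(data.frame(G0 = f$G0, Gmax = f$Gmax, n = f$n, t50 = f$t50,
                         TMGR = f$TMGR,
                         final_germination = f$final_germination),
              file.path(out, "germination_fit.csv"), row.names = FALSE)
  if (!is.null(res$hypocotyl)) {
    hs <- do.call(rbind, lapply(names(res$hypocotyl), function(id) {
      h <- res$hypocotyl[[id]]
      rbind(cbind(kind = "raw", as.data.frame(h$raw)),
            cbind(kind = "clean", as.data.frame(h$clean)))
    }))
    write.csv(hs, file.path(out, "hypocotyl.csv"), row.names = FALSE)
  }
  if (!is.null(res$plant)) {
    pa <- do.call(rbind, lapply(res$plant, function(p)
      rbind(as.data.frame(p$area), as.data.frame(p$root_length))))
    write.csv(pa, file.path(out, "plant_measures.csv"), row.names = FALSE)
  }
}
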