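# Architectural and angular trait computation from labeled axes.
#
# Image coordinate convention: y increases downward, so a root growing
# straight down has angle 0 degrees from the vertical.

#' Base-tip angle of a lateral root
#'
#' Overall orientation relative to the vertical, from the base and tip
#' positions: `acos((y_t - y_b) / ||tip - base||) * 180 / pi`. 0 degrees is
#' straight down; 90 degrees is horizontal.
#'
#' @param base,tip Numeric `c(x, y)` points in pixel coordinates (y grows
#'   downward). `c(row, col)` matrices from axis paths should be passed as
#'   `c(x = col, y = row)`.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
base_tip_angle <- function(base, tip) {
  v <- c(tip[1] - base[1], tip[2] - base[2])
  nrm <- sqrt(sum(v^2))
  if (nrm < 1e-12) stop("base and tip coincide; angle undefined")
  acos(max(-1, min(1, v[2] / nrm))) * 180 / pi
}

#' Emergence angle of a lateral root
#'
#' The initial trajectory angle, measured between the vertical and the
#' chord from the base to the point reached at arc length `d` along the
#' path (default 2 mm). Paths shorter than `d` yield `NA` (measurement
#' deferred until the lateral is long enough).
#'
#' @param path Ordered pixel path, n x 2 matrix of (row, col).
#' @param d_mm Distance from the base along the path, mm.
#' @param scale mm per pixel.
#' @return Angle in degrees or `NA` if the path is shorter than `d_mm`.
#' @export
emergence_angle <- function(path, d_mm = 2, scale = 0.04, base = NULL) {
  if (is.null(path) || nrow(path) < 2L) return(NA_real_)
  if (is.null(base)) base <- path[1, ]
  offset <- sqrt(sum((base - path[1, ])^2)) * scale
  arc <- path_cum_arc(path) * scale + offset
  if (arc[length(arc)] < d_mm) return(NA_real_)
  i <- which(arc >= d_mm)[1]
  pd <- path[i, ]
  # (row, col) -> (x = col, y = row)
  base_tip_angle(c(base[2], base[1]), c(pd[2], pd[1]))
}

# Sub-pixel refinement of a lateral's base: thinning drags the branch point
# a few pixels down the main axis, so the base is re-estimated as the point
# where the lateral's initial direction (chord over its first pixels beyond
# the junction zone) back-projects onto the main path.
refine_lateral_base <- function(lat_path, main_path) {
  fallback <- lat_path[1, ]
  if (is.null(main_path) || nrow(lat_path) < 5L) return(fallback)
  arc <- path_cum_arc(lat_path)
  sel <- which(arc >= 5 & arc <= 24)
  if (length(sel) < 2L) sel <- which(arc >= 3 & arc <= 15)
  if (length(sel) < 2L) return(fallback)
  a <- lat_path[sel[1], ]; b <- lat_path[sel[length(sel)], ]
  v <- b - a; nv <- sqrt(sum(v^2))
  if (nv < 1e-9) return(fallback)
  v <- v / nv
  d0 <- sqrt((main_path[, 1] - fallback[1])^2 +
               (main_path[, 2] - fallback[2])^2)
  cand <- which(d0 <= 12)
  if (!length(cand)) return(fallback)
  rel <- sweep(main_path[cand, , drop = FALSE], 2, a)
  t_ <- as.numeric(rel %*% v)
  perp2 <- rowSums(rel^2) - t_^2
  best <- which.min(perp2)
  refined <- a + t_[best] * v
  if (sqrt(sum((refined - fallback)^2)) > 8) return(fallback)
  refined
}

#' Basic architecture metrics from labeled axes
#'
#' Main-root length, total lateral length, total root length, lateral count,
#' discrete lateral density (`10 * n_LR / MR_cm` i.e. LRs per cm of main
#' root) and the main-over-total ratio. When the main root has zero length
#' the density and ratio are `NA` (undefined, not 0).
#'
#' @param axes An `axis_labeling` (see [classify_axes()]).
#' @param scale mm per pixel.
#' @return Named list: `mr_mm`, `lr_mm`, `tr_mm`, `n_lr`, `density_lr_cm`,
#'   `main_over_total`.
#' @export
architecture_metrics <- function(axes, scale = 0.04) {
  mr <- axes$main$length_px * scale
  lr <- sum(vapply(axes$laterals, `[[`, numeric(1), "length_px")) * scale
  n <- length(axes$laterals)
  tr <- mr + lr
  list(
    mr_mm = mr, lr_mm = lr, tr_mm = tr, n_lr = n,
    density_lr_cm = if (mr > 0) 10 * n / mr else NA_real_,
    main_over_total = if (tr > 0) mr / tr else NA_real_
  )
}

#' Convex hull metrics of a root system
#'
#' Convex hull of the root pixel cloud in mm: area (shoelace formula on the
#' hull polygon), width (max horizontal extent), height (max vertical
#' extent), root density (total root length / hull area) and aspect ratio
#' (height / width). Degenerate clouds (fewer than 3 non-collinear points)
#' have zero area and `NA` density.
#'
#' @param pixels n x 2 matrix of root pixel (row, col) coordinates.
#' @param scale mm per pixel.
#' @param total_root_length_mm Total root length for the density, mm.
#' @return Named list: `area_mm2`, `width_mm`, `height_mm`,
#'   `density_mm_mm2`, `aspect`.
#' @export
convex_hull_metrics <- function(pixels, scale = 0.04,
                                total_root_length_mm = NA_real_) {
  if (is.null(pixels) || nrow(pixels) == 0L)
    return(list(area_mm2 = 0, width_mm = 0, height_mm = 0,
                density_mm_mm2 = NA_real_, aspect = NA_real_))
  x <- pixels[, 2] * scale
  y <- pixels[, 1] * scale
  w <- diff(range(x)); h <- diff(range(y))
  area <- 0
  if (nrow(pixels) >= 3L) {
    hull <- chull(x, y)
    if (length(hull) >= 3L) {
      hx <- x[hull]; hy <- y[hull]
      area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
    }
  }
  list(
    area_mm2 = area, width_mm = w, height_mm = h,
    density_mm_mm2 = if (area > 0) total_root_length_mm / area else NA_real_,
    aspect = if (w > 0) h / w else NA_real_
  )
}

#' Angle measurements for every lateral of a labeling
#'
#' @param axes An `axis_labeling`.
#' @param scale mm per pixel.
#' @param d_mm Emergence-angle distance from the base, mm.
#' @return Data frame `lateral_id`, `theta_bt`, `theta_e`, `base_row`,
#'   `base_col`, `tip_row`, `tip_col`, `length_mm`.
#' @export
lateral_angles <- function(axes, scale = 0.04, d_mm = 2) {
  if (length(axes$laterals) == 0L)
    return(data.frame(lateral_id = integer(0), theta_bt = numeric(0),
                      theta_e = numeric(0), base_row = numeric(0),
                      base_col = numeric(0), tip_row = numeric(0),
                      tip_col = numeric(0), length_mm = numeric(0)))
  do.call(rbind, lapply(axes$laterals, function(l) {
    sp <- path_smooth(l$path)
    base <- refine_lateral_base(sp, axes$main$path)
    tbt <- if (!all(base == l$tip_rc))
      base_tip_angle(c(base[2], base[1]),
                     c(l$tip_rc[2], l$tip_rc[1])) else NA_real_
    data.frame(
      lateral_id = l$id, theta_bt = tbt,
      theta_e = emergence_angle(sp, d_mm = d_mm, scale = scale,
                                base = base),
      base_row = base[1], base_col = base[2],
      tip_row = l$tip_rc[1], tip_col = l$tip_rc[2],
      length_mm = l$length_px * scale
    )
  }))
}
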