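# Root System Markup Language (RSML) export and import.
#
# The document stores the hierarchical main/lateral structure with polyline
# coordinates in pixels; the metadata block carries the spatial resolution
# (pixels per mm) so consumers can convert. Writing is fully deterministic:
# a write -> read -> write round trip is byte-identical.

fmt_num <- function(v) {
  ifelse(abs(v - round(v)) < 1e-9, sprintf("%d", as.integer(round(v))),
         sprintf("%.4f", v))
}

#' Convert labeled axes to an RSML scene
#'
#' @param axes_list List of `axis_labeling` objects, one per plant (or a
#'   single `axis_labeling`).
#' @param scale mm per pixel.
#' @param dt Frame interval in minutes (stored as metadata).
#' @param plant_ids Optional plant identifiers.
#' @return An `rsml_scene` list (metadata + plants + nested roots).
#' @export
as_rsml_scene <- function(axes_list, scale = 0.04, dt = 15,
                          plant_ids = NULL) {
  if (inherits(axes_list, "axis_labeling")) axes_list <- list(axes_list)
  if (is.null(plant_ids)) plant_ids <- seq_along(axes_list)
  plants <- lapply(seq_along(axes_list), function(i) {
    ax <- axes_list[[i]]
    if (is.null(ax) || is.null(ax$main))
      return(list(id = plant_ids[i], roots = list()))
    main_path <- ax$main$path
    laterals <- lapply(ax$laterals, function(l) {
      props <- list(length = l$length_px * scale)
      ang <- tryCatch(
        base_tip_angle(c(l$base_rc[2], l$base_rc[1]),
                       c(l$tip_rc[2], l$tip_rc[1])), error = function(e) NA)
      if (is.finite(ang)) props$theta_bt <- ang
      te <- emergence_angle(l$path, scale = scale)
      if (is.finite(te)) props$theta_e <- te
      if (!is.null(l$emergence_time_h) && is.finite(l$emergence_time_h))
        props$emergence_time_h <- l$emergence_time_h
      list(id = paste0(plant_ids[i], ".1.", l$id), order = 2L,
           path = cbind(x = l$path[, 2], y = l$path[, 1]),
           props = props, children = list())
    })
    root <- list(id = paste0(plant_ids[i], ".1"), order = 1L,
                 path = cbind(x = main_path[, 2], y = main_path[, 1]),
                 props = list(length = ax$main$length_px * scale),
                 children = laterals)
    list(id = plant_ids[i], roots = list(root))
  })
  structure(list(
    metadata = list(version = "1.0", unit = "mm",
                    resolution = 1 / scale, dt_min = dt,
                    software = "rhizolapse"),
    plants = plants
  ), class = "rsml_scene")
}

append_root_node <- function(parent, root) {
  rn <- xml2::xml_add_child(parent, "root", id = as.character(root$id),
                            label = if (root$order == 1L) "main" else "lateral",
                            order = as.character(root$order))
  geom <- xml2::xml_add_child(rn, "geometry")
  poly <- xml2::xml_add_child(geom, "polyline")
  if (is.null(root$path) || nrow(root$path) == 0L)
    stop("root polyline must be non-empty")
  for (i in seq_len(nrow(root$path))) {
    xml2::xml_add_child(poly, "point", x = fmt_num(root$path[i, 1]),
                        y = fmt_num(root$path[i, 2]))
  }
  if (length(root$props)) {
    pn <- xml2::xml_add_child(rn, "properties")
    for (nm in names(root$props)) {
      v <- root$props[[nm]]
      vn <- xml2::xml_add_child(pn, nm)
      xml2::xml_set_text(vn, if (is.numeric(v)) fmt_num(v) else
        as.character(v))
    }
  }
  for (ch in root$children) append_root_node(rn, ch)
  invisible(rn)
}

#' Write an RSML document
#'
#' Serializes labeled root axes (or a parsed `rsml_scene`) to RSML 1.x XML
#' with coordinates in pixels and the mm-per-pixel calibration carried in
#' the metadata `resolution` (pixels per `unit`). Output is deterministic.
#'
#' @param x An `axis_labeling`, list of them, or an `rsml_scene`.
#' @param file Output path.
#' @param scale,dt,plant_ids Passed to [as_rsml_scene()] when `x` is not
#'   already a scene.
#' @return `file`, invisibly.
#' @export
write_rsml <- function(x, file, scale = 0.04, dt = 15, plant_ids = NULL) {
  scene <- if (inherits(x, "rsml_scene")) x else
    as_rsml_scene(x, scale = scale, dt = dt, plant_ids = plant_ids)
  doc <- xml2::xml_new_root("rsml")
  md <- xml2::xml_add_child(doc, "metadata")
  xml2::xml_add_child(md, "version", scene$metadata$version)
  xml2::xml_add_child(md, "unit", scene$metadata$unit)
  xml2::xml_add_child(md, "resolution", fmt_num(scene$metadata$resolution))
  xml2::xml_add_child(md, "software", scene$metadata$software)
  if (!is.null(scene$metadata$dt_min))
    xml2::xml_add_child(md, "observation-interval",
                        fmt_num(scene$metadata$dt_min))
  sc <- xml2::xml_add_child(doc, "scene")
  for (pl in scene$plants) {
    pn <- xml2::xml_add_child(sc, "plant", id = as.character(pl$id))
    for (rt in pl$roots) {
      if (rt$order != 1L)
        stop("top-level roots of a plant must be order 1 (main)")
      append_root_node(pn, rt)
    }
  }
  xml2::write_xml(doc, file)
  invisible(file)
}

parse_root_node <- function(rn, depth = 1L) {
  order <- xml2::xml_attr(rn, "order")
  order <- if (is.na(order)) depth else as.integer(order)
  pts <- xml2::xml_find_all(rn, "./geometry/polyline/point")
  if (length(pts) == 0L)
    stop("RSML error: root '", xml2::xml_attr(rn, "id"),
         "' has an empty polyline")
  path <- cbind(x = as.numeric(xml2::xml_attr(pts, "x")),
                y = as.numeric(xml2::xml_attr(pts, "y")))
  props <- list()
  for (p in xml2::xml_children(xml2::xml_find_first(rn, "./properties"))) {
    val <- xml2::xml_text(p)
    num <- suppressWarnings(as.numeric(val))
    props[[xml2::xml_name(p)]] <- if (!is.na(num)) num else val
  }
  children <- lapply(xml2::xml_find_all(rn, "./root"), parse_root_node,
                     depth = depth + 1L)
  list(id = xml2::xml_attr(rn, "id"), order = order, path = path,
       props = props, children = children)
}

#' Read an RSML document
#'
#' Inverse of [write_rsml()] for documents this package writes, and a
#' tolerant reader for foreign files (absent optional properties load as
#' missing). Structural violations — a lateral (order 2) root attached
#' directly to a plant, an empty polyline — are rejected with a diagnostic.
#'
#' @param file RSML file path.
#' @return An `rsml_scene`.
#' @export
read_rsml <- function(file) {
  doc <- xml2::read_xml(file)
  if (xml2::xml_name(doc) != "rsml") stop("not an RSML document")
  md <- xml2::xml_find_first(doc, "./metadata")
  meta <- list(
    version = xml2::xml_text(xml2::xml_find_first(md, "./version")),
    unit = xml2::xml_text(xml2::xml_find_first(md, "./unit")),
    resolution = as.numeric(
      xml2::xml_text(xml2::xml_find_first(md, "./resolution"))),
    software = xml2::xml_text(xml2::xml_find_first(md, "./software"))
  )
  oi <- xml2::xml_find_first(md, "./observation-interval")
  if (!inherits(oi, "xml_missing"))
    meta$dt_min <- as.numeric(xml2::xml_text(oi))
  plants <- lapply(xml2::xml_find_all(doc, "./scene/plant"), function(pn) {
    roots <- lapply(xml2::xml_find_all(pn, "./root"), parse_root_node)
    for (rt in roots) {
      if (rt$order != 1L)
        stop("RSML error: order-", rt$order,
             " root nested directly under plant '",
             xml2::xml_attr(pn, "id"), "' (laterals must nest in a root)")
    }
    list(id = xml2::xml_attr(pn, "id"), roots = roots)
  })
  structure(list(metadata = meta, plants = plants), class = "rsml_scene")
}

#' Validate the structure of an RSML document
#'
#' Checks the structural contract this package relies on: an `rsml` root
#' with a metadata block (version, unit, resolution), a scene, plants whose
#' top-level roots are order 1, non-empty polylines with numeric x/y on
#' every point, and laterals nested within their parent root.
#'
#' @param file RSML file path.
#' @return `TRUE` on success; otherwise an error describing the violation.
#' @export
validate_rsml <- function(file) {
  scene <- read_rsml(file)
  if (is.na(scene$metadata$resolution) || scene$metadata$resolution <= 0)
    stop("RSML error: missing or non-positive resolution")
  if (!nzchar(scene$metadata$unit)) stop("RSML error: missing unit")
  check_root <- function(rt) {
    if (any(!is.finite(rt$path))) stop("RSML error: non-numeric coordinates")
    for (ch in rt$children) {
      if (ch$order <= rt$order)
        stop("RSML error: child root order must exceed parent order")
      check_root(ch)
    }
  }
  for (pl in scene$plants) for (rt in pl$roots) check_root(rt)
  TRUE
}
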