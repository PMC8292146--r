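#' Write scene annotations as ASAP XML
#'
#' Serializes ground-truth dots (one per cell-marker membership, grouped by
#' marker), ROI inclusion polygons (group `"cortex"`), exclusion polygons
#' (group `"exclusion"`) and the capsule polyline (group `"capsule"`) in the
#' XML dialect of the ASAP slide-annotation platform. Coordinates are global
#' pixels.
#'
#' @param scene a `scene_gt`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(scene, path) {
  stop_if_not(inherits(scene, "scene_gt"), "scene must be a scene_gt")
  dots <- scene_dots(scene)
  doc <- xml2::xml_new_root("ASAP_Annotations")
  anns <- xml2::xml_add_child(doc, "Annotations")
  add_ann <- function(name, type, group, coords) {
    a <- xml2::xml_add_child(anns, "Annotation", Name = name, Type = type,
                             PartOfGroup = group, Color = "#F4FA58")
    cs <- xml2::xml_add_child(a, "Coordinates")
    for (i in seq_len(nrow(coords)))
      xml2::xml_add_child(cs, "Coordinate", Order = as.character(i - 1),
                          X = format(coords[i, 1], digits = 17),
                          Y = format(coords[i, 2], digits = 17))
  }
  for (i in seq_len(nrow(dots)))
    add_ann(sprintf("dot_%d", i), "Dot", dots$marker[i],
            cbind(dots$x[i], dots$y[i]))
  r <- scene$roi
  for (i in seq_along(r$inclusions))
    add_ann(sprintf("cortex_%d", i), "Polygon", "cortex", r$inclusions[[i]])
  for (i in seq_along(r$exclusions))
    add_ann(sprintf("exclusion_%d", i), "Polygon", "exclusion", r$exclusions[[i]])
  if (!is.null(r$capsule))
    add_ann("capsule", "Spline", "capsule", r$capsule)
  groups <- xml2::xml_add_child(doc, "AnnotationGroups")
  for (g in unique(c(dots$marker, "cortex", "exclusion", "capsule")))
    xml2::xml_add_child(groups, "Group", Name = g, PartOfGroup = "None",
                        Color = "#64FE2E")
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read ASAP XML annotations
#'
#' Parses dot annotations and polygon/polyline annotations from an ASAP XML
#' file. Dots become a [detection_table()]; polygons in group `"cortex"` /
#' `"exclusion"` and the `"capsule"` polyline are assembled into an [roi]
#' when present.
#'
#' @param path XML file path.
#' @param pixel_size micrometers per pixel recorded on the returned ROI.
#' @return List with `dots` (data frame) and `roi` ([roi] or `NULL`).
#' @export
read_annotations <- function(path, pixel_size = 0.49) {
  doc <- xml2::read_xml(path)
  anns <- xml2::xml_find_all(doc, ".//Annotation")
  dots <- list(); incl <- list(); excl <- list(); capsule <- NULL
  for (a in anns) {
    type <- xml2::xml_attr(a, "Type")
    group <- xml2::xml_attr(a, "PartOfGroup")
    cs <- xml2::xml_find_all(a, ".//Coordinate")
    xy <- cbind(x = as.numeric(xml2::xml_attr(cs, "X")),
                y = as.numeric(xml2::xml_attr(cs, "Y")))
    ord <- as.numeric(xml2::xml_attr(cs, "Order"))
    xy <- xy[order(ord), , drop = FALSE]
    if (identical(type, "Dot")) {
      dots[[length(dots) + 1]] <- data.frame(
        marker = group, x = xy[1, 1], y = xy[1, 2], confidence = 1,
        stringsAsFactors = FALSE)
    } else if (identical(group, "cortex")) {
      incl[[length(incl) + 1]] <- xy
    } else if (identical(group, "exclusion")) {
      excl[[length(excl) + 1]] <- xy
    } else if (identical(group, "capsule")) {
      capsule <- xy
    }
  }
  dots <- if (length(dots)) do.call(rbind, dots) else detection_table()
  r <- if (length(incl))
    roi(incl, excl, capsule, pixel_size = pixel_size) else NULL
  list(dots = dots, roi = r)
}

#' Write / read a detection table as CSV
#'
#' Columns: `marker`, `x_px`, `y_px`, `x_um`, `y_um`, `confidence`.
#'
#' @param dets a [detection_table()].
#' @param path CSV path.
#' @param pixel_size micrometers per pixel.
#' @return The path / the detection table.
#' @export
write_detections_csv <- function(dets, path, pixel_size = 0.49) {
  out <- data.frame(marker = dets$marker,
                    x_px = dets$x, y_px = dets$y,
                    x_um = dets$x * pixel_size, y_um = dets$y * pixel_size,
                    confidence = dets$confidence)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detections_csv
#' @export
read_detections_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  detection_table(d$marker, d$x_px, d$y_px, d$confidence)
}
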