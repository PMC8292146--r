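#' Region of interest
#'
#' An ROI models the annotated cortical tubulointerstitium of a biopsy:
#' inclusion polygons, exclusion polygons (glomeruli, arteries, capsule) and
#' an optional capsule polyline used to derive the subcapsular band. All
#' polygon vertices are in global pixel coordinates; areas are reported in
#' square millimeters via the pixel size.
#'
#' @param inclusions list of two-column matrices (x, y vertices, px).
#' @param exclusions list of two-column matrices, assumed to lie inside the
#'   inclusions.
#' @param capsule optional two-column matrix: a polyline tracing the capsule.
#' @param pixel_size micrometers per pixel.
#' @return An object of class `roi`.
#' @export
roi <- function(inclusions, exclusions = list(), capsule = NULL,
                pixel_size = 0.49) {
  stop_if_not(length(inclusions) >= 1, "at least one inclusion polygon required")
  chk <- function(p) {
    p <- as.matrix(p)
    stop_if_not(ncol(p) == 2 && nrow(p) >= 3, "polygons need >= 3 x,y vertices")
    colnames(p) <- c("x", "y")
    p
  }
  inclusions <- lapply(inclusions, chk)
  exclusions <- lapply(exclusions, chk)
  if (!is.null(capsule)) {
    capsule <- as.matrix(capsule)
    stop_if_not(ncol(capsule) == 2 && nrow(capsule) >= 2,
                "capsule must be a polyline with >= 2 vertices")
    colnames(capsule) <- c("x", "y")
  }
  out <- structure(list(inclusions = inclusions, exclusions = exclusions,
                        capsule = capsule, pixel_size = pixel_size),
                   class = "roi")
  stop_if_not(roi_area_mm2(out) > 0, "ROI area must be strictly positive")
  out
}

#' @export
print.roi <- function(x, ...) {
  cat("roi:", length(x$inclusions), "inclusion(s),",
      length(x$exclusions), "exclusion(s),",
      if (is.null(x$capsule)) "no capsule," else "capsule present,",
      sprintf("area %.4f mm2\n", roi_area_mm2(x)))
  invisible(x)
}

# Shoelace polygon area (px^2), sign-free.
polygon_area_px2 <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  n <- nrow(p)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' ROI area in square millimeters
#'
#' Polygon area of the inclusions minus the exclusions (shoelace formula),
#' converted through the pixel size.
#'
#' @param x an [roi].
#' @return Area in mm^2.
#' @export
roi_area_mm2 <- function(x) {
  px2 <- sum(vapply(x$inclusions, polygon_area_px2, numeric(1))) -
    sum(vapply(x$exclusions, polygon_area_px2, numeric(1)))
  px2 * (x$pixel_size / 1000)^2
}

#' Even-odd point-in-polygon test
#'
#' Vectorized over points; points on a polygon edge count as inside
#' (tolerance `eps` in pixel units).
#'
#' @param px,py point coordinates.
#' @param poly two-column vertex matrix.
#' @param eps boundary tolerance.
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, poly, eps = 1e-9) {
  vx <- poly[, 1]; vy <- poly[, 2]
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    # boundary: point within eps of segment (i, j)
    dx <- xj - xi; dy <- yj - yi
    len2 <- dx * dx + dy * dy
    t <- if (len2 > 0) pmin(1, pmax(0, ((px - xi) * dx + (py - yi) * dy) / len2)) else 0
    d2 <- (px - (xi + t * dx))^2 + (py - (yi + t * dy))^2
    on_edge <- on_edge | d2 <= eps^2
    # even-odd ray cast
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross & !is.na(cross))
    j <- i
  }
  inside | on_edge
}

#' Minimum distance from points to a polyline
#'
#' @param px,py point coordinates (px).
#' @param line two-column vertex matrix of the polyline.
#' @return Distance in the same (pixel) units, vectorized over points.
#' @export
dist_to_polyline <- function(px, py, line) {
  best <- rep(Inf, length(px))
  for (i in seq_len(nrow(line) - 1)) {
    xi <- line[i, 1]; yi <- line[i, 2]
    dx <- line[i + 1, 1] - xi; dy <- line[i + 1, 2] - yi
    len2 <- dx * dx + dy * dy
    t <- if (len2 > 0) pmin(1, pmax(0, ((px - xi) * dx + (py - yi) * dy) / len2)) else 0
    d2 <- (px - (xi + t * dx))^2 + (py - (yi + t * dy))^2
    best <- pmin(best, d2)
  }
  sqrt(best)
}

roi_contains <- function(x, px, py) {
  inc <- rep(FALSE, length(px))
  for (p in x$inclusions) inc <- inc | point_in_polygon(px, py, p)
  exc <- rep(FALSE, length(px))
  # only the strict interior of an exclusion is removed: a point sitting on
  # an exclusion boundary still counts as ROI, mirroring the inclusive
  # convention on inclusion boundaries
  for (p in x$exclusions)
    exc <- exc | (point_in_polygon(px, py, p) & !on_polygon_edge(px, py, p))
  inc & !exc
}

on_polygon_edge <- function(px, py, poly, eps = 1e-9) {
  res <- rep(FALSE, length(px))
  n <- nrow(poly)
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[j, 1]; yi <- poly[j, 2]
    dx <- poly[i, 1] - xi; dy <- poly[i, 2] - yi
    len2 <- dx * dx + dy * dy
    t <- if (len2 > 0) pmin(1, pmax(0, ((px - xi) * dx + (py - yi) * dy) / len2)) else 0
    d2 <- (px - (xi + t * dx))^2 + (py - (yi + t * dy))^2
    res <- res | d2 <= eps^2
    j <- i
  }
  res
}

#' Split an ROI at the subcapsular band
#'
#' The subcapsular band is the part of the ROI lying within `band_um`
#' (default 400 um, the conventional depth below the renal capsule within
#' which inflammation is regarded as non-specific) Euclidean distance of the
#' capsule polyline. Returns two region objects that partition the ROI:
#' points belong to the band iff their distance to the capsule is
#' `<= band_um`, and to the interior otherwise.
#'
#' @param x an [roi] with a capsule polyline.
#' @param band_um band width in micrometers.
#' @return List with elements `interior` and `band`, both of class
#'   `roi_region`, supporting [region_contains()] and [region_area_mm2()].
#' @export
subcapsular_band <- function(x, band_um = 400) {
  stop_if_not(inherits(x, "roi"), "x must be an roi")
  if (is.null(x$capsule))
    stop("subcapsular band requested but the ROI has no capsule polyline",
         call. = FALSE)
  stop_if_not(band_um >= 0, "band_um must be non-negative")
  mk <- function(side) structure(list(roi = x, band_um = band_um, side = side),
                                 class = "roi_region")
  list(interior = mk("interior"), band = mk("band"))
}

#' Membership test for an ROI or subcapsular region
#'
#' @param region an [roi] or an `roi_region` from [subcapsular_band()].
#' @param px,py global pixel coordinates.
#' @return Logical vector.
#' @export
region_contains <- function(region, px, py) {
  if (inherits(region, "roi")) return(roi_contains(region, px, py))
  stop_if_not(inherits(region, "roi_region"), "not an roi or roi_region")
  base <- roi_contains(region$roi, px, py)
  band_px <- region$band_um / region$roi$pixel_size
  d <- dist_to_polyline(px, py, region$roi$capsule)
  if (region$side == "band") base & d <= band_px & region$band_um > 0
  else base & !(d <= band_px & region$band_um > 0)
}

#' Area of an ROI or subcapsular region
#'
#' Polygonal ROIs use the exact shoelace area; band-split regions are
#' measured by rasterizing the region on the pixel grid (pixel centers at
#' integer coordinates), so their accuracy is one pixel around the band
#' boundary.
#'
#' @param region an [roi] or `roi_region`.
#' @param grid_step rasterization step in pixels (1 = native resolution).
#' @return Area in mm^2.
#' @export
region_area_mm2 <- function(region, grid_step = 1) {
  if (inherits(region, "roi")) return(roi_area_mm2(region))
  stop_if_not(inherits(region, "roi_region"), "not an roi or roi_region")
  r <- region$roi
  all_v <- do.call(rbind, r$inclusions)
  xr <- range(all_v[, 1]); yr <- range(all_v[, 2])
  gx <- seq(floor(xr[1]), ceiling(xr[2]), by = grid_step)
  gy <- seq(floor(yr[1]), ceiling(yr[2]), by = grid_step)
  px <- rep(gx, times = length(gy))
  py <- rep(gy, each = length(gx))
  keep <- region_contains(region, px, py)
  sum(keep) * (grid_step * r$pixel_size / 1000)^2
}
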