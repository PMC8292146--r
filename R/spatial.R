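#' Restrict points to a region of interest
#'
#' Keeps points inside an inclusion polygon and outside all exclusion
#' polygons (boundary points count as inside). Accepts a plain [roi] or a
#' subcapsular region from [subcapsular_band()].
#'
#' @param points a [detection_table()] in the ROI's pixel frame.
#' @param region an [roi] or `roi_region`.
#' @return The retained rows of `points`.
#' @export
filter_to_roi <- function(points, region) {
  if (nrow(points) == 0) return(points)
  keep <- region_contains(region, points$x, points$y)
  points[keep, , drop = FALSE]
}

#' Cell count and density inside a region
#'
#' @param points a [detection_table()].
#' @param region an [roi] or `roi_region` with positive area.
#' @param population label stored on the result (defaults to the points'
#'   marker).
#' @return Object of class `population_quant`: `population`, `count`,
#'   `area_mm2`, `density` (cells/mm^2).
#' @export
cell_density <- function(points, region, population = NULL) {
  area <- region_area_mm2(region)
  stop_if_not(area > 0, "region area must be positive")
  inside <- filter_to_roi(points, region)
  if (is.null(population))
    population <- if (nrow(points) > 0) paste(unique(points$marker),
                                              collapse = "/") else NA_character_
  structure(list(population = population, count = nrow(inside),
                 area_mm2 = area, density = nrow(inside) / area),
            class = "population_quant")
}

#' @export
print.population_quant <- function(x, ...) {
  cat(sprintf("%s: %d cells in %.4f mm2 = %.1f cells/mm2\n",
              x$population, x$count, x$area_mm2, x$density))
  invisible(x)
}

# one-to-one greedy pairing in ascending distance; strict "<" per the
# double-positivity convention, ties broken by (A index, B index)
greedy_pairs <- function(a, b, radius_um, pixel_size, strict = TRUE) {
  na <- nrow(a); nb <- nrow(b)
  if (na == 0 || nb == 0)
    return(data.frame(a = integer(), b = integer(), dist_um = numeric()))
  dmat <- sqrt(outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2) * pixel_size
  ok <- if (strict) which(dmat < radius_um) else which(dmat <= radius_um)
  out <- data.frame(a = integer(), b = integer(), dist_um = numeric())
  if (length(ok)) {
    ai <- (ok - 1) %% na + 1
    bi <- (ok - 1) %/% na + 1
    dd <- dmat[ok]
    ord <- order(dd, ai, bi)
    ua <- rep(FALSE, na); ub <- rep(FALSE, nb)
    for (k in ord) {
      if (ua[ai[k]] || ub[bi[k]]) next
      ua[ai[k]] <- TRUE; ub[bi[k]] <- TRUE
      out <- rbind(out, data.frame(a = ai[k], b = bi[k], dist_um = dd[k]))
    }
  }
  out
}

#' Double-positive cells from two marker channels
#'
#' A cell detected in channel A is double-positive when a detection in
#' channel B lies strictly within `radius_um` of it; pairing is one-to-one
#' greedy in ascending distance, so one B detection cannot validate two A
#' detections. The conventional radii are the cell diameters: 4 um for
#' lymphocyte pairs, 21 um for macrophage pairs.
#'
#' @param dets_a,dets_b [detection_table()]s for the two channels.
#' @param radius_um pairing radius in micrometers (> 0); strict `<`.
#' @param pixel_size micrometers per pixel.
#' @return The paired rows of `dets_a`, with extra columns `partner`
#'   (row index into `dets_b`) and `pair_dist_um`.
#' @export
double_positive <- function(dets_a, dets_b, radius_um, pixel_size = 0.49) {
  stop_if_not(radius_um > 0, "radius must be positive")
  pr <- greedy_pairs(dets_a, dets_b, radius_um, pixel_size, strict = TRUE)
  out <- dets_a[pr$a, , drop = FALSE]
  out$partner <- pr$b
  out$pair_dist_um <- pr$dist_um
  out
}

#' Geometric subtraction of one population from another
#'
#' Returns the A detections left unpaired by the [double_positive()]
#' pairing, i.e. the A+B- population (e.g. CD3+CD8- T cells). Together with
#' [double_positive()] this partitions A for any input.
#'
#' @inheritParams double_positive
#' @return The unpaired rows of `dets_a`.
#' @export
subtract_population <- function(dets_a, dets_b, radius_um, pixel_size = 0.49) {
  stop_if_not(radius_um > 0, "radius must be positive")
  pr <- greedy_pairs(dets_a, dets_b, radius_um, pixel_size, strict = TRUE)
  keep <- setdiff(seq_len(nrow(dets_a)), pr$a)
  dets_a[keep, , drop = FALSE]
}

#' Ratio of two population counts
#'
#' @param quant_a,quant_b `population_quant` objects (or bare counts).
#' @return The count ratio, or `NA` with a warning when the denominator is
#'   zero (the per-patient value is then excluded from group statistics).
#' @export
population_ratio <- function(quant_a, quant_b) {
  ca <- if (inherits(quant_a, "population_quant")) quant_a$count else quant_a
  cb <- if (inherits(quant_b, "population_quant")) quant_b$count else quant_b
  if (cb == 0) {
    warning("zero denominator population; ratio flagged as missing",
            call. = FALSE)
    return(NA_real_)
  }
  ca / cb
}

#' Mean shortest distance between two cell populations
#'
#' For every source cell, the Euclidean distance to its nearest target cell;
#' the summary is the mean over source cells, reported both in micrometers
#' and in pixels. The measure is directional: source-to-target need not
#' equal target-to-source.
#'
#' @param source_dets,target_dets [detection_table()]s.
#' @param pixel_size micrometers per pixel.
#' @return Object of class `distance_summary`: `mean_um`, `mean_px`,
#'   `n_source`, `n_target`, `defined` (FALSE when either population is
#'   empty).
#' @export
mean_shortest_distance <- function(source_dets, target_dets,
                                   pixel_size = 0.49) {
  ns <- nrow(source_dets); nt <- nrow(target_dets)
  if (ns == 0 || nt == 0)
    return(structure(list(mean_um = NA_real_, mean_px = NA_real_,
                          n_source = ns, n_target = nt, defined = FALSE),
                     class = "distance_summary"))
  dmat <- sqrt(outer(source_dets$x, target_dets$x, "-")^2 +
                 outer(source_dets$y, target_dets$y, "-")^2)
  nn_px <- apply(dmat, 1, min)
  structure(list(mean_um = mean(nn_px) * pixel_size, mean_px = mean(nn_px),
                 n_source = ns, n_target = nt, defined = TRUE),
            class = "distance_summary")
}

#' @export
print.distance_summary <- function(x, ...) {
  if (!x$defined) cat("distance_summary: undefined (empty population)\n")
  else cat(sprintf("mean shortest distance: %.2f um (%.2f px) over %d cells\n",
                   x$mean_um, x$mean_px, x$n_source))
  invisible(x)
}

#' Otsu threshold of a value vector
#'
#' Maximizes between-class variance over a histogram of `levels` equal-width
#' bins spanning the data range; returns the lower edge of the first bin of
#' the upper class, so `value >= threshold` selects the positive class.
#'
#' @param values numeric vector.
#' @param levels number of histogram bins.
#' @return Threshold on the value scale.
#' @export
otsu_threshold <- function(values, levels = 256) {
  values <- values[is.finite(values)]
  stop_if_not(length(values) > 0, "no finite values to threshold")
  rng <- range(values)
  if (rng[1] == rng[2]) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = levels + 1)
  h <- tabulate(findInterval(values, br, rightmost.closed = TRUE),
                nbins = levels)
  w <- h / sum(h)
  mids <- (br[-1] + br[-(levels + 1)]) / 2
  w0 <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[levels]
  sb <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- 0
  k <- which.max(sb[-levels])
  br[k + 1]
}

#' Positive-pixel percentage of a plane inside a region
#'
#' Thresholds the plane (automatic Otsu threshold computed on the ROI
#' pixels, or a fixed value) and reports positive pixels as a percentage of
#' all pixels inside the region. Used for endothelial (CD34) capillary
#' extent.
#'
#' @param plane a [channel_plane] or matrix (origin (0,0) assumed for bare
#'   matrices).
#' @param region an [roi] or `roi_region` overlapping the plane.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold fixed threshold (required for `method = "fixed"`).
#' @return List: `percentage`, `threshold`, `n_roi_px`, `n_positive_px`.
#' @export
positive_pixel_fraction <- function(plane, region, method = c("otsu", "fixed"),
                                    threshold = NULL) {
  method <- match.arg(method)
  origin <- c(0, 0)
  if (inherits(plane, "channel_plane")) {
    origin <- plane$origin
    plane <- plane$abundance
  }
  cx <- rep(seq_len(ncol(plane)) - 1 + origin[1], each = nrow(plane))
  cy <- rep(seq_len(nrow(plane)) - 1 + origin[2], times = ncol(plane))
  inside <- region_contains(region, cx, cy)
  if (!any(inside))
    stop("region does not overlap the plane", call. = FALSE)
  vals <- plane[inside]
  thr <- switch(method,
                otsu = otsu_threshold(vals),
                fixed = {
                  stop_if_not(!is.null(threshold), "fixed method needs a threshold")
                  threshold
                })
  list(percentage = 100 * mean(vals >= thr), threshold = thr,
       n_roi_px = length(vals), n_positive_px = sum(vals >= thr))
}
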