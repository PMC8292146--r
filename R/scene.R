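#' Marker panel vocabulary
#'
#' Marker labels understood by the synthetic-scene generator, together with
#' the cell class each one stains. CD68 and CD163 are macrophage markers
#' (nominal cell diameter 21 um); CD3, CD4, CD8, CD20, Tbet and GATA3 are
#' lymphocyte markers (nominal diameter 4 um); CD34 marks capillary
#' endothelium and is rendered as a region mask, not as point cells; DAPI is
#' the nuclear counterstain carried by every cell.
#'
#' @return Named character vector mapping marker to cell class.
#' @export
marker_classes <- function() {
  c(CD3 = "lymphocyte", CD4 = "lymphocyte", CD8 = "lymphocyte",
    CD20 = "lymphocyte", Tbet = "lymphocyte", GATA3 = "lymphocyte",
    CD68 = "macrophage", CD163 = "macrophage",
    CD34 = "capillary", DAPI = "nuclear")
}

#' Nominal cell size by class
#'
#' @param class character vector of cell classes.
#' @return Cell diameter in micrometers (4 for lymphocytes, 21 for
#'   macrophages).
#' @export
cell_size_um <- function(class) {
  unname(c(lymphocyte = 4, macrophage = 21)[class])
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a ground-truthed synthetic tissue scene
#'
#' Plants point cells with known marker memberships, a capillary mask with a
#' known positive-area fraction, a rectangular cortical region of interest
#' with optional circular exclusions (emulating glomeruli), and a capsule
#' polyline along the top edge of the ROI. Every downstream stage of the
#' pipeline can be scored against the returned ground truth.
#'
#' Each named entry of `n_cells` plants one population carrying that marker
#' (plus DAPI). A co-localization entry `(A, B, f)` additionally gives marker
#' `B` to exactly `round(f * n_A)` randomly chosen cells of population `A`,
#' so planted double-positive counts are exact by construction.
#'
#' Cells are placed uniformly inside the ROI (outside exclusions) with a
#' minimum center separation of one cell radius, which permits clustered but
#' not fully coincident cells.
#'
#' @param n_cells named integer vector of population sizes, names drawn from
#'   [marker_classes()] (CD34 and DAPI are not valid population labels).
#' @param coloc_fractions `data.frame` with columns `a`, `b`, `fraction`
#'   (fractions in `[0, 1]`), or `NULL`.
#' @param scene_um scene width/height in micrometers (scalar or length 2).
#' @param pixel_size micrometers per pixel (default 0.49, a 20x multispectral
#'   scan).
#' @param capillary_fraction target positive-area fraction of the capillary
#'   mask inside the scene.
#' @param roi_margin_um margin between scene border and the ROI rectangle.
#' @param n_exclusions number of circular exclusion regions planted inside
#'   the ROI.
#' @param seed integer seed; the same seed reproduces the identical scene.
#' @return An object of class `scene_gt` with fields `cells` (data frame:
#'   `x_um`, `y_um`, `class`, `markers` list-column), `capillary_mask`,
#'   `capillary_fraction` (achieved), `roi` (a [roi] in pixel coordinates),
#'   `pixel_size`, `scene_um`, `dims_px`, `seed`.
#' @export
generate_scene <- function(n_cells,
                           coloc_fractions = NULL,
                           scene_um = 400,
                           pixel_size = 0.49,
                           capillary_fraction = 0.08,
                           roi_margin_um = 20,
                           n_exclusions = 0,
                           seed = 1L) {
  stop_if_not(length(n_cells) == 0 ||
                (!is.null(names(n_cells)) && all(nzchar(names(n_cells)))),
              "n_cells must be a named vector of population sizes")
  stop_if_not(all(n_cells >= 0), "population sizes must be non-negative")
  classes <- marker_classes()
  bad <- setdiff(names(n_cells), names(classes)[classes %in% c("lymphocyte", "macrophage")])
  stop_if_not(length(bad) == 0,
              paste("invalid population markers:", paste(bad, collapse = ", ")))
  if (!is.null(coloc_fractions)) {
    stop_if_not(is.data.frame(coloc_fractions) &&
                  all(c("a", "b", "fraction") %in% names(coloc_fractions)),
                "coloc_fractions must have columns a, b, fraction")
    stop_if_not(all(coloc_fractions$fraction >= 0 & coloc_fractions$fraction <= 1),
                "co-localization fractions must lie in [0, 1]")
  }
  stop_if_not(all(scene_um > 0), "scene_um must be positive")
  scene_um <- rep(as.numeric(scene_um), length.out = 2)
  dims_px <- pmax(1L, as.integer(round(scene_um / pixel_size)))

  with_seed(seed, {
    cells <- place_cells(n_cells, scene_um, roi_margin_um, n_exclusions,
                         pixel_size)
    if (!is.null(coloc_fractions)) {
      for (i in seq_len(nrow(coloc_fractions))) {
        a <- coloc_fractions$a[i]; b <- coloc_fractions$b[i]
        f <- coloc_fractions$fraction[i]
        idx <- which(cells$df$population == a)
        k <- round(f * length(idx))
        if (k > 0) {
          chosen <- if (k == length(idx)) idx else sample(idx, k)
          cells$df$markers[chosen] <- lapply(cells$df$markers[chosen],
                                             function(m) union(m, b))
        }
      }
    }
    mask <- capillary_mask(dims_px, capillary_fraction)
    structure(list(
      cells = cells$df,
      capillary_mask = mask,
      capillary_fraction = mean(mask),
      roi = cells$roi,
      pixel_size = pixel_size,
      scene_um = scene_um,
      dims_px = dims_px,
      seed = seed), class = "scene_gt")
  })
}

# Uniform placement inside the ROI rectangle minus exclusion discs, with a
# minimum separation of one cell radius from already placed cells.
place_cells <- function(n_cells, scene_um, margin_um, n_exclusions,
                        pixel_size) {
  classes <- marker_classes()
  w <- scene_um[1]; h <- scene_um[2]
  x0 <- margin_um; x1 <- w - margin_um; y0 <- margin_um; y1 <- h - margin_um
  stop_if_not(x1 > x0 && y1 > y0, "ROI margin leaves no interior")

  excl <- list()
  if (n_exclusions > 0) {
    for (i in seq_len(n_exclusions)) {
      r <- min(x1 - x0, y1 - y0) * 0.08
      cx <- runif(1, x0 + 2 * r, x1 - 2 * r)
      cy <- runif(1, y0 + 2 * r, y1 - 2 * r)
      th <- seq(0, 2 * pi, length.out = 25)[-25]
      excl[[i]] <- cbind(x = cx + r * cos(th), y = cy + r * sin(th))
    }
  }
  in_excl <- function(x, y)
    length(excl) > 0 && any(vapply(excl, function(p)
      point_in_polygon(x, y, p), logical(1)))

  xs <- numeric(0); ys <- numeric(0)
  pop <- character(0); cls <- character(0); markers <- list()
  for (m in names(n_cells)) {
    klass <- classes[[m]]
    sep <- cell_size_um(klass) / 2
    for (i in seq_len(n_cells[[m]])) {
      placed <- FALSE
      for (attempt in 1:2000) {
        px <- runif(1, x0, x1); py <- runif(1, y0, y1)
        if (in_excl(px, py)) next
        if (length(xs) == 0 || min(sqrt((xs - px)^2 + (ys - py)^2)) >= sep) {
          xs <- c(xs, px); ys <- c(ys, py)
          pop <- c(pop, m); cls <- c(cls, klass)
          markers <- c(markers, list(c("DAPI", m)))
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place cell: scene too crowded for requested counts",
             call. = FALSE)
    }
  }
  df <- data.frame(x_um = xs, y_um = ys, population = pop, class = cls,
                   stringsAsFactors = FALSE)
  df$markers <- markers

  incl <- cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
  capsule <- cbind(x = c(x0, x1), y = c(y0, y0))
  roi <- roi(inclusions = list(incl / pixel_size),
             exclusions = lapply(excl, function(p) p / pixel_size),
             capsule = capsule / pixel_size,
             pixel_size = pixel_size)
  list(df = df, roi = roi)
}

# Smooth random field thresholded at the (1 - fraction) quantile: the
# positive area matches the target fraction to within one pixel's worth.
capillary_mask <- function(dims_px, fraction) {
  if (fraction <= 0) return(matrix(0L, dims_px[2], dims_px[1]))
  field <- matrix(rnorm(prod(dims_px)), dims_px[2], dims_px[1])
  field <- as.matrix(EBImage::gblur(field, sigma = 6))
  thr <- quantile(field, 1 - fraction, names = FALSE)
  mask <- (field >= thr) * 1L
  storage.mode(mask) <- "integer"
  mask
}

#' @export
print.scene_gt <- function(x, ...) {
  cat("scene_gt:", nrow(x$cells), "cells,",
      paste(x$scene_um, collapse = " x "), "um,",
      "pixel size", x$pixel_size, "um/px, seed", x$seed, "\n")
  if (nrow(x$cells) > 0)
    print(table(x$cells$population))
  invisible(x)
}

#' Ground-truth dot annotations for a scene
#'
#' Returns the planted cell centers carrying `marker` as a detection table
#' in global pixel coordinates (a cell contributes a dot for every marker in
#' its marker set).
#'
#' @param scene a `scene_gt`.
#' @param marker marker label, or `NULL` for all non-DAPI markers.
#' @return A [detection_table()] data frame.
#' @export
scene_dots <- function(scene, marker = NULL) {
  cells <- scene$cells
  if (nrow(cells) == 0) return(detection_table())
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    mk <- setdiff(cells$markers[[i]], "DAPI")
    if (!is.null(marker)) mk <- intersect(mk, marker)
    if (length(mk) == 0) return(NULL)
    data.frame(marker = mk,
               x = cells$x_um[i] / scene$pixel_size,
               y = cells$y_um[i] / scene$pixel_size,
               confidence = 1, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) detection_table() else out
}
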