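#' Single-fluorophore abundance plane
#'
#' @param abundance non-negative numeric matrix (H x W).
#' @param fluorophore fluorophore label.
#' @param marker antibody/marker label mapped to the fluorophore (or `NA`).
#' @param origin global (x, y) pixel origin, 0-based.
#' @param pixel_size micrometers per pixel.
#' @return An object of class `channel_plane`.
#' @export
channel_plane <- function(abundance, fluorophore, marker = NA_character_,
                          origin = c(0, 0), pixel_size = 0.49) {
  abundance <- as.matrix(abundance)
  stop_if_not(all(abundance >= 0), "abundance must be non-negative")
  stop_if_not(all(origin >= 0), "origin must be >= (0, 0)")
  structure(list(abundance = abundance, fluorophore = fluorophore,
                 marker = marker, origin = as.numeric(origin),
                 pixel_size = pixel_size), class = "channel_plane")
}

#' @export
print.channel_plane <- function(x, ...) {
  cat(sprintf("channel_plane %s (marker %s): %d x %d px at origin (%g, %g)\n",
              x$fluorophore, x$marker, ncol(x$abundance), nrow(x$abundance),
              x$origin[1], x$origin[2]))
  invisible(x)
}

#' Unmix a multispectral tile into per-fluorophore abundance planes
#'
#' Per-pixel linear unmixing: each pixel's band vector is decomposed as a
#' non-negative combination of the library spectra by non-negative least
#' squares, yielding one abundance plane per fluorophore. The unconstrained
#' least-squares solution is used directly wherever it is already
#' non-negative (the common case for clean signal); only pixels whose
#' unconstrained solution violates non-negativity are re-solved with the
#' Lawson-Hanson active-set algorithm.
#'
#' @param tile an `ms_tile` (fields `intensities` H x W x B, `origin`,
#'   `pixel_size`).
#' @param library a [spectral_library]; its band count must match the tile.
#' @param markers optional named character vector fluorophore -> marker used
#'   to label the returned planes.
#' @return List of [channel_plane] objects, one per library fluorophore, in
#'   library order.
#' @export
unmix_tile <- function(tile, library, markers = NULL) {
  stop_if_not(inherits(library, "spectral_library"),
              "library must be a spectral_library")
  arr <- tile$intensities
  stop_if_not(length(dim(arr)) == 3, "tile intensities must be H x W x B")
  B <- dim(arr)[3]
  if (B != n_bands(library))
    stop(sprintf("band mismatch: tile has %d bands, library %d", B,
                 n_bands(library)), call. = FALSE)
  stop_if_not(B >= n_fluorophores(library),
              "need at least as many bands as fluorophores")
  H <- dim(arr)[1]; W <- dim(arr)[2]
  L <- library$spectra                       # B x F
  Y <- matrix(arr, nrow = H * W, ncol = B)   # pixels x B

  # unconstrained LS for all pixels at once
  G <- crossprod(L)
  A <- Y %*% L %*% solve(G)                  # pixels x F
  neg <- which(rowSums(A < -1e-10) > 0)
  for (i in neg) A[i, ] <- pracma::lsqnonneg(L, Y[i, ])$x
  A[A < 0] <- 0

  fl <- fluorophore_labels(library)
  lapply(seq_along(fl), function(j) {
    mk <- if (!is.null(markers) && fl[j] %in% names(markers))
      markers[[fl[j]]] else NA_character_
    channel_plane(matrix(A[, j], H, W), fluorophore = fl[j], marker = mk,
                  origin = tile$origin, pixel_size = tile$pixel_size)
  })
}

#' Unmix every tile of a rendered or loaded tile set
#'
#' @param tiles list of `ms_tile` objects.
#' @param library a [spectral_library].
#' @param markers optional fluorophore -> marker labels.
#' @return List (one element per tile) of lists of [channel_plane]s.
#' @export
unmix_tiles <- function(tiles, library, markers = NULL) {
  lapply(tiles, unmix_tile, library = library, markers = markers)
}

#' Stitch single-fluorophore tiles into a whole-slide plane
#'
#' Places each tile at its stored global origin on a zero-initialized
#' canvas. Overlapping tiles follow a last-written-wins rule with a warning;
#' for non-overlapping tilings the result is independent of input order.
#'
#' @param planes list of [channel_plane]s sharing one fluorophore and pixel
#'   size.
#' @param canvas_px canvas size `(width, height)` in pixels; defaults to the
#'   tight bounding box of the tiles.
#' @return A single [channel_plane] with origin (0, 0).
#' @export
stitch_planes <- function(planes, canvas_px = NULL) {
  stop_if_not(length(planes) >= 1, "no planes to stitch")
  fl <- unique(vapply(planes, function(p) p$fluorophore, character(1)))
  stop_if_not(length(fl) == 1, "all planes must share one fluorophore")
  ps <- unique(vapply(planes, function(p) p$pixel_size, numeric(1)))
  stop_if_not(length(ps) == 1, "all planes must share one pixel size")
  if (is.null(canvas_px)) {
    canvas_px <- c(
      max(vapply(planes, function(p) p$origin[1] + ncol(p$abundance), numeric(1))),
      max(vapply(planes, function(p) p$origin[2] + nrow(p$abundance), numeric(1))))
  }
  W <- canvas_px[1]; H <- canvas_px[2]
  canvas <- matrix(0, H, W)
  covered <- matrix(FALSE, H, W)
  overlap <- FALSE
  for (p in planes) {
    x0 <- p$origin[1]; y0 <- p$origin[2]
    w <- ncol(p$abundance); h <- nrow(p$abundance)
    if (x0 + w > W || y0 + h > H)
      stop("tile exceeds canvas bounds", call. = FALSE)
    rs <- (y0 + 1):(y0 + h); cs <- (x0 + 1):(x0 + w)
    if (any(covered[rs, cs])) overlap <- TRUE
    canvas[rs, cs] <- p$abundance
    covered[rs, cs] <- TRUE
  }
  if (overlap)
    warning("overlapping tiles: last-written-wins", call. = FALSE)
  channel_plane(canvas, fluorophore = fl, marker = planes[[1]]$marker,
                origin = c(0, 0), pixel_size = ps)
}

#' Unmix and stitch a full tile set into whole-slide marker planes
#'
#' Convenience wrapper: unmixes every tile against the library, then
#' stitches the per-fluorophore planes into whole-slide planes and labels
#' them with their markers.
#'
#' @param tiles list of `ms_tile`.
#' @param library a [spectral_library].
#' @param marker_map named character vector marker -> fluorophore.
#' @param canvas_px canvas `(width, height)` in px.
#' @return Named list of whole-slide [channel_plane]s, one per marker in
#'   `marker_map`.
#' @export
unmix_and_stitch <- function(tiles, library, marker_map, canvas_px = NULL) {
  fl2marker <- setNames(names(marker_map), marker_map)
  per_tile <- unmix_tiles(tiles, library, markers = fl2marker)
  out <- lapply(names(marker_map), function(m) {
    f <- marker_map[[m]]
    idx <- which(fluorophore_labels(library) == f)
    stitch_planes(lapply(per_tile, `[[`, idx), canvas_px = canvas_px)
  })
  names(out) <- names(marker_map)
  out
}
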