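#' Write / read multispectral tiles and channel planes as TIFF
#'
#' Tiles are stored as multi-page 32-bit float TIFF (one page per band,
#' values scaled to `[0, 1]`) with a JSON sidecar (`<file>.json`) holding
#' the global tile origin, pixel size, the intensity scale and, for channel
#' planes, the fluorophore/marker labels. `read_ms_tile` /
#' `read_channel_plane` restore the in-memory objects from the pair.
#'
#' @param tile an `ms_tile` (H x W x B `intensities`, `origin`,
#'   `pixel_size`).
#' @param path TIFF file path; the sidecar is written next to it.
#' @return The path, invisibly.
#' @export
write_ms_tile <- function(tile, path) {
  arr <- tile$intensities
  scale <- max(arr, 1e-12)
  pages <- lapply(seq_len(dim(arr)[3]), function(b) arr[, , b] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  jsonlite::write_json(
    list(origin = tile$origin, pixel_size = tile$pixel_size, scale = scale),
    paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ms_tile
#' @export
read_ms_tile <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (b in seq_along(pages)) arr[, , b] <- pages[[b]] * meta$scale
  structure(list(intensities = arr, origin = meta$origin,
                 pixel_size = meta$pixel_size), class = "ms_tile")
}

#' @param plane a `channel_plane`.
#' @rdname write_ms_tile
#' @export
write_channel_plane <- function(plane, path) {
  scale <- max(plane$abundance, 1e-12)
  tiff::writeTIFF(plane$abundance / scale, path, bits.per.sample = 32,
                  reduce = FALSE)
  jsonlite::write_json(
    list(origin = plane$origin, pixel_size = plane$pixel_size, scale = scale,
         fluorophore = plane$fluorophore, marker = plane$marker),
    paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ms_tile
#' @export
read_channel_plane <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- tiff::readTIFF(path)
  channel_plane(m * meta$scale, fluorophore = meta$fluorophore,
                marker = meta$marker, origin = meta$origin,
                pixel_size = meta$pixel_size)
}

#' Write an RGB brightfield image as 8-bit TIFF
#'
#' @param img a `brightfield_image` (from [convert_to_brightfield()]).
#' @param path TIFF path.
#' @return The path, invisibly.
#' @export
write_brightfield_tiff <- function(img, path) {
  tiff::writeTIFF(img$rgb / 255, path, bits.per.sample = 8, reduce = FALSE)
  invisible(path)
}
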