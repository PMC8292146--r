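#' Rendering configuration for synthetic multispectral scenes
#'
#' Controls how a [generate_scene()] ground truth is turned into raw
#' multispectral tiles: which fluorophore carries each marker, per-marker
#' brightness, additive band-wise Gaussian noise, and a fluorophore-level
#' bleed (cross-talk) matrix. The default marker map pins CD4 to Opal520 and
#' CD68 to Opal540, the spectrally adjacent pair through which a strong
#' macrophage signal can bleed into the T-helper channel.
#'
#' @param library a [spectral_library].
#' @param brightness scalar or named numeric: peak abundance per marker.
#' @param noise_sd standard deviation of additive Gaussian band noise
#'   (clipped at zero), in the same units as abundance; must be >= 0.
#' @param bleed fluorophore x fluorophore cross-talk matrix (row = source,
#'   column = target, diagonal 1, off-diagonal in `[0, 1)`), or `NULL` for
#'   identity.
#' @param marker_map named character vector marker -> fluorophore, or `NULL`
#'   to assign automatically.
#' @param af_background constant autofluorescence abundance added to the AF
#'   channel (0 disables).
#' @return An object of class `render_config`.
#' @export
render_config <- function(library = default_spectral_library(),
                          brightness = 1,
                          noise_sd = 0,
                          bleed = NULL,
                          marker_map = NULL,
                          af_background = 0) {
  stop_if_not(inherits(library, "spectral_library"), "library must be a spectral_library")
  stop_if_not(noise_sd >= 0, "noise_sd must be >= 0")
  if (!is.null(bleed)) {
    bleed <- as.matrix(bleed)
    fl <- fluorophore_labels(library)
    stop_if_not(nrow(bleed) == ncol(bleed) &&
                  !is.null(rownames(bleed)) &&
                  all(rownames(bleed) %in% fl) &&
                  identical(rownames(bleed), colnames(bleed)),
                "bleed must be square with fluorophore dimnames from the library")
    stop_if_not(all(diag(bleed) == 1), "bleed matrix diagonal must be 1")
    off <- bleed[row(bleed) != col(bleed)]
    stop_if_not(all(off >= 0 & off < 1), "cross-talk weights must lie in [0, 1)")
  }
  structure(list(library = library, brightness = brightness,
                 noise_sd = noise_sd, bleed = bleed,
                 marker_map = marker_map, af_background = af_background),
            class = "render_config")
}

# Deterministic default assignment of markers to fluorophores: DAPI and the
# CD4/CD68 spectral-neighbour pair are pinned, remaining markers take the
# remaining Opal channels in panel order. CD34 rides on Opal690 (far red)
# when free.
default_marker_map <- function(markers, library) {
  fl <- fluorophore_labels(library)
  map <- character(0)
  pin <- c(DAPI = "DAPI", CD4 = "Opal520", CD68 = "Opal540", CD34 = "Opal690")
  for (m in names(pin)) if (m %in% markers && pin[[m]] %in% fl) map[m] <- pin[[m]]
  rest <- setdiff(markers, names(map))
  free <- setdiff(fl, c(map, "AF"))
  if (length(rest) > length(free))
    stop("more markers than available fluorophores in the library", call. = FALSE)
  map[rest] <- free[seq_along(rest)]
  map
}

#' Render a scene into multispectral tiles
#'
#' Cells become isotropic Gaussian intensity bumps (sigma = half the cell
#' radius, i.e. a quarter of the nominal diameter) in their markers'
#' abundance planes; the
#' capillary mask becomes the CD34 plane. Marker planes are routed to
#' fluorophore planes via the marker map, mixed across fluorophores by the
#' bleed matrix, projected through the spectral library into acquisition
#' bands, and cut into tiles carrying their global origin. Band-wise Gaussian
#' noise (clipped at zero) is added last.
#'
#' @param scene a [generate_scene()] result.
#' @param cfg a [render_config()].
#' @param tile_size_px tile side length in pixels; border tiles are
#'   truncated.
#' @param seed seed for the noise draw (defaults to the scene seed).
#' @return List of class `rendered_scene`: `tiles` (list of `ms_tile`, each
#'   with `intensities` H x W x B, `origin` (x, y) 0-based px, `pixel_size`),
#'   `abundance` (named list of full-scene per-fluorophore planes after
#'   bleed, the ground truth that unmixing should recover when noise is
#'   zero), `marker_map`, `library`.
#' @export
render_multispectral <- function(scene, cfg = render_config(),
                                 tile_size_px = 128, seed = scene$seed) {
  stop_if_not(inherits(scene, "scene_gt"), "scene must be a scene_gt")
  stop_if_not(inherits(cfg, "render_config"), "cfg must be a render_config")
  stop_if_not(tile_size_px >= 1, "tile_size_px must be >= 1")
  lib <- cfg$library
  if (n_fluorophores(lib) == 0) stop("empty spectral library", call. = FALSE)

  W <- scene$dims_px[1]; H <- scene$dims_px[2]
  markers <- unique(c("DAPI", unlist(scene$cells$markers)))
  if (scene$capillary_fraction > 0) markers <- unique(c(markers, "CD34"))
  map <- cfg$marker_map
  if (is.null(map)) map <- default_marker_map(markers, lib)
  stop_if_not(all(markers %in% names(map)),
              "marker_map must cover every marker present in the scene")
  stop_if_not(all(map[markers] %in% fluorophore_labels(lib)),
              "marker_map targets unknown fluorophores")

  bright <- function(m) {
    if (length(cfg$brightness) == 1 && is.null(names(cfg$brightness)))
      return(cfg$brightness)
    if (m %in% names(cfg$brightness)) cfg$brightness[[m]] else 1
  }

  # per-marker abundance planes
  planes <- lapply(markers, function(m) matrix(0, H, W))
  names(planes) <- markers
  cells <- scene$cells
  for (i in seq_len(nrow(cells))) {
    cx <- cells$x_um[i] / scene$pixel_size
    cy <- cells$y_um[i] / scene$pixel_size
    for (m in cells$markers[[i]]) {
      size <- if (m == "DAPI") 4 else cell_size_um(marker_classes()[[m]])
      sigma <- (size / 4) / scene$pixel_size  # half the cell radius
      planes[[m]] <- add_gaussian_bump(planes[[m]], cx, cy, sigma, bright(m))
    }
  }
  if ("CD34" %in% markers)
    planes[["CD34"]] <- planes[["CD34"]] + scene$capillary_mask * bright("CD34")

  # marker planes -> fluorophore planes
  fl <- fluorophore_labels(lib)
  fplanes <- lapply(fl, function(f) matrix(0, H, W))
  names(fplanes) <- fl
  for (m in markers) fplanes[[map[[m]]]] <- fplanes[[map[[m]]]] + planes[[m]]
  if (cfg$af_background > 0 && "AF" %in% fl)
    fplanes[["AF"]] <- fplanes[["AF"]] + cfg$af_background

  # fluorophore-level bleed
  if (!is.null(cfg$bleed)) {
    src <- rownames(cfg$bleed)
    mixed <- lapply(fl, function(f) {
      acc <- matrix(0, H, W)
      for (s in fl) {
        w <- if (s %in% src && f %in% src) cfg$bleed[s, f] else as.numeric(s == f)
        if (w != 0) acc <- acc + w * fplanes[[s]]
      }
      acc
    })
    names(mixed) <- fl
    fplanes <- mixed
  }

  # tile and project through the library
  L <- lib$spectra  # bands x fluorophores
  nx <- ceiling(W / tile_size_px); ny <- ceiling(H / tile_size_px)
  tiles <- list()
  with_seed(seed, {
    for (ty in seq_len(ny)) for (tx in seq_len(nx)) {
      x0 <- (tx - 1) * tile_size_px; y0 <- (ty - 1) * tile_size_px
      cs <- (x0 + 1):min(x0 + tile_size_px, W)
      rs <- (y0 + 1):min(y0 + tile_size_px, H)
      h <- length(rs); w <- length(cs)
      A <- vapply(fl, function(f) as.vector(fplanes[[f]][rs, cs, drop = FALSE]),
                  numeric(h * w))           # (h*w) x F
      Y <- A %*% t(L)                        # (h*w) x B
      if (cfg$noise_sd > 0)
        Y <- pmax(Y + rnorm(length(Y), sd = cfg$noise_sd), 0)
      tiles[[length(tiles) + 1]] <- structure(
        list(intensities = array(Y, dim = c(h, w, nrow(L))),
             origin = c(x0, y0), pixel_size = scene$pixel_size),
        class = "ms_tile")
    }
  })
  structure(list(tiles = tiles, abundance = fplanes, marker_map = map,
                 library = lib, dims_px = scene$dims_px,
                 pixel_size = scene$pixel_size),
            class = "rendered_scene")
}

# Accumulate amp * exp(-((x-cx)^2+(y-cy)^2) / (2 sigma^2)) within a +/- 4
# sigma window. Pixel centers at 0-based integer coordinates.
add_gaussian_bump <- function(plane, cx, cy, sigma, amp) {
  H <- nrow(plane); W <- ncol(plane)
  r <- ceiling(4 * sigma)
  cs <- max(1, floor(cx) + 1 - r):min(W, ceiling(cx) + 1 + r)
  rs <- max(1, floor(cy) + 1 - r):min(H, ceiling(cy) + 1 + r)
  if (length(cs) == 0 || length(rs) == 0) return(plane)
  gx <- exp(-((cs - 1 - cx)^2) / (2 * sigma^2))
  gy <- exp(-((rs - 1 - cy)^2) / (2 * sigma^2))
  plane[rs, cs] <- plane[rs, cs] + amp * outer(gy, gx)
  plane
}
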