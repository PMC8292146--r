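#' Stain vector of a brightfield dye
#'
#' The light-absorption coefficients of a dye in the red, green and blue
#' parts of the spectrum. Defaults are the widely used hematoxylin and DAB
#' optical-density triplets from the Ruifrok-Johnston colour-deconvolution
#' convention.
#'
#' @param dye `"hematoxylin"` or `"dab"`, or any label when `coefficients`
#'   is given.
#' @param coefficients numeric length-3 `(c_R, c_G, c_B)`, all >= 0, not all
#'   zero; `NULL` selects the built-in triplet for `dye`.
#' @return An object of class `stain_vector`.
#' @export
stain_vector <- function(dye = c("hematoxylin", "dab"), coefficients = NULL) {
  if (is.null(coefficients)) {
    dye <- match.arg(dye)
    coefficients <- switch(dye,
                           hematoxylin = c(0.650, 0.704, 0.286),
                           dab = c(0.268, 0.570, 0.776))
  }
  stop_if_not(length(coefficients) == 3 && all(coefficients >= 0) &&
                any(coefficients > 0),
              "stain vector needs 3 non-negative coefficients, not all zero")
  structure(list(dye = dye, coefficients = as.numeric(coefficients)),
            class = "stain_vector")
}

#' Normalize a fluorescence plane to [0, 1]
#'
#' Divides by `scale_max` and clips to `[0, 1]`. By default `scale_max` is
#' the plane's 99.9th percentile (robust to hot pixels); pass a fixed
#' constant for reproducible scaling across slides.
#'
#' @param plane a [channel_plane] or bare matrix.
#' @param scale_max positive intensity mapped to 1, or `NULL` for the
#'   percentile default.
#' @param percentile percentile used when `scale_max` is `NULL`.
#' @return Same type as the input, with values in `[0, 1]`.
#' @export
normalize_intensity <- function(plane, scale_max = NULL, percentile = 0.999) {
  m <- if (inherits(plane, "channel_plane")) plane$abundance else plane
  if (is.null(scale_max)) {
    scale_max <- quantile(m, percentile, names = FALSE)
    if (scale_max <= 0) scale_max <- 1
  }
  stop_if_not(scale_max > 0, "scale_max must be positive")
  out <- pmin(pmax(m / scale_max, 0), 1)
  if (inherits(plane, "channel_plane")) {
    plane$abundance <- out
    plane
  } else out
}

#' Convert DAPI + marker planes to an artificial brightfield IHC image
#'
#' Applies the Beer-Lambert synthesis: for each channel `ch` in R, G, B,
#' \deqn{out_{ch} = 255 \cdot e^{-(I_{DAPI} c_{ch,Hem} + I_{IHC} c_{ch,DAB})}}
#' so DAPI renders as hematoxylin blue and the marker as DAB brown, and
#' pixels with no signal are white (255, 255, 255). Inputs must be
#' normalized to `[0, 1]` (see [normalize_intensity()]). All math is in
#' floating point; quantization rounds half away from zero to 8 bits at the
#' final step only.
#'
#' @param i_dapi,i_ihc numeric matrices in `[0, 1]`, same dimensions.
#' @param hem,dab [stain_vector]s for the counterstain and the chromogen.
#' @param marker marker label stored as provenance.
#' @param quantize if `FALSE`, return the continuous float image in
#'   `[0, 255]` instead of 8-bit integers (useful for optical-density
#'   inversion checks).
#' @return Object of class `brightfield_image`: `rgb` H x W x 3 array,
#'   `marker`, `hem`, `dab`, `quantized`.
#' @export
convert_to_brightfield <- function(i_dapi, i_ihc,
                                   hem = stain_vector("hematoxylin"),
                                   dab = stain_vector("dab"),
                                   marker = NA_character_,
                                   quantize = TRUE) {
  if (inherits(i_dapi, "channel_plane")) i_dapi <- i_dapi$abundance
  if (inherits(i_ihc, "channel_plane")) i_ihc <- i_ihc$abundance
  stop_if_not(identical(dim(i_dapi), dim(i_ihc)),
              "DAPI and marker planes must share geometry")
  stop_if_not(all(i_dapi >= 0 & i_dapi <= 1) && all(i_ihc >= 0 & i_ihc <= 1),
              "planes must be normalized to [0, 1]")
  H <- nrow(i_dapi); W <- ncol(i_dapi)
  rgb <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) {
    od <- i_dapi * hem$coefficients[ch] + i_ihc * dab$coefficients[ch]
    v <- 255 * exp(-od)
    rgb[, , ch] <- if (quantize) floor(v + 0.5) else v
  }
  structure(list(rgb = rgb, marker = marker, hem = hem, dab = dab,
                 quantized = quantize), class = "brightfield_image")
}

#' Recover stain intensities from a brightfield image
#'
#' Inverts the Beer-Lambert synthesis: converts the image back to optical
#' densities `OD_ch = -log(out_ch / 255)` and solves the 3 x 2 linear system
#' for `(I_DAPI, I_IHC)` per pixel by least squares. Exact (up to float
#' precision) on un-quantized images when the two stain vectors are linearly
#' independent.
#'
#' @param img a `brightfield_image`.
#' @return List with matrices `i_dapi` and `i_ihc`.
#' @export
invert_brightfield <- function(img) {
  M <- cbind(img$hem$coefficients, img$dab$coefficients)  # 3 x 2
  stop_if_not(qr(M)$rank == 2, "stain vectors are collinear; cannot invert")
  H <- dim(img$rgb)[1]; W <- dim(img$rgb)[2]
  od <- vapply(1:3, function(ch) -log(pmax(img$rgb[, , ch], 1e-12) / 255),
               matrix(0, H, W))
  OD <- matrix(od, nrow = H * W, ncol = 3)
  sol <- t(qr.solve(M, t(OD)))  # pixels x 2
  list(i_dapi = matrix(sol[, 1], H, W), i_ihc = matrix(sol[, 2], H, W))
}

#' Pair every marker plane with the DAPI plane and synthesize brightfield
#'
#' @param stack named list of whole-slide [channel_plane]s (or matrices),
#'   one of them the DAPI counterstain.
#' @param dapi_label name of the DAPI entry in `stack`.
#' @param hem,dab [stain_vector]s.
#' @param scale_max fixed normalization constant, or `NULL` for per-plane
#'   percentile scaling.
#' @return Named list of `brightfield_image`s, one per non-DAPI marker.
#' @export
assemble_pairs <- function(stack, dapi_label = "DAPI",
                           hem = stain_vector("hematoxylin"),
                           dab = stain_vector("dab"),
                           scale_max = NULL) {
  if (!dapi_label %in% names(stack))
    stop("DAPI plane missing from the stack", call. = FALSE)
  i_dapi <- normalize_intensity(stack[[dapi_label]], scale_max = scale_max)
  if (inherits(i_dapi, "channel_plane")) i_dapi <- i_dapi$abundance
  rest <- setdiff(names(stack), dapi_label)
  out <- lapply(rest, function(m) {
    i_ihc <- normalize_intensity(stack[[m]], scale_max = scale_max)
    if (inherits(i_ihc, "channel_plane")) i_ihc <- i_ihc$abundance
    convert_to_brightfield(i_dapi, i_ihc, hem = hem, dab = dab, marker = m)
  })
  names(out) <- rest
  out
}
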