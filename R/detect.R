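#' Decode a probability map into point detections
#'
#' Thresholds the map, labels connected components, and merges components
#' whose centroids are closer than `min_separation_um` (single-linkage
#' clustering on centroid distances, the natural closure of "merge if
#' closer than"). Each surviving group becomes one detection at its
#' area-weighted centroid with confidence equal to the maximum probability
#' over its pixels.
#'
#' Decoding thresholds in the motivating application: 0.7 for strongly
#' stained cytoplasmic markers (CD3), 0.4 for weaker cytoplasmic and for
#' nuclear lymphocyte markers, at 0.49 um/px with `min_separation_um = 4`
#' (one lymphocyte diameter).
#'
#' @param prob numeric matrix with values in `[0, 1]`.
#' @param threshold detection threshold in `[0, 1]`.
#' @param min_separation_um centroid merge distance in micrometers.
#' @param pixel_size micrometers per pixel of the map.
#' @param marker marker label attached to the detections.
#' @param origin global (x, y) origin of the map, 0-based px.
#' @return A [detection_table()].
#' @export
decode_probability_map <- function(prob, threshold, min_separation_um = 4,
                                   pixel_size = 0.49, marker = NA_character_,
                                   origin = c(0, 0)) {
  stop_if_not(threshold >= 0 && threshold <= 1, "threshold must be in [0, 1]")
  if (any(!is.finite(prob)))
    stop("probability map contains non-finite values", call. = FALSE)
  lab <- EBImage::bwlabel((prob >= threshold) * 1)
  n <- max(lab)
  if (n == 0) return(detection_table())
  idx <- which(lab > 0)
  comp <- lab[idx]
  rr <- (idx - 1) %% nrow(prob)          # 0-based row = y
  cc <- (idx - 1) %/% nrow(prob)         # 0-based col = x
  cx <- tapply(cc, comp, mean)
  cy <- tapply(rr, comp, mean)
  sz <- tapply(comp, comp, length)
  cmax <- tapply(prob[idx], comp, max)

  grp <- seq_len(n)
  if (n > 1 && min_separation_um > 0) {
    d <- dist(cbind(cx, cy)) * pixel_size
    grp <- cutree(hclust(d, method = "single"), h = min_separation_um)
    # cutree cuts at height <= h; "closer than" is strict, which coincides
    # except on exact ties -- acceptable for continuous centroids
  }
  x <- tapply(cx * sz, grp, sum) / tapply(sz, grp, sum)
  y <- tapply(cy * sz, grp, sum) / tapply(sz, grp, sum)
  conf <- tapply(cmax, grp, max)
  detection_table(marker = rep(marker, length(x)),
                  x = as.numeric(x) + origin[1],
                  y = as.numeric(y) + origin[2],
                  confidence = as.numeric(conf))
}

#' Greedy non-maximum suppression of box candidates
#'
#' Drops candidates below `objectness_threshold`, then keeps boxes greedily
#' in descending objectness, suppressing any remaining candidate whose
#' intersection-over-union with an already kept box exceeds
#' `overlap_threshold`. Ties in objectness are broken by `(y, x)`
#' lexicographic order, making the result deterministic.
#'
#' The motivating macrophage detector used 21 um boxes at 0.98 um/px with
#' objectness threshold 0.45 and suppression parameter 0.05 (interpreted
#' here as the IoU threshold).
#'
#' @param cands data frame with columns `x`, `y` (box centers, px), `side`
#'   (box side length, px) and `objectness` in `[0, 1]`.
#' @param objectness_threshold minimum objectness kept.
#' @param overlap_threshold IoU above which a candidate is suppressed.
#' @param marker marker label attached to surviving detections.
#' @return A [detection_table()] of the kept box centers (confidence =
#'   objectness).
#' @export
non_maximum_suppression <- function(cands, objectness_threshold = 0.45,
                                    overlap_threshold = 0.05,
                                    marker = NA_character_) {
  stop_if_not(objectness_threshold >= 0 && objectness_threshold <= 1 &&
                overlap_threshold >= 0 && overlap_threshold <= 1,
              "thresholds must lie in [0, 1]")
  if (is.null(cands) || nrow(cands) == 0) return(detection_table())
  stop_if_not(all(cands$side > 0), "box side lengths must be positive")
  keep_pool <- cands[cands$objectness >= objectness_threshold, , drop = FALSE]
  if (nrow(keep_pool) == 0) return(detection_table())
  ord <- order(-keep_pool$objectness, keep_pool$y, keep_pool$x)
  keep_pool <- keep_pool[ord, , drop = FALSE]
  kept <- integer(0)
  alive <- rep(TRUE, nrow(keep_pool))
  for (i in seq_len(nrow(keep_pool))) {
    if (!alive[i]) next
    kept <- c(kept, i)
    if (i < nrow(keep_pool)) {
      j <- which(alive & seq_along(alive) > i)
      if (length(j)) {
        ious <- box_iou(keep_pool[i, ], keep_pool[j, , drop = FALSE])
        alive[j[ious > overlap_threshold]] <- FALSE
      }
    }
  }
  k <- keep_pool[kept, , drop = FALSE]
  detection_table(marker = rep(marker, nrow(k)), x = k$x, y = k$y,
                  confidence = k$objectness)
}

box_iou <- function(a, b) {
  ah <- a$side / 2; bh <- b$side / 2
  ix <- pmax(0, pmin(a$x + ah, b$x + bh) - pmax(a$x - ah, b$x - bh))
  iy <- pmax(0, pmin(a$y + ah, b$y + bh) - pmax(a$y - ah, b$y - bh))
  inter <- ix * iy
  inter / (a$side^2 + b$side^2 - inter)
}

#' Classical scale-matched blob detector
#'
#' Deterministic Laplacian-of-Gaussian reference detector used to exercise
#' the pipeline on synthetic scenes in place of a trained network: filters
#' the plane with a scale-normalized LoG kernel at `sigma = r / sqrt(2)`
#' (with `r` the cell radius in pixels), finds local response maxima, and
#' keeps those with response at least `relative_threshold` times the
#' maximum response.
#'
#' @param plane a [channel_plane] or matrix.
#' @param cell_size_um nominal cell diameter in micrometers (4 lymphocyte,
#'   21 macrophage).
#' @param relative_threshold fraction of the peak response required.
#' @param pixel_size micrometers per pixel (taken from the plane when
#'   available).
#' @param marker marker label for the detections.
#' @return A [detection_table()] in global pixel coordinates (confidence =
#'   response relative to the maximum).
#' @export
reference_blob_detector <- function(plane, cell_size_um,
                                    relative_threshold = 0.15,
                                    pixel_size = NULL,
                                    marker = NA_character_) {
  stop_if_not(cell_size_um > 0, "cell size must be positive")
  origin <- c(0, 0)
  if (inherits(plane, "channel_plane")) {
    if (is.null(pixel_size)) pixel_size <- plane$pixel_size
    origin <- plane$origin
    if (is.na(marker) && !is.na(plane$marker)) marker <- plane$marker
    plane <- plane$abundance
  }
  if (is.null(pixel_size)) pixel_size <- 0.49
  if (all(plane == 0)) return(detection_table())
  r_px <- (cell_size_um / 2) / pixel_size
  sigma <- r_px / sqrt(2)
  resp <- log_response(plane, sigma)
  mx <- max(resp)
  if (mx <= 0) return(detection_table())
  peaks <- local_maxima(resp) & resp >= relative_threshold * mx
  idx <- which(peaks)
  if (length(idx) == 0) return(detection_table())
  y <- (idx - 1) %% nrow(resp)
  x <- (idx - 1) %/% nrow(resp)
  detection_table(marker = rep(marker, length(idx)),
                  x = x + origin[1], y = y + origin[2],
                  confidence = resp[idx] / mx)
}

# negated, scale-normalized LoG filter response (bright blobs -> positive
# peaks); zero-padded convolution via EBImage::filter2
log_response <- function(m, sigma) {
  r <- max(1, ceiling(4 * sigma))
  ax <- -r:r
  g <- exp(-(ax^2) / (2 * sigma^2))
  G <- outer(g, g)
  rr2 <- outer(ax^2, ax^2, "+")
  K <- -(rr2 - 2 * sigma^2) / sigma^2 * G   # -sigma^2 * LoG (normalized)
  K <- K - mean(K)                          # zero response on flat input
  pad <- r
  P <- matrix(0, nrow(m) + 2 * pad, ncol(m) + 2 * pad)
  P[(pad + 1):(pad + nrow(m)), (pad + 1):(pad + ncol(m))] <- m
  R <- as.matrix(EBImage::filter2(P, K, boundary = 0))
  R[(pad + 1):(pad + nrow(m)), (pad + 1):(pad + ncol(m))]
}

# strict local maxima over the 8-neighbourhood (plateaus break toward the
# top-left pixel so one detection per plateau survives)
local_maxima <- function(m) {
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(-Inf, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- m
  res <- matrix(TRUE, H, W)
  shifts <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                 c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  for (s in shifts) {
    nb <- pad[2:(H + 1) + s[1], 2:(W + 1) + s[2]]
    strict_before <- (s[1] < 0) || (s[1] == 0 && s[2] < 0)
    res <- res & (if (strict_before) m > nb else m >= nb)
  }
  res
}
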