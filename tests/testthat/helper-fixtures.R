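# small, well-separated 3-fluorophore library on 5 bands
tiny_library <- function() {
  spectral_library(cbind(
    A = c(1, 0.4, 0.05, 0, 0),
    B = c(0.05, 0.5, 1, 0.5, 0.05),
    C = c(0, 0, 0.05, 0.4, 1)))
}

# rectangular ROI in pixel coordinates with capsule along the top edge
rect_roi <- function(x0, y0, x1, y1, pixel_size = 0.49, capsule = TRUE,
                     exclusions = list()) {
  roi(inclusions = list(cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))),
      exclusions = exclusions,
      capsule = if (capsule) cbind(c(x0, x1), c(y0, y0)) else NULL,
      pixel_size = pixel_size)
}

random_dets <- function(n, w = 100, h = 100, marker = "CD3") {
  detection_table(rep(marker, n), runif(n, 0, w), runif(n, 0, h),
                  runif(n))
}

# exhaustive maximum-cardinality one-to-one assignment on the thresholded
# distance graph (oracle for small matching instances)
max_cardinality_matching <- function(dets, gts, radius_um, pixel_size) {
  nd <- nrow(dets); ng <- nrow(gts)
  if (nd == 0 || ng == 0) return(0L)
  dmat <- sqrt(outer(dets$x, gts$x, "-")^2 +
                 outer(dets$y, gts$y, "-")^2) * pixel_size
  allowed <- dmat <= radius_um
  best <- 0L
  recurse <- function(d, used_g, count) {
    if (count + (nd - d + 1) <= best) return()
    if (d > nd) {
      if (count > best) best <<- count
      return()
    }
    for (g in seq_len(ng)) {
      if (!used_g[g] && allowed[d, g]) {
        ug <- used_g; ug[g] <- TRUE
        recurse(d + 1, ug, count + 1L)
      }
    }
    recurse(d + 1, used_g, count)
    if (count > best) best <<- count
  }
  recurse(1L, rep(FALSE, ng), 0L)
  best
}
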