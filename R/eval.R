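#' Match detections to ground-truth dot annotations
#'
#' One-to-one greedy matching over all (detection, annotation) pairs within
#' `radius_um`, taken in ascending distance order (ties broken by annotation
#' index, then detection index). A detection within the radius of an
#' annotation is a true positive only if it is the closest still-unmatched
#' one, reproducing the closest-detection tie-break rule; unmatched
#' detections are false positives, unmatched annotations false negatives.
#'
#' In the motivating application the radius is the average cell diameter:
#' 4 um for lymphocytes, 21 um for macrophages.
#'
#' @param dets,gts [detection_table()]s in the same pixel frame.
#' @param radius_um matching radius in micrometers (> 0).
#' @param pixel_size micrometers per pixel.
#' @param strict if `TRUE`, require distance strictly below the radius;
#'   the default counts distance equal to the radius as within.
#' @return Object of class `match_result`: integers `tp`, `fp`, `fn` and a
#'   data frame `pairs` (`det`, `gt`, `dist_um`).
#' @export
match_detections <- function(dets, gts, radius_um, pixel_size = 0.49,
                             strict = FALSE) {
  stop_if_not(radius_um > 0, "radius must be positive")
  nd <- nrow(dets); ng <- nrow(gts)
  pairs <- data.frame(det = integer(), gt = integer(), dist_um = numeric())
  if (nd > 0 && ng > 0) {
    dmat <- sqrt(outer(dets$x, gts$x, "-")^2 +
                   outer(dets$y, gts$y, "-")^2) * pixel_size
    ok <- if (strict) which(dmat < radius_um) else which(dmat <= radius_um)
    if (length(ok)) {
      di <- (ok - 1) %% nd + 1
      gi <- (ok - 1) %/% nd + 1
      dd <- dmat[ok]
      ord <- order(dd, gi, di)
      used_d <- rep(FALSE, nd); used_g <- rep(FALSE, ng)
      for (k in ord) {
        if (used_d[di[k]] || used_g[gi[k]]) next
        used_d[di[k]] <- TRUE; used_g[gi[k]] <- TRUE
        pairs <- rbind(pairs, data.frame(det = di[k], gt = gi[k],
                                         dist_um = dd[k]))
      }
    }
  }
  tp <- nrow(pairs)
  structure(list(tp = tp, fp = nd - tp, fn = ng - tp, pairs = pairs),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("match_result: tp=%d fp=%d fn=%d\n", x$tp, x$fp, x$fn))
  invisible(x)
}

#' Precision, recall and F1 from match counts
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`,
#' `F1 = 2 P R / (P + R)`; every 0/0 ratio is defined as 0.
#'
#' @param tp,fp,fn non-negative counts, or a `match_result` as `tp`.
#' @return List of class `prf1_score` with `precision`, `recall`, `f1`.
#' @export
prf1 <- function(tp, fp = NULL, fn = NULL) {
  if (inherits(tp, "match_result")) {
    fp <- tp$fp; fn <- tp$fn; tp <- tp$tp
  }
  stop_if_not(tp >= 0 && fp >= 0 && fn >= 0, "counts must be non-negative")
  safe <- function(num, den) if (den == 0) 0 else num / den
  p <- safe(tp, tp + fp)
  r <- safe(tp, tp + fn)
  f1 <- safe(2 * p * r, p + r)
  structure(list(precision = p, recall = r, f1 = f1), class = "prf1_score")
}

#' @export
print.prf1_score <- function(x, ...) {
  cat(sprintf("precision %.3f  recall %.3f  F1 %.3f\n",
              x$precision, x$recall, x$f1))
  invisible(x)
}

#' Evaluate detections over a slide set
#'
#' Matches detections to annotations per slide and per marker, then pools
#' TP/FP/FN counts over slides (scores are recomputed from the summed
#' counts, not averaged).
#'
#' @param det_list,gt_list lists (one entry per slide) of
#'   [detection_table()]s; names identify the slides.
#' @param radius_by_marker named numeric vector marker -> matching radius
#'   (um); every marker present must have a radius.
#' @param pixel_size micrometers per pixel.
#' @param strict passed to [match_detections()].
#' @return List with `per_slide` (data frame: slide, marker, tp, fp, fn,
#'   precision, recall, f1) and `pooled` (data frame per marker plus an
#'   `"all"` row).
#' @export
evaluate_slide_set <- function(det_list, gt_list, radius_by_marker,
                               pixel_size = 0.49, strict = FALSE) {
  stop_if_not(length(det_list) == length(gt_list),
              "detection and annotation lists must have equal length")
  slides <- names(det_list)
  if (is.null(slides)) slides <- as.character(seq_along(det_list))
  rows <- list()
  for (s in seq_along(det_list)) {
    dets <- det_list[[s]]; gts <- gt_list[[s]]
    mks <- unique(c(dets$marker, gts$marker))
    missing <- setdiff(mks, names(radius_by_marker))
    if (length(missing))
      stop("no matching radius configured for marker(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    for (m in mks) {
      mr <- match_detections(dets[dets$marker == m, , drop = FALSE],
                             gts[gts$marker == m, , drop = FALSE],
                             radius_um = radius_by_marker[[m]],
                             pixel_size = pixel_size, strict = strict)
      sc <- prf1(mr)
      rows[[length(rows) + 1]] <- data.frame(
        slide = slides[s], marker = m, tp = mr$tp, fp = mr$fp, fn = mr$fn,
        precision = sc$precision, recall = sc$recall, f1 = sc$f1,
        stringsAsFactors = FALSE)
    }
  }
  per_slide <- do.call(rbind, rows)
  pool <- function(df, label) {
    sc <- prf1(sum(df$tp), sum(df$fp), sum(df$fn))
    data.frame(marker = label, tp = sum(df$tp), fp = sum(df$fp),
               fn = sum(df$fn), precision = sc$precision, recall = sc$recall,
               f1 = sc$f1, stringsAsFactors = FALSE)
  }
  pooled <- do.call(rbind, c(
    lapply(split(per_slide, per_slide$marker),
           function(df) pool(df, df$marker[1])),
    list(pool(per_slide, "all"))))
  rownames(pooled) <- NULL
  list(per_slide = per_slide, pooled = pooled)
}
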