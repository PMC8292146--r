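dt <- function(x, y, marker = "CD3")
  detection_table(rep(marker, length(x)), x, y)

test_that("matching handles empty and exact cases", {
  gts <- dt(c(1, 5, 9, 13, 17), rep(2, 5))
  m0 <- match_detections(dt(numeric(0), numeric(0)), gts, 4)
  expect_equal(c(m0$tp, m0$fp, m0$fn), c(0, 0, 5))

  m1 <- match_detections(dt(3, 7), dt(3, 7), 4)
  expect_equal(c(m1$tp, m1$fp, m1$fn), c(1, 0, 0))
  expect_equal(m1$pairs$dist_um, 0)
})

test_that("only the closest of two nearby detections is a true positive", {
  # detections 1 um and 3 um from one annotation, radius 4 um
  ps <- 0.49
  gt <- dt(10, 10)
  dets <- dt(c(10 + 1 / ps, 10 + 3 / ps), c(10, 10))
  m <- match_detections(dets, gt, radius_um = 4, pixel_size = ps)
  expect_equal(c(m$tp, m$fp, m$fn), c(1, 1, 0))
  expect_equal(m$pairs$det, 1)
  expect_equal(m$pairs$dist_um, 1, tolerance = 1e-9)
})

test_that("count identities hold on fuzzed instances", {
  set.seed(71)
  for (k in 1:1000) {
    nd <- sample(0:12, 1); ng <- sample(0:12, 1)
    dets <- dt(runif(nd, 0, 30), runif(nd, 0, 30))
    gts <- dt(runif(ng, 0, 30), runif(ng, 0, 30))
    m <- match_detections(dets, gts, radius_um = 4, pixel_size = 0.49)
    expect_identical(m$tp, nrow(m$pairs))
    expect_identical(m$tp + m$fn, ng)
    expect_identical(m$tp + m$fp, nd)
    if (m$tp > 0) {
      expect_true(all(m$pairs$dist_um <= 4))
      expect_false(any(duplicated(m$pairs$det)))
      expect_false(any(duplicated(m$pairs$gt)))
    }
  }
})

test_that("greedy matching agrees with the exhaustive assignment oracle", {
  set.seed(72)
  n_diff <- 0
  for (k in 1:300) {
    nd <- sample(0:6, 1); ng <- sample(0:6, 1)
    dets <- dt(runif(nd, 0, 6), runif(nd, 0, 6))
    gts <- dt(runif(ng, 0, 6), runif(ng, 0, 6))
    m <- match_detections(dets, gts, radius_um = 4, pixel_size = 0.49)
    best <- max_cardinality_matching(dets, gts, 4, 0.49)
    # ascending-distance greedy can fall below the maximum cardinality in
    # rare crossing configurations, never above it
    expect_lte(m$tp, best)
    if (m$tp < best) n_diff <- n_diff + 1
  }
  # the suboptimal configurations must be the rare exception
  expect_lt(n_diff / 300, 0.05)
})

test_that("matching is invariant under rigid motions of the frame", {
  set.seed(73)
  dets <- dt(runif(8, 0, 20), runif(8, 0, 20))
  gts <- dt(runif(6, 0, 20), runif(6, 0, 20))
  base <- match_detections(dets, gts, 4, 0.49)
  th <- 0.7; Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  tf <- function(d) {
    xy <- as.matrix(d[, c("x", "y")]) %*% t(Rm)
    dt(xy[, 1] + 50, xy[, 2] + 30)
  }
  moved <- match_detections(tf(dets), tf(gts), 4, 0.49)
  expect_equal(c(base$tp, base$fp, base$fn),
               c(moved$tp, moved$fp, moved$fn))
})

test_that("precision/recall/F1 follow the defining formulas", {
  s <- prf1(10, 0, 0)
  expect_equal(c(s$precision, s$recall, s$f1), c(1, 1, 1))
  s0 <- prf1(0, 0, 0)
  expect_equal(c(s0$precision, s0$recall, s0$f1), c(0, 0, 0))
  s2 <- prf1(6, 2, 3)
  expect_equal(s2$precision, 0.75)
  expect_equal(s2$recall, 2 / 3)
  expect_equal(s2$f1, 2 * 0.75 * (2 / 3) / (0.75 + 2 / 3))
  # scale invariance
  for (k in c(2, 5, 11)) {
    sk <- prf1(6 * k, 2 * k, 3 * k)
    expect_equal(sk$f1, s2$f1)
    expect_equal(sk$precision, s2$precision)
  }
  # F1 between min and max of P and R
  set.seed(74)
  for (i in 1:50) {
    cts <- sample(0:20, 3, replace = TRUE)
    sc <- prf1(cts[1], cts[2], cts[3])
    expect_gte(sc$f1, min(sc$precision, sc$recall) - 1e-12)
    expect_lte(sc$f1, max(sc$precision, sc$recall) + 1e-12)
  }
})

test_that("slide-set evaluation pools counts, not scores", {
  one <- evaluate_slide_set(list(s1 = dt(3, 3)), list(s1 = dt(3, 3)),
                            c(CD3 = 4))
  expect_equal(one$pooled[one$pooled$marker == "CD3", "f1"],
               one$per_slide$f1[1])

  # slides with (tp,fp,fn) = (1,0,0) and (0,1,1) pool to P = R = F1 = 0.5
  s1d <- dt(0, 0); s1g <- dt(0, 0)
  s2d <- dt(100, 100); s2g <- dt(500, 500)
  ev <- evaluate_slide_set(list(a = s1d, b = s2d), list(a = s1g, b = s2g),
                           c(CD3 = 4))
  pooled <- ev$pooled[ev$pooled$marker == "all", ]
  expect_equal(c(pooled$precision, pooled$recall, pooled$f1),
               c(0.5, 0.5, 0.5))

  expect_error(evaluate_slide_set(list(dt(1, 1, "CD99")), list(dt(1, 1, "CD99")),
                                  c(CD3 = 4)), "no matching radius")
})

test_that("pooled scores equal recomputation from concatenated detections", {
  set.seed(75)
  det_list <- list(); gt_list <- list()
  off <- 0
  for (s in 1:3) {
    g <- dt(runif(15, 0, 40) + off, runif(15, 0, 40))
    keep <- runif(15) < 0.8
    d <- dt(g$x[keep] + rnorm(sum(keep), 0, 1), g$y[keep] + rnorm(sum(keep), 0, 1))
    d <- rbind(d, dt(runif(3, 0, 40) + off, runif(3, 60, 80)))
    det_list[[s]] <- d; gt_list[[s]] <- g
    off <- off + 1000  # slides live in disjoint frames
  }
  ev <- evaluate_slide_set(det_list, gt_list, c(CD3 = 4))
  pooled <- ev$pooled[ev$pooled$marker == "all", ]
  cat_m <- match_detections(do.call(rbind, det_list), do.call(rbind, gt_list),
                            4, 0.49)
  cat_s <- prf1(cat_m)
  expect_equal(pooled$f1, cat_s$f1)
  expect_equal(pooled$tp, cat_m$tp)
})
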