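pdt <- function(x, y, marker = "CD3")
  detection_table(rep(marker, length(x)), x, y)

test_that("subcapsular band area matches the closed form for a straight capsule", {
  ps <- 0.49
  # 2000 x 1500 um rectangle, capsule along the full top edge
  r <- rect_roi(0, 0, 2000 / ps, 1500 / ps, pixel_size = ps)
  parts <- subcapsular_band(r, band_um = 400)
  band_mm2 <- region_area_mm2(parts$band, grid_step = 2)
  interior_mm2 <- region_area_mm2(parts$interior, grid_step = 2)
  expect_equal(band_mm2, 2.0 * 0.4, tolerance = 0.01)
  expect_equal(band_mm2 + interior_mm2, roi_area_mm2(r), tolerance = 0.01)
})

test_that("degenerate band widths behave", {
  r <- rect_roi(0, 0, 400, 300)
  z <- subcapsular_band(r, band_um = 0)
  expect_equal(region_area_mm2(z$band, grid_step = 4), 0)
  pts <- pdt(c(50, 200), c(50, 150))
  expect_equal(nrow(filter_to_roi(pts, z$interior)), 2)

  # ROI entirely deeper than the band: capsule far above the polygon
  r2 <- roi(list(cbind(c(0, 400, 400, 0), c(2000, 2000, 2300, 2300))),
            capsule = cbind(c(0, 400), c(0, 0)), pixel_size = 0.49)
  parts2 <- subcapsular_band(r2, 400)
  expect_equal(region_area_mm2(parts2$band, grid_step = 4), 0)
  expect_error(subcapsular_band(rect_roi(0, 0, 10, 10, capsule = FALSE)),
               "no capsule")
})

test_that("ROI filtering matches an independent point-in-polygon oracle", {
  skip_if_not_installed("mgcv")
  set.seed(81)
  hex <- cbind(60 + 50 * cos(seq(0, 2 * pi, length.out = 7)[-7]),
               60 + 50 * sin(seq(0, 2 * pi, length.out = 7)[-7]))
  hole <- cbind(60 + 12 * cos(seq(0, 2 * pi, length.out = 9)[-9]),
                60 + 12 * sin(seq(0, 2 * pi, length.out = 9)[-9]))
  r <- roi(list(hex), list(hole), pixel_size = 0.49)
  pts <- pdt(runif(1000, 0, 120), runif(1000, 0, 120))
  kept <- filter_to_roi(pts, r)
  in_hex <- mgcv::in.out(rbind(hex, hex[1, ]), as.matrix(pts[, c("x", "y")]))
  in_hole <- mgcv::in.out(rbind(hole, hole[1, ]), as.matrix(pts[, c("x", "y")]))
  expect_setequal(rownames(kept), rownames(pts[in_hex & !in_hole, ]))

  # centroid retained, hole center removed, boundary inclusive
  expect_equal(nrow(filter_to_roi(pdt(60 + 20, 60), r)), 1)
  expect_equal(nrow(filter_to_roi(pdt(60, 60), r)), 0)
  expect_equal(nrow(filter_to_roi(pdt(110, 60), r)), 1)  # on hex vertex
})

test_that("cell densities recover planted ground truth", {
  ps <- 0.49
  # exactly 1 mm^2 square with 10 points inside
  side <- 1000 / ps
  r <- rect_roi(0, 0, side, side, pixel_size = ps, capsule = FALSE)
  expect_equal(roi_area_mm2(r), 1, tolerance = 1e-12)
  q <- cell_density(pdt(seq(100, 1000, length.out = 10), rep(500, 10)), r)
  expect_equal(q$density, 10)
  expect_equal(cell_density(pdt(numeric(0), numeric(0)), r)$density, 0)

  s <- generate_scene(c(CD3 = 80), scene_um = 500, seed = 82)
  q2 <- cell_density(scene_dots(s, "CD3"), s$roi)
  planted <- 80 / roi_area_mm2(s$roi)
  expect_lt(abs(q2$density - planted) / planted, 0.05)
})

test_that("double positivity pairs one-to-one with a strict radius", {
  a <- pdt(c(10, 50), c(10, 10), "CD3")
  b <- pdt(c(10, 50), c(10, 10), "CD8")
  dp <- double_positive(a, b, radius_um = 4, pixel_size = 0.49)
  expect_equal(nrow(dp), 2)

  # 5 um apart with a 4 um strict radius: not double positive
  far <- pdt(10 + 5 / 0.49, 10, "CD8")
  expect_equal(nrow(double_positive(pdt(10, 10), far, 4, 0.49)), 0)
  # exactly at the radius (8 px at 0.5 um/px): strict "<" excludes
  at <- pdt(10 + 8, 10, "CD8")
  expect_equal(nrow(double_positive(pdt(10, 10), at, 4, 0.5)), 0)
  expect_equal(nrow(double_positive(pdt(10, 10), at, 4.001, 0.5)), 1)

  # one B cannot validate two A
  a2 <- pdt(c(10, 11), c(10, 10))
  b1 <- pdt(10.5, 10, "CD8")
  expect_equal(nrow(double_positive(a2, b1, 4, 0.49)), 1)
})

test_that("double_positive and subtract_population partition A", {
  set.seed(83)
  for (k in 1:50) {
    na <- sample(0:15, 1); nb <- sample(0:15, 1)
    a <- pdt(runif(na, 0, 40), runif(na, 0, 40))
    b <- pdt(runif(nb, 0, 40), runif(nb, 0, 40), "CD8")
    dp <- double_positive(a, b, 4, 0.49)
    sub <- subtract_population(a, b, 4, 0.49)
    expect_equal(nrow(dp) + nrow(sub), na)
    expect_length(intersect(rownames(dp), rownames(sub)), 0)
  }
  # planted co-localization recovered exactly from ground-truth coordinates
  s <- generate_scene(c(CD68 = 40),
                      coloc_fractions = data.frame(a = "CD68", b = "CD163",
                                                   fraction = 0.5),
                      scene_um = 1200, seed = 84)
  dp <- double_positive(scene_dots(s, "CD68"), scene_dots(s, "CD163"),
                        radius_um = 21, pixel_size = s$pixel_size)
  expect_equal(nrow(dp), 20)
})

test_that("population ratios flag zero denominators", {
  expect_equal(population_ratio(20, 10), 2)
  expect_equal(population_ratio(10, 10), 1)
  expect_warning(r0 <- population_ratio(5, 0), "missing")
  expect_true(is.na(r0))
})

test_that("mean shortest distance matches the brute-force oracle", {
  src <- pdt(c(0, 10), c(0, 0))
  expect_equal(mean_shortest_distance(src, src)$mean_px, 0)
  one <- mean_shortest_distance(pdt(0, 0), pdt(3, 4), pixel_size = 0.5)
  expect_equal(one$mean_px, 5)
  expect_equal(one$mean_um, 2.5)
  expect_false(mean_shortest_distance(pdt(numeric(0), numeric(0)),
                                      pdt(0, 0))$defined)

  set.seed(85)
  a <- pdt(runif(50, 0, 100), runif(50, 0, 100))
  b <- pdt(runif(50, 0, 100), runif(50, 0, 100), "CD68")
  got <- mean_shortest_distance(a, b)$mean_px
  oracle <- mean(vapply(seq_len(50), function(i)
    min(sqrt((a$x[i] - b$x)^2 + (a$y[i] - b$y)^2)), numeric(1)))
  expect_equal(got, oracle, tolerance = 1e-9)
  # directional measure: A->B need not equal B->A, both non-negative
  expect_gte(mean_shortest_distance(b, a)$mean_px, 0)
})

test_that("positive-pixel fractions recover planted area", {
  r <- rect_roi(0, 0, 40, 40, capsule = FALSE)
  half <- matrix(0, 50, 50); half[, 1:21] <- 1  # left half of the 0..40 ROI
  got <- positive_pixel_fraction(half, r, method = "fixed", threshold = 0.5)
  expect_equal(got$percentage, 21 / 41 * 100, tolerance = 1e-9)
  expect_equal(positive_pixel_fraction(matrix(0, 50, 50), r, "fixed",
                                       threshold = 0.5)$percentage, 0)

  s <- generate_scene(c(CD3 = 0), scene_um = 300, capillary_fraction = 0.1,
                      seed = 86)
  plane <- channel_plane(s$capillary_mask + 0, "Opal690", "CD34",
                         pixel_size = s$pixel_size)
  auto <- positive_pixel_fraction(plane, s$roi, method = "otsu")
  expect_lt(abs(auto$percentage - 10), 1)
})

test_that("otsu threshold separates classes like the reference implementation", {
  set.seed(87)
  v <- c(rnorm(600, 0.2, 0.04), rnorm(400, 0.75, 0.05))
  thr <- otsu_threshold(v)
  ref <- EBImage::otsu(matrix(v, 50, 20), range = range(v))
  expect_identical(v >= thr, v >= ref)
})

test_that("excluding the subcapsular band never increases counts", {
  set.seed(88)
  for (k in 1:10) {
    s <- generate_scene(c(CD3 = 40), scene_um = 500, seed = 880 + k)
    parts <- subcapsular_band(s$roi, band_um = 150)
    dots <- scene_dots(s, "CD3")
    n_full <- nrow(filter_to_roi(dots, s$roi))
    n_int <- nrow(filter_to_roi(dots, parts$interior))
    n_band <- nrow(filter_to_roi(dots, parts$band))
    expect_lte(n_int, n_full)
    expect_equal(n_int + n_band, n_full)
  }
})
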