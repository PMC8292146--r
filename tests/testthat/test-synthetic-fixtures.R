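test_that("empty and degenerate scenes are valid", {
  s <- generate_scene(c(CD3 = 0, CD68 = 0), scene_um = 100, seed = 1)
  expect_equal(nrow(s$cells), 0)
  expect_equal(nrow(scene_dots(s)), 0)
})

test_that("parameter validation rejects bad inputs", {
  expect_error(generate_scene(c(CD3 = -1), seed = 1), "non-negative")
  expect_error(generate_scene(c(CD3 = 5),
                              coloc_fractions = data.frame(a = "CD3", b = "CD8",
                                                           fraction = 1.5),
                              seed = 1), "\\[0, 1\\]")
  expect_error(generate_scene(c(XYZ = 5), seed = 1), "invalid population")
  expect_error(generate_scene(c(CD34 = 5), seed = 1), "invalid population")
})

test_that("planted co-localization counts are exact by construction", {
  s1 <- generate_scene(c(CD3 = 20),
                       coloc_fractions = data.frame(a = "CD3", b = "CD8",
                                                    fraction = 1.0),
                       scene_um = 300, seed = 5)
  n_cd8 <- sum(vapply(s1$cells$markers, function(m) "CD8" %in% m, logical(1)))
  expect_equal(n_cd8, 20)

  s2 <- generate_scene(c(CD68 = 40),
                       coloc_fractions = data.frame(a = "CD68", b = "CD163",
                                                    fraction = 0.5),
                       scene_um = 900, seed = 11)
  dbl <- sum(vapply(s2$cells$markers,
                    function(m) all(c("CD68", "CD163") %in% m), logical(1)))
  expect_equal(dbl, round(0.5 * 40))
  # fraction invariance across seeds (by construction, not sampling)
  for (sd in 2:4) {
    s <- generate_scene(c(CD68 = 30),
                        coloc_fractions = data.frame(a = "CD68", b = "CD163",
                                                     fraction = 0.3),
                        scene_um = 800, seed = sd)
    dbl <- sum(vapply(s$cells$markers,
                      function(m) all(c("CD68", "CD163") %in% m), logical(1)))
    expect_equal(dbl, round(0.3 * 30))
  }
})

test_that("scene generation is bit-for-bit deterministic under a seed", {
  a <- generate_scene(c(CD3 = 15, CD68 = 5), scene_um = 300,
                      n_exclusions = 1, seed = 42)
  b <- generate_scene(c(CD3 = 15, CD68 = 5), scene_um = 300,
                      n_exclusions = 1, seed = 42)
  expect_identical(a, b)
  c <- generate_scene(c(CD3 = 15, CD68 = 5), scene_um = 300,
                      n_exclusions = 1, seed = 43)
  expect_false(identical(a$cells, c$cells))
})

test_that("scene invariants: cells in bounds, markers from the panel", {
  s <- generate_scene(c(CD3 = 30, CD68 = 8, GATA3 = 10), scene_um = 400,
                      seed = 9)
  expect_true(all(s$cells$x_um >= 0 & s$cells$x_um <= 400))
  expect_true(all(s$cells$y_um >= 0 & s$cells$y_um <= 400))
  vocab <- names(marker_classes())
  expect_true(all(unlist(s$cells$markers) %in% vocab))
  # count conservation: one dot per cell-marker membership
  expect_equal(nrow(scene_dots(s, "CD3")), 30)
  expect_equal(nrow(scene_dots(s, "CD68")), 8)
})

test_that("rendering: single cell gives one compact region, deterministic", {
  s <- generate_scene(c(CD3 = 1), scene_um = 80, capillary_fraction = 0,
                      seed = 2)
  r1 <- render_multispectral(s, render_config(), tile_size_px = 64)
  r2 <- render_multispectral(s, render_config(), tile_size_px = 64)
  expect_identical(r1, r2)
  # stitch band-summed tiles and count connected bright regions
  planes <- lapply(r1$tiles, function(t)
    channel_plane(apply(t$intensities, c(1, 2), sum), "sum",
                  origin = t$origin, pixel_size = t$pixel_size))
  whole <- stitch_planes(planes, canvas_px = s$dims_px)
  lab <- EBImage::bwlabel(whole$abundance > 0.05 * max(whole$abundance))
  expect_equal(max(lab), 1)
})

test_that("noise-free pixels are non-negative library combinations (CLS oracle)", {
  s <- generate_scene(c(CD3 = 6, CD68 = 3), scene_um = 150, seed = 8)
  r <- render_multispectral(s, render_config(noise_sd = 0), tile_size_px = 128)
  L <- r$library$spectra
  fl <- colnames(L)
  tile <- r$tiles[[1]]
  H <- dim(tile$intensities)[1]
  set.seed(1)
  for (k in 1:25) {
    rr <- sample(H, 1); cc <- sample(dim(tile$intensities)[2], 1)
    y <- tile$intensities[rr, cc, ]
    a_hat <- pracma::lsqnonneg(L, y)$x
    a_true <- vapply(fl, function(f)
      r$abundance[[f]][tile$origin[2] + rr, tile$origin[1] + cc], numeric(1))
    expect_lt(max(abs(a_hat - a_true)), 1e-6)
  }
})

test_that("noise raises no negatives and bleeds cross channels as configured", {
  s <- generate_scene(c(CD68 = 4), scene_um = 150, capillary_fraction = 0,
                      seed = 3)
  lib <- default_spectral_library()
  fl <- colnames(lib$spectra)
  bl <- diag(length(fl)); dimnames(bl) <- list(fl, fl)
  bl["Opal540", "Opal520"] <- 0.3   # CD68 channel bleeding into CD4 channel
  cfg <- render_config(lib, noise_sd = 0.01, bleed = bl,
                       marker_map = c(DAPI = "DAPI", CD68 = "Opal540"))
  r <- render_multispectral(s, cfg, tile_size_px = 256)
  expect_true(all(vapply(r$tiles, function(t) all(t$intensities >= 0),
                         logical(1))))
  # the CD4 fluorophore plane now carries scaled macrophage signal
  expect_equal(r$abundance[["Opal520"]], 0.3 * r$abundance[["Opal540"]] / 1,
               tolerance = 1e-12)
})

test_that("annotations round-trip through ASAP XML without coordinate loss", {
  s <- generate_scene(c(CD3 = 3), scene_um = 120, n_exclusions = 1, seed = 4)
  f <- tempfile(fileext = ".xml")
  write_annotations(s, f)
  back <- read_annotations(f, pixel_size = s$pixel_size)
  expect_equal(nrow(back$dots), 3)
  orig <- scene_dots(s)
  ord <- order(orig$x); bord <- order(back$dots$x)
  expect_lt(max(abs(orig$x[ord] - back$dots$x[bord]),
                abs(orig$y[ord] - back$dots$y[bord])), 1e-3)
  expect_s3_class(back$roi, "roi")
  expect_equal(roi_area_mm2(back$roi), roi_area_mm2(s$roi), tolerance = 1e-9)
  expect_equal(back$roi$capsule, s$roi$capsule, ignore_attr = TRUE)

  # empty scene still yields a valid, readable file
  s0 <- generate_scene(c(CD3 = 0), scene_um = 100, seed = 1)
  f0 <- tempfile(fileext = ".xml")
  write_annotations(s0, f0)
  expect_equal(nrow(read_annotations(f0)$dots), 0)
})

test_that("large dot sets round-trip below 1e-3 px error", {
  s <- generate_scene(c(CD3 = 1000), scene_um = 600, capillary_fraction = 0,
                      seed = 17)
  f <- tempfile(fileext = ".xml")
  write_annotations(s, f)
  back <- read_annotations(f)
  expect_equal(nrow(back$dots), 1000)
  orig <- scene_dots(s)
  key <- function(d) d[order(d$x, d$y), ]
  expect_lt(max(abs(key(orig)$x - key(back$dots)$x),
                abs(key(orig)$y - key(back$dots)$y)), 1e-3)
})

test_that("tile and plane files round-trip with origin metadata", {
  s <- generate_scene(c(CD3 = 2), scene_um = 60, seed = 6)
  r <- render_multispectral(s, render_config(), tile_size_px = 64)
  f <- tempfile(fileext = ".tif")
  write_ms_tile(r$tiles[[1]], f)
  back <- read_ms_tile(f)
  expect_equal(back$origin, r$tiles[[1]]$origin)
  expect_equal(back$intensities, r$tiles[[1]]$intensities,
               tolerance = 1e-6)
  p <- channel_plane(matrix(runif(30) * 7, 5, 6), "Opal520", "CD4",
                     origin = c(10, 20))
  fp <- tempfile(fileext = ".tif")
  write_channel_plane(p, fp)
  bp <- read_channel_plane(fp)
  expect_equal(bp$abundance, p$abundance, tolerance = 1e-6)
  expect_equal(bp$origin, c(10, 20))
  expect_equal(bp$marker, "CD4")
})
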