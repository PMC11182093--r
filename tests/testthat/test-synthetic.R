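test_that("phantom generators are bit deterministic in the seed", {
  m1 <- gen_mosaic(field_um = c(100, 100), density = 10000,
                   dark_cone_fraction = 0.2, seed = 33)
  m2 <- gen_mosaic(field_um = c(100, 100), density = 10000,
                   dark_cone_fraction = 0.2, seed = 33)
  expect_identical(m1, m2)
  expect_false(identical(
    m1$centers,
    gen_mosaic(field_um = c(100, 100), density = 10000,
               dark_cone_fraction = 0.2, seed = 34)$centers))
  f1 <- gen_frames(test_base_image(), n_frames = 3, seed = 5)
  f2 <- gen_frames(test_base_image(), n_frames = 3, seed = 5)
  expect_identical(f1$frames, f2$frames)
  o1 <- gen_oct(n_ascans = 50, speckle_snr = 4, seed = 9)
  o2 <- gen_oct(n_ascans = 50, speckle_snr = 4, seed = 9)
  expect_identical(o1$volume$bscans, o2$volume$bscans)
  # the generator does not disturb the caller's RNG stream
  set.seed(1); before <- runif(3)
  set.seed(1); invisible(gen_mosaic(seed = 2)); after <- runif(3)
  expect_identical(before, after)
})

test_that("mosaic generator matches its target density and dark fraction", {
  realized <- vapply(1:10, function(s) {
    mo <- gen_mosaic(field_um = c(220, 220), density = 10000,
                     jitter_fraction = 0.1, seed = s)
    cm <- cell_mosaic(data.frame(x_px = mo$centers$x_um,
                                 y_px = mo$centers$y_um), "cone",
                      scale = modality_scale(1, 1),
                      expected_spacing_um = mo$spacing_um)
    voronoi_metrics(cm, roi(c(110, 110), 150, 150))$bounded_density_mm2
  }, numeric(1))
  expect_lt(abs(mean(realized) - 10000) / 10000, 0.02)
  mo <- gen_mosaic(field_um = c(400, 400), density = 12000,
                   dark_cone_fraction = 0.25, seed = 4)
  expect_lt(abs(mean(mo$centers$dark) - 0.25), 0.03)
  # no dark cones: confocal and split ground truth coincide
  mo0 <- gen_mosaic(field_um = c(100, 100), density = 10000,
                    dark_cone_fraction = 0, seed = 1)
  expect_true(all(!mo0$centers$dark))
})

test_that("an eccentricity-dependent density profile is tracked locally", {
  prof <- function(e) 25000 * exp(-1.2 * e) + 4000
  mo <- gen_mosaic(field_um = c(900, 900), density = prof,
                   jitter_fraction = 0.08, seed = 21)
  cm <- cell_mosaic(data.frame(x_px = mo$centers$x_um,
                               y_px = mo$centers$y_um), "cone",
                    scale = modality_scale(1, 1))
  ctr <- voronoi_metrics(cm, roi(c(450, 450), 120, 120),
                         guard_um = 30)$bounded_density_mm2
  edge <- voronoi_metrics(cm, roi(c(830, 450), 120, 120),
                          guard_um = 30)$bounded_density_mm2
  expect_lt(abs(ctr - prof(0)) / prof(0), 0.10)
  expect_lt(abs(edge - prof(0.38)) / prof(0.38), 0.15)
  expect_gt(ctr, edge)
})

test_that("rendered channels respect the dark-cone contract", {
  mo <- gen_mosaic(field_um = c(150, 150), density = 12000,
                   dark_cone_fraction = 0.2, seed = 7)
  rc <- render_channels(mo, um_per_px = 1, snr = Inf, seed = 7)
  expect_identical(nrow(rc$truth), nrow(mo$centers))
  # a noise-free single-cell render is localised to half a pixel
  one <- list(centers = data.frame(x_um = 30.3, y_um = 28.7, dark = FALSE),
              field_um = c(60, 60), spacing_um = 10)
  r1 <- render_channels(one, um_per_px = 1, psf_sigma_um = 1.5, snr = Inf)
  cm <- detect_cells(r1$confocal, "cone", 10, r1$scale)
  expect_identical(nrow(cm$centers), 1L)
  expect_lt(abs(cm$centers$x_px - r1$truth$x_px), 0.5)
  expect_lt(abs(cm$centers$y_px - r1$truth$y_px), 0.5)
})

test_that("frame generator honours its motion and default length contracts", {
  base <- test_base_image()
  gf0 <- gen_frames(base, n_frames = 4, amplitude_px = 0,
                    dy_amplitude_px = 0, noise_sd = 0, seed = 2)
  expect_true(all(gf0$dx == 0) && all(gf0$dy == 0))
  expect_equal(max(abs(gf0$frames[[1]] - gf0$reference)), 0)
  expect_identical(formals(gen_frames)$n_frames, 150)
  gf <- gen_frames(base, n_frames = 6, amplitude_px = 2.5, seed = 3)
  expect_lte(max(abs(gf$dx)), 2.5)
  expect_error(gen_frames(base[1:20, 1:20], amplitude_px = 10), "too small")
})

test_that("OCT and ruling phantoms enforce their invariants", {
  expect_error(gen_oct(boundaries = list(ilm = 150, opl = 100, ez = 170,
                                         rpe = 188)), "ILM <= OPL")
  o <- gen_oct(n_ascans = 40, seed = 2)
  expect_equal(o$volume$axial_um_per_px, 3.5)
  expect_equal(o$volume$lateral_um_per_px, 14)
  ru <- gen_ruling(width = 300, height = 20, seed = 3)
  expect_true(all(diff(ru$lut_true) > 0))
  nt <- gen_normative(seed = 5)
  expect_s3_class(nt, "normative_table")
  expect_true(all(nt$sd > 0))
  # foveal cone density lies in the healthy adult range
  fov <- nt[nt$measure == "cone_density" & nt$eccentricity_mm == 0, ]
  expect_true(all(fov$mean > 1e5 & fov$mean < 1.7e5))
})
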