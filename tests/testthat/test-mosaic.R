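sc1 <- modality_scale(1, 1)

test_that("square lattice metrics are exact", {
  g <- expand.grid(x = seq(5, 195, 10), y = seq(5, 195, 10))
  cm <- cell_mosaic(data.frame(x_px = g$x + 0.5, y_px = g$y + 0.5),
                    "cone", scale = sc1, expected_spacing_um = 10)
  m <- voronoi_metrics(cm, roi(c(100, 100), 100, 100))
  expect_equal(m$bounded_density_mm2, 10000, tolerance = 1e-9)
  expect_equal(m$mean_cell_area_um2, 100, tolerance = 1e-9)
  expect_equal(m$sd_cell_area_um2, 0, tolerance = 1e-7)
  expect_identical(m$n_bounded, 100L)
})

test_that("hexagonal lattice density matches 2/(sqrt(3) s^2) exactly", {
  s <- 3.2
  pts <- hex_points(s, 120, 120)
  cm <- cell_mosaic(data.frame(x_px = pts[, 1] + 0.5, y_px = pts[, 2] + 0.5),
                    "cone", scale = sc1, expected_spacing_um = s)
  m <- voronoi_metrics(cm, roi(c(60, 60), 50, 50))
  expect_equal(m$bounded_density_mm2, 2 / (sqrt(3) * s^2) * 1e6,
               tolerance = 1e-9)
  expect_equal(m$mean_spacing_um, s, tolerance = 1e-9)
  # bounded-density identity: density x total bounded area = n_bounded
  expect_equal(m$bounded_density_mm2 *
                 (m$n_bounded * m$mean_cell_area_um2 / 1e6),
               m$n_bounded, tolerance = 1e-9)
})

test_that("metrics are invariant to translation and 90-degree rotation", {
  set.seed(9)
  pts <- hex_points(5, 150, 150)
  pts <- pts + matrix(rnorm(length(pts), 0, 0.5), ncol = 2)
  mk <- function(p) cell_mosaic(data.frame(x_px = p[, 1], y_px = p[, 2]),
                                "cone", scale = sc1,
                                expected_spacing_um = 5)
  m0 <- voronoi_metrics(mk(pts), roi(c(75, 75), 60, 60))
  mt <- voronoi_metrics(mk(pts + 13.7), roi(c(75, 75) + 13.7, 60, 60))
  # 90-degree rotation about the ROI centre in um space (centres map to
  # um as px - 0.5, hence the extra unit in the reflection)
  rot <- cbind(151 - pts[, 2], pts[, 1])
  mr <- voronoi_metrics(mk(rot), roi(c(75, 75), 60, 60))
  expect_equal(mt$bounded_density_mm2, m0$bounded_density_mm2,
               tolerance = 1e-9)
  expect_equal(mr$bounded_density_mm2, m0$bounded_density_mm2,
               tolerance = 1e-9)
  expect_identical(mt$n_bounded, m0$n_bounded)
  expect_identical(mr$n_bounded, m0$n_bounded)
})

test_that("Poisson phantom density is recovered near its intensity", {
  lambda <- 8000                              # cells per mm^2
  dens <- vapply(1:12, function(seed) {
    set.seed(seed)
    n <- rpois(1, lambda * (260 / 1000)^2)
    p <- cbind(runif(n, 0, 260), runif(n, 0, 260))
    cm <- cell_mosaic(data.frame(x_px = p[, 1], y_px = p[, 2]), "cone",
                      scale = sc1, expected_spacing_um = sqrt(1e6 / lambda))
    voronoi_metrics(cm, roi(c(130, 130), 160, 160))$bounded_density_mm2
  }, numeric(1))
  expect_lt(abs(mean(dens) - lambda) / lambda, 0.03)
})

test_that("detection achieves high recall and precision on a jittered phantom", {
  mo <- gen_mosaic(field_um = c(150, 150), density = 12000,
                   jitter_fraction = 0.10, seed = 8)
  rc <- render_channels(mo, um_per_px = 0.75, snr = 10, seed = 8)
  cm <- detect_cells(rc$confocal, "cone", mo$spacing_um, rc$scale)
  sp_px <- mo$spacing_um / 0.75
  lim <- function(df) df[df$x_px > sp_px & df$x_px < 200 - sp_px &
                           df$y_px > sp_px & df$y_px < 200 - sp_px, ]
  tr <- lim(rc$truth)
  tp <- count_matches(cm$centers, tr, 0.4 * sp_px)
  expect_gte(tp / nrow(tr), 0.99)
  expect_gte(tp / nrow(lim(cm$centers)), 0.99)
})

test_that("detection edge cases: blank image, close pair, Nyquist gate", {
  expect_identical(nrow(detect_cells(matrix(0.3, 60, 60), "cone", 8,
                                     sc1)$centers), 0L)
  # two spots closer than the separation rule keep exactly one centre
  img <- matrix(0, 64, 64)
  for (p in list(c(32, 30), c(32, 33.2))) {    # 3.2 px apart, min sep 4
    dx <- outer(rep(1, 64), seq_len(64) - p[2])
    dy <- outer(seq_len(64) - p[1], rep(1, 64))
    img <- img + exp(-(dx^2 + dy^2) / (2 * 1.5^2))
  }
  cm <- detect_cells(img, "cone", 8, sc1)
  expect_identical(nrow(cm$centers), 1L)
  expect_error(detect_cells(img, "cone", 1.5, sc1), "Nyquist")
})

test_that("manual edits add, remove and log deterministically", {
  mo <- gen_mosaic(field_um = c(80, 80), density = 10000, seed = 3)
  rc <- render_channels(mo, um_per_px = 1, snr = Inf, seed = 3)
  cm <- detect_cells(rc$confocal, "cone", mo$spacing_um, rc$scale)
  n0 <- nrow(cm$centers)
  expect_identical(nrow(apply_edits(cm)$centers), n0)
  # add then remove the same point leaves the set unchanged but logged
  p <- data.frame(x_px = 40.2, y_px = 41.3)
  cm2 <- apply_edits(apply_edits(cm, add = p), remove = p)
  expect_identical(nrow(cm2$centers), n0)
  expect_length(cm2$edit_log, 2)
  # removing k of n auto centres leaves n - k
  k <- 5L
  cm3 <- apply_edits(cm, remove = cm$centers[1:k, 1:2])
  expect_identical(nrow(cm3$centers), n0 - k)
  expect_identical(nrow(cm3$removed), k)
  expect_warning(apply_edits(cm, remove = data.frame(x_px = 1, y_px = 1),
                             tolerance_px = 0.5), "no centre")
})

test_that("dark-cone discordance counts unmatched split-detection cells", {
  a <- data.frame(x_px = c(10, 20, 30), y_px = c(10, 20, 30))
  mk <- function(df) cell_mosaic(df, "cone", scale = sc1,
                                 expected_spacing_um = 10)
  r <- roi(c(20, 20), 40, 40)
  ident <- dark_cone_discordance(mk(a), mk(a), r, match_radius_um = 2)
  expect_identical(ident$n_unmatched_split, 0L)
  far <- data.frame(x_px = c(11, 21, 31) + 5, y_px = c(10, 20, 30) + 5)
  disj <- dark_cone_discordance(mk(a), mk(far), r, match_radius_um = 1)
  expect_identical(disj$n_unmatched_split, 3L)
  # phantom with a 20% dark fraction
  mo <- gen_mosaic(field_um = c(250, 250), density = 12000,
                   jitter_fraction = 0.1, dark_cone_fraction = 0.2,
                   seed = 12)
  rc <- render_channels(mo, um_per_px = 1, psf_sigma_um = 1.6, snr = 10,
                        seed = 12)
  cmc <- detect_cells(rc$confocal, "cone", mo$spacing_um, rc$scale)
  W <- ncol(rc$split)
  resp <- 0.5 - (rc$split[, c(2:W, W)] - rc$split[, c(1, 1:(W - 1))]) / 2
  cms <- detect_cells(resp, "cone", mo$spacing_um, rc$scale)
  dc <- dark_cone_discordance(cmc, cms, roi(c(125, 125), 180, 180),
                              match_radius_um = 0.35 * mo$spacing_um)
  expect_lt(abs(dc$unmatched_fraction - 0.2), 0.04)
})
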