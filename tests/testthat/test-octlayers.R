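test_that("noiseless flat phantom boundaries are recovered exactly", {
  ph <- gen_oct(n_ascans = 200, boundaries = list(ilm = 100, opl = 150,
                                                  ez = 170, rpe = 188),
                speckle_snr = Inf, seed = 1)
  seg <- segment_layers(ph$volume)
  for (b in c("ilm", "opl", "ez", "rpe"))
    expect_lt(max(abs(seg[[b]] - ph$truth[[b]])), 0.1)
  tp <- thickness_profile(seg)
  expect_equal(mean(tp$rt_um), 308, tolerance = 1e-9)
  expect_equal(mean(tp$orl_um), 133, tolerance = 1e-9)
  # fractional boundary positions are recovered too (area sampling)
  ph2 <- gen_oct(n_ascans = 60, boundaries = list(ilm = 100.37, opl = 150.21,
                                                  ez = 170.6, rpe = 187.83),
                 speckle_snr = Inf, seed = 1)
  seg2 <- segment_layers(ph2$volume)
  for (b in c("ilm", "opl", "ez", "rpe"))
    expect_lt(max(abs(seg2[[b]] - ph2$truth[[b]])), 0.1)
})

test_that("speckled sinusoidal phantoms segment to about one pixel", {
  bfun <- function(base, amp, per, ph = 0)
    function(a) base + amp * sin(2 * pi * a / per + ph)
  ph <- gen_oct(n_ascans = 300,
                boundaries = list(ilm = bfun(95, 6, 150),
                                  opl = bfun(148, 5, 170, 1),
                                  ez = bfun(168, 4, 190, 2),
                                  rpe = bfun(186, 4, 210, 0.5)),
                speckle_snr = 5, seed = 2)
  seg <- segment_layers(ph$volume)
  for (b in c("ilm", "opl", "ez", "rpe"))
    expect_lte(mean(abs(seg[[b]] - ph$truth[[b]])), 1)
  # ordering invariant on output
  ok <- !is.na(seg$ilm) & !is.na(seg$opl) & !is.na(seg$ez) & !is.na(seg$rpe)
  expect_true(all((seg$ilm <= seg$opl & seg$opl <= seg$ez &
                     seg$ez <= seg$rpe)[ok]))
  tp <- thickness_profile(seg)
  expect_true(all((tp$rt_um >= tp$orl_um)[ok]))
})

test_that("seed polylines act as hard constraints", {
  ph <- gen_oct(n_ascans = 120, boundaries = list(ilm = 100, opl = 150,
                                                  ez = 170, rpe = 188),
                speckle_snr = Inf, seed = 1)
  seeds <- list(ilm = data.frame(ascan = c(10, 60, 110),
                                 row = c(95, 103, 99)))
  seg <- segment_layers(ph$volume, seeds = seeds)
  expect_equal(seg$ilm[10, 1], 95)
  expect_equal(seg$ilm[60, 1], 103)
  expect_equal(seg$ilm[110, 1], 99)
  # points between seeds interpolate the polyline
  expect_equal(seg$ilm[35, 1], stats::approx(c(10, 60), c(95, 103),
                                             xout = 35)$y)
})

test_that("degenerate A-scans are marked undefined, not guessed", {
  ph <- gen_oct(n_ascans = 100, boundaries = list(ilm = 100, opl = 150,
                                                  ez = 170, rpe = 188),
                speckle_snr = Inf, seed = 1)
  v <- ph$volume
  v$bscans[[1]][, 40:45] <- 0.05            # contrast-free A-scans
  seg <- segment_layers(v)
  expect_true(all(is.na(seg$ilm[40:45, 1])))
  tp <- thickness_profile(seg)
  expect_true(all(is.na(tp$rt_um[40:45, 1])))
})

test_that("thickness arithmetic and windowed extraction are exact", {
  seg <- structure(list(ilm = matrix(100, 50, 1), opl = matrix(150, 50, 1),
                        ez = matrix(170, 50, 1), rpe = matrix(188, 50, 1),
                        quality = matrix(1, 50, 1), axial_um_per_px = 3.5,
                        lateral_um_per_px = 14, bscan_spacing_um = 120),
                   class = "layer_segmentation")
  tp <- thickness_profile(seg)
  expect_equal(tp$rt_um[1, 1], 308)
  expect_equal(tp$orl_um[1, 1], 133)
  # zero-thickness degenerate case
  seg0 <- seg; seg0$ilm <- seg0$rpe
  expect_equal(thickness_profile(seg0)$rt_um[1, 1], 0)
  # linear thickness gradient: window mean equals the analytic mean
  na <- 400
  segl <- seg
  segl$ilm <- matrix(100, na, 1)
  segl$opl <- matrix(150, na, 1)
  segl$ez <- matrix(170, na, 1)
  segl$rpe <- matrix(188 + 0.05 * seq_len(na), na, 1)
  tpl <- thickness_profile(segl)
  res <- extract_thickness_at(tpl, fovea_ascan = 20,
                              offsets_mm = c(2.5, 3.0, 3.5), window = 10)
  expect_identical(res$offset_mm, c(2.5, 3.0, 3.5))
  for (i in 1:3) {
    center <- 20 + res$offset_mm[i] * 1000 / 14
    lo <- ceiling(center - 5); idx <- lo:(lo + 9)
    expect_equal(res$rt_um[i], mean((88 + 0.05 * idx) * 3.5),
                 tolerance = 1e-9)
  }
  expect_true(all(res$n_defined == 10))
  # constant phantom: same value at every offset
  resc <- extract_thickness_at(tp, fovea_ascan = 5,
                               offsets_mm = c(0.1, 0.2), window = 10)
  expect_true(all(resc$rt_um == 308))
  # window running off the scan is flagged partial
  resp <- extract_thickness_at(tp, fovea_ascan = 45, offsets_mm = 1,
                               window = 10)
  expect_true(resp$partial_window[1])
})
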