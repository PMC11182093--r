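test_that("similarity fit recovers exact parameters and rejects degeneracy", {
  set.seed(2)
  A <- cbind(runif(3, 0, 100), runif(3, 0, 100))
  th <- 10 * pi / 180; s <- 1.02
  R <- s * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  B <- t(R %*% t(A)) + rep(c(5, -3), each = 3)
  tf <- estimate_transform(A, B, "similarity")
  expect_lt(max(abs(tf$matrix - cbind(R, c(5, -3)))), 1e-9)
  expect_lt(tf$residual_rms, 1e-9)
  expect_error(estimate_transform(rbind(c(1, 1), c(1, 1)),
                                  rbind(c(2, 2), c(3, 3)), "similarity"),
               "coincident")
  expect_error(estimate_transform(cbind(1:4, 1:4), cbind(1:4, 2 * (1:4)),
                                  "affine"), "collinear")
})

test_that("affine residual equals the closed-form least-squares oracle", {
  set.seed(3)
  A <- cbind(runif(10, 0, 100), runif(10, 0, 100))
  M <- matrix(c(1.01, 0.03, -0.02, 0.99), 2, 2)
  B <- t(M %*% t(A)) + rep(c(4, -7), each = 10) +
    matrix(rnorm(20, 0, 0.5), 10, 2)
  tf <- estimate_transform(A, B, "affine")
  X <- cbind(A, 1)
  coef <- solve(t(X) %*% X, t(X) %*% B)     # normal equations oracle
  rms <- sqrt(mean(rowSums((X %*% coef - B)^2)))
  expect_equal(tf$residual_rms, rms, tolerance = 1e-9)
})

test_that("transform algebra composes, inverts and stays consistent", {
  t1 <- estimate_transform(cbind(c(0, 10, 3), c(0, 0, 8)),
                           cbind(c(2, 12.2, 5.1), c(1, 0.4, 9.0)),
                           "similarity")
  t2 <- transform2d(cbind(matrix(c(0.9, 0.1, -0.1, 0.9), 2, 2), c(5, 5)),
                    kind = "similarity")
  p <- cbind(runif(5, -20, 20), runif(5, -20, 20))
  expect_equal(tf_apply(tf_compose(t1, t2), p),
               tf_apply(t1, tf_apply(t2, p)), tolerance = 1e-12)
  expect_equal(tf_apply(tf_invert(t1), tf_apply(t1, p)), p,
               tolerance = 1e-9)
})

test_that("montage refinement places phantom tiles to sub-pixel accuracy", {
  mo <- gen_mosaic(field_um = c(260, 160), density = 12000, seed = 6)
  big <- render_channels(mo, um_per_px = 1, snr = Inf, seed = 6)$confocal
  t1 <- big[1:160, 1:160]
  t2 <- big[1:160, 101:260]                 # true offset 100 px
  sc <- modality_scale(1, 1)
  rmf <- 0.291
  fix_true <- rbind(c(0, 0), c(100 / (rmf * 1000), 0))
  res <- montage_place(list(t1, t2), fix_true, sc, rmf, refine = TRUE)
  d <- unlist(res$placements[2, c("x_px", "y_px")]) -
    unlist(res$placements[1, c("x_px", "y_px")])
  expect_lt(max(abs(d - c(100, 0))), 0.5)
  # deliberately wrong fixation labels are recovered by NCC refinement
  fix_bad <- rbind(c(0, 0), c(104.5 / (rmf * 1000), -3.2 / (rmf * 1000)))
  res2 <- montage_place(list(t1, t2), fix_bad, sc, rmf, refine = TRUE,
                        search_px = 10)
  d2 <- unlist(res2$placements[2, c("x_px", "y_px")]) -
    unlist(res2$placements[1, c("x_px", "y_px")])
  expect_lt(max(abs(d2 - c(100, 0))), 0.5)
  # the blended canvas reproduces the source mosaic in the overlap
  ov <- res$canvas[10:150, 111:150]
  src <- big[10:150, 111:150]
  expect_lt(mean(abs(ov - src), na.rm = TRUE) / mean(src), 0.02)
  # a single image montage is the image itself
  res1 <- montage_place(list(t1), rbind(c(0, 0)), sc, rmf, refine = TRUE)
  expect_equal(dim(res1$canvas) >= dim(t1), c(TRUE, TRUE))
})

test_that("foveal centre propagates through layers with round-trip accuracy", {
  rmf <- 0.291
  map <- retinal_map(eye = "OD", rmf = rmf)
  img_a <- matrix(runif(100 * 100), 100, 100)
  img_b <- matrix(runif(80 * 80), 80, 80)
  tf_a <- transform2d(cbind(diag(c(1.2, 1.2)), c(-60, -60)))
  th <- 3 * pi / 180
  tf_b <- transform2d(cbind(2 * matrix(c(cos(th), sin(th), -sin(th),
                                         cos(th)), 2, 2), c(-80, -75)))
  map <- map_add_layer(map, "aoslo", img_a, modality_scale(1.2, 1.2), tf_a)
  map <- map_add_layer(map, "oct_enface", img_b, modality_scale(2, 2), tf_b)
  map <- set_foveal_center(map, c(40, 37), "oct_enface")
  p_a <- map_project(map, map$foveal_center, "aoslo")
  back <- as.numeric(tf_apply(tf_a, p_a))
  expect_lt(max(abs(back - map$foveal_center)), 1e-6)
  # identity transform and P = (1, 1) -> fovea (1, 1) position in um
  map2 <- retinal_map("OD", rmf)
  map2 <- map_add_layer(map2, "oct_enface", img_b, modality_scale(1, 1),
                        transform2d())
  map2 <- set_foveal_center(map2, c(1, 1), "oct_enface")
  expect_equal(map2$foveal_center, c(1, 1))
  expect_error(set_foveal_center(map2, c(500, 1), "oct_enface"), "outside")
})

test_that("eccentricity arithmetic and meridian labelling are laterality aware", {
  rmf <- 0.291
  mk <- function(eye) {
    m <- retinal_map(eye, rmf)
    m <- map_add_layer(m, "l", matrix(0, 10, 10), modality_scale(1, 1),
                       transform2d())
    set_foveal_center(m, c(1, 1), "l")
  }
  od <- mk("OD")
  expect_equal(eccentricity_of(od, od$foveal_center)$mm, 0)
  e <- eccentricity_of(od, od$foveal_center + c(1500, 0))
  expect_equal(e$mm, 1.5)
  expect_equal(e$degrees, 1.5 / rmf, tolerance = 1e-12)
  os <- mk("OS")
  lab_od <- eccentricity_of(od, od$foveal_center + c(1000, 0))$meridian
  lab_os <- eccentricity_of(os, os$foveal_center + c(1000, 0))$meridian
  expect_true(lab_od != lab_os)
  expect_setequal(c(lab_od, lab_os), c("nasal", "temporal"))
  expect_equal(eccentricity_of(od, od$foveal_center + c(0, 800))$meridian,
               "inferior")
  expect_equal(eccentricity_of(od, od$foveal_center + c(0, -800))$meridian,
               "superior")
})
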