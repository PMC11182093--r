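base_img <- test_base_image()

test_that("frame ranking: reference scores 1, noisier frames rank lower", {
  ref <- base_img[11:150, 11:150]
  with_noise <- function(s, seed) {
    set.seed(seed)
    ref + matrix(rnorm(length(ref), 0, s), nrow(ref))
  }
  # mean score over replicates decreases strictly with noise level
  sds <- c(0.02, 0.06, 0.12, 0.25)
  means <- vapply(sds, function(s) {
    mean(vapply(1:20, function(k) {
      st <- list(ref, with_noise(s, k))
      rank_frames_by_ncc(st, 1)$score[2]
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) < 0))
  rk <- rank_frames_by_ncc(list(ref, with_noise(0.1, 1)), 1)
  expect_identical(rk$score[rk$index == 1], 1)
  # constant frame is flagged degenerate with -Inf score
  rk2 <- rank_frames_by_ncc(list(ref, matrix(0.5, nrow(ref), ncol(ref))), 1)
  expect_true(rk2$degenerate[rk2$index == 2])
  expect_identical(rk2$score[rk2$index == 2], -Inf)
})

test_that("top-n selection returns exactly n frames from a 150-frame stack", {
  gf <- gen_frames(base_img, n_frames = 150, amplitude_px = 1,
                   noise_sd = 0.02, seed = 2)
  rk <- rank_frames_by_ncc(gf$frames, 1)
  top <- rk$index[seq_len(50)]
  expect_length(top, 50)
  expect_length(unique(top), 50)
})

test_that("strip registration recovers integer and subpixel shifts", {
  ref <- base_img[31:170, 31:170]
  fr <- base_img[31:170 - 2, 31:170 + 3]       # = ref shifted by (-3, +2)
  so <- strip_register(fr, ref, strip_height = 32, search_radius = 8)
  acc <- so$strips[so$strips$accepted, ]
  expect_gt(nrow(acc), 4)
  expect_true(all(acc$dx == -3 & acc$dy == 2))
  # identity registration
  so0 <- strip_register(ref, ref, strip_height = 32, search_radius = 8)
  a0 <- so0$strips[so0$strips$accepted, ]
  expect_true(all(a0$dx == 0 & a0$dy == 0))
  expect_true(all(abs(a0$ncc - 1) < 1e-9))
  # subpixel at SNR 10
  dx <- 1.37; dy <- -0.62
  fr2 <- shift_image(base_img, dx, dy)[31:170, 31:170]
  set.seed(7)
  fr2 <- fr2 + matrix(rnorm(length(fr2), 0, 0.06), nrow(fr2))
  so2 <- strip_register(fr2, ref, strip_height = 32, search_radius = 8)
  a2 <- so2$strips[so2$strips$accepted, ]
  expect_lt(max(abs(a2$dx - dx)), 0.25)
  expect_lt(max(abs(a2$dy - dy)), 0.25)
})

test_that("per-strip offsets track a sinusoidal motion waveform", {
  gf <- gen_frames(base_img, n_frames = 12, amplitude_px = 3,
                   noise_sd = 0.05, seed = 5)
  errs <- unlist(lapply(1:12, function(f) {
    so <- strip_register(gf$frames[[f]], gf$reference, strip_height = 32,
                         search_radius = 8)
    st <- so$strips[so$strips$accepted, ]
    truth <- vapply(seq_len(nrow(st)), function(k)
      mean(gf$dx[st$row_start[k]:st$row_end[k], f]), numeric(1))
    st$dx - truth
  }))
  expect_lt(sqrt(mean(errs^2)), 0.5)
})

test_that("an unusable frame (all strips rejected) is flagged", {
  ref <- base_img[31:150, 31:150]
  flat <- matrix(0.5, nrow(ref), ncol(ref))
  so <- strip_register(flat, ref, strip_height = 32, search_radius = 8)
  expect_false(so$usable)
})

test_that("averaging identical frames reproduces the frame and top_n=1 uses one", {
  ref <- base_img[31:150, 31:150]
  # two frames, non-overlapping strips: per-pixel sums are powers of two,
  # so the mean of identical frames is bit exact
  frames2 <- list(ref, ref)
  offs2 <- lapply(frames2, strip_register, reference = ref,
                  strip_height = 32, search_radius = 8, overlap = 0)
  av2 <- average_registered(frames2, offs2, top_n = 2)
  full2 <- av2$coverage > 0
  expect_identical(av2$average[full2], ref[full2])
  frames <- list(ref, ref, ref)
  offs <- lapply(frames, strip_register, reference = ref,
                 strip_height = 32, search_radius = 8)
  av <- average_registered(frames, offs, top_n = 3)
  full <- av$coverage > 0
  expect_equal(av$average[full], ref[full], tolerance = 1e-14)
  av1 <- average_registered(frames, offs, top_n = 1)
  expect_length(av1$frames_used, 1)
  expect_error(average_registered(frames, offs, top_n = 0), "top_n")
})

test_that("averaging n noisy frames shrinks noise like 1/sqrt(n)", {
  ref <- base_img[31:150, 31:150]
  set.seed(11)
  frames <- lapply(1:25, function(i)
    ref + matrix(rnorm(length(ref), 0, 0.1), nrow(ref)))
  offs <- lapply(frames, strip_register, reference = ref,
                 strip_height = 32, search_radius = 8)
  av <- average_registered(frames, offs, top_n = 25)
  resid <- (av$average - ref)[av$coverage == 25]
  expect_lt(abs(stats::sd(resid) - 0.1 / 5), 0.1 / 5 * 0.10)
})
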