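toy_table <- normative_table(data.frame(
  measure = "cone_density", eccentricity_mm = c(0.5, 1, 1.5),
  meridian = "nasal", mean = c(40, 10, 8) * 1000, sd = c(8, 2, 1.6) * 1000,
  n = 10))

test_that("z-score definition, matching and the strict abnormality rule", {
  z <- zscore(5000, toy_table, "cone_density", 1, "nasal")
  expect_equal(z$z, -2.5)
  expect_true(z$abnormal)
  expect_false(zscore(10000, toy_table, "cone_density", 1, "nasal")$abnormal)
  expect_equal(zscore(10000, toy_table, "cone_density", 1, "nasal")$z, 0)
  # z = -2 exactly is NOT abnormal (strict inequality)
  z2 <- zscore(6000, toy_table, "cone_density", 1, "nasal")
  expect_equal(z2$z, -2)
  expect_false(z2$abnormal)
  # nearest-eccentricity matching within tolerance; error beyond it
  expect_equal(zscore(5000, toy_table, "cone_density", 1.1, "nasal")$z, -2.5)
  expect_error(zscore(5000, toy_table, "cone_density", 2.5, "nasal"),
               "available")
  expect_error(zscore(5000, toy_table, "cone_density", 1, "temporal"),
               "meridian")
})

test_that("z-score is affine equivariant", {
  set.seed(4)
  for (i in 1:20) {
    mu <- runif(1, 5, 50); sd <- runif(1, 1, 10); v <- rnorm(1, mu, sd)
    shift <- runif(1, -20, 20); fac <- runif(1, 0.1, 10)
    tab1 <- normative_table(data.frame(measure = "m", eccentricity_mm = 1,
                                       meridian = "nasal", mean = mu,
                                       sd = sd, n = 5))
    tab2 <- normative_table(data.frame(measure = "m", eccentricity_mm = 1,
                                       meridian = "nasal", mean = mu + shift,
                                       sd = sd, n = 5))
    tab3 <- normative_table(data.frame(measure = "m", eccentricity_mm = 1,
                                       meridian = "nasal", mean = fac * mu,
                                       sd = fac * sd, n = 5))
    z0 <- zscore(v, tab1, "m", 1, "nasal")$z
    expect_equal(zscore(v + shift, tab2, "m", 1, "nasal")$z, z0,
                 tolerance = 1e-12)
    expect_equal(zscore(fac * v, tab3, "m", 1, "nasal")$z, z0,
                 tolerance = 1e-12)
  }
})

test_that("normative table invariants are enforced", {
  bad_sd <- data.frame(measure = "m", eccentricity_mm = 1, meridian = "n",
                       mean = 1, sd = 0, n = 5)
  expect_error(normative_table(bad_sd), "SD")
  dup <- data.frame(measure = "m", eccentricity_mm = c(1, 1),
                    meridian = "n", mean = 1:2, sd = 1, n = 5)
  expect_error(normative_table(dup), "duplicate")
  expect_error(gen_normative(cv = 0), "positive")
})

test_that("exact Wilcoxon p equals full enumeration and matches wilcox.test", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6), "exact")$p, 0.1)
  # identical samples: p = 1 and degenerate flag
  w <- wilcoxon_rank_sum(c(2, 2, 2), c(2, 2), "exact")
  expect_equal(w$p, 1)
  expect_true(w$degenerate)
  set.seed(7)
  for (i in 1:25) {
    x <- rnorm(5); y <- rnorm(7)
    expect_equal(wilcoxon_rank_sum(x, y, "exact")$p,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("exact p is symmetric in the samples and lies in (0, 1]", {
  set.seed(8)
  for (i in 1:20) {
    x <- rnorm(6); y <- rnorm(9, 0.5)
    p1 <- wilcoxon_rank_sum(x, y, "exact")$p
    p2 <- wilcoxon_rank_sum(y, x, "exact")$p
    expect_equal(p1, p2, tolerance = 1e-12)
    expect_true(p1 > 0 && p1 <= 1)
  }
})

test_that("normal approximation tracks the exact p-value", {
  set.seed(9)
  dmax <- 0
  for (i in 1:60) {
    x <- rnorm(7); y <- rnorm(15)
    dmax <- max(dmax, abs(wilcoxon_rank_sum(x, y, "exact")$p -
                            wilcoxon_rank_sum(x, y, "normal_approx")$p))
  }
  expect_lt(dmax, 0.02)
})

test_that("ICC(A,1) matches an aov sums-of-squares oracle", {
  set.seed(5)
  m <- matrix(rnorm(12, 10), 4, 3) + rnorm(4)
  got <- icc_a1(m)
  df <- data.frame(y = as.vector(m), s = factor(rep(1:4, 3)),
                   r = factor(rep(1:3, each = 4)))
  a <- stats::anova(stats::aov(y ~ s + r, df))
  msr <- a["s", "Mean Sq"]; msc <- a["r", "Mean Sq"]
  mse <- a["Residuals", "Mean Sq"]
  oracle <- (msr - mse) / (msr + 2 * mse + (3 / 4) * (msc - mse))
  expect_equal(got$icc, oracle, tolerance = 1e-10)
  expect_true(got$ci_low <= got$icc && got$icc <= got$ci_high)
})

test_that("ICC edge cases: perfect agreement, permutation invariance, noise", {
  perfect <- cbind(c(1, 5, 9, 13), c(1, 5, 9, 13))
  expect_equal(icc_a1(perfect)$icc, 1)
  set.seed(6)
  m <- matrix(rnorm(10, 50, 8), 5, 2) + rnorm(5, 0, 4)
  expect_equal(icc_a1(m[sample(5), ])$icc, icc_a1(m)$icc, tolerance = 1e-12)
  expect_warning(icc_a1(matrix(3, 4, 2)), "variance")
  # adding iid noise lowers the ICC monotonically (Monte Carlo means)
  subj <- rnorm(12, 100, 20)
  mean_icc <- vapply(c(1, 5, 15), function(s) {
    mean(vapply(1:50, function(k) {
      set.seed(1000 * s + k)
      icc_a1(cbind(subj + rnorm(12, 0, s), subj + rnorm(12, 0, s)))$icc
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_icc) < 0))
})
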