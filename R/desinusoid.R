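# Correction of the sinusoidal fast-axis distortion introduced by a
# resonant scanner. Calibration: an image of a regular grid (Ronchi
# ruling) of known period; the detected line centres are fitted to an
# arcsine pixel-position model and retinal images are then resampled
# onto a grid of equally spaced positions.

# Detect sub-pixel line-centre columns from a ruling image: column-mean
# profile, matched-filter (Gaussian line template) NCC, strict local
# maxima above a relative threshold, parabolic sub-pixel refinement.
detect_line_centers <- function(img, template_sigma = 2, min_rel = 0.35) {
  prof <- colMeans(img)
  if (stats::sd(prof) < 1e-9)
    stop("no lines detected: calibration image is featureless", call. = FALSE)
  tw <- max(3L, ceiling(3 * template_sigma))
  tpl <- exp(-(seq(-tw, tw))^2 / (2 * template_sigma^2))
  tplz <- tpl - mean(tpl)
  n <- length(prof)
  rng <- diff(range(prof))
  score <- rep(NA_real_, n)
  for (i in seq_len(n - 2 * tw)) {
    seg <- prof[i:(i + 2 * tw)]
    s <- stats::sd(seg)
    # NCC is scale invariant, so gate on amplitude too: a real line must
    # modulate the profile by a sizeable fraction of its full range
    if (s > 0 && diff(range(seg)) > 0.25 * rng)
      score[i + tw] <- sum((seg - mean(seg)) * tplz) /
        (sqrt(sum(tplz^2)) * s * sqrt(2 * tw))
  }
  ok <- which(!is.na(score))
  if (!length(ok)) stop("no lines detected", call. = FALSE)
  thr <- min_rel * max(score, na.rm = TRUE)
  centers <- numeric(0)
  for (i in ok) {
    if (i <= 1L || i >= n) next
    if (is.na(score[i - 1]) || is.na(score[i + 1])) next
    if (score[i] > score[i - 1] && score[i] >= score[i + 1] &&
        score[i] > thr) {
      centers <- c(centers,
                   i + parabolic_offset(score[i - 1], score[i], score[i + 1]))
    }
  }
  sort(centers)
}

#' Fit a desinusoiding look-up table from a Ronchi-ruling image
#'
#' Detects the (approximately vertical) ruling line centres and fits the
#' arcsine pixel-position model of a resonant scanner,
#' `u(c) = A * sin(B * (c - c0) + phase) + offset`, where `u` is the true
#' (uniformly spaced) grid coordinate in line-period units and `c` the
#' recorded column. The fitted model is inverted into a per-output-column
#' look-up table of fractional source columns, so that resampling along
#' the LUT yields uniform line spacing.
#'
#' @param grid_image Matrix: the calibration image (lines near vertical).
#' @param line_period Physical line period (same unit as `distance`);
#'   only the ratio matters, so the default of 1 period-unit is fine when
#'   the physical geometry is not needed.
#' @param min_lines Minimum number of detected lines required.
#' @return An object of class `desinusoid_lut` with fields
#'   `source_width`, `mapping` (strictly increasing fractional source
#'   columns, one per output column), `fit_params`
#'   (`amplitude`, `freq`, `phase`, `offset`, `c0`, in period units) and
#'   `residual_px` (RMS of the fit in pixels).
#' @examples
#' ph <- gen_ruling(width = 256, height = 32, n_lines = 10, seed = 2)
#' lut <- fit_desinusoid(ph$image)
#' lut$residual_px
#' @export
fit_desinusoid <- function(grid_image, line_period = 1, min_lines = 8) {
  centers <- detect_line_centers(grid_image)
  if (length(centers) < min_lines)
    stop(sprintf("too few ruling lines detected (%d < %d)",
                 length(centers), min_lines), call. = FALSE)
  if (any(diff(centers) <= 0))
    stop("detected line centres are not monotone", call. = FALSE)
  W <- ncol(grid_image)
  c0 <- (W + 1) / 2
  k <- seq_along(centers) - 1          # line index; positions k * period
  u_t <- k * line_period
  # for fixed B the model is linear in (a, b, d):
  #   u = a sin(B (c - c0)) + b cos(B (c - c0)) + d
  sse_for <- function(B) {
    X <- cbind(sin(B * (centers - c0)), cos(B * (centers - c0)), 1)
    fit <- stats::lm.fit(X, u_t)
    sum(fit$residuals^2)
  }
  opt <- stats::optimize(sse_for, interval = c(1e-5, 1.05 * pi / W))
  B <- opt$minimum
  X <- cbind(sin(B * (centers - c0)), cos(B * (centers - c0)), 1)
  fit <- stats::lm.fit(X, u_t)
  a <- fit$coefficients[1]; b <- fit$coefficients[2]
  d <- fit$coefficients[3]
  A <- sqrt(a^2 + b^2)
  phase <- atan2(b, a)
  ufun <- function(cc) A * sin(B * (cc - c0) + phase) + d
  # residual in pixels via the local scan speed du/dc
  slope <- A * B * cos(B * (centers - c0) + phase)
  if (any(abs(slope) < 1e-12))
    stop("degenerate fit: zero scan speed at a detected line", call. = FALSE)
  residual_px <- sqrt(mean((fit$residuals / slope)^2))
  # invert onto a uniform u grid spanning the recorded field
  cc <- seq_len(W)
  uu <- ufun(cc)
  if (any(diff(uu) <= 0))
    stop("fitted scan model is not monotone over the image width",
         call. = FALSE)
  ugrid <- seq(uu[1], uu[W], length.out = W)
  arg <- clampi((ugrid - d) / A, -1, 1)
  mapping <- c0 + (asin(arg) - phase) / B
  mapping <- clampi(mapping, 1, W)
  if (any(diff(mapping) <= 0))
    stop("derived LUT mapping is not strictly increasing", call. = FALSE)
  structure(list(source_width = W, mapping = mapping,
                 fit_params = list(amplitude = A, freq = B, phase = phase,
                                   offset = d, c0 = c0,
                                   line_period = line_period),
                 residual_px = residual_px,
                 n_lines = length(centers)),
            class = "desinusoid_lut")
}

#' @export
print.desinusoid_lut <- function(x, ...) {
  cat(sprintf(
    "Desinusoid LUT: width %d, %d lines, amplitude %.3f periods, RMS %.4f px\n",
    x$source_width, x$n_lines, x$fit_params$amplitude, x$residual_px))
  invisible(x)
}

# Keys cubic-convolution weights (a = -0.5) for fractional offset f in [0,1):
# taps at source columns i0-1, i0, i0+1, i0+2.
cubic_weights <- function(f) {
  a <- -0.5
  w <- function(x) {
    x <- abs(x)
    ifelse(x <= 1, (a + 2) * x^3 - (a + 3) * x^2 + 1,
           ifelse(x < 2, a * x^3 - 5 * a * x^2 + 8 * a * x - 4 * a, 0))
  }
  c(w(1 + f), w(f), w(1 - f), w(2 - f))
}

#' Resample an image along a desinusoiding look-up table
#'
#' Applies a fitted [fit_desinusoid()] LUT: each output column `j` is
#' interpolated from the source image at fractional column
#' `lut$mapping[j]`, identically for every row. The output has the same
#' width as the input (the same pixel count resampled onto an equally
#' spaced grid); note that applying a LUT twice is not the same as
#' applying it once, since resampling composes.
#'
#' @param image Matrix with `ncol(image) == lut$source_width`.
#' @param lut A `desinusoid_lut`.
#' @param kernel `"cubic"` (Keys cubic convolution) or `"linear"`.
#' @return The resampled matrix, same dimensions as the input.
#' @export
apply_desinusoid <- function(image, lut, kernel = c("cubic", "linear")) {
  kernel <- match.arg(kernel)
  stopifnot(inherits(lut, "desinusoid_lut"))
  W <- ncol(image)
  if (W != lut$source_width)
    stop(sprintf("image width %d does not match LUT source width %d",
                 W, lut$source_width), call. = FALSE)
  out <- matrix(0, nrow(image), W)
  s <- lut$mapping
  i0 <- floor(s); f <- s - i0
  for (j in seq_len(W)) {
    if (f[j] == 0) {                   # exact column: copy bit-exactly
      out[, j] <- image[, i0[j]]
    } else if (kernel == "linear") {
      c1 <- clampi(i0[j], 1, W); c2 <- clampi(i0[j] + 1L, 1, W)
      out[, j] <- (1 - f[j]) * image[, c1] + f[j] * image[, c2]
    } else {
      wts <- cubic_weights(f[j])
      cols <- clampi(i0[j] + (-1L:2L), 1, W)
      out[, j] <- image[, cols, drop = FALSE] %*% wts
    }
  }
  out
}
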