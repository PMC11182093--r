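# Internal helpers shared across modules. Nothing here is exported.

# Evaluate `code` under a fixed RNG state without disturbing the caller's
# stream. Restores (or removes) .Random.seed afterwards.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed derived from a master seed and a named key, so each
# phantom sub-generator has its own stable stream (keys below 2^31).
fork_seed <- function(seed, key) {
  h <- as.numeric(seed) %% 2147483647
  for (k in utf8ToInt(as.character(key))) h <- (h * 31 + k) %% 2147483647
  as.integer(h)
}

clampi <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Quadratic (parabolic) interpolation of a peak from three samples.
# Returns the sub-sample offset in (-0.5, 0.5) relative to the centre sample.
parabolic_offset <- function(ym1, y0, yp1) {
  denom <- ym1 - 2 * y0 + yp1
  if (!is.finite(denom) || abs(denom) < .Machine$double.eps) return(0)
  d <- 0.5 * (ym1 - yp1) / denom
  max(-0.5, min(0.5, d))
}

# Bilinear sampling of matrix `img` at fractional (row, col) positions
# (1-based, pixel-centre convention). Out-of-range positions return NA.
bilinear_sample <- function(img, row, col) {
  row <- as.numeric(row); col <- as.numeric(col)
  nr <- nrow(img); nc <- ncol(img)
  ok <- row >= 1 & row <= nr & col >= 1 & col <= nc
  r0 <- clampi(floor(row), 1, nr - 1)
  c0 <- clampi(floor(col), 1, nc - 1)
  fr <- row - r0; fc <- col - c0
  idx <- function(r, c) img[cbind(r, c)]
  v <- (1 - fr) * (1 - fc) * idx(r0, c0) +
       (1 - fr) * fc       * idx(r0, c0 + 1) +
       fr       * (1 - fc) * idx(r0 + 1, c0) +
       fr       * fc       * idx(r0 + 1, c0 + 1)
  v[!ok] <- NA_real_
  v
}

# Separable Gaussian smoothing with replicate padding.
gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# 1-D convolution of each column (axis = 1) or row (axis = 2) of a matrix,
# replicate-padded, kernel assumed odd-length and normalised by the caller.
conv_axis <- function(img, k, axis = 1) {
  if (length(k) == 1L) return(img * k)
  r <- (length(k) - 1L) / 2L
  if (axis == 1) {
    nr <- nrow(img)
    pad <- rbind(img[rep(1L, r), , drop = FALSE], img,
                 img[rep(nr, r), , drop = FALSE])
    out <- matrix(0, nr, ncol(img))
    for (i in seq_along(k))
      out <- out + k[i] * pad[i:(i + nr - 1L), , drop = FALSE]
    out
  } else {
    t(conv_axis(t(img), k, axis = 1))
  }
}

gauss_blur <- function(img, sigma) {
  k <- gauss_kernel(sigma)
  conv_axis(conv_axis(img, k, 1), k, 2)
}

# Polygon area by the shoelace formula; `poly` is an n x 2 matrix.
shoelace_area <- function(poly) {
  n <- nrow(poly)
  if (is.null(n) || n < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Clip a convex polygon by the half-plane {x : a . x <= b}
# (Sutherland-Hodgman, convex input and convex result).
clip_halfplane <- function(poly, a, b) {
  n <- nrow(poly)
  if (is.null(n) || n == 0) return(poly)
  d <- poly %*% a - b
  inside <- d <= 0
  if (all(inside)) return(poly)
  if (!any(inside)) return(poly[0, , drop = FALSE])
  out <- matrix(numeric(0), 0, 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (inside[i]) out <- rbind(out, poly[i, ])
    if (xor(inside[i], inside[j])) {
      t <- d[i] / (d[i] - d[j])
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

# Pearson/zero-mean normalised cross correlation of two equal-size arrays.
ncc_scalar <- function(a, b) {
  a <- as.vector(a); b <- as.vector(b)
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) return(NA_real_)
  mean((a - mean(a)) * (b - mean(b))) / (sa * sb) * length(a) / (length(a) - 1)
}

# Summed-area table with a leading zero row/column, so that the sum of
# img[r1:r2, c1:c2] is sat[r2+1,c2+1]-sat[r1,c2+1]-sat[r2+1,c1]+sat[r1,c1].
integral_image <- function(img) {
  s <- apply(img, 2, cumsum)
  s <- t(apply(s, 1, cumsum))
  rbind(0, cbind(0, s))
}

window_sums <- function(sat, h, w) {
  H <- nrow(sat) - 1L; W <- ncol(sat) - 1L
  nr <- H - h + 1L; nc <- W - w + 1L
  r1 <- seq_len(nr); c1 <- seq_len(nc)
  sat[r1 + h, c1 + w, drop = FALSE] - sat[r1, c1 + w, drop = FALSE] -
    sat[r1 + h, c1, drop = FALSE] + sat[r1, c1, drop = FALSE]
}

# Normalised cross-correlation of `template` against every valid placement
# inside `region` (both matrices). FFT numerator, integral-image
# normalisation. Returns an (Hr-Ht+1) x (Wr-Wt+1) matrix of NCC values.
normxcorr <- function(template, region) {
  ht <- nrow(template); wt <- ncol(template)
  hr <- nrow(region);   wr <- ncol(region)
  stopifnot(ht <= hr, wt <= wr)
  n <- ht * wt
  tz <- template - mean(template)
  st <- sqrt(sum(tz^2))
  out_h <- hr - ht + 1L; out_w <- wr - wt + 1L
  # cross-correlation numerator via zero-padded FFT
  ph <- hr; pw <- wr
  A <- matrix(0, ph, pw); A[1:hr, 1:wr] <- region
  B <- matrix(0, ph, pw); B[1:ht, 1:wt] <- tz
  num <- Re(stats::fft(stats::fft(A) * Conj(stats::fft(B)), inverse = TRUE)) /
    (ph * pw)
  num <- num[1:out_h, 1:out_w, drop = FALSE]
  s1 <- window_sums(integral_image(region), ht, wt)
  s2 <- window_sums(integral_image(region^2), ht, wt)
  denom <- sqrt(pmax(s2 - s1^2 / n, 0)) * st
  ncc <- num / denom
  ncc[!is.finite(ncc)] <- NA_real_
  ncc[denom < 1e-12 * n] <- NA_real_
  ncc
}

# Locate the peak of an NCC surface with parabolic sub-pixel refinement.
# Returns list(row, col, value) in fractional surface coordinates.
peak_subpixel <- function(surf) {
  if (all(is.na(surf))) return(list(row = NA_real_, col = NA_real_, value = NA_real_))
  idx <- which(surf == max(surf, na.rm = TRUE), arr.ind = TRUE)[1, ]
  r <- idx[1]; c <- idx[2]
  on_border <- r == 1 || r == nrow(surf) || c == 1 || c == ncol(surf)
  # a numerically perfect match needs no refinement (and refinement would
  # only add interpolation noise to an exact integer alignment)
  if (surf[r, c] >= 1 - 1e-9)
    return(list(row = as.numeric(r), col = as.numeric(c),
                value = surf[r, c], on_border = on_border))
  dr <- dc <- 0
  if (r > 1 && r < nrow(surf) &&
      all(is.finite(surf[(r - 1):(r + 1), c])))
    dr <- parabolic_offset(surf[r - 1, c], surf[r, c], surf[r + 1, c])
  if (c > 1 && c < ncol(surf) &&
      all(is.finite(surf[r, (c - 1):(c + 1)])))
    dc <- parabolic_offset(surf[r, c - 1], surf[r, c], surf[r, c + 1])
  list(row = r + dr, col = c + dc, value = surf[r, c],
       on_border = on_border)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
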