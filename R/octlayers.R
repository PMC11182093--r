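# OCT layer segmentation and thickness extraction: four boundaries
# (ILM, posterior OPL, EZ centre, posterior RPE-BrM) found per A-scan
# from axial structure and refined by an energy-minimising contour
# (image gradient term + curvature smoothness term, solved by dynamic
# programming with sub-pixel refinement); retinal thickness (RT,
# ILM -> RPE-BrM) and outer-retinal-layer thickness (ORL,
# OPL -> RPE-BrM) follow in micrometres.

#' Construct an OCT volume
#'
#' @param bscans List of B-scan matrices (rows = axial, cols = A-scans),
#'   all the same size.
#' @param axial_um_per_px Axial pitch, um/px (default 3.5).
#' @param lateral_um_per_px Lateral pitch along the B-scan, um/px
#'   (default 14).
#' @param bscan_spacing_um Spacing between B-scans, um.
#' @param enface_transform Optional `transform2d` of the en-face
#'   projection into the common frame (x = A-scan, y = B-scan index).
#' @return An object of class `oct_volume`.
#' @export
oct_volume <- function(bscans, axial_um_per_px = 3.5,
                       lateral_um_per_px = 14, bscan_spacing_um = 120,
                       enface_transform = NULL) {
  if (!length(bscans)) stop("need at least one B-scan", call. = FALSE)
  dims <- vapply(bscans, dim, integer(2))
  if (any(dims != dims[, 1]))
    stop("all B-scans must have the same dimensions", call. = FALSE)
  if (axial_um_per_px <= 0 || lateral_um_per_px <= 0)
    stop("voxel scales must be positive", call. = FALSE)
  structure(list(bscans = bscans, axial_um_per_px = axial_um_per_px,
                 lateral_um_per_px = lateral_um_per_px,
                 bscan_spacing_um = bscan_spacing_um,
                 enface_transform = enface_transform),
            class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$bscans[[1]])
  cat(sprintf("OCT volume: %d B-scan(s) of %d rows x %d A-scans (%.1f um ",
              length(x$bscans), d[1], d[2], x$axial_um_per_px),
      sprintf("axial, %.1f um lateral)\n", x$lateral_um_per_px), sep = "")
  invisible(x)
}

# Dynamic-programming contour: choose one row per A-scan maximising
# sum(score) - smooth_w * sum((row_i+1 - row_i)^2), states restricted to
# `band` rows around `init`. Seeded columns are clamped to their seed row.
dp_contour <- function(score, init, band = 8, smooth_w = 0.5,
                       seed_rows = NULL) {
  n_rows <- nrow(score); n_a <- ncol(score)
  states <- -band:band
  ns <- length(states)
  cand <- outer(states, init, "+")           # ns x n_a candidate rows
  cand <- clampi(cand, 1, n_rows)
  if (!is.null(seed_rows)) {
    fixed <- which(!is.na(seed_rows))
    for (a in fixed) cand[, a] <- clampi(round(seed_rows[a]), 1, n_rows)
  }
  val <- matrix(-Inf, ns, n_a)
  ptr <- matrix(0L, ns, n_a)
  sc <- function(a) score[cbind(cand[, a], rep(a, ns))]
  val[, 1] <- sc(1)
  for (a in 2:n_a) {
    prev_rows <- cand[, a - 1]
    for (s in seq_len(ns)) {
      trans <- val[, a - 1] - smooth_w * (cand[s, a] - prev_rows)^2
      b <- which.max(trans)
      val[s, a] <- trans[b]
      ptr[s, a] <- b
    }
    val[, a] <- val[, a] + sc(a)
  }
  path <- integer(n_a)
  path[n_a] <- which.max(val[, n_a])
  for (a in n_a:2) path[a - 1] <- ptr[path[a], a]
  rows <- cand[cbind(path, seq_len(n_a))]
  as.numeric(rows)
}

# Sub-pixel edge localisation: centroid of |forward difference| of the
# (smoothed) profile around the integer row, signed by `polarity`
# (+1: intensity increases downward across the boundary). Positions of
# forward differences sit at r + 0.5, which makes the centroid exact for
# an area-sampled step edge.
edge_subpixel <- function(prof, r, polarity, halfw = 2) {
  n <- length(prof)
  i0 <- max(1L, r - halfw); i1 <- min(n - 1L, r + halfw - 1L)
  if (i1 < i0) return(r)
  d <- (prof[(i0 + 1):(i1 + 1)] - prof[i0:i1]) * polarity
  d[d < 0] <- 0
  if (sum(d) <= 0) return(r)
  sum((i0:i1 + 0.5) * d) / sum(d)
}

# Sub-pixel ridge-centre localisation for the EZ band: the midpoint of
# the band's rising and falling edges (each located by the
# gradient-centroid rule, exact for area-sampled steps). Falls back to
# an intensity centroid when either edge is missing.
ridge_subpixel <- function(prof, r, halfw = 5) {
  n <- length(prof)
  up <- edge_subpixel(prof, max(1L, r - 2L), +1, halfw = halfw)
  dn <- edge_subpixel(prof, min(n, r + 2L), -1, halfw = halfw)
  if (is.finite(up) && is.finite(dn) && dn > up) return((up + dn) / 2)
  i0 <- max(1L, r - halfw); i1 <- min(n, r + halfw)
  w <- prof[i0:i1] - min(prof[i0:i1])
  if (sum(w) <= 0) return(r)
  sum((i0:i1) * w) / sum(w)
}

#' Segment retinal boundaries on OCT B-scans
#'
#' Boundaries are found per B-scan in axial order: the ILM as the first
#' strong positive axial gradient (dark vitreous to bright retina), the
#' posterior RPE-BrM as the deepest strong negative gradient, the
#' posterior OPL as the strongest negative gradient between them and the
#' EZ centre as the intensity ridge between OPL and RPE-BrM. Each
#' boundary is refined by an energy-minimising contour (dynamic
#' programming over a band of candidate rows, image-gradient data term
#' and squared-difference smoothness), then localised to sub-pixel
#' precision; optional seed polylines act as hard constraints and are
#' interpolated exactly. The ordering ILM <= OPL <= EZ <= RPE-BrM is
#' enforced on output (violations are repaired by projection and
#' flagged). Per-A-scan quality comes from local contrast; A-scans with
#' no detectable gradient structure are marked undefined (NA).
#'
#' @param volume An [oct_volume()].
#' @param seeds Optional list (one entry per boundary name `ilm`, `opl`,
#'   `ez`, `rpe`) of data.frames with `ascan`, `row` (and optionally
#'   `bscan`, default 1): hard constraint points, linearly interpolated
#'   across A-scans in between.
#' @param smooth_sigma Lateral Gaussian smoothing applied before
#'   gradient extraction, px.
#' @param band Half-width of the contour search band, rows.
#' @param smooth_w Contour smoothness weight (squared row step).
#' @param min_contrast Minimum local intensity range for an A-scan to be
#'   considered defined.
#' @return A `layer_segmentation`: list of boundary matrices (`ilm`,
#'   `opl`, `ez`, `rpe`, each A-scans x B-scans, fractional rows, NA
#'   where undefined), `quality` matrix, and the volume geometry.
#' @export
segment_layers <- function(volume, seeds = NULL, smooth_sigma = 2,
                           band = 8, smooth_w = 0.5, min_contrast = 0.1) {
  stopifnot(inherits(volume, "oct_volume"))
  nb <- length(volume$bscans)
  na <- ncol(volume$bscans[[1]])
  nr <- nrow(volume$bscans[[1]])
  bnames <- c("ilm", "opl", "ez", "rpe")
  out <- lapply(bnames, function(b) matrix(NA_real_, na, nb))
  names(out) <- bnames
  quality <- matrix(0, na, nb)
  seed_vec <- function(bname, bi) {
    if (is.null(seeds) || is.null(seeds[[bname]])) return(NULL)
    s <- seeds[[bname]]
    if (is.null(s$bscan)) s$bscan <- 1L
    s <- s[s$bscan == bi, , drop = FALSE]
    if (!nrow(s)) return(NULL)
    v <- rep(NA_real_, na)
    if (nrow(s) == 1) v[round(s$ascan)] <- s$row
    else {
      s <- s[order(s$ascan), ]
      idx <- clampi(round(s$ascan), 1, na)
      rng <- min(idx):max(idx)
      v[rng] <- stats::approx(idx, s$row, xout = rng)$y
    }
    v
  }
  for (bi in seq_len(nb)) {
    img <- gauss_blur(volume$bscans[[bi]], smooth_sigma)
    # axial gradient (central differences)
    g <- img[c(2:nr, nr), ] - img[c(1, 1:(nr - 1)), ]
    rng <- apply(volume$bscans[[bi]], 2, function(v) diff(range(v)))
    quality[, bi] <- rng
    defined <- rng >= min_contrast
    if (!any(defined)) next
    # per-column initial estimates, taken in anatomical order: the ILM
    # is the FIRST strong brightening from the vitreous (the EZ onset is
    # brighter still, so a global gradient max would skip to it); the
    # RPE-BrM posterior is the DEEPEST strong darkening; the EZ centre
    # is the intensity ridge between them; the posterior OPL is the
    # darkening between the ILM and the EZ band onset. A running median
    # across A-scans suppresses speckle outliers before DP refinement.
    ilm0 <- rpe0 <- ez0 <- opl0 <- rep(NA_real_, na)
    for (a in which(defined)) {
      ga <- g[, a]
      up <- which(ga > 0.4 * max(ga)); dn <- which(ga < 0.4 * min(ga))
      if (!length(up) || !length(dn)) { defined[a] <- FALSE; next }
      ilm0[a] <- min(up); rpe0[a] <- max(dn)
      if (rpe0[a] <= ilm0[a] + 12) { defined[a] <- FALSE; next }
      # keep the EZ search clear of the RPE band (the two bright outer
      # bands are separated by at least ~9 rows axially)
      ezr <- (ilm0[a] + 8):max(ilm0[a] + 9, rpe0[a] - 9)
      ez0[a] <- ezr[which.max(img[ezr, a])]
      inner <- (ilm0[a] + 2):max(ilm0[a] + 3, ez0[a] - 6)
      opl0[a] <- inner[which.min(ga[inner])]
    }
    if (!any(defined)) next
    fill_med <- function(v) {
      ok <- which(!is.na(v))
      if (!length(ok)) return(v)
      v <- stats::approx(ok, v[ok], xout = seq_len(na), rule = 2)$y
      if (na >= 9) v <- stats::runmed(v, 9, endrule = "median")
      round(v)
    }
    ilm0 <- fill_med(ilm0); rpe0 <- fill_med(rpe0)
    ez0 <- fill_med(ez0);   opl0 <- fill_med(opl0)
    # per-boundary DP refinement with gradient data terms
    ilm <- dp_contour(g, ilm0, band, smooth_w, seed_vec("ilm", bi))
    rpe <- dp_contour(-g, rpe0, band, smooth_w, seed_vec("rpe", bi))
    opl <- dp_contour(-g, opl0, band, smooth_w, seed_vec("opl", bi))
    ez <- dp_contour(img, ez0, band, smooth_w, seed_vec("ez", bi))
    # sub-pixel localisation on the raw (unsmoothed laterally) columns
    raw <- volume$bscans[[bi]]
    for (a in seq_len(na)) {
      if (!defined[a]) next
      prof <- raw[, a]
      out$ilm[a, bi] <- edge_subpixel(prof, ilm[a], +1)
      out$opl[a, bi] <- edge_subpixel(prof, opl[a], -1)
      out$rpe[a, bi] <- edge_subpixel(prof, rpe[a], -1)
      out$ez[a, bi] <- ridge_subpixel(prof, ez[a])
    }
    # hard seed constraints are honoured exactly
    for (bn in bnames) {
      sv <- seed_vec(bn, bi)
      if (!is.null(sv)) out[[bn]][!is.na(sv), bi] <- sv[!is.na(sv)]
    }
    # enforce ordering by isotonic projection across the four boundaries
    for (a in seq_len(na)) {
      v <- c(out$ilm[a, bi], out$opl[a, bi], out$ez[a, bi], out$rpe[a, bi])
      if (any(is.na(v))) next
      if (any(diff(v) < 0)) {
        v <- sort(v)
        out$ilm[a, bi] <- v[1]; out$opl[a, bi] <- v[2]
        out$ez[a, bi] <- v[3]; out$rpe[a, bi] <- v[4]
        quality[a, bi] <- -abs(quality[a, bi])   # flag repaired A-scans
      }
    }
  }
  structure(list(ilm = out$ilm, opl = out$opl, ez = out$ez, rpe = out$rpe,
                 quality = quality, axial_um_per_px = volume$axial_um_per_px,
                 lateral_um_per_px = volume$lateral_um_per_px,
                 bscan_spacing_um = volume$bscan_spacing_um),
            class = "layer_segmentation")
}

#' @export
print.layer_segmentation <- function(x, ...) {
  cat(sprintf("Layer segmentation: %d A-scans x %d B-scans; %.1f%% defined\n",
              nrow(x$ilm), ncol(x$ilm),
              100 * mean(!is.na(x$ilm) & !is.na(x$rpe))))
  invisible(x)
}

#' Thickness profiles from a layer segmentation
#'
#' Retinal thickness `RT = (RPE-BrM - ILM) * axial_scale` and
#' outer-retinal-layer thickness `ORL = (RPE-BrM - OPL) * axial_scale`,
#' in micrometres, per A-scan and B-scan; undefined wherever an input
#' boundary is undefined. Positions are kept fractional throughout, so
#' no rounding enters the thickness.
#'
#' @param seg A `layer_segmentation`.
#' @return A `thickness_profile`: matrices `rt_um` and `orl_um`
#'   (A-scans x B-scans) plus the lateral geometry.
#' @export
thickness_profile <- function(seg) {
  stopifnot(inherits(seg, "layer_segmentation"))
  rt <- (seg$rpe - seg$ilm) * seg$axial_um_per_px
  orl <- (seg$rpe - seg$opl) * seg$axial_um_per_px
  structure(list(rt_um = rt, orl_um = orl,
                 lateral_um_per_px = seg$lateral_um_per_px,
                 bscan_spacing_um = seg$bscan_spacing_um),
            class = "thickness_profile")
}

#' Mean thickness over windows at nasal offsets from the fovea
#'
#' Extracts mean RT and ORL over a window of A-scans (default 10)
#' centred at given offsets (default 2.5, 3.0 and 3.5 mm) along the
#' nasal direction from the foveal centre within one B-scan.
#'
#' @param profile A [thickness_profile()].
#' @param fovea_ascan A-scan index of the foveal centre in the B-scan.
#' @param offsets_mm Offsets from the fovea along the nasal direction, mm.
#' @param window Window size in A-scans.
#' @param bscan B-scan index containing the fovea.
#' @param nasal_direction `+1` if the nasal retina lies toward increasing
#'   A-scan index, `-1` otherwise.
#' @return Data.frame with `offset_mm`, `rt_um`, `orl_um`,
#'   `n_defined`, `partial_window`.
#' @export
extract_thickness_at <- function(profile, fovea_ascan,
                                 offsets_mm = c(2.5, 3.0, 3.5),
                                 window = 10, bscan = 1,
                                 nasal_direction = +1) {
  stopifnot(inherits(profile, "thickness_profile"))
  na <- nrow(profile$rt_um)
  res <- lapply(offsets_mm, function(off) {
    center <- fovea_ascan + nasal_direction * off * 1000 /
      profile$lateral_um_per_px
    lo <- ceiling(center - window / 2)
    hi <- lo + window - 1L
    idx <- lo:hi
    partial <- any(idx < 1 | idx > na)
    idx <- idx[idx >= 1 & idx <= na]
    if (!length(idx))
      return(data.frame(offset_mm = off, rt_um = NA_real_,
                        orl_um = NA_real_, n_defined = 0L,
                        partial_window = TRUE))
    rt <- profile$rt_um[idx, bscan]
    orl <- profile$orl_um[idx, bscan]
    data.frame(offset_mm = off, rt_um = mean(rt, na.rm = TRUE),
               orl_um = mean(orl, na.rm = TRUE),
               n_defined = sum(!is.na(rt)), partial_window = partial)
  })
  do.call(rbind, res)
}
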