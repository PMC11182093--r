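# Montaging and multimodal alignment: similarity/affine transforms fitted
# to landmark pairs, placement of registered AOSLO averages from fixation
# coordinates with NCC refinement, a retinal map holding every modality
# in one micrometre-scale frame, the foveal-centre anchor and
# eccentricity queries.
#
# Coordinate conventions: in image space points are (x, y) with x along
# columns (rightward) and y along rows (downward), 1-based pixel centres
# in R; serialized transforms use 0-based pixel centres (stated in the
# JSON). The common frame is in micrometres.

#' Build a 2-D transform
#'
#' @param matrix A 2x3 matrix mapping `(x, y)` to
#'   `matrix %*% c(x, y, 1)`.
#' @param kind `"similarity"` or `"affine"`.
#' @param residual_rms Fit residual (RMS point distance), if known.
#' @return An object of class `transform2d`.
#' @export
transform2d <- function(matrix = cbind(diag(2), c(0, 0)),
                        kind = "similarity", residual_rms = 0) {
  matrix <- base::matrix(as.numeric(matrix), 2, 3)
  L <- matrix[, 1:2]
  if (abs(det(L)) < 1e-12)
    stop("transform linear part is singular", call. = FALSE)
  if (kind == "similarity") {
    # isotropic scale + rotation: columns orthogonal with equal norm
    if (abs(sum(L[, 1] * L[, 2])) > 1e-9 * sum(L^2) ||
        abs(sum(L[, 1]^2) - sum(L[, 2]^2)) > 1e-9 * sum(L^2))
      stop("matrix is not a similarity (shear or anisotropic scale)",
           call. = FALSE)
  }
  structure(list(matrix = matrix, kind = kind, residual_rms = residual_rms),
            class = "transform2d")
}

#' Apply a transform to points
#'
#' @param tf A `transform2d`.
#' @param xy N x 2 matrix (or length-2 vector) of `(x, y)` points.
#' @return N x 2 matrix of mapped points.
#' @export
tf_apply <- function(tf, xy) {
  xy <- rbind(c(0, 0), xy)[-1, , drop = FALSE]
  t(tf$matrix %*% t(cbind(xy, 1)))
}

#' Invert a transform
#' @param tf A `transform2d`.
#' @return The inverse `transform2d`.
#' @export
tf_invert <- function(tf) {
  L <- tf$matrix[, 1:2]; t0 <- tf$matrix[, 3]
  Li <- solve(L)
  transform2d(cbind(Li, -Li %*% t0), kind = tf$kind,
              residual_rms = tf$residual_rms)
}

#' Compose two transforms
#'
#' `tf_compose(a, b)` maps points first through `b`, then through `a`.
#' @param a,b `transform2d` objects.
#' @return The composed `transform2d`.
#' @export
tf_compose <- function(a, b) {
  La <- a$matrix[, 1:2]
  m <- cbind(La %*% b$matrix[, 1:2], La %*% b$matrix[, 3] + a$matrix[, 3])
  kind <- if (a$kind == "similarity" && b$kind == "similarity")
    "similarity" else "affine"
  transform2d(m, kind = kind,
              residual_rms = sqrt(a$residual_rms^2 + b$residual_rms^2))
}

#' @export
print.transform2d <- function(x, ...) {
  cat(sprintf("2-D %s transform (residual RMS %.4g):\n", x$kind,
              x$residual_rms))
  print(round(x$matrix, 6))
  invisible(x)
}

#' Fit a transform to landmark pairs
#'
#' Least-squares fit of a similarity (isotropic scale + rotation +
#' translation) or full affine transform mapping `points_a` onto
#' `points_b`. Points are expected to be supplied in scaled (micrometre)
#' space, so the transform absorbs only residual rotation, translation
#' and a small scale factor.
#'
#' @param points_a,points_b N x 2 matrices of corresponding `(x, y)`
#'   points (N >= 2 for similarity, N >= 3 and non-collinear for affine).
#' @param kind `"similarity"` or `"affine"`.
#' @return A `transform2d` with `residual_rms` set to the RMS residual
#'   point distance.
#' @examples
#' a <- cbind(c(0, 10, 3), c(0, 0, 8))
#' tf <- estimate_transform(a, a + 5, kind = "similarity")
#' tf$matrix
#' @export
estimate_transform <- function(points_a, points_b,
                               kind = c("similarity", "affine")) {
  kind <- match.arg(kind)
  A <- base::matrix(as.numeric(points_a), ncol = 2)
  B <- base::matrix(as.numeric(points_b), ncol = 2)
  if (nrow(A) != nrow(B)) stop("point sets differ in size", call. = FALSE)
  n <- nrow(A)
  dupA <- duplicated(round(A, 9)); dupB <- duplicated(round(B, 9))
  if (any(dupA) || any(dupB))
    stop("coincident landmark points", call. = FALSE)
  if (kind == "similarity") {
    if (n < 2) stop("similarity needs >= 2 landmark pairs", call. = FALSE)
    # closed form via complex regression: zb = m * za + t
    za <- complex(real = A[, 1], imaginary = A[, 2])
    zb <- complex(real = B[, 1], imaginary = B[, 2])
    ma <- mean(za); mb <- mean(zb)
    den <- sum(Mod(za - ma)^2)
    if (den < 1e-12) stop("degenerate landmark configuration", call. = FALSE)
    m <- sum((zb - mb) * Conj(za - ma)) / den
    t0 <- mb - m * ma
    M <- cbind(base::matrix(c(Re(m), Im(m), -Im(m), Re(m)), 2, 2),
               c(Re(t0), Im(t0)))
  } else {
    if (n < 3) stop("affine needs >= 3 landmark pairs", call. = FALSE)
    X <- cbind(A, 1)
    if (qr(X)$rank < 3)
      stop("landmark points are collinear: affine transform is not " ,
           "determined", call. = FALSE)
    coef <- qr.solve(X, B)            # 3 x 2
    M <- t(coef)[, c(1, 2, 3), drop = FALSE]
  }
  pred <- t(M %*% t(cbind(A, 1)))
  rms <- sqrt(mean(rowSums((pred - B)^2)))
  transform2d(M, kind = kind, residual_rms = rms)
}

#' Place registered images into a montage
#'
#' Initial tile placement comes from the fixation-target coordinates of
#' each acquisition (degrees, converted to micrometres through the RMF);
#' optionally each tile is then refined by normalised cross-correlation
#' against the already-placed mosaic over a bounded search, following a
#' breadth-first traversal of the tile overlap graph from the first
#' tile. Tiles whose overlap supports no reliable NCC peak keep their
#' fixation-based placement and are flagged. Overlaps are blended by
#' linear distance-to-edge feathering.
#'
#' @param images List of image matrices (registered averages).
#' @param fixation_deg N x 2 matrix of fixation coordinates in degrees
#'   (x, y).
#' @param scale `modality_scale` of the images (um/px).
#' @param rmf RMF in mm/deg used to convert fixation degrees to um.
#' @param refine Logical: NCC-refine placements against overlapping
#'   neighbours.
#' @param search_px Search radius for refinement, px.
#' @return List with `canvas` (blended montage), `origin_um` (um
#'   coordinate of canvas pixel (1, 1) centre), `placements` (data.frame
#'   `x_px`, `y_px`, `x_um`, `y_um`, `refined`, `flagged`), and
#'   `tf` (`transform2d` mapping canvas px to um).
#' @export
montage_place <- function(images, fixation_deg, scale, rmf, refine = TRUE,
                          search_px = 10) {
  n <- length(images)
  fixation_deg <- base::matrix(as.numeric(fixation_deg), ncol = 2)
  if (nrow(fixation_deg) != n)
    stop("need one fixation coordinate pair per image", call. = FALSE)
  mppx <- scale$microns_per_pixel_x; mppy <- scale$microns_per_pixel_y
  pos_um <- fixation_deg * rmf * 1000          # tile-centre positions
  pos_px <- cbind(pos_um[, 1] / mppx, pos_um[, 2] / mppy)
  dims <- t(vapply(images, dim, integer(2)))   # rows, cols
  # top-left pixel-centre position of each tile, px (common px frame)
  tl <- cbind(pos_px[, 1] - (dims[, 2] - 1) / 2,
              pos_px[, 2] - (dims[, 1] - 1) / 2)
  refined <- rep(FALSE, n); flagged <- rep(FALSE, n)
  if (refine && n > 1) {
    placed <- rep(FALSE, n); placed[1] <- TRUE
    ord <- bfs_overlap_order(tl, dims)
    for (i in ord[-1]) {
      # refine tile i against the union of already-placed tiles
      adj <- refine_tile(images, tl, dims, i, which(placed), search_px)
      if (is.null(adj)) flagged[i] <- TRUE
      else { tl[i, ] <- tl[i, ] + adj; refined[i] <- TRUE }
      placed[i] <- TRUE
    }
  }
  # canvas bounds: the canvas grid is anchored on tile 1's pixel grid so
  # integer placements copy pixels without interpolation blur
  x0 <- tl[1, 1] + floor(min(tl[, 1]) - tl[1, 1])
  y0 <- tl[1, 2] + floor(min(tl[, 2]) - tl[1, 2])
  W <- as.integer(ceiling(max(tl[, 1] + dims[, 2] - 1) - x0)) + 1L
  H <- as.integer(ceiling(max(tl[, 2] + dims[, 1] - 1) - y0)) + 1L
  acc <- base::matrix(0, H, W); wt <- base::matrix(0, H, W)
  for (i in seq_len(n)) {
    h <- dims[i, 1]; w <- dims[i, 2]
    fw <- feather_weights(h, w)
    # canvas indices whose positions fall inside tile i
    ux <- tl[i, 1] - x0; uy <- tl[i, 2] - y0   # tile origin in grid units
    cc <- max(1L, floor(ux) + 1L):min(W, ceiling(ux + w))
    rr <- max(1L, floor(uy) + 1L):min(H, ceiling(uy + h))
    g <- expand.grid(r = rr, c = cc)
    src_r <- g$r - 1 - uy + 1
    src_c <- g$c - 1 - ux + 1
    v <- bilinear_sample(images[[i]], src_r, src_c)
    fwv <- bilinear_sample(fw, src_r, src_c)
    ok <- !is.na(v) & !is.na(fwv)
    idx <- cbind(g$r[ok], g$c[ok])
    acc[idx] <- acc[idx] + v[ok] * fwv[ok]
    wt[idx] <- wt[idx] + fwv[ok]
  }
  canvas <- acc / wt
  canvas[wt == 0] <- NA_real_
  origin_um <- c((x0 - 1) * mppx, (y0 - 1) * mppy)
  tf <- transform2d(cbind(diag(c(mppx, mppy)), origin_um),
                    kind = "affine")
  list(canvas = canvas, origin_um = origin_um,
       placements = data.frame(x_px = tl[, 1], y_px = tl[, 2],
                               x_um = tl[, 1] * mppx, y_um = tl[, 2] * mppy,
                               refined = refined, flagged = flagged),
       tf = tf)
}

# Feathering weight map: linear distance to the nearest tile edge.
feather_weights <- function(h, w) {
  ry <- pmin(seq_len(h), h + 1 - seq_len(h))
  rx <- pmin(seq_len(w), w + 1 - seq_len(w))
  outer(ry, rx, pmin)
}

# Breadth-first order over the tile overlap graph starting from tile 1;
# unconnected tiles are appended at the end (they will be flagged).
bfs_overlap_order <- function(tl, dims) {
  n <- nrow(tl)
  overlaps <- function(i, j) {
    ox <- min(tl[i, 1] + dims[i, 2], tl[j, 1] + dims[j, 2]) -
      max(tl[i, 1], tl[j, 1])
    oy <- min(tl[i, 2] + dims[i, 1], tl[j, 2] + dims[j, 1]) -
      max(tl[i, 2], tl[j, 2])
    ox > 16 && oy > 16
  }
  visited <- c(1L); queue <- c(1L)
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    for (j in setdiff(seq_len(n), visited))
      if (overlaps(cur, j)) { visited <- c(visited, j); queue <- c(queue, j) }
  }
  c(visited, setdiff(seq_len(n), visited))
}

# NCC-refine tile i against the first placed tile it overlaps.
# Returns a length-2 (dx, dy) adjustment in px, or NULL.
refine_tile <- function(images, tl, dims, i, placed, search_px) {
  for (j in placed) {
    ox0 <- max(tl[i, 1], tl[j, 1])
    ox1 <- min(tl[i, 1] + dims[i, 2] - 1, tl[j, 1] + dims[j, 2] - 1)
    oy0 <- max(tl[i, 2], tl[j, 2])
    oy1 <- min(tl[i, 2] + dims[i, 1] - 1, tl[j, 2] + dims[j, 1] - 1)
    if (ox1 - ox0 < 24 || oy1 - oy0 < 24) next
    # template: tile i's overlap interior, trimmed by the search radius
    tx0 <- ceiling(ox0 - tl[i, 1] + 1) + search_px
    tx1 <- floor(ox1 - tl[i, 1] + 1) - search_px
    ty0 <- ceiling(oy0 - tl[i, 2] + 1) + search_px
    ty1 <- floor(oy1 - tl[i, 2] + 1) - search_px
    if (tx1 - tx0 < 8 || ty1 - ty0 < 8) next
    tpl <- images[[i]][ty0:ty1, tx0:tx1, drop = FALSE]
    # region: same area in tile j, expanded by the search radius
    jx0 <- clampi(round(tl[i, 1] + tx0 - 1 - tl[j, 1] + 1) - search_px,
                  1, dims[j, 2])
    jy0 <- clampi(round(tl[i, 2] + ty0 - 1 - tl[j, 2] + 1) - search_px,
                  1, dims[j, 1])
    jx1 <- clampi(jx0 + ncol(tpl) + 2 * search_px - 1, 1, dims[j, 2])
    jy1 <- clampi(jy0 + nrow(tpl) + 2 * search_px - 1, 1, dims[j, 1])
    if (jx1 - jx0 + 1 < ncol(tpl) || jy1 - jy0 + 1 < nrow(tpl)) next
    region <- images[[j]][jy0:jy1, jx0:jx1, drop = FALSE]
    surf <- normxcorr(tpl, region)
    pk <- peak_subpixel(surf)
    if (!is.finite(pk$value) || pk$value < 0.5 || isTRUE(pk$on_border)) next
    # position of the template in the common frame implied by the match
    match_x <- tl[j, 1] + (jx0 - 1) + (pk$col - 1)
    match_y <- tl[j, 2] + (jy0 - 1) + (pk$row - 1)
    cur_x <- tl[i, 1] + tx0 - 1
    cur_y <- tl[i, 2] + ty0 - 1
    return(c(match_x - cur_x, match_y - cur_y))
  }
  NULL
}

#' Create a retinal map
#'
#' A retinal map holds one layer per modality: the image, its pixel
#' scale and a `transform2d` from image pixels into the common
#' micrometre frame. The foveal centre (set with
#' [set_foveal_center()]) anchors eccentricity queries.
#'
#' @param eye `"OD"` (right) or `"OS"` (left).
#' @param rmf RMF in mm/deg.
#' @param flipped Logical: images were horizontally flipped at import so
#'   that +x is temporal for both eyes. When `FALSE` (default), standard
#'   fundus orientation is assumed and nasal/temporal labelling follows
#'   the eye's laterality.
#' @return An object of class `retinal_map`.
#' @export
retinal_map <- function(eye = c("OD", "OS"), rmf, flipped = FALSE) {
  eye <- match.arg(eye)
  stopifnot(is_number(rmf), rmf > 0)
  structure(list(layers = list(), foveal_center = NULL, eye = eye,
                 rmf = rmf, flipped = flipped),
            class = "retinal_map")
}

#' Add a modality layer to a retinal map
#'
#' @param map A `retinal_map`.
#' @param name Layer name (e.g. `"aoslo"`, `"oct_enface"`, `"faf"`).
#' @param image Image matrix.
#' @param scale `modality_scale` for the image.
#' @param tf `transform2d` mapping image px (x, y) to common-frame um.
#' @return The updated map.
#' @export
map_add_layer <- function(map, name, image, scale, tf) {
  stopifnot(inherits(map, "retinal_map"), inherits(tf, "transform2d"))
  if (any(!is.finite(tf$matrix)))
    stop("layer transform must be finite", call. = FALSE)
  map$layers[[name]] <- list(image = image, scale = scale, tf = tf)
  map
}

#' Mark the anatomical foveal centre
#'
#' The foveal centre is identified on one layer (clinically: marked on
#' the OCT scan) and stored in the common micrometre frame, from which
#' its location in every other layer follows through the layer
#' transforms.
#'
#' @param map A `retinal_map`.
#' @param point Length-2 `(x, y)` pixel position on `layer`.
#' @param layer Name of the layer the point was marked on.
#' @return The updated map.
#' @export
set_foveal_center <- function(map, point, layer) {
  stopifnot(inherits(map, "retinal_map"))
  ly <- map$layers[[layer]]
  if (is.null(ly)) stop(sprintf("layer '%s' not present", layer),
                        call. = FALSE)
  img <- ly$image
  if (!is.null(img) &&
      (point[1] < 1 || point[1] > ncol(img) ||
       point[2] < 1 || point[2] > nrow(img)))
    stop("foveal point lies outside the layer image", call. = FALSE)
  map$foveal_center <- as.numeric(tf_apply(ly$tf, point))
  map
}

#' Project a common-frame point into a layer
#'
#' @param map A `retinal_map`.
#' @param point_um Length-2 common-frame point, um.
#' @param layer Layer name.
#' @return Length-2 `(x, y)` pixel position in the layer (possibly
#'   outside the image; an attribute `inside` says whether it falls
#'   within the image bounds).
#' @export
map_project <- function(map, point_um, layer) {
  ly <- map$layers[[layer]]
  if (is.null(ly)) stop(sprintf("layer '%s' not present", layer),
                        call. = FALSE)
  p <- as.numeric(tf_apply(tf_invert(ly$tf), point_um))
  img <- ly$image
  inside <- is.null(img) ||
    (p[1] >= 1 && p[1] <= ncol(img) && p[2] >= 1 && p[2] <= nrow(img))
  attr(p, "inside") <- inside
  p
}

#' Eccentricity of a common-frame point
#'
#' Distance from the foveal centre in mm and degrees (through the RMF),
#' with a meridian label assigned by 90-degree angular sector. In
#' standard fundus orientation the horizontal labels depend on
#' laterality (for a right eye +x is nasal, for a left eye temporal);
#' if the map was imported with `flipped = TRUE`, +x is temporal for
#' both eyes. +y (image down) is labelled inferior.
#'
#' @param map A `retinal_map` with the foveal centre set.
#' @param point_um Length-2 common-frame point, um.
#' @return List with `mm`, `degrees`, `meridian`.
#' @export
eccentricity_of <- function(map, point_um) {
  stopifnot(inherits(map, "retinal_map"))
  if (is.null(map$foveal_center))
    stop("foveal centre not set; call set_foveal_center() first",
         call. = FALSE)
  d <- as.numeric(point_um) - map$foveal_center
  mm <- sqrt(sum(d^2)) / 1000
  deg <- mm / map$rmf
  ang <- atan2(d[2], d[1])             # y down
  xpos_label <- if (map$flipped) "temporal"
                else if (map$eye == "OD") "nasal" else "temporal"
  xneg_label <- if (xpos_label == "nasal") "temporal" else "nasal"
  meridian <- if (mm == 0) "none"
    else if (abs(ang) <= pi / 4) xpos_label
    else if (abs(ang) >= 3 * pi / 4) xneg_label
    else if (ang > 0) "inferior" else "superior"
  list(mm = mm, degrees = deg, meridian = meridian)
}

#' @export
print.retinal_map <- function(x, ...) {
  cat(sprintf("Retinal map (%s, RMF %.4f mm/deg): %d layer(s)\n",
              x$eye, x$rmf, length(x$layers)))
  for (nm in names(x$layers)) cat("  -", nm, "\n")
  if (!is.null(x$foveal_center))
    cat(sprintf("  fovea at (%.1f, %.1f) um\n", x$foveal_center[1],
                x$foveal_center[2]))
  invisible(x)
}
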