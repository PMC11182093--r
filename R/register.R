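# Strip-based registration of AOSLO video frames: rank frames by
# whole-frame normalised cross correlation against a manually selected
# reference, estimate per-strip translations by NCC peak with sub-pixel
# refinement, and average the best frames to improve SNR.

#' Construct a frame stack
#'
#' @param frames List of equal-size image matrices.
#' @param modality Modality label.
#' @param scale Optional `modality_scale`.
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, modality = "aoslo_confocal", scale = NULL) {
  if (!length(frames)) stop("frame stack must contain at least one frame",
                            call. = FALSE)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must have the same dimensions", call. = FALSE)
  structure(list(frames = frames, frame_count = length(frames),
                 modality = modality, scale = scale),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("Frame stack: %d frames of %d x %d (%s)\n",
              x$frame_count, d[1], d[2], x$modality))
  invisible(x)
}

#' Rank frames by normalised cross correlation against a reference
#'
#' Whole-frame zero-mean NCC of every frame against a chosen reference
#' frame, returned in descending order. The reference scores exactly 1.
#' Constant-intensity frames have undefined NCC; they are assigned
#' `-Inf` and flagged.
#'
#' @param stack A [frame_stack()] (or plain list of matrices).
#' @param reference_index Index of the reference frame.
#' @return A data.frame with columns `index`, `score`, `degenerate`,
#'   sorted by decreasing score.
#' @export
rank_frames_by_ncc <- function(stack, reference_index = 1) {
  frames <- if (inherits(stack, "frame_stack")) stack$frames else stack
  n <- length(frames)
  if (reference_index < 1 || reference_index > n)
    stop("reference_index out of range", call. = FALSE)
  ref <- frames[[reference_index]]
  score <- vapply(frames, function(f) {
    s <- ncc_scalar(f, ref)
    if (is.na(s)) -Inf else s
  }, numeric(1))
  score[reference_index] <- 1
  out <- data.frame(index = seq_len(n), score = score,
                    degenerate = !is.finite(score))
  out[order(-out$score, out$index), , drop = FALSE]
}

#' Register one frame to a reference by horizontal strips
#'
#' The frame is divided into horizontal strips (50% overlap by default);
#' each strip's translation relative to the reference is estimated as
#' the peak of its normalised cross-correlation surface over a bounded
#' search, refined to sub-pixel precision by parabolic interpolation.
#' Strips whose peak NCC falls below `ncc_threshold` are rejected
#' (blink / tear-film dropout handling).
#'
#' Offsets follow the generator convention: a returned `(dx, dy)` means
#' the strip content equals the reference translated by `+dx` columns
#' and `+dy` rows, so aligning the strip onto the reference requires
#' shifting it by `(-dx, -dy)`.
#'
#' @param frame,reference Equal-size image matrices.
#' @param strip_height Strip height in px (>= 8).
#' @param search_radius Maximum |offset| searched, px.
#' @param overlap Fractional strip overlap in `[0, 0.9]`.
#' @param ncc_threshold Minimum accepted peak NCC.
#' @return An object of class `strip_offsets`: data.frame `strips` with
#'   `row_start`, `row_end`, `dx`, `dy`, `ncc`, `accepted`, plus the
#'   parameters. A frame whose strips are all rejected is flagged
#'   `usable = FALSE`.
#' @export
strip_register <- function(frame, reference, strip_height = 32,
                           search_radius = 12, overlap = 0.5,
                           ncc_threshold = 0.5) {
  if (!all(dim(frame) == dim(reference)))
    stop("frame and reference must have identical dimensions", call. = FALSE)
  if (strip_height < 8) stop("strip_height must be >= 8 px", call. = FALSE)
  H <- nrow(frame); W <- ncol(frame)
  sr <- as.integer(search_radius)
  if (W - 2 * sr < 8) stop("search radius too large for image width",
                           call. = FALSE)
  step <- max(1L, as.integer(round(strip_height * (1 - overlap))))
  # strips live in the interior margin: trimmed by the search radius on
  # every side so that any true displacement within the radius has its
  # full support inside the reference
  starts <- seq(1L + sr, max(1L + sr, H - sr - strip_height + 1L),
                by = step)
  res <- lapply(starts, function(r0) {
    r1 <- min(H - sr, r0 + strip_height - 1L)
    tpl <- frame[r0:r1, (1 + sr):(W - sr), drop = FALSE]
    rr0 <- max(1L, r0 - sr); rr1 <- min(H, r1 + sr)
    region <- reference[rr0:rr1, , drop = FALSE]
    surf <- normxcorr(tpl, region)
    pk <- peak_subpixel(surf)
    if (!is.finite(pk$value))
      return(data.frame(row_start = r0, row_end = r1, dx = NA_real_,
                        dy = NA_real_, ncc = -Inf, accepted = FALSE))
    # surf[i, j]: template placed at region rows (rr0+i-1), cols j.
    # frame = ref shifted by (dx, dy) => template matches ref at
    # rows r0 - dy, cols (1+sr) - dx.
    dy <- r0 - (rr0 + pk$row - 1)
    dx <- (1 + sr) - pk$col
    # peak prominence: a genuine alignment stands clearly above the rest
    # of the correlation surface, whereas a strip whose true match lies
    # outside the searched area produces several comparable random peaks
    ir <- round(pk$row); ic <- round(pk$col)
    masked <- surf
    masked[max(1, ir - 2):min(nrow(surf), ir + 2),
           max(1, ic - 2):min(ncol(surf), ic + 2)] <- NA
    secondary <- suppressWarnings(max(masked, na.rm = TRUE))
    prominent <- !is.finite(secondary) || pk$value - secondary >= 0.1
    # a peak on the border of the search surface cannot be trusted either
    acc <- is.finite(pk$value) && pk$value >= ncc_threshold &&
      prominent && !isTRUE(pk$on_border) && abs(dx) <= sr && abs(dy) <= sr
    data.frame(row_start = r0, row_end = r1, dx = dx, dy = dy,
               ncc = pk$value, accepted = acc)
  })
  strips <- do.call(rbind, res)
  structure(list(strips = strips, strip_height = strip_height,
                 search_radius = sr, ncc_threshold = ncc_threshold,
                 usable = any(strips$accepted)),
            class = "strip_offsets")
}

#' @export
print.strip_offsets <- function(x, ...) {
  cat(sprintf("Strip offsets: %d strips, %d accepted (threshold %.2f)%s\n",
              nrow(x$strips), sum(x$strips$accepted), x$ncc_threshold,
              if (x$usable) "" else " [frame unusable]"))
  invisible(x)
}

#' Average registered frames
#'
#' Shifts every accepted strip of the selected frames by the negative of
#' its estimated offset (bilinear interpolation for sub-pixel offsets;
#' direct copy for integer ones) and accumulates a per-pixel mean over
#' all contributing frames, together with a coverage map counting
#' contributions. Pixels never covered are `NA`.
#'
#' @param stack A [frame_stack()] or list of matrices.
#' @param offsets List of [strip_register()] results, one per frame in
#'   `stack` (entries may be `NULL` for frames not considered).
#' @param top_n Number of frames to average. If `ranking` is given, the
#'   `top_n` highest-ranked usable frames are used; otherwise the first
#'   `top_n` usable frames.
#' @param ranking Optional result of [rank_frames_by_ncc()].
#' @return List with `average` (matrix, `NA` where uncovered),
#'   `coverage` (integer matrix) and `frames_used` (indices).
#' @export
average_registered <- function(stack, offsets, top_n = 50, ranking = NULL) {
  frames <- if (inherits(stack, "frame_stack")) stack$frames else stack
  if (top_n < 1) stop("top_n must be >= 1", call. = FALSE)
  if (top_n > length(frames))
    stop("top_n exceeds the number of frames", call. = FALSE)
  usable <- vapply(seq_along(frames), function(i) {
    o <- offsets[[i]]
    !is.null(o) && isTRUE(o$usable)
  }, logical(1))
  cand <- if (!is.null(ranking)) ranking$index[ranking$index %in%
                                                 which(usable)]
          else which(usable)
  if (!length(cand)) stop("no usable frames to average", call. = FALSE)
  use <- cand[seq_len(min(top_n, length(cand)))]
  H <- nrow(frames[[1]]); W <- ncol(frames[[1]])
  acc <- matrix(0, H, W); cov <- matrix(0L, H, W)
  cols <- seq_len(W)
  for (i in use) {
    fr <- frames[[i]]
    st <- offsets[[i]]$strips
    for (k in seq_len(nrow(st))) {
      if (!st$accepted[k]) next
      r0 <- st$row_start[k]; r1 <- st$row_end[k]
      dx <- st$dx[k]; dy <- st$dy[k]
      rows <- r0:r1
      if (dx == round(dx) && dy == round(dy)) {
        src_r <- rows + as.integer(round(dy))
        src_c <- cols + as.integer(round(dx))
        vr <- src_r >= 1 & src_r <= H
        vc <- src_c >= 1 & src_c <= W
        if (!any(vr) || !any(vc)) next
        acc[rows[vr], cols[vc]] <- acc[rows[vr], cols[vc]] +
          fr[src_r[vr], src_c[vc], drop = FALSE]
        cov[rows[vr], cols[vc]] <- cov[rows[vr], cols[vc]] + 1L
      } else {
        for (r in rows) {
          v <- bilinear_sample(fr, rep(r + dy, W), cols + dx)
          ok <- !is.na(v)
          acc[r, ok] <- acc[r, ok] + v[ok]
          cov[r, ok] <- cov[r, ok] + 1L
        }
      }
    }
  }
  avg <- acc / cov
  avg[cov == 0L] <- NA_real_
  list(average = avg, coverage = cov, frames_used = use)
}

#' Register and average an AOSLO frame stack
#'
#' Convenience wrapper: rank frames against the reference, strip-register
#' the `top_n` best, and average them.
#'
#' @inheritParams rank_frames_by_ncc
#' @inheritParams strip_register
#' @inheritParams average_registered
#' @return As [average_registered()], plus `ranking` and `offsets`.
#' @export
register_stack <- function(stack, reference_index = 1, top_n = 50,
                           strip_height = 32, search_radius = 12,
                           overlap = 0.5, ncc_threshold = 0.5) {
  frames <- if (inherits(stack, "frame_stack")) stack$frames else stack
  rk <- rank_frames_by_ncc(stack, reference_index)
  top_n <- min(top_n, length(frames))
  sel <- rk$index[!rk$degenerate][seq_len(top_n)]
  ref <- frames[[reference_index]]
  offsets <- vector("list", length(frames))
  for (i in sel)
    offsets[[i]] <- strip_register(frames[[i]], ref, strip_height,
                                   search_radius, overlap, ncc_threshold)
  out <- average_registered(stack, offsets, top_n = top_n, ranking = rk)
  out$ranking <- rk
  out$offsets <- offsets
  out
}
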