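# Interchange formats and pipeline orchestration: TIFF/PNG image IO with
# range metadata, JSON serialisation of transforms and scales, a session
# manifest, a packaged end-to-end phantom session, and the `run_pipeline`
# driver with line-delimited JSON provenance logging.

#' Load a grayscale image (TIFF or PNG)
#'
#' Images are held internally as numeric matrices in `[0, 1]`. RGB(A)
#' input is collapsed to grayscale by channel averaging. Multi-page TIFF
#' returns a list of matrices. The source bit depth is kept in the
#' `bits` attribute so that save/load round-trips preserve pixel values.
#'
#' @param path File path (`.tif`, `.tiff` or `.png`).
#' @return Matrix (or list of matrices for multi-page TIFF) with
#'   attribute `bits`.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  to_gray <- function(a) {
    if (length(dim(a)) == 3) a <- apply(a[, , 1:min(3, dim(a)[3]),
                                          drop = FALSE], c(1, 2), mean)
    a
  }
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    bits <- attr(pages[[1]], "bits.per.sample") %||% 16L
    out <- lapply(pages, to_gray)
    if (length(out) == 1) out <- out[[1]]
    attr(out, "bits") <- as.integer(bits)
    out
  } else if (ext == "png") {
    a <- to_gray(png::readPNG(path))
    attr(a, "bits") <- 8L
    a
  } else {
    stop("unsupported image format: .", ext, " (use TIFF or PNG)",
         call. = FALSE)
  }
}

#' Save a grayscale image (TIFF or PNG)
#'
#' @param image Matrix in `[0, 1]`, or a list of matrices (multi-page
#'   TIFF). Values are clipped to `[0, 1]` on write.
#' @param path Output path; format follows the extension.
#' @param bits Bits per sample for TIFF (8 or 16).
#' @return `path`, invisibly.
#' @export
save_image <- function(image, path, bits = 16L) {
  ext <- tolower(tools::file_ext(path))
  clip <- function(m) pmin(pmax(m, 0), 1)
  if (ext %in% c("tif", "tiff")) {
    if (is.list(image)) tiff::writeTIFF(lapply(image, clip), path,
                                        bits.per.sample = bits)
    else tiff::writeTIFF(clip(image), path, bits.per.sample = bits)
  } else if (ext == "png") {
    if (is.list(image)) stop("PNG cannot hold multiple pages", call. = FALSE)
    png::writePNG(clip(image), path)
  } else {
    stop("unsupported image format: .", ext, call. = FALSE)
  }
  invisible(path)
}

#' Serialise a transform (or modality scale) to JSON
#'
#' Transforms are written with an explicit statement of the pixel
#' convention (0-based, pixel-centre, x right / y down); the in-memory
#' representation is 1-based, so the translation column is adjusted on
#' write and read.
#'
#' @param tf A `transform2d`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_transform_json <- function(tf, path) {
  m <- tf$matrix
  # 0-based input point p0 = p1 - 1, so the serialized translation column
  # is t0 = t1 + L %*% (1, 1)
  t0 <- as.numeric(m[, 3] + m[, 1:2] %*% c(1, 1))
  obj <- list(kind = tf$kind, residual_rms = tf$residual_rms,
              linear = list(a11 = m[1, 1], a12 = m[1, 2],
                            a21 = m[2, 1], a22 = m[2, 2]),
              translation = list(tx = t0[1], ty = t0[2]),
              convention = "0-based pixel centres, x right, y down")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  L <- matrix(c(obj$linear$a11, obj$linear$a21,
                obj$linear$a12, obj$linear$a22), 2, 2)
  t0 <- c(obj$translation$tx, obj$translation$ty)
  t1 <- t0 - as.numeric(L %*% c(1, 1))
  transform2d(cbind(L, t1), kind = obj$kind,
              residual_rms = obj$residual_rms %||% 0)
}

# Append one line-delimited JSON record to the processing log.
log_event <- function(log_path, stage, params = list()) {
  rec <- c(list(stage = stage, time = format(Sys.time(), tz = "UTC")),
           params)
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
      file = log_path, append = TRUE, sep = "")
  invisible(NULL)
}

fmt3 <- function(x) sprintf("%.3f", x)

#' Build the packaged phantom session
#'
#' Generates a complete synthetic imaging session on disk with known
#' ground truth: a distorted Ronchi ruling, two overlapping AOSLO
#' confocal video stacks (fixation 0 and 1 degree nasal) rendered from
#' one cone mosaic containing a seeded dark-cone fraction, the matching
#' split-detection tile, a layered OCT volume, a normative table and a
#' YAML manifest tying them together. Every file is reproducible from
#' the seed.
#'
#' @param dir Session directory (created if needed).
#' @param seed Master seed.
#' @param n_frames Frames per AOSLO stack.
#' @param density_mm2 Cone density of the phantom mosaic.
#' @param dark_fraction Dark-cone fraction of the mosaic.
#' @return The manifest (also written to `manifest.yaml`), invisibly.
#' @export
build_phantom_session <- function(dir, seed = 1, n_frames = 24,
                                  density_mm2 = 12000,
                                  dark_fraction = 0.15) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  al <- 24.2
  sm <- compute_rmf(biometry(al), model = "four_surface")
  fov <- 1.75; npx <- 512
  mpp <- sm$rmf * 1000 * fov / npx
  # one mosaic field covering both tiles (plus registration margins)
  step_um <- sm$rmf * 1000                    # 1 degree fixation step
  field <- c(npx * mpp + step_um + 80, npx * mpp + 80)
  mo <- gen_mosaic(field_um = field, density = density_mm2,
                   jitter_fraction = 0.10, dark_cone_fraction = dark_fraction,
                   seed = fork_seed(seed, "session_mosaic"))
  rc <- render_channels(mo, um_per_px = mpp, psf_sigma_um = 1.6, snr = Inf,
                        seed = seed)
  # ruling calibration image
  ru <- gen_ruling(width = npx, height = 64, n_lines = 16,
                   distortion = 0.8, noise_sd = 0.01,
                   seed = fork_seed(seed, "session_ruling"))
  save_image(ru$image, file.path(dir, "ruling.tif"))
  # two confocal stacks; tile centres 1 degree apart horizontally
  px_step <- step_um / mpp
  H <- nrow(rc$confocal); W <- ncol(rc$confocal)
  r0 <- floor((H - npx) / 2)
  tile_cols <- list(tile1 = 0L, tile2 = as.integer(round(px_step)))
  for (tn in names(tile_cols)) {
    c0 <- 20L + tile_cols[[tn]]
    base <- rc$confocal[(r0 - 11):(r0 + npx + 12),
                        (c0 - 11):(c0 + npx + 12)]
    gf <- gen_frames(base, n_frames = n_frames, amplitude_px = 3,
                     dy_amplitude_px = 1.5, noise_sd = 0.05,
                     seed = fork_seed(seed, paste0("session_", tn)))
    save_image(gf$frames, file.path(dir, paste0(tn, "_stack.tif")))
    if (tn == "tile1") {
      # split tile cut to coincide pixel-for-pixel with the stack's
      # registration reference (the central crop of `base`)
      m <- (nrow(base) - nrow(gf$reference)) / 2
      split_tile <- rc$split[(r0 - 11 + m) + seq_len(nrow(gf$reference)) - 1,
                             (c0 - 11 + m) + seq_len(ncol(gf$reference)) - 1]
      save_image(split_tile, file.path(dir, "tile1_split.tif"))
    }
  }
  # OCT volume: gently curved boundaries, fovea at a known A-scan
  n_asc <- 512; n_b <- 9
  bnd <- list(
    ilm = function(a) 96 + 4 * sin(2 * pi * a / 480),
    opl = function(a) 148 + 3 * sin(2 * pi * a / 420 + 1),
    ez = function(a) 168 + 2 * sin(2 * pi * a / 530 + 2),
    rpe = function(a) 187 + 2 * sin(2 * pi * a / 610 + 0.5))
  oc <- gen_oct(n_ascans = n_asc, n_bscans = n_b, boundaries = bnd,
                n_rows = 256, speckle_snr = 6,
                seed = fork_seed(seed, "session_oct"))
  save_image(oc$volume$bscans, file.path(dir, "oct_volume.tif"))
  jsonlite::write_json(list(axial_um_per_px = 3.5, lateral_um_per_px = 14,
                            bscan_spacing_um = 120),
                       file.path(dir, "oct_volume.json"), auto_unbox = TRUE)
  # normative table
  nt <- gen_normative(seed = fork_seed(seed, "session_norm"))
  write_normative_table(nt, file.path(dir, "normative.csv"))
  # landmarks between the OCT en-face grid and the AOSLO common frame:
  # the phantom fovea sits at common-frame (0, 0), OCT A-scan 160 /
  # B-scan 5, with the nasal direction along +x (right eye)
  fovea_ascan <- 160; fovea_bscan <- 5
  lm_ascan <- c(60, 260, 420, 130, 350)
  lm_bscan <- c(2, 3, 5, 7, 8)
  lm <- data.frame(
    modality_a = "oct_enface", x_a = lm_ascan, y_a = lm_bscan,
    modality_b = "common_um",
    x_b = (lm_ascan - fovea_ascan) * 14,
    y_b = (lm_bscan - fovea_bscan) * 120,
    label = paste0("vessel_", seq_along(lm_ascan)))
  utils::write.csv(lm, file.path(dir, "landmarks.csv"), row.names = FALSE)
  manifest <- list(
    subject = "phantom01", eye = "OD", seed = seed,
    biometry = list(axial_length_mm = al),
    aoslo = list(fov_deg = fov, pixels = npx, n_frames = n_frames,
                 stacks = list(
                   tile1 = list(file = "tile1_stack.tif",
                                fixation_deg = c(0, 0)),
                   tile2 = list(file = "tile2_stack.tif",
                                fixation_deg = c(1, 0))),
                 split_tile = "tile1_split.tif",
                 expected_spacing_um = mo$spacing_um,
                 dark_fraction = dark_fraction),
    ruling = list(file = "ruling.tif"),
    oct = list(file = "oct_volume.tif", sidecar = "oct_volume.json",
               fovea_ascan = fovea_ascan, fovea_bscan = fovea_bscan),
    normative = "normative.csv",
    landmarks = "landmarks.csv")
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(manifest)
}

#' Run the full analysis pipeline on a session
#'
#' Orchestrates every stage on a session directory produced by
#' [build_phantom_session()] (or hand-assembled to the same manifest
#' schema): retinal-magnification scaling, desinusoid calibration, strip
#' registration and averaging of each AOSLO stack, montaging, multimodal
#' alignment from the landmark file, foveal-centre anchoring, OCT layer
#' segmentation with nasal thickness extraction, ROI cone metrics,
#' dark-cone discordance and normative z-scores. Results are written as
#' CSV (micrometre coordinates fixed to three decimals for diff-stable
#' output) and every stage is logged as line-delimited JSON.
#'
#' @param session_dir Directory containing `manifest.yaml`.
#' @param out_dir Output directory (default `file.path(session_dir,
#'   "results")`).
#' @param top_n Frames averaged per stack.
#' @param roi_centers_mm ROI centres along the nasal meridian, mm.
#' @param roi_size_um ROI side length, um.
#' @return List with the metric, z-score and thickness data.frames and
#'   the `retinal_map`, invisibly.
#' @export
run_pipeline <- function(session_dir, out_dir = file.path(session_dir,
                                                          "results"),
                         top_n = 12,
                         roi_centers_mm = c(0.30, 0.45),
                         roi_size_um = 100) {
  mf_path <- file.path(session_dir, "manifest.yaml")
  if (!file.exists(mf_path))
    stop("manifest.yaml not found in ", session_dir, call. = FALSE)
  mf <- yaml::read_yaml(mf_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline_log.jsonl")
  if (file.exists(log_path)) unlink(log_path)
  stage <- function(name, code) {
    log_event(log_path, name)
    tryCatch(code, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  ## scale
  sm <- NULL; mpp <- NULL; scale <- NULL
  stage("scale", {
    sm <- compute_rmf(biometry(mf$biometry$axial_length_mm),
                       model = "four_surface")
    scale <- microns_per_pixel(sm, mf$aoslo$fov_deg, mf$aoslo$pixels)
    mpp <- scale$microns_per_pixel_x
    log_event(log_path, "scale.result",
              list(rmf_mm_per_deg = sm$rmf, um_per_px = mpp))
  })
  ## desinusoid calibration
  lut <- NULL
  stage("desinusoid", {
    ruling <- load_image(file.path(session_dir, mf$ruling$file))
    lut <- fit_desinusoid(ruling)
    log_event(log_path, "desinusoid.result",
              list(residual_px = lut$residual_px, n_lines = lut$n_lines))
  })
  ## registration of each stack
  tiles <- list(); fixations <- NULL
  stage("register", {
    for (tn in names(mf$aoslo$stacks)) {
      st <- mf$aoslo$stacks[[tn]]
      frames <- load_image(file.path(session_dir, st$file))
      if (!is.list(frames)) frames <- list(frames)
      reg <- register_stack(frames, reference_index = 1, top_n = top_n,
                            strip_height = 32, search_radius = 8)
      avg <- reg$average
      avg[is.na(avg)] <- stats::median(avg, na.rm = TRUE)
      tiles[[tn]] <- avg
      fixations <- rbind(fixations, unlist(st$fixation_deg))
      utils::write.csv(
        data.frame(frame = rep(reg$frames_used,
                               each = nrow(reg$offsets[[reg$frames_used[1]]]$strips)),
                   do.call(rbind, lapply(reg$offsets[reg$frames_used],
                                         function(o) o$strips))),
        file.path(out_dir, paste0(tn, "_offsets.csv")), row.names = FALSE)
    }
  })
  ## montage
  mont <- NULL
  stage("montage", {
    mont <- montage_place(tiles, fixations, scale, sm$rmf, refine = TRUE,
                           search_px = 10)
    canvas <- mont$canvas
    canvas[is.na(canvas)] <- 0
    save_image(canvas, file.path(out_dir, "montage.tif"))
    pl <- mont$placements
    pl$x_um <- fmt3(pl$x_um); pl$y_um <- fmt3(pl$y_um)
    utils::write.csv(pl, file.path(out_dir, "placements.csv"),
                     row.names = FALSE)
  })
  ## multimodal alignment + map + fovea
  map <- NULL; oct_seg <- NULL; oct_vol <- NULL
  stage("align", {
    map <- retinal_map(eye = mf$eye, rmf = sm$rmf)
    map <- map_add_layer(map, "aoslo", mont$canvas, scale, mont$tf)
    side <- jsonlite::read_json(file.path(session_dir, mf$oct$sidecar),
                                simplifyVector = TRUE)
    bs <- load_image(file.path(session_dir, mf$oct$file))
    if (!is.list(bs)) bs <- list(bs)
    oct_vol <- oct_volume(bs, side$axial_um_per_px, side$lateral_um_per_px,
                           side$bscan_spacing_um)
    lm <- utils::read.csv(file.path(session_dir, mf$landmarks))
    # en-face grid: x = A-scan, y = B-scan; scale to um, then similarity
    oct_scaled <- cbind(lm$x_a * side$lateral_um_per_px,
                        lm$y_a * side$bscan_spacing_um)
    tf_oct <- estimate_transform(oct_scaled, cbind(lm$x_b, lm$y_b),
                                 kind = "similarity")
    pre <- transform2d(cbind(diag(c(side$lateral_um_per_px,
                                    side$bscan_spacing_um)), c(0, 0)),
                       kind = "affine")
    enface <- vapply(bs, function(b) colMeans(b), numeric(ncol(bs[[1]])))
    map <- map_add_layer(map, "oct_enface", t(enface),
                          modality_scale(side$lateral_um_per_px,
                                         side$bscan_spacing_um, "oct_enface"),
                          tf_compose(tf_oct, pre))
    map <- set_foveal_center(map, c(mf$oct$fovea_ascan, mf$oct$fovea_bscan),
                              "oct_enface")
    log_event(log_path, "align.result",
              list(fovea_um = as.numeric(map$foveal_center),
                   oct_residual_rms = tf_oct$residual_rms))
  })
  ## OCT segmentation and nasal thickness
  thick <- NULL
  stage("oct", {
    oct_seg <- segment_layers(oct_vol)
    prof <- thickness_profile(oct_seg)
    thick <- extract_thickness_at(prof, fovea_ascan = mf$oct$fovea_ascan,
                                   offsets_mm = c(2.5, 3.0, 3.5),
                                   window = 10, bscan = mf$oct$fovea_bscan,
                                   nasal_direction = +1)
    utils::write.csv(data.frame(thick, row.names = NULL),
                     file.path(out_dir, "thickness.csv"), row.names = FALSE)
  })
  ## ROI cone metrics on the montage
  metrics <- NULL
  stage("mosaic", {
    canvas <- mont$canvas
    canvas[is.na(canvas)] <- stats::median(canvas, na.rm = TRUE)
    cm <- detect_cells(canvas, "cone", mf$aoslo$expected_spacing_um,
                       scale, tf = mont$tf)
    rows <- lapply(roi_centers_mm, function(ecc) {
      # nasal = +x for a right eye in unflipped fundus orientation
      ctr_um <- map$foveal_center + c(ecc * 1000, 0)
      r <- roi(ctr_um, roi_size_um)
      vm <- voronoi_metrics(cm, r)
      ec <- eccentricity_of(map, ctr_um)
      data.frame(roi_x_um = fmt3(ctr_um[1]), roi_y_um = fmt3(ctr_um[2]),
                 ecc_mm = ec$mm, meridian = ec$meridian,
                 n_marked = vm$n_marked, n_bounded = vm$n_bounded,
                 density_mm2 = vm$bounded_density_mm2,
                 mean_area_um2 = vm$mean_cell_area_um2,
                 mean_spacing_um = vm$mean_spacing_um,
                 low_quality = vm$low_quality)
    })
    metrics <- do.call(rbind, rows)
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
  })
  ## dark-cone discordance on tile 1
  dark <- NULL
  stage("darkcones", {
    split_img <- load_image(file.path(session_dir, mf$aoslo$split_tile))
    sp <- mf$aoslo$expected_spacing_um
    tl1 <- as.numeric(mont$placements[1, c("x_px", "y_px")])
    tf_tile1 <- transform2d(cbind(diag(c(mpp, mpp)), (tl1 - 1) * mpp),
                            kind = "similarity")
    # split-detection cells are signed edge pairs; the cell centre is the
    # zero crossing, i.e. the peak of the negated horizontal derivative
    W <- ncol(split_img)
    split_resp <- 0.5 - (split_img[, c(2:W, W)] -
                           split_img[, c(1, 1:(W - 1))]) / 2
    cm_split <- detect_cells(split_resp, "cone", sp, scale,
                             tf = tf_tile1)
    cm_conf <- detect_cells(tiles[[1]], "cone", sp, scale, tf = tf_tile1)
    ctr_um <- map$foveal_center + c(-0.1 * 1000, 0)
    r <- roi(ctr_um, 150, 150)
    dark <- dark_cone_discordance(cm_conf, cm_split, r,
                                   match_radius_um = 0.35 * sp)
    log_event(log_path, "darkcones.result", dark[1:5])
  })
  ## z-scores
  zs <- NULL
  stage("stats", {
    nt <- read_normative_table(file.path(session_dir, mf$normative))
    zrows <- list()
    for (i in seq_len(nrow(metrics))) {
      if (metrics$low_quality[i]) next
      zr <- zscore(metrics$density_mm2[i], nt, "cone_density",
                   metrics$ecc_mm[i], metrics$meridian[i],
                   tolerance_mm = 0.25)
      zrows[[length(zrows) + 1]] <-
        data.frame(measure = "cone_density", ecc_mm = metrics$ecc_mm[i],
                   meridian = metrics$meridian[i],
                   value = metrics$density_mm2[i], normal_mean = zr$normal_mean,
                   normal_sd = zr$normal_sd, z = zr$z, abnormal = zr$abnormal)
    }
    for (i in seq_len(nrow(thick))) {
      for (ms in c("rt", "orl")) {
        val <- thick[[paste0(ms, "_um")]][i]
        if (!is.finite(val)) next
        zr <- zscore(val, nt, ms, thick$offset_mm[i], "nasal",
                     tolerance_mm = 0.25)
        zrows[[length(zrows) + 1]] <-
          data.frame(measure = ms, ecc_mm = thick$offset_mm[i],
                     meridian = "nasal", value = val,
                     normal_mean = zr$normal_mean, normal_sd = zr$normal_sd,
                     z = zr$z, abnormal = zr$abnormal)
      }
    }
    zs <- do.call(rbind, zrows)
    utils::write.csv(zs, file.path(out_dir, "zscores.csv"),
                     row.names = FALSE)
  })
  log_event(log_path, "done")
  invisible(list(metrics = metrics, zscores = zs, thickness = thick,
                 dark_cones = dark, map = map, montage = mont))
}
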