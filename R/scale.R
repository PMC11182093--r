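#' Ocular biometry
#'
#' Bundle the biometric parameters needed to compute the retinal
#' magnification factor (RMF). Only the axial length is mandatory; any
#' missing anterior-segment parameter falls back to the Le Grand full
#' theoretical (four refracting surface) schematic eye, so a measurement
#' set as sparse as an IOL-Master axial length is sufficient.
#'
#' @param axial_length Axial length of the eye in mm (must lie in (15, 40)).
#' @param corneal_front_radius,corneal_back_radius Corneal radii of
#'   curvature in mm (positive = convex toward the incoming light).
#' @param anterior_chamber_depth Distance from the posterior cornea to the
#'   anterior lens surface, mm.
#' @param lens_front_radius,lens_back_radius Crystalline-lens radii, mm
#'   (the back radius is negative in the sign convention used here).
#' @param lens_thickness Lens thickness, mm.
#' @param corneal_thickness Central corneal thickness, mm.
#' @param refractive_indices Named numeric vector with entries
#'   `air`, `cornea`, `aqueous`, `lens`, `vitreous`.
#' @return An object of class `biometry`.
#' @examples
#' biometry(axial_length = 24.46)
#' @export
biometry <- function(axial_length,
                     corneal_front_radius = NULL,
                     corneal_back_radius = NULL,
                     anterior_chamber_depth = NULL,
                     lens_front_radius = NULL,
                     lens_back_radius = NULL,
                     lens_thickness = NULL,
                     corneal_thickness = NULL,
                     refractive_indices = NULL) {
  if (!is_number(axial_length))
    stop("axial_length must be a single finite number (mm)", call. = FALSE)
  if (axial_length <= 15 || axial_length >= 40)
    stop(sprintf("non-physical axial length %.3f mm (must lie in (15, 40))",
                 axial_length), call. = FALSE)
  d <- le_grand_eye()
  b <- list(
    axial_length = axial_length,
    corneal_front_radius = corneal_front_radius %||% d$corneal_front_radius,
    corneal_back_radius = corneal_back_radius %||% d$corneal_back_radius,
    anterior_chamber_depth = anterior_chamber_depth %||% d$anterior_chamber_depth,
    lens_front_radius = lens_front_radius %||% d$lens_front_radius,
    lens_back_radius = lens_back_radius %||% d$lens_back_radius,
    lens_thickness = lens_thickness %||% d$lens_thickness,
    corneal_thickness = corneal_thickness %||% d$corneal_thickness,
    refractive_indices = refractive_indices %||% d$refractive_indices
  )
  radii <- c(b$corneal_front_radius, b$corneal_back_radius,
             b$lens_front_radius, b$lens_back_radius)
  if (any(!is.finite(radii)) || any(radii == 0))
    stop("all surface radii must be finite and nonzero", call. = FALSE)
  ni <- b$refractive_indices
  need <- c("air", "cornea", "aqueous", "lens", "vitreous")
  if (!all(need %in% names(ni)))
    stop("refractive_indices must name: ", paste(need, collapse = ", "),
         call. = FALSE)
  structure(b, class = "biometry")
}

#' Le Grand full theoretical eye parameters
#'
#' The unaccommodated Le Grand schematic eye: four refracting surfaces
#' (anterior/posterior cornea, anterior/posterior lens) with the standard
#' radii, separations and refractive indices. Used as the default
#' parameter set whenever an individual biometric value is unavailable.
#'
#' @return A named list of surface radii (mm), separations (mm) and media
#'   refractive indices.
#' @export
le_grand_eye <- function() {
  list(
    corneal_front_radius = 7.80,
    corneal_back_radius = 6.50,
    lens_front_radius = 10.20,
    lens_back_radius = -6.00,
    corneal_thickness = 0.55,
    anterior_chamber_depth = 3.05,
    lens_thickness = 4.00,
    axial_length = 24.197,
    refractive_indices = c(air = 1.000, cornea = 1.3771, aqueous = 1.3374,
                           lens = 1.4200, vitreous = 1.3360)
  )
}

# Surface-by-surface paraxial trace of the 4-surface eye described by a
# biometry object. Traces a ray parallel to the axis (y = 1, nu = 0)
# through the surfaces using the scalar recurrences
#   refraction:  nu' = nu - y * P,   P = (n2 - n1) / R
#   transfer:    y'  = y + d * nu / n
# and returns the cardinal quantities needed for the RMF.
paraxial_eye_trace <- function(b, lens_power = 0, lens_distance = 0) {
  ni <- b$refractive_indices
  surf_R <- c(b$corneal_front_radius, b$corneal_back_radius,
              b$lens_front_radius, b$lens_back_radius)
  media <- c(ni[["air"]], ni[["cornea"]], ni[["aqueous"]], ni[["lens"]],
             ni[["vitreous"]])
  gaps <- c(b$corneal_thickness, b$anterior_chamber_depth, b$lens_thickness)
  y <- 1; nu <- 0
  if (lens_power != 0) {           # thin corrective lens in air, then a gap
    nu <- nu - y * lens_power / 1000   # diopters -> mm^-1
    y <- y + lens_distance * nu        # propagation in air (n = 1)
  }
  for (i in 1:4) {
    P <- (media[i + 1] - media[i]) / surf_R[i]
    nu <- nu - y * P
    if (i < 4) y <- y + gaps[i] * nu / media[i + 1]
  }
  n_img <- media[5]
  P_eq <- -nu                       # equivalent power in mm^-1 (y0 = 1)
  if (P_eq <= 0) stop("non-physical biometry: non-positive equivalent power",
                      call. = FALSE)
  z_last <- sum(gaps)               # posterior lens vertex from the cornea
  bfd <- -n_img * y / nu            # back focal distance from last vertex
  f_img <- n_img / P_eq             # image-space focal length
  z_principal <- z_last + bfd - f_img
  z_nodal <- z_principal + (n_img - media[1]) / P_eq
  list(power = P_eq, z_nodal = z_nodal, z_principal = z_principal,
       bfd = bfd, n_image = n_img)
}

#' Retinal magnification factor from ocular biometry
#'
#' Computes the retinal magnification factor (RMF), the length of retina
#' in mm subtended by one degree of visual angle, either from a paraxial
#' trace of a four-surface schematic eye individualised with the supplied
#' biometry (`model = "four_surface"`), or from Bennett's reduced-eye
#' closed form `0.01306 * (axial_length - 1.82)` (`model = "reduced"`).
#'
#' For the four-surface model the RMF is the posterior nodal distance
#' (axial length minus the second nodal point position) converted from
#' mm/radian to mm/degree.
#'
#' @param biometry A [biometry()] object (or a single axial length in mm).
#' @param model `"four_surface"` or `"reduced"`.
#' @return An object of class `scale_model` with fields `rmf` (mm/deg),
#'   `model_name`, and `lens_correction` (initially 1).
#' @examples
#' compute_rmf(biometry(24.46), model = "reduced")
#' @export
compute_rmf <- function(biometry, model = c("four_surface", "reduced")) {
  model <- match.arg(model)
  if (is.numeric(biometry)) biometry <- biometry(biometry)
  if (!inherits(biometry, "biometry"))
    stop("biometry must be a biometry object or an axial length in mm",
         call. = FALSE)
  al <- biometry$axial_length
  if (model == "reduced") {
    rmf <- 0.01306 * (al - 1.82)
  } else {
    tr <- paraxial_eye_trace(biometry)
    pnd <- al - tr$z_nodal           # posterior nodal distance, mm
    rmf <- pnd * pi / 180
  }
  if (!is.finite(rmf) || rmf <= 0)
    stop("non-physical biometry: computed RMF is not positive", call. = FALSE)
  structure(list(rmf = rmf, model_name = model, lens_correction = 1,
                 biometry = biometry),
            class = "scale_model")
}

#' @export
print.scale_model <- function(x, ...) {
  cat(sprintf("Retinal scale model (%s)\n", x$model_name))
  cat(sprintf("  RMF: %.5f mm/deg", x$rmf))
  if (x$lens_correction != 1)
    cat(sprintf("  (lens correction %.5f applied)", x$lens_correction))
  cat("\n")
  invisible(x)
}

#' Contact-lens correction of the retinal magnification factor
#'
#' When images are acquired through a corrective contact lens the lateral
#' magnification of the eye+lens system differs from that of the bare
#' eye. The correction is computed paraxially as the ratio of equivalent
#' powers, bare eye over eye-plus-lens, with the thin lens placed
#' `effective_distance` mm in front of the cornea (0 = lens on the
#' cornea). The corrected RMF replaces the bare-eye RMF downstream.
#'
#' @param scale A `scale_model` from [compute_rmf()].
#' @param lens_power Back-vertex power of the contact lens, diopters.
#' @param effective_distance Distance from lens to cornea, mm (>= 0).
#' @return The `scale_model` with `lens_correction` set and `rmf` scaled.
#' @examples
#' sm <- compute_rmf(biometry(24.0))
#' apply_contact_lens_correction(sm, lens_power = -5)
#' @export
apply_contact_lens_correction <- function(scale, lens_power,
                                          effective_distance = 0) {
  stopifnot(inherits(scale, "scale_model"))
  if (!is_number(lens_power))
    stop("lens_power must be a single finite number (D)", call. = FALSE)
  if (!is_number(effective_distance) || effective_distance < 0)
    stop("effective_distance must be >= 0 mm", call. = FALSE)
  if (lens_power == 0) {
    scale$lens_correction <- 1
    return(scale)
  }
  b <- scale$biometry %||% biometry(le_grand_eye()$axial_length)
  bare <- paraxial_eye_trace(b)
  sys <- paraxial_eye_trace(b, lens_power = lens_power,
                            lens_distance = effective_distance)
  corr <- bare$power / sys$power
  base_rmf <- scale$rmf / scale$lens_correction
  scale$lens_correction <- corr
  scale$rmf <- base_rmf * corr
  scale
}

#' Micrometres per pixel for an acquisition geometry
#'
#' Converts a field of view in degrees and a pixel count to the retinal
#' sampling scale in micrometres per pixel, using the (lens-corrected)
#' RMF: `um_per_px = rmf * 1000 * fov_deg / pixels`.
#'
#' @param scale A `scale_model`.
#' @param field_of_view Field of view in degrees; length 1 or 2 (x, y).
#' @param pixels_across Pixel count across that field; length 1 or 2.
#' @param modality Label stored with the result (e.g. `"aoslo_confocal"`).
#' @return An object of class `modality_scale` with `microns_per_pixel_x`,
#'   `microns_per_pixel_y` and `modality`.
#' @examples
#' sm <- compute_rmf(biometry(24.46), model = "reduced")
#' microns_per_pixel(sm, field_of_view = 1, pixels_across = 512)
#' @export
microns_per_pixel <- function(scale, field_of_view, pixels_across,
                              modality = "aoslo_confocal") {
  stopifnot(inherits(scale, "scale_model"))
  if (any(!is.finite(field_of_view)) || any(field_of_view <= 0))
    stop("field_of_view must be positive degrees", call. = FALSE)
  if (any(!is.finite(pixels_across)) || any(pixels_across < 1))
    stop("pixels_across must be >= 1", call. = FALSE)
  fov <- rep_len(field_of_view, 2)
  px <- rep_len(pixels_across, 2)
  mpp <- scale$rmf * 1000 * fov / px
  modality_scale(mpp[1], mpp[2], modality)
}

#' Construct a per-modality pixel scale
#'
#' @param microns_per_pixel_x,microns_per_pixel_y Pixel pitch, um/px.
#' @param modality Modality label.
#' @return An object of class `modality_scale`.
#' @export
modality_scale <- function(microns_per_pixel_x,
                           microns_per_pixel_y = microns_per_pixel_x,
                           modality = "generic") {
  if (!is_number(microns_per_pixel_x) || microns_per_pixel_x <= 0 ||
      !is_number(microns_per_pixel_y) || microns_per_pixel_y <= 0)
    stop("pixel scales must be positive and finite", call. = FALSE)
  structure(list(modality = modality,
                 microns_per_pixel_x = microns_per_pixel_x,
                 microns_per_pixel_y = microns_per_pixel_y),
            class = "modality_scale")
}

#' @export
print.modality_scale <- function(x, ...) {
  cat(sprintf("%s: %.4f x %.4f um/px\n", x$modality,
              x$microns_per_pixel_x, x$microns_per_pixel_y))
  invisible(x)
}
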