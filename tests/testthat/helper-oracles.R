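# Independent oracles and small fixture builders used across tests.

# Paraxial ray-transfer-matrix oracle for the four-surface schematic eye,
# written with explicit 2x2 matrix products (the package implementation
# uses scalar surface-by-surface recurrences instead). Returns the
# equivalent power (mm^-1), the second nodal point (mm from the anterior
# cornea) and the RMF in mm/deg.
rtm_eye_oracle <- function(b, lens_power_d = 0, lens_distance_mm = 0) {
  ni <- b$refractive_indices
  refr <- function(P) matrix(c(1, -P, 0, 1), 2, 2)
  tran <- function(d, n) matrix(c(1, 0, d / n, 1), 2, 2)
  M <- diag(2)
  if (lens_power_d != 0) {
    M <- tran(lens_distance_mm, 1) %*% refr(lens_power_d / 1000) %*% M
  }
  surf <- list(
    list(R = b$corneal_front_radius, n1 = ni[["air"]], n2 = ni[["cornea"]],
         d = b$corneal_thickness),
    list(R = b$corneal_back_radius, n1 = ni[["cornea"]], n2 = ni[["aqueous"]],
         d = b$anterior_chamber_depth),
    list(R = b$lens_front_radius, n1 = ni[["aqueous"]], n2 = ni[["lens"]],
         d = b$lens_thickness),
    list(R = b$lens_back_radius, n1 = ni[["lens"]], n2 = ni[["vitreous"]],
         d = NA))
  for (s in surf) {
    M <- refr((s$n2 - s$n1) / s$R) %*% M
    if (!is.na(s$d)) M <- tran(s$d, s$n2) %*% M
  }
  n_img <- ni[["vitreous"]]
  P <- -M[2, 1]
  bfd <- -n_img * M[1, 1] / M[2, 1]
  z_last <- b$corneal_thickness + b$anterior_chamber_depth + b$lens_thickness
  z_H2 <- z_last + bfd - n_img / P
  z_N2 <- z_H2 + (n_img - 1) / P
  list(power = P, z_nodal = z_N2,
       rmf = (b$axial_length - z_N2) * pi / 180)
}

# Greedy one-to-one matching of detected centres to ground truth within
# `radius` px; returns the number of true positives.
count_matches <- function(det, truth, radius) {
  if (!nrow(det) || !nrow(truth)) return(0L)
  used <- rep(FALSE, nrow(det)); tp <- 0L
  for (i in seq_len(nrow(truth))) {
    d2 <- (det$x_px - truth$x_px[i])^2 + (det$y_px - truth$y_px[i])^2
    d2[used] <- Inf
    j <- which.min(d2)
    if (d2[j] < radius^2) { tp <- tp + 1L; used[j] <- TRUE }
  }
  tp
}

# Regular hexagonal lattice points with spacing `s` covering [0,w]x[0,h].
hex_points <- function(s, w, h, margin = 0) {
  rows <- seq(-margin, h + margin, by = s * sqrt(3) / 2)
  do.call(rbind, lapply(seq_along(rows), function(j) {
    off <- if (j %% 2 == 0) s / 2 else 0
    cbind(seq(-margin + off, w + margin, by = s), rows[j])
  }))
}

# Shift an image by a (possibly fractional) translation using the same
# sampling convention as the registration phantoms:
# out(r, c) = img(r - dy, c - dx); rows/cols falling outside are NA.
shift_image <- function(img, dx, dy) {
  H <- nrow(img); W <- ncol(img)
  g <- expand.grid(r = seq_len(H), c = seq_len(W))
  v <- retmap:::bilinear_sample(img, g$r - dy, g$c - dx)
  matrix(v, H, W)
}

# A moderately structured noise-free test image (cone-mosaic render).
test_base_image <- function(field = c(150, 150), density = 15000,
                            um_per_px = 0.75, seed = 4) {
  mo <- gen_mosaic(field_um = field, density = density, seed = seed)
  render_channels(mo, um_per_px = um_per_px, snr = Inf,
                  seed = seed)$confocal
}
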