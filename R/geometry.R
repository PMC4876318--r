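# Coordinate conventions (fixed throughout the package):
#   laboratory frame: x_L along the incident beam, y_L vertical up,
#   z_L horizontal transverse; detector azimuth chi is measured
#   counterclockwise viewed from the source, chi = 0 along +z_L and
#   chi = 90 along +y_L.
#   body frame: the lamella plane is the x-z plane, fibrils at in-plane
#   angle gamma have axis u(gamma) = (cos gamma, 0, -sin gamma).
# Angles are degrees at every public interface, radians internally.

.DEG <- pi / 180

#' Scattering geometry for an equatorial diffraction ring
#'
#' Bundles the X-ray wavelength, the magnitude of the scattering vector of
#' the ring under analysis (for alpha-chitin (110), q = 2*pi/d with
#' d approximately 4.6 Angstrom), and the optional flat-detector
#' calibration (sample-detector distance, beam centre, pixel size).
#'
#' @param wavelength X-ray wavelength in Angstrom (> 0).
#' @param q_ring magnitude of the ring scattering vector in inverse
#'   Angstrom; give either this or `d_spacing`.
#' @param d_spacing lattice spacing in Angstrom; `q_ring = 2*pi/d_spacing`.
#' @param distance sample-to-detector distance in mm (optional, needed for
#'   pixel transforms).
#' @param beam_centre length-2 numeric, beam centre in pixels `(px, py)`
#'   with `px` horizontal (+z_L) and `py` vertical up (+y_L).
#' @param pixel_size detector pixel edge in mm.
#' @return an object of class `scattering_geometry`.
#' @examples
#' g <- scattering_geometry(wavelength = 0.6888, d_spacing = 4.6)
#' wavenumber(g)
#' @export
scattering_geometry <- function(wavelength, q_ring = NULL, d_spacing = NULL,
                                distance = NA_real_,
                                beam_centre = c(NA_real_, NA_real_),
                                pixel_size = NA_real_) {
  if (!is.numeric(wavelength) || length(wavelength) != 1L ||
      !is.finite(wavelength) || wavelength <= 0) {
    stop("invalid geometry: wavelength must be a single positive number ",
         "(Angstrom)", call. = FALSE)
  }
  if (is.null(q_ring)) {
    if (is.null(d_spacing)) {
      stop("invalid geometry: give either q_ring or d_spacing", call. = FALSE)
    }
    if (d_spacing <= 0) stop("invalid geometry: d_spacing must be > 0",
                             call. = FALSE)
    q_ring <- 2 * pi / d_spacing
  }
  if (!is.finite(q_ring) || q_ring <= 0) {
    stop("invalid geometry: q_ring must be > 0", call. = FALSE)
  }
  k <- 2 * pi / wavelength
  if (q_ring >= 2 * k) {
    stop("no intersection: q_ring = ", format(q_ring),
         " is not reachable at wavelength ", format(wavelength),
         " (requires q_ring < 2k = ", format(2 * k), ")", call. = FALSE)
  }
  structure(list(wavelength = wavelength, q_ring = q_ring,
                 distance = distance,
                 beam_centre = as.numeric(beam_centre),
                 pixel_size = pixel_size),
            class = "scattering_geometry")
}

#' @export
print.scattering_geometry <- function(x, ...) {
  cat("Scattering geometry\n")
  cat(sprintf("  wavelength : %.6g Angstrom (k = %.6g 1/Angstrom)\n",
              x$wavelength, 2 * pi / x$wavelength))
  cat(sprintf("  q_ring     : %.6g 1/Angstrom (d = %.6g Angstrom)\n",
              x$q_ring, 2 * pi / x$q_ring))
  if (is.finite(x$distance))
    cat(sprintf("  distance   : %.6g mm\n", x$distance))
  if (all(is.finite(x$beam_centre)))
    cat(sprintf("  beam centre: (%.6g, %.6g) px\n",
                x$beam_centre[1], x$beam_centre[2]))
  if (is.finite(x$pixel_size))
    cat(sprintf("  pixel size : %.6g mm\n", x$pixel_size))
  invisible(x)
}

#' Convenience geometry for the chitin (110) ring
#'
#' A fully calibrated geometry with defaults matching a microfocus WAXD
#' setup on a Pilatus-class detector: 0.6888 Angstrom wavelength,
#' 262.3 mm sample-detector distance, 0.172 mm pixels, and the (110)
#' ring of alpha-chitin at d = 4.6 Angstrom.
#'
#' @param wavelength,d_spacing,distance,pixel_size,beam_centre see
#'   [scattering_geometry()].
#' @return a `scattering_geometry`.
#' @export
chitin_geometry <- function(wavelength = 0.6888, d_spacing = 4.6,
                            distance = 262.3, pixel_size = 0.172,
                            beam_centre = c(309.5, 243.5)) {
  scattering_geometry(wavelength = wavelength, d_spacing = d_spacing,
                      distance = distance, beam_centre = beam_centre,
                      pixel_size = pixel_size)
}

#' Wavenumber of the incident beam
#'
#' @param geometry a [scattering_geometry()].
#' @return `k = 2*pi/wavelength` in inverse Angstrom.
#' @export
wavenumber <- function(geometry) {
  stopifnot(inherits(geometry, "scattering_geometry"))
  2 * pi / geometry$wavelength
}

#' Laboratory-frame scattering vector on the Ewald intersection circle
#'
#' All ring intensity recorded on the detector lies on the circle where the
#' Ewald sphere cuts the sphere of radius `q_ring`. For elastic scattering
#' the beam-axis component is the constant curvature offset
#' `qx = -q_ring^2/(2 k)`; the transverse component of magnitude
#' `sqrt(q_ring^2 - qx^2)` points along +y_L at chi = 90 deg and +z_L at
#' chi = 0 deg.
#'
#' @param chi detector azimuth(s) in degrees (any real; periodic).
#' @param geometry a [scattering_geometry()].
#' @return numeric matrix with one row per `chi` and columns
#'   `qx`, `qy`, `qz` (laboratory frame, inverse Angstrom).
#' @export
ewald_ring_point <- function(chi, geometry) {
  stopifnot(inherits(geometry, "scattering_geometry"))
  q <- geometry$q_ring
  k <- wavenumber(geometry)
  qx <- -q^2 / (2 * k)
  qp <- sqrt(q^2 - qx^2)
  ch <- chi * .DEG
  cbind(qx = rep_len(qx, length(ch)), qy = qp * sin(ch), qz = qp * cos(ch))
}

# 3x3 rotation taking body-frame components to laboratory-frame components.
# alpha tilts the lamella in the laboratory x-y plane (rotation about z_L,
# positive alpha strengthens the upper, chi = 90 deg, peak); beta tilts it
# in the y-z plane (rotation about the beam axis, positive beta shifts both
# detector peaks toward larger chi). alpha is applied first.
rotation_body_to_lab <- function(alpha, beta) {
  a <- alpha * .DEG
  b <- beta * .DEG
  rz <- matrix(c(cos(a), sin(a), 0,
                 -sin(a), cos(a), 0,
                 0, 0, 1), 3, 3)
  rx <- matrix(c(1, 0, 0,
                 0, cos(b), -sin(b),
                 0, sin(b), cos(b)), 3, 3)
  rx %*% rz
}

.as_q_matrix <- function(q) {
  if (is.null(dim(q))) {
    stopifnot(length(q) == 3L)
    q <- matrix(as.numeric(q), 1L, 3L)
  }
  stopifnot(ncol(q) == 3L)
  q
}

#' Rotate laboratory-frame q-vectors into the lamella body frame
#'
#' The lamella orientation is parameterized by two tilts: `alpha` in the
#' laboratory x-y plane and `beta` in the y-z plane (about the beam axis).
#' `lab_to_body` and [body_to_lab()] are exact inverses.
#'
#' @param q numeric length-3 vector or n x 3 matrix of components
#'   (qx, qy, qz).
#' @param alpha,beta lamella tilt angles in degrees.
#' @return matrix of the same shape (n x 3) with body-frame components.
#' @export
lab_to_body <- function(q, alpha, beta) {
  q <- .as_q_matrix(q)
  r <- rotation_body_to_lab(alpha, beta)
  out <- q %*% r          # q %*% R == t(t(R) %*% t(q)): applies R^T rowwise
  colnames(out) <- c("qx", "qy", "qz")
  out
}

#' @rdname lab_to_body
#' @export
body_to_lab <- function(q, alpha, beta) {
  q <- .as_q_matrix(q)
  r <- rotation_body_to_lab(alpha, beta)
  out <- q %*% t(r)
  colnames(out) <- c("qx", "qy", "qz")
  out
}

#' Flag detector azimuths in the degenerate zone of the limiting profile
#'
#' In the a_x -> 0 limit the closed-form profile divides by
#' `sqrt(qx_body^2 + qz_body^2)`, whose minimum over chi is the Ewald
#' curvature offset `|q_ring^2/(2k)|`. Azimuths where the denominator is
#' within `factor` of that minimum sit in the narrow zone around the
#' vertical where the limiting function develops its artefactual minimum;
#' comparisons against the finite-a_x integral model exclude them.
#'
#' @param chi azimuths in degrees.
#' @param geometry a [scattering_geometry()].
#' @param alpha,beta lamella tilts in degrees.
#' @param factor multiple of the minimal denominator defining the zone.
#' @return logical vector, `TRUE` inside the degenerate zone.
#' @export
degenerate_zone <- function(chi, geometry, alpha = 0, beta = 0, factor = 3) {
  qlab <- ewald_ring_point(chi, geometry)
  qb <- lab_to_body(qlab, alpha, beta)
  denom <- sqrt(qb[, 1]^2 + qb[, 3]^2)
  qx0 <- abs(geometry$q_ring^2 / (2 * wavenumber(geometry)))
  denom < factor * qx0
}

#' Read / write a flat key-value geometry configuration file
#'
#' Recognised keys: `wavelength_A`, `q_ring_invA` or `d_spacing_A`,
#' `distance_mm`, `beam_centre_x_px`, `beam_centre_y_px`, `pixel_size_mm`.
#' Lines may use `key value`, `key = value` or `key: value`; `#` starts a
#' comment.
#'
#' @param path file path.
#' @return `read_geometry` returns a [scattering_geometry()].
#' @export
read_geometry <- function(path) {
  if (!file.exists(path)) stop("geometry file not found: ", path,
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "[=:[:space:]]+")[[1]]
    if (length(parts) < 2) next
    kv[[parts[1]]] <- as.numeric(parts[2])
  }
  scattering_geometry(
    wavelength = kv[["wavelength_A"]],
    q_ring = kv[["q_ring_invA"]],
    d_spacing = kv[["d_spacing_A"]],
    distance = if (is.null(kv[["distance_mm"]])) NA_real_ else kv[["distance_mm"]],
    beam_centre = c(if (is.null(kv[["beam_centre_x_px"]])) NA_real_ else kv[["beam_centre_x_px"]],
                    if (is.null(kv[["beam_centre_y_px"]])) NA_real_ else kv[["beam_centre_y_px"]]),
    pixel_size = if (is.null(kv[["pixel_size_mm"]])) NA_real_ else kv[["pixel_size_mm"]])
}

#' @rdname read_geometry
#' @param geometry a [scattering_geometry()] to write.
#' @export
write_geometry <- function(geometry, path) {
  stopifnot(inherits(geometry, "scattering_geometry"))
  lines <- c(sprintf("wavelength_A %.12g", geometry$wavelength),
             sprintf("q_ring_invA %.12g", geometry$q_ring))
  if (is.finite(geometry$distance))
    lines <- c(lines, sprintf("distance_mm %.12g", geometry$distance))
  if (all(is.finite(geometry$beam_centre)))
    lines <- c(lines,
               sprintf("beam_centre_x_px %.12g", geometry$beam_centre[1]),
               sprintf("beam_centre_y_px %.12g", geometry$beam_centre[2]))
  if (is.finite(geometry$pixel_size))
    lines <- c(lines, sprintf("pixel_size_mm %.12g", geometry$pixel_size))
  writeLines(lines, path)
  invisible(path)
}
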