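# Forward model: intensity on the QS110 sphere from a lamella of fibrils,
# its restriction to the Ewald intersection circle (the measured azimuthal
# profile), the a_x -> 0 closed-form limiting profile, the narrow Gaussian
# beta-convolution that regularizes the limit, and the two-family sum.

#' Single fibre-family lamella model
#'
#' One family of fibrils in a planar lamella: tilts `alpha` (laboratory
#' x-y plane) and `beta` (y-z plane, about the beam axis), an in-plane
#' orientation distribution (`gamma0`, `dgamma0`), and a non-negative
#' intensity scale factor lambda.
#'
#' @param alpha,beta lamella tilts in degrees.
#' @param gamma0,dgamma0 centre and width (degrees) of the in-plane
#'   fibril distribution, see [fibre_distribution()].
#' @param scale non-negative intensity scale factor.
#' @return an object of class `lamella_model`.
#' @export
lamella_model <- function(alpha = 0, beta = 0, gamma0 = 0, dgamma0 = 30,
                          scale = 1) {
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale < 0) {
    stop("invalid model: scale must be a single non-negative number",
         call. = FALSE)
  }
  stopifnot(is.finite(alpha), is.finite(beta))
  structure(list(alpha = alpha, beta = beta,
                 distribution = fibre_distribution(gamma0, dgamma0),
                 scale = scale),
            class = "lamella_model")
}

#' @export
print.lamella_model <- function(x, ...) {
  cat(sprintf(paste0("Lamella: alpha = %g, beta = %g, gamma0 = %g, ",
                     "dgamma0 = %g deg; scale = %g\n"),
              x$alpha, x$beta, x$distribution$gamma0,
              x$distribution$dgamma0, x$scale))
  invisible(x)
}

#' Two-family (in-plane + out-of-plane) lamella model
#'
#' Crustacean cuticle shows two coexisting fibre families: in-plane (IP)
#' fibres of the Bouligand stacks and out-of-plane (OP) fibres along the
#' pore canals. The measured profile is the sum of one single-family
#' profile per family plus a constant background.
#'
#' @param ip,op [lamella_model()] objects for the IP and OP families; the
#'   family scale factors lambda1 and lambda2 live inside them.
#' @param background non-negative constant intensity offset.
#' @return an object of class `two_family_model`.
#' @export
two_family_model <- function(ip, op = lamella_model(scale = 0),
                             background = 0) {
  stopifnot(inherits(ip, "lamella_model"), inherits(op, "lamella_model"))
  if (!is.numeric(background) || length(background) != 1L ||
      !is.finite(background) || background < 0) {
    stop("invalid model: background must be a single non-negative number",
         call. = FALSE)
  }
  structure(list(ip = ip, op = op, background = background),
            class = "two_family_model")
}

#' @export
print.two_family_model <- function(x, ...) {
  cat("Two-family model\n  IP: ")
  print(x$ip)
  cat("  OP: ")
  print(x$op)
  cat(sprintf("  background = %g\n", x$background))
  invisible(x)
}

# body-frame axial component of q for a fibril at in-plane angle gamma:
# u(gamma) = (cos gamma, 0, -sin gamma), g = q . u
axial_component <- function(qx, qz, gamma_rad) {
  qx * cos(gamma_rad) - qz * sin(gamma_rad)
}

#' Intensity on the QS110 sphere (body frame)
#'
#' Weighted sum over the fibril population of the single-fibril ring
#' kernel: `I(q) = integral of w(gamma) * K(q . u(gamma); a_x) dgamma`
#' over one 180-degree period, with `u(gamma)` the fibril axis. Evaluated
#' by midpoint quadrature on a uniform gamma grid (spectrally accurate for
#' this periodic integrand).
#'
#' @param q_body length-3 vector or n x 3 matrix of body-frame components
#'   on the ring sphere.
#' @param dist a [fibre_distribution()].
#' @param a_x ring kernel width, inverse Angstrom.
#' @param q_ring if supplied, each `q_body` row is checked to lie on the
#'   sphere of this radius (relative tolerance 1e-9).
#' @param n_quad number of quadrature nodes over one period.
#' @return intensity value(s), one per row of `q_body`.
#' @export
qs_intensity <- function(q_body, dist, a_x, q_ring = NULL, n_quad = 2048L) {
  stopifnot(inherits(dist, "fibre_distribution"))
  q_body <- .as_q_matrix(q_body)
  if (!is.null(q_ring)) {
    r <- sqrt(rowSums(q_body^2))
    if (any(abs(r - q_ring) > 1e-9 * q_ring)) {
      stop("q_body does not lie on the sphere of radius q_ring",
           call. = FALSE)
    }
  }
  gam <- (seq_len(n_quad) - 0.5) / n_quad * pi
  w <- weight_rad(gam, dist$gamma0, dist$dgamma0)
  # n x n_quad axial components
  g <- outer(q_body[, 1], cos(gam)) - outer(q_body[, 3], sin(gam))
  kern <- exp(-(g / a_x)^2) / (a_x * sqrt(pi))
  as.numeric(kern %*% w) * (pi / n_quad)
}

#' Spherical map of ring-sphere intensity for a tilted lamella
#'
#' Evaluates [qs_intensity()] on a regular laboratory-frame spherical mesh
#' after rotating each mesh point into the body frame. The polar angle
#' `theta` is measured from the +y_L (vertical) axis, so the untilted
#' lamella's intensity maxima sit at `theta = 0` and `180` degrees; `phi`
#' rotates about y_L with `phi = 0` along +z_L.
#'
#' @param dist a [fibre_distribution()].
#' @param alpha,beta lamella tilts in degrees.
#' @param a_x ring kernel width, inverse Angstrom.
#' @param n_theta,n_phi mesh sizes (>= 2).
#' @param q_ring sphere radius, inverse Angstrom.
#' @param n_quad quadrature nodes passed to [qs_intensity()].
#' @return data frame with columns `theta_deg`, `phi_deg`, `intensity`.
#' @export
qs_map <- function(dist, alpha = 0, beta = 0, a_x = 0.02,
                   n_theta = 37L, n_phi = 72L, q_ring = 1, n_quad = 512L) {
  stopifnot(n_theta >= 2L, n_phi >= 2L)
  theta <- seq(0, 180, length.out = n_theta)
  phi <- seq(0, 360 - 360 / n_phi, length.out = n_phi)
  mesh <- expand.grid(theta_deg = theta, phi_deg = phi,
                      KEEP.OUT.ATTRS = FALSE)
  th <- mesh$theta_deg * .DEG
  ph <- mesh$phi_deg * .DEG
  q_lab <- cbind(q_ring * sin(th) * sin(ph),   # x_L
                 q_ring * cos(th),             # y_L
                 q_ring * sin(th) * cos(ph))   # z_L
  q_body <- lab_to_body(q_lab, alpha, beta)
  mesh$intensity <- qs_intensity(q_body, dist, a_x, n_quad = n_quad)
  mesh
}

#' Azimuthal profile by exact numerical integration (reference model)
#'
#' For each detector azimuth, rotates the Ewald-circle point into the body
#' frame and integrates the fibril population against the finite-width
#' ring kernel. This is the slow reference model; the closed form
#' [profile_closed()] is its a_x -> 0 limit.
#'
#' @param chi azimuths in degrees.
#' @param lamella a [lamella_model()].
#' @param geometry a [scattering_geometry()].
#' @param a_x ring kernel width, inverse Angstrom.
#' @param n_quad quadrature nodes (2048 is converged to < 1e-6 relative
#'   for a_x >= 5e-3 at typical WAXD geometries).
#' @return intensity vector, one value per `chi`.
#' @export
profile_integral <- function(chi, lamella, geometry, a_x, n_quad = 2048L) {
  stopifnot(inherits(lamella, "lamella_model"))
  q_body <- lab_to_body(ewald_ring_point(chi, geometry),
                        lamella$alpha, lamella$beta)
  lamella$scale * qs_intensity(q_body, lamella$distribution, a_x,
                               n_quad = n_quad)
}

#' Closed-form limiting azimuthal profile
#'
#' In the limit of perfect intrafibrillar alignment (a_x -> 0) the ring
#' kernel becomes a delta function and the population integral collapses
#' onto the fibrils whose ring passes exactly through the Ewald-circle
#' point: `I(chi) = scale * 2 * w(gamma_r) / sqrt(qx^2 + qz^2)` with
#' body-frame components and `gamma_r = atan2(qx, qz)` (mod 180 deg) the
#' root of `q . u(gamma) = 0`. The factor 2 counts both coincident roots
#' of the 180-degree-periodic weight. The denominator is floored at
#' `eps_frac * q_ring`; floored azimuths are flagged in the `"degenerate"`
#' attribute (remedied in practice by [beta_smoothed_profile()]).
#'
#' @param chi azimuths in degrees.
#' @param lamella a [lamella_model()].
#' @param geometry a [scattering_geometry()].
#' @param eps_frac denominator floor as a fraction of `q_ring`.
#' @return intensity vector with logical attribute `"degenerate"`.
#' @export
profile_closed <- function(chi, lamella, geometry, eps_frac = 1e-6) {
  stopifnot(inherits(lamella, "lamella_model"))
  qb <- lab_to_body(ewald_ring_point(chi, geometry),
                    lamella$alpha, lamella$beta)
  denom <- sqrt(qb[, 1]^2 + qb[, 3]^2)
  eps <- eps_frac * geometry$q_ring
  flagged <- denom < eps
  denom <- pmax(denom, eps)
  gamma_r <- atan2(qb[, 1], qb[, 3])
  w <- weight_rad(gamma_r, lamella$distribution$gamma0,
                  lamella$distribution$dgamma0)
  out <- lamella$scale * 2 * w / denom
  attr(out, "degenerate") <- flagged
  out
}

# Normalized Gaussian kernel weights at equally spaced offsets (degrees)
# spanning +/- span_factor * delta_beta.
beta_kernel <- function(delta_beta, step, n_kernel = 11L,
                        span_factor = 2.5) {
  stopifnot(delta_beta > 0, n_kernel >= 3L)
  half <- span_factor * delta_beta
  m <- max((n_kernel - 1L) %/% 2L, ceiling(half / step))
  offsets <- seq(-m, m) * (half / m)
  w <- exp(-(offsets / delta_beta)^2)
  list(offsets = offsets, weights = w / sum(w))
}

#' Beta-convolved closed-form profile
#'
#' Numerical convolution of [profile_closed()] with a narrow Gaussian
#' kernel of width `delta_beta` (default 5 degrees). A residual tilt of
#' the lamella about the beam axis turns a single principal fibril
#' direction into a narrow fan in the y-z plane; for the untilted lamella
#' a beta offset is exactly a rigid shift of the profile along chi, so
#' the fan is realised as a one-dimensional circular convolution of
#' I(chi). Numerically this removes the artefactual minimum that the
#' a_x -> 0 limit develops near the vertical (chi = +/- 90 degrees) and
#' yields a smooth objective for fitting; this convolved form is the
#' model function used by [fit_profile()].
#'
#' The convolution is evaluated on a fine internal chi grid (step
#' `resolution`) with an FFT and interpolated to the requested azimuths;
#' the denominator floor of the closed form is widened to the value half
#' an internal grid step away from exact degeneracy, so a grid point
#' landing on the degenerate pole contributes what an honest Riemann sum
#' would.
#'
#' @param chi azimuths in degrees.
#' @param lamella a [lamella_model()].
#' @param geometry a [scattering_geometry()].
#' @param delta_beta Gaussian kernel width in degrees (> 0); widths below
#'   `resolution/2` degenerate to the unconvolved closed form.
#' @param n_kernel minimum number of kernel nodes over the +/- 2.5
#'   `delta_beta` span (more are used when the internal grid is finer).
#' @param eps_frac lower bound on the denominator floor, as a fraction of
#'   `q_ring`; see [profile_closed()].
#' @param resolution internal evaluation grid step in degrees.
#' @return intensity vector, one value per `chi`.
#' @export
beta_smoothed_profile <- function(chi, lamella, geometry, delta_beta = 5,
                                  n_kernel = 11L, eps_frac = 1e-6,
                                  resolution = 0.25) {
  if (delta_beta <= resolution / 2) {
    return(as.numeric(profile_closed(chi, lamella, geometry, eps_frac)))
  }
  n <- round(360 / resolution)
  chif <- seq(0, 360 - resolution, length.out = n)
  # discretization-consistent floor: denominator half a grid step from
  # exact degeneracy
  qx0 <- geometry$q_ring^2 / (2 * wavenumber(geometry))
  qp <- sqrt(geometry$q_ring^2 - qx0^2)
  eps_eff <- max(eps_frac, qp * (resolution / 2) * .DEG / geometry$q_ring)
  y <- as.numeric(profile_closed(chif, lamella, geometry, eps_eff))
  k <- beta_kernel(delta_beta, resolution, n_kernel)
  m <- (length(k$offsets) - 1L) %/% 2L
  kpad <- numeric(n)
  kpad[1L] <- k$weights[m + 1L]
  kpad[seq_len(m) + 1L] <- k$weights[(m + 2L):(2L * m + 1L)]
  kpad[n - seq_len(m) + 1L] <- k$weights[m:1L]
  ys <- Re(stats::fft(stats::fft(y) * stats::fft(kpad), inverse = TRUE)) / n
  # circular linear interpolation onto the requested azimuths
  pos <- (chi %% 360) / resolution
  i0 <- floor(pos)
  frac <- pos - i0
  i0 <- (i0 %% n) + 1L
  i1 <- (i0 %% n) + 1L
  ys[i0] * (1 - frac) + ys[i1] * frac
}

#' Two-family azimuthal profile
#'
#' Sum of the beta-convolved closed-form profiles of the in-plane and
#' out-of-plane families plus a constant background; the family scale
#' factors lambda1 and lambda2 live in the component [lamella_model()]s.
#'
#' @param chi azimuths in degrees.
#' @param model a [two_family_model()].
#' @param geometry a [scattering_geometry()].
#' @param delta_beta,n_kernel,eps_frac see [beta_smoothed_profile()].
#' @return intensity vector.
#' @export
two_family_profile <- function(chi, model, geometry, delta_beta = 5,
                               n_kernel = 11L, eps_frac = 1e-6) {
  stopifnot(inherits(model, "two_family_model"))
  beta_smoothed_profile(chi, model$ip, geometry, delta_beta, n_kernel,
                        eps_frac) +
    beta_smoothed_profile(chi, model$op, geometry, delta_beta, n_kernel,
                          eps_frac) +
    model$background
}
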