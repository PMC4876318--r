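# In-plane fibril orientation distribution and the ring kernel.
# Fibrils are apolar: gamma and gamma + 180 deg describe the same fibril,
# so the Gaussian weight is wrapped with period 180 deg. Gaussian widths
# follow the width-parameter convention f(u) ~ exp(-u^2/a^2), i.e.
# a = sqrt(2) * sigma.

#' Gaussian in-plane fibril orientation distribution
#'
#' Normalized weight `w(gamma; gamma0, dgamma0)` of fibrils at in-plane
#' angle `gamma` within a lamella: a Gaussian of width parameter `dgamma0`
#' centred on the principal fibre direction `gamma0`, wrapped with period
#' 180 degrees (apolar fibrils). Integrates to 1 over one period.
#'
#' @param gamma0 principal fibre direction in degrees.
#' @param dgamma0 width parameter in degrees (> 0).
#' @return an object of class `fibre_distribution`.
#' @examples
#' d <- fibre_distribution(gamma0 = 20, dgamma0 = 45)
#' weight(20, d)          # peak density, per degree
#' @export
fibre_distribution <- function(gamma0, dgamma0) {
  if (!is.numeric(dgamma0) || length(dgamma0) != 1L || !is.finite(dgamma0) ||
      dgamma0 <= 0) {
    stop("invalid distribution: dgamma0 must be a single positive number ",
         "(degrees)", call. = FALSE)
  }
  stopifnot(is.numeric(gamma0), length(gamma0) == 1L, is.finite(gamma0))
  structure(list(gamma0 = gamma0, dgamma0 = dgamma0),
            class = "fibre_distribution")
}

#' @export
print.fibre_distribution <- function(x, ...) {
  cat(sprintf("Fibre distribution: gamma0 = %g deg, dgamma0 = %g deg\n",
              x$gamma0, x$dgamma0))
  invisible(x)
}

# Wrapped Gaussian density, per unit of `delta` (same angular unit as
# `width` and `period`). Enough wrap terms are summed that the truncation
# error is below 1e-12 for widths up to ~period/2.
wrapped_gaussian <- function(delta, width, period) {
  kmax <- max(2L, ceiling(5 * width / period))
  delta <- ((delta + period / 2) %% period) - period / 2
  acc <- 0
  for (k in -kmax:kmax) {
    acc <- acc + exp(-((delta + k * period) / width)^2)
  }
  acc / (width * sqrt(pi))
}

#' Evaluate the fibril orientation weight
#'
#' @param gamma in-plane angle(s) in degrees.
#' @param dist a [fibre_distribution()].
#' @return density in inverse degrees; 180-degree periodic in `gamma` and
#'   symmetric about `gamma0`.
#' @export
weight <- function(gamma, dist) {
  stopifnot(inherits(dist, "fibre_distribution"))
  wrapped_gaussian(gamma - dist$gamma0, dist$dgamma0, 180)
}

# Same distribution expressed per radian, used by the intensity models.
weight_rad <- function(gamma_rad, gamma0_deg, dgamma0_deg) {
  wrapped_gaussian(gamma_rad - gamma0_deg * .DEG, dgamma0_deg * .DEG, pi)
}

#' Generalized delta-function ring kernel
#'
#' Intensity kernel of a single fibril's diffraction ring as a function of
#' `u`, the component of the scattering vector along the fibril axis:
#' `(1/(a_x*sqrt(pi))) * exp(-u^2/a_x^2)`. The width `a_x` measures the
#' intrafibrillar alignment of unit cells; the kernel approaches a sharp
#' band (a delta function) as `a_x -> 0`. Normalized to unit integral
#' over u.
#'
#' @param u axial component(s) of q, inverse Angstrom.
#' @param a_x width parameter, inverse Angstrom (> 0).
#' @return kernel density values.
#' @export
ring_kernel <- function(u, a_x) {
  if (!is.numeric(a_x) || length(a_x) != 1L || !is.finite(a_x) || a_x <= 0) {
    stop("invalid parameter: a_x must be a single positive number",
         call. = FALSE)
  }
  exp(-(u / a_x)^2) / (a_x * sqrt(pi))
}

#' Thickness of the sublamella at in-plane angle gamma
#'
#' For a Bouligand layer of total thickness `t` whose fibril angles follow
#' `w(gamma; gamma0, dgamma0)`, the sublamella containing fibrils within
#' `[gamma, gamma + d_gamma]` has thickness `t * w(gamma) * d_gamma`.
#' Summing over a partition of one 180-degree period recovers `t`.
#'
#' @param t total lamella thickness (micrometres).
#' @param gamma in-plane angle(s) in degrees.
#' @param d_gamma angular resolution between adjacent sublamellae, degrees.
#' @param dist a [fibre_distribution()].
#' @return sublamella thickness in the units of `t`.
#' @export
sublamella_thickness <- function(t, gamma, d_gamma, dist) {
  stopifnot(is.numeric(t), length(t) == 1L, t > 0,
            is.numeric(d_gamma), length(d_gamma) == 1L, d_gamma > 0)
  t * weight(gamma, dist) * d_gamma
}
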