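test_that("ring-sphere intensity peaks at the poles and validates input", {
  g <- std_geometry()
  d <- fibre_distribution(0, 30)
  qr <- g$q_ring
  pole <- qs_intensity(c(0, qr, 0), d, a_x = 0.02)
  # every fibril's ring passes through the poles: global maximum there
  set.seed(3)
  th <- stats::runif(50, 0, pi)
  ph <- stats::runif(50, 0, 2 * pi)
  pts <- cbind(qr * sin(th) * sin(ph), qr * cos(th), qr * sin(th) * cos(ph))
  expect_true(all(qs_intensity(pts, d, a_x = 0.02) <= pole + 1e-12))
  # fibril axis parallel to q kills the reflection for tight distributions
  expect_lt(qs_intensity(c(qr, 0, 0), d, a_x = 0.005), 1e-3 * pole)
  expect_error(qs_intensity(c(0, 2 * qr, 0), d, a_x = 0.02, q_ring = qr),
               "sphere")
})

test_that("total diffracted power on the sphere is rotation-invariant", {
  g <- std_geometry()
  pw <- function(mp) sum(mp$intensity * sin(mp$theta_deg * pi / 180))
  args <- list(a_x = 0.15, n_theta = 145L, n_phi = 288L,
               q_ring = g$q_ring, n_quad = 256L)
  m0 <- do.call(qs_map, c(list(fibre_distribution(0, 30), 0, 0), args))
  m1 <- do.call(qs_map, c(list(fibre_distribution(30, 30), 0, 0), args))
  m2 <- do.call(qs_map, c(list(fibre_distribution(30, 30), 10, 40), args))
  expect_equal(pw(m1), pw(m0), tolerance = 1e-3)
  expect_equal(pw(m2), pw(m0), tolerance = 1e-3)
})

test_that("spherical maps rotate rigidly with the lamella tilts", {
  g <- std_geometry()
  d <- fibre_distribution(0, 30)
  m0 <- qs_map(d, 0, 0, a_x = 0.05, n_theta = 73, n_phi = 144,
               q_ring = g$q_ring, n_quad = 256L)
  # untilted: maxima at the +/- y poles
  expect_lte(min(abs(m0$theta_deg[which.max(m0$intensity)] - c(0, 180))),
             2.5)
  # beta tilt: the maximum direction, rotated back, returns to the pole
  mb <- qs_map(d, 0, 45, a_x = 0.05, n_theta = 73, n_phi = 144,
               q_ring = g$q_ring, n_quad = 256L)
  i <- which.max(mb$intensity)
  th <- mb$theta_deg[i] * pi / 180
  ph <- mb$phi_deg[i] * pi / 180
  v <- c(sin(th) * sin(ph), cos(th), sin(th) * cos(ph))
  vb <- lab_to_body(v, 0, 45)
  expect_lt(acos(abs(vb[2])) * 180 / pi, 3)
  # apolar fibrils: gamma0 + 180 is the same map
  ma <- qs_map(fibre_distribution(20, 40), 5, 30, a_x = 0.05,
               n_theta = 19, n_phi = 36, q_ring = g$q_ring, n_quad = 256L)
  mc <- qs_map(fibre_distribution(200, 40), 5, 30, a_x = 0.05,
               n_theta = 19, n_phi = 36, q_ring = g$q_ring, n_quad = 256L)
  expect_equal(ma$intensity, mc$intensity, tolerance = 1e-12)
})

test_that("closed form reproduces the untilted two-peak geometry", {
  g <- std_geometry()
  chi <- seq(0, 359.9, by = 0.1)
  y <- profile_closed(chi, lamella_model(0, 0, 0, 30), g)
  s <- peak_separation(chi, as.numeric(y))
  expect_equal(s$separation, 180, tolerance = 1e-6)
  expect_equal(sort((s$positions)), c(90, 270), tolerance = 1e-6)
  expect_lt(abs(diff(s$heights)) / max(s$heights), 1e-9)
  # zero scale kills the profile
  expect_true(all(profile_closed(chi, lamella_model(0, 0, 0, 30,
                                                    scale = 0), g) == 0))
  expect_type(attr(y, "degenerate"), "logical")
})

test_that("alpha tilt makes the upper peak stronger", {
  g <- std_geometry()
  chi <- seq(0, 359.9, by = 0.1)
  s <- peak_separation(chi, as.numeric(
    profile_closed(chi, lamella_model(5, 0, 0, 30), g)))
  up <- which.min(abs(s$positions - 90))
  dn <- 3 - up
  expect_gt(s$heights[up], s$heights[dn])
  # and the mirror case
  s2 <- peak_separation(chi, as.numeric(
    profile_closed(chi, lamella_model(-5, 0, 0, 30), g)))
  up2 <- which.min(abs(s2$positions - 90))
  expect_lt(s2$heights[up2], s2$heights[3 - up2])
})

test_that("integral profile respects scale linearity", {
  g <- std_geometry()
  chi <- seq(0, 350, by = 10)
  expect_true(all(profile_integral(chi, lamella_model(0, 0, 0, 30,
                                                      scale = 0), g,
                                   0.02) == 0))
  y1 <- profile_integral(chi, lamella_model(0, 0, 10, 30, scale = 1), g,
                         0.02)
  y3 <- profile_integral(chi, lamella_model(0, 0, 10, 30, scale = 3), g,
                         0.02)
  expect_equal(y3, 3 * y1, tolerance = 1e-12)
})

test_that("beta convolution degenerates to the closed form and removes
           the vertical artefact", {
  g <- std_geometry()
  chi <- seq(0.5, 359.5, by = 1)
  lam <- lamella_model(0, 15, 25, 50)
  away <- !degenerate_zone(chi, g, lam$alpha, lam$beta, factor = 4)
  y0 <- as.numeric(profile_closed(chi, lam, g))
  ys <- beta_smoothed_profile(chi, lam, g, delta_beta = 0.01)
  expect_equal(ys[away], y0[away], tolerance = 1e-3)
  # near-isotropic untilted lamella: no artefactual interior minimum
  # remains within +/- 3 degrees of the vertical after convolution
  chif <- seq(0, 359.9, by = 0.1)
  for (dg in c(75, 83, 88)) {
    y <- beta_smoothed_profile(chif, lamella_model(0, 0, 0, dg), g)
    win <- which(abs(chif - 90) <= 3)
    imin <- win[which.min(y[win])]
    expect_true(chif[imin] <= 87.05 || chif[imin] >= 92.95)
  }
})

test_that("two-family profile is the background-shifted family sum", {
  g <- std_geometry()
  chi <- chi_grid_1deg()
  ip <- lamella_model(2, 10, 30, 60, 1.2)
  op <- lamella_model(0, -85, 10, 12, 0.4)
  m <- two_family_model(ip, op, background = 3)
  y <- two_family_profile(chi, m, g)
  # op scale 0, background 0 -> IP profile alone
  m_ip <- two_family_model(ip, lamella_model(scale = 0), background = 0)
  expect_equal(two_family_profile(chi, m_ip, g),
               beta_smoothed_profile(chi, ip, g), tolerance = 1e-12)
  # pointwise linearity in the scales and background
  m2 <- two_family_model(lamella_model(2, 10, 30, 60, 2.4),
                         lamella_model(0, -85, 10, 12, 0.8),
                         background = 6)
  expect_equal(two_family_profile(chi, m2, g), 2 * y, tolerance = 1e-12)
})

test_that("a published two-family parameter set yields four lobes", {
  g <- std_geometry()
  chi <- chi_grid_1deg()
  m <- location_model(carina_locations()$I, amplitude = 1)
  pk <- detect_peaks(chi, two_family_profile(chi, m, g),
                     min_separation = 30)
  expect_equal(nrow(pk), 4L)
  # one near-vertical pair (IP, beta ~ 4.7) and one near-horizontal
  # pair (OP, beta ~ -87)
  near_vertical <- pmin(abs(pk$position - 90), abs(pk$position - 270)) < 30
  expect_equal(sum(near_vertical), 2L)
})

test_that("beta produces an exact rigid shift of the closed form", {
  g <- std_geometry()
  chi <- chi_grid_1deg()
  for (b0 in c(25, -40, 117)) {
    shifted <- as.numeric(profile_closed(chi, lamella_model(0, b0, 20, 35),
                                         g))
    base <- as.numeric(profile_closed(chi - b0, lamella_model(0, 0, 20, 35),
                                      g))
    expect_equal(shifted, base, tolerance = 1e-12)
  }
  # lobe positions shift rigidly, separation preserved
  s0 <- peak_separation(chi, beta_smoothed_profile(
    chi, lamella_model(0, 0, 0, 30), g))
  sb <- peak_separation(chi, beta_smoothed_profile(
    chi, lamella_model(0, 25, 0, 30), g))
  expect_equal(sb$separation, s0$separation, tolerance = 0.2)
  expect_equal(sort((sb$positions - 25) %% 360), sort(s0$positions),
               tolerance = 0.2)
})

test_that("alpha mirror symmetry holds pointwise", {
  g <- std_geometry()
  chi <- chi_grid_1deg()
  for (a in c(3, 7.5)) {
    lhs <- as.numeric(profile_closed(chi, lamella_model(-a, 0, 0, 40), g))
    rhs <- as.numeric(profile_closed(-chi, lamella_model(a, 0, 0, 40), g))
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("peak separation tracks the sign of gamma0", {
  g <- std_geometry()
  chi <- seq(0, 359.9, by = 0.1)
  sep <- function(g0) {
    peak_separation(chi, as.numeric(
      profile_closed(chi, lamella_model(0, 0, g0, 30), g)))$separation
  }
  expect_equal(sep(0), 180, tolerance = 1e-6)
  for (g0 in c(15, 40, 45, 75)) expect_lt(sep(g0), 180)
  for (g0 in c(-15, -40, -75)) expect_gt(sep(g0), 180)
})

test_that("peak width decreases as the fibril distribution broadens", {
  g <- std_geometry()
  chi <- seq(0, 359.75, by = 0.25)
  widths <- sapply(seq(20, 80, by = 10), function(dg) {
    pk <- detect_peaks(chi, beta_smoothed_profile(
      chi, lamella_model(0, 0, 0, dg), g), min_separation = 90)
    pk$width[1]
  })
  expect_true(all(diff(widths) < 0))
})
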