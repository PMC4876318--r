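test_that("pixel transform matches the exact flat-detector relations", {
  g <- std_geometry()
  ctr <- g$beam_centre
  # beam centre: q = 0, azimuth undefined
  at_ctr <- pixel_to_q(ctr[1], ctr[2], g)
  expect_equal(at_ctr$q, 0)
  expect_true(is.nan(at_ctr$chi))
  # straight above the centre: chi = 90
  expect_equal(pixel_to_q(ctr[1], ctr[2] + 50, g)$chi, 90)
  expect_equal(pixel_to_q(ctr[1] + 50, ctr[2], g)$chi, 0)
  # independent trigonometric evaluation of q(r)
  set.seed(8)
  px <- ctr[1] + stats::runif(20, -200, 200)
  py <- ctr[2] + stats::runif(20, -200, 200)
  got <- pixel_to_q(px, py, g)$q
  r <- sqrt((px - ctr[1])^2 + (py - ctr[2])^2) * g$pixel_size
  want <- 4 * pi / g$wavelength * sin(0.5 * atan(r / g$distance))
  expect_equal(got, want, tolerance = 1e-10)
  # missing calibration
  expect_error(pixel_to_q(1, 1, scattering_geometry(0.6888,
                                                    d_spacing = 4.6)),
               "configuration")
})

test_that("regrouping an isotropic ring gives a flat profile and
           conserves counts", {
  g <- std_geometry()
  ny <- 487L
  nx <- 619L
  px <- rep(seq_len(nx), each = ny)
  py <- rep(seq_len(ny), nx)
  qc <- pixel_to_q(px, py, g)
  mu <- 400 * exp(-((qc$q - g$q_ring) / 0.03)^2)
  set.seed(13)
  img <- detector_image(matrix(stats::rpois(length(mu), mu), ny, nx))
  prof <- azimuthal_regroup(img, g)
  expect_false(attr(prof, "sparse"))
  v <- prof$intensity[is.finite(prof$intensity)]
  expect_lt(stats::sd(v) / mean(v), 0.05)       # isotropy
  # exact count conservation over the annulus
  n_pix <- attr(prof, "n_pixels")
  sel <- qc$q >= g$q_ring - 0.05 & qc$q <= g$q_ring + 0.05 &
    is.finite(qc$chi)
  expect_equal(sum(prof$intensity * n_pix, na.rm = TRUE),
               sum(img$counts[cbind(py[sel], px[sel])]))
})

test_that("chi binning is rotation-consistent", {
  g <- std_geometry()
  m <- two_family_model(lamella_model(0, 0, 0, 60, 1))
  i0 <- render_image(m, g, peak_counts = 2e4, seed = 4)
  i1 <- render_image(two_family_model(lamella_model(0, 30, 0, 60, 1)), g,
                     peak_counts = 2e4, seed = 4)
  p0 <- azimuthal_regroup(i0, g)
  p1 <- azimuthal_regroup(i1, g)
  s0 <- peak_separation(p0$chi, p0$intensity)
  s1 <- peak_separation(p1$chi, p1$intensity)
  shift <- (s1$positions - s0$positions) %% 360
  expect_equal(shift, c(30, 30), tolerance = 1.5)
})

test_that("regrouped profiles match the generating model", {
  g <- std_geometry()
  m <- two_family_model(lamella_model(2, 8, 30, 50, 1),
                        lamella_model(0, -85, 0, 12, 0.3))
  img <- render_image(m, g, peak_counts = 1e5, seed = 7)
  prof <- azimuthal_regroup(img, g, background = "flanking")
  ref <- two_family_profile(prof$chi, m, g)
  a <- prof$intensity / max(prof$intensity, na.rm = TRUE)
  b <- ref / max(ref)
  ok <- is.finite(a)
  expect_lt(sqrt(sum((a[ok] - b[ok])^2) / sum(b[ok]^2)), 0.02)
})

test_that("regrouping rejects annuli the detector cannot see", {
  g <- chitin_geometry(beam_centre = c(25.5, 25.5))
  img <- detector_image(matrix(1, 50, 50))  # ring radius ~231 px: outside
  expect_error(azimuthal_regroup(img, g), "empty annulus")
  gg <- std_geometry()
  img2 <- detector_image(matrix(NA_real_, 487, 619))
  expect_error(azimuthal_regroup(img2, gg), "empty annulus")
  img3 <- detector_image(matrix(1, 487, 619))
  expect_error(azimuthal_regroup(img3, gg, q_lo = 2, q_hi = 3),
               "bracket")
})

test_that("frames round-trip through text and TIFF formats", {
  set.seed(21)
  counts <- matrix(stats::rpois(60 * 40, 300), 60, 40)
  counts[5, 7] <- NA            # masked pixel
  img <- detector_image(counts)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  save_image(img, tsv)
  back <- load_image(tsv)
  expect_identical(back$counts, counts)
  # TIFF (16-bit integers; masked pixels not representable -> drop mask)
  img2 <- detector_image(matrix(stats::rpois(60 * 40, 300), 60, 40))
  tif <- withr::local_tempfile(fileext = ".tif")
  save_image(img2, tif)
  back2 <- load_image(tif)
  expect_equal(back2$counts, img2$counts, ignore_attr = TRUE)
})

test_that("unreadable or unsupported frames give descriptive errors", {
  expect_error(load_image(file.path(tempdir(), "missing.tif")),
               "not found")
  edf <- withr::local_tempfile(fileext = ".edf")
  writeLines("x", edf)
  expect_error(load_image(edf), "EDF/HDF5")
  odd <- withr::local_tempfile(fileext = ".xyz")
  writeLines("x", odd)
  expect_error(load_image(odd), "unknown image format")
  expect_error(detector_image(matrix(-1, 2, 2)), "negative")
})
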