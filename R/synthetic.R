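# Synthetic-data generators: azimuthal profiles, 2D detector frames and
# scan grids with known ground truth and Poisson counting noise, so that
# every stage of the pipeline is testable without beamline data. The scan
# generator emulates a microfocus mesh scan across a telson carina:
# a 7 x 12 grid at 100 micrometre spacing by default, with the in-plane
# lamella tilt beta following the local surface curvature.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Simulate a noisy azimuthal profile with known ground truth
#'
#' Evaluates the two-family forward model on a uniform chi grid, rescales
#' it so the maximum expected value equals `peak_counts`, and draws
#' independent Poisson counts per bin. The generating model and the
#' applied rescaling factor are attached as attributes so recovery tests
#' can read the truth back machine-readably.
#'
#' @param model a [two_family_model()] (or a [lamella_model()], promoted
#'   to a single-family model).
#' @param geometry a [scattering_geometry()].
#' @param n_chi number of azimuth bins.
#' @param peak_counts expected counts at the profile maximum (> 0).
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @param delta_beta model convolution width, see
#'   [beta_smoothed_profile()].
#' @return an [azimuthal_profile()] with `sigma = sqrt(max(counts, 1))`
#'   and attributes `"truth"` (the rescaled generating
#'   [two_family_model()]) and `"noiseless"` (the expected counts).
#' @export
simulate_profile <- function(model, geometry, n_chi = 360L,
                             peak_counts = 1e4, seed = NULL,
                             delta_beta = 5) {
  if (inherits(model, "lamella_model")) {
    model <- two_family_model(model)
  }
  stopifnot(inherits(model, "two_family_model"))
  if (peak_counts <= 0) stop("peak_counts must be > 0", call. = FALSE)
  chi <- (seq_len(n_chi) - 0.5) * 360 / n_chi
  mu <- two_family_profile(chi, model, geometry, delta_beta = delta_beta)
  fac <- peak_counts / max(mu)
  mu <- mu * fac
  counts <- .with_seed(seed, stats::rpois(n_chi, mu))
  prof <- azimuthal_profile(chi, counts, sqrt(pmax(counts, 1)))
  truth <- model
  truth$ip$scale <- model$ip$scale * fac
  truth$op$scale <- model$op$scale * fac
  truth$background <- model$background * fac
  attr(prof, "truth") <- truth
  attr(prof, "noiseless") <- mu
  prof
}

#' Render a synthetic 2D detector frame
#'
#' Per-pixel expected counts are the azimuthal forward model evaluated at
#' the pixel's azimuth, modulated by a radially Gaussian ring profile
#' `exp(-(q - q_ring)^2 / ring_width^2)`, plus a uniform background;
#' counts are Poisson-sampled. Geometry must carry the full detector
#' calibration.
#'
#' @param model a [two_family_model()] or [lamella_model()].
#' @param geometry a fully calibrated [scattering_geometry()].
#' @param shape image dimensions `c(ny, nx)` in pixels (Pilatus-class
#'   default).
#' @param ring_width radial Gaussian width in inverse Angstrom.
#' @param peak_counts expected counts at the brightest ring pixel;
#'   0 yields an all-zero frame.
#' @param flat_background uniform expected background counts per pixel.
#' @param seed integer seed.
#' @param delta_beta model convolution width.
#' @return a [detector_image()] with the generating model in
#'   `metadata$truth`.
#' @export
render_image <- function(model, geometry, shape = c(487L, 619L),
                         ring_width = 0.03, peak_counts = 1e3,
                         flat_background = 0, seed = NULL,
                         delta_beta = 5) {
  if (inherits(model, "lamella_model")) model <- two_family_model(model)
  stopifnot(inherits(model, "two_family_model"))
  geometry <- .full_geometry(geometry)
  if (peak_counts < 0) stop("peak_counts must be >= 0", call. = FALSE)
  ny <- shape[1]
  nx <- shape[2]
  px <- rep(seq_len(nx), each = ny)
  py <- rep(seq_len(ny), nx)
  qc <- pixel_to_q(px, py, geometry)
  # azimuthal factor from a fine lookup (pixels share the chi resolution
  # of the model's internal grid)
  chi_grid <- seq(0, 359.75, by = 0.25)
  prof <- two_family_profile(chi_grid, model, geometry,
                             delta_beta = delta_beta)
  idx <- (round((qc$chi %% 360) / 0.25) %% length(chi_grid)) + 1L
  az <- prof[idx]
  az[!is.finite(qc$chi)] <- mean(prof)
  radial <- exp(-((qc$q - geometry$q_ring) / ring_width)^2)
  mu <- az * radial
  if (peak_counts > 0 && max(mu) > 0) {
    mu <- mu * peak_counts / max(mu)
  } else {
    mu <- mu * 0
  }
  mu <- mu + flat_background
  counts <- .with_seed(seed, stats::rpois(length(mu), mu))
  detector_image(matrix(counts, ny, nx),
                 pixel_size = geometry$pixel_size,
                 beam_centre = geometry$beam_centre,
                 metadata = list(truth = model, ring_width = ring_width,
                                 peak_counts = peak_counts))
}

#' Parameter field for a mesh scan across a curved carina
#'
#' Builds a table of per-point ground-truth models on a regular grid,
#' with the in-plane beta tilt varying linearly along the horizontal
#' axis (the lamellae follow the local surface curvature: positive beta
#' on the left of the ridge centreline, negative on the right) and all
#' other parameters constant.
#'
#' @param nx,ny grid dimensions (defaults emulate a 7 x 12 mesh).
#' @param spacing_mm grid spacing in mm (100 micrometres by default).
#' @param beta_span IP beta at the left and right grid edges, degrees.
#' @param ip,op template [lamella_model()]s (the IP beta is overwritten
#'   by the gradient).
#' @param background constant background level.
#' @return data frame with columns `x_mm`, `y_mm` and one column per
#'   model parameter (`ip_alpha`, ..., `op_scale`, `background`).
#' @export
carina_param_field <- function(nx = 7L, ny = 12L, spacing_mm = 0.1,
                               beta_span = c(17.5, -15.1),
                               ip = lamella_model(1, 0, -40, 75, 0.66),
                               op = lamella_model(0, -81, 75, 10.1, 0.34),
                               background = 0) {
  grid <- expand.grid(ix = seq_len(nx), iy = seq_len(ny),
                      KEEP.OUT.ATTRS = FALSE)
  frac <- if (nx > 1L) (grid$ix - 1) / (nx - 1) else 0.5
  data.frame(x_mm = (grid$ix - 1) * spacing_mm,
             y_mm = (grid$iy - 1) * spacing_mm,
             ip_alpha = ip$alpha,
             ip_beta = beta_span[1] + frac * diff(beta_span),
             ip_gamma0 = ip$distribution$gamma0,
             ip_dgamma0 = ip$distribution$dgamma0,
             ip_scale = ip$scale,
             op_alpha = op$alpha, op_beta = op$beta,
             op_gamma0 = op$distribution$gamma0,
             op_dgamma0 = op$distribution$dgamma0,
             op_scale = op$scale,
             background = background)
}

.model_from_row <- function(row) {
  two_family_model(
    lamella_model(row$ip_alpha, row$ip_beta, row$ip_gamma0,
                  row$ip_dgamma0, row$ip_scale),
    lamella_model(row$op_alpha, row$op_beta, row$op_gamma0,
                  row$op_dgamma0, row$op_scale),
    background = row$background)
}

#' Simulate a scan-grid dataset
#'
#' Generates one profile (or detector frame) per grid point of a
#' parameter field, with independent Poisson noise, and returns a scan
#' object carrying the machine-readable ground truth. Optionally writes
#' the dataset to a directory: a `manifest.tsv` (point id, position,
#' file), one profile/frame file per point, the ground truth as
#' `truth.tsv` and the geometry as `geometry.txt`.
#'
#' @param param_field data frame as from [carina_param_field()]: columns
#'   `x_mm`, `y_mm` plus the model parameter columns. Positions must be
#'   unique.
#' @param geometry a [scattering_geometry()].
#' @param kind `"profile"` (default) or `"image"`.
#' @param n_chi,peak_counts,delta_beta,shape,ring_width see
#'   [simulate_profile()] and [render_image()].
#' @param seed integer seed for the whole scan (per-point streams are
#'   derived deterministically).
#' @param dir optional output directory.
#' @return an object of class `waxd_scan`: list with `points` (the
#'   parameter field), `kind`, `geometry`, and `profiles` or `images`.
#' @export
simulate_scan <- function(param_field, geometry,
                          kind = c("profile", "image"), n_chi = 360L,
                          peak_counts = 1e4, delta_beta = 5,
                          shape = c(487L, 619L), ring_width = 0.03,
                          seed = 1L, dir = NULL) {
  kind <- match.arg(kind)
  stopifnot(nrow(param_field) >= 1L)
  if (anyDuplicated(param_field[, c("x_mm", "y_mm")])) {
    stop("duplicate scan positions in param_field", call. = FALSE)
  }
  n <- nrow(param_field)
  items <- vector("list", n)
  for (i in seq_len(n)) {
    m <- .model_from_row(param_field[i, ])
    pt_seed <- if (is.null(seed)) NULL else (seed + i * 7919L) %% .Machine$integer.max
    items[[i]] <- if (kind == "profile") {
      simulate_profile(m, geometry, n_chi, peak_counts, pt_seed,
                       delta_beta)
    } else {
      render_image(m, geometry, shape, ring_width, peak_counts,
                   seed = pt_seed, delta_beta = delta_beta)
    }
  }
  scan <- structure(list(points = param_field, kind = kind,
                         geometry = geometry), class = "waxd_scan")
  if (kind == "profile") scan$profiles <- items else scan$images <- items
  if (!is.null(dir)) write_scan(scan, dir)
  scan
}

#' @export
print.waxd_scan <- function(x, ...) {
  cat(sprintf("WAXD scan: %d points (%s data)\n", nrow(x$points), x$kind))
  invisible(x)
}

#' Write / read a scan dataset directory
#'
#' Layout: `manifest.tsv` (columns `id`, `x_mm`, `y_mm`, `file`), one
#' data file per point, `truth.tsv` with the generating parameters when
#' known, and `geometry.txt`.
#'
#' @param scan a `waxd_scan`.
#' @param dir directory path.
#' @return `read_scan` returns a `waxd_scan` (without ground truth if no
#'   `truth.tsv` is present).
#' @export
write_scan <- function(scan, dir) {
  stopifnot(inherits(scan, "waxd_scan"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- nrow(scan$points)
  ext <- if (scan$kind == "profile") "tsv" else "tif"
  files <- sprintf("point_%03d.%s", seq_len(n), ext)
  for (i in seq_len(n)) {
    pth <- file.path(dir, files[i])
    if (scan$kind == "profile") {
      write_profile(scan$profiles[[i]], pth)
    } else {
      save_image(scan$images[[i]], pth)
    }
  }
  manifest <- data.frame(id = seq_len(n), x_mm = scan$points$x_mm,
                         y_mm = scan$points$y_mm, file = files)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(scan$points, file.path(dir, "truth.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  write_geometry(scan$geometry, file.path(dir, "geometry.txt"))
  invisible(dir)
}

#' @rdname write_scan
#' @export
read_scan <- function(dir) {
  man_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(man_path)) {
    stop("not a scan directory (no manifest.tsv): ", dir, call. = FALSE)
  }
  manifest <- utils::read.delim(man_path)
  geometry <- read_geometry(file.path(dir, "geometry.txt"))
  files <- file.path(dir, manifest$file)
  is_img <- grepl("\\.tiff?$", manifest$file, ignore.case = TRUE)
  kind <- if (any(is_img)) "image" else "profile"
  items <- lapply(seq_along(files), function(i) {
    if (kind == "profile") read_profile(files[i]) else load_image(files[i])
  })
  truth_path <- file.path(dir, "truth.tsv")
  points <- if (file.exists(truth_path)) {
    utils::read.delim(truth_path)
  } else {
    manifest[, c("x_mm", "y_mm")]
  }
  scan <- structure(list(points = points, kind = kind,
                         geometry = geometry), class = "waxd_scan")
  if (kind == "profile") scan$profiles <- items else scan$images <- items
  scan
}
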