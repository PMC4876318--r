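# Detector frames: containers, TIFF / plain-text I/O, the flat-detector
# pixel -> (q, chi) transform, and cake-style azimuthal regrouping around
# the ring under analysis.
#
# Image convention: counts[row, col] with row = py counted from the BOTTOM
# of the detector (py increases upward, along +y_L) and col = px
# (horizontal, along +z_L). Masked pixels are NA.

#' Detector image container
#'
#' @param counts numeric matrix of photon counts; `NA` marks masked
#'   pixels, all finite values must be non-negative. Rows index the
#'   vertical detector axis from the bottom.
#' @param pixel_size pixel edge in mm (optional; may come from the
#'   geometry instead).
#' @param beam_centre optional `(px, py)` beam centre in pixels.
#' @param metadata free-form list (exposure, scan position, ...).
#' @return an object of class `detector_image`.
#' @export
detector_image <- function(counts, pixel_size = NA_real_,
                           beam_centre = NULL, metadata = list()) {
  stopifnot(is.matrix(counts))
  if (any(counts < 0, na.rm = TRUE)) {
    stop("invalid image: negative counts (use NA for masked pixels)",
         call. = FALSE)
  }
  structure(list(counts = counts, pixel_size = pixel_size,
                 beam_centre = beam_centre, metadata = metadata),
            class = "detector_image")
}

#' @export
print.detector_image <- function(x, ...) {
  cat(sprintf("Detector image: %d x %d px, %d masked, total %.4g counts\n",
              nrow(x$counts), ncol(x$counts), sum(is.na(x$counts)),
              sum(x$counts, na.rm = TRUE)))
  invisible(x)
}

#' Load a detector frame
#'
#' Supported formats: TIFF (`.tif`/`.tiff`, read with the tiff package;
#' 16-bit unsigned counts) and plain-text matrices (`.tsv`/`.txt`/`.dat`/
#' `.csv`, whitespace- or comma-separated counts, `NA` for masked
#' pixels). Files store the frame top row first (image convention); rows
#' are flipped on read so that row 1 of the in-memory matrix is the
#' detector bottom.
#'
#' @param path file path.
#' @param pixel_size,beam_centre,metadata forwarded to
#'   [detector_image()].
#' @return a [detector_image()].
#' @export
load_image <- function(path, pixel_size = NA_real_, beam_centre = NULL,
                       metadata = list()) {
  if (!file.exists(path)) {
    stop("image file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    m <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    counts <- m[rev(seq_len(nrow(m))), , drop = FALSE]  # row 1 = bottom
  } else if (ext %in% c("tsv", "txt", "dat", "csv")) {
    sep <- if (ext == "csv") "," else ""
    m <- as.matrix(utils::read.table(path, header = FALSE, sep = sep))
    dimnames(m) <- NULL
    counts <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  } else if (ext %in% c("edf", "h5", "hdf5", "nxs")) {
    stop("unsupported image format '.", ext, "': no reader for EDF/HDF5 ",
         "frames is available in this build; convert frames to TIFF or ",
         "plain-text TSV", call. = FALSE)
  } else {
    stop("unknown image format '.", ext, "' (supported: .tif/.tiff, ",
         ".tsv/.txt/.dat/.csv)", call. = FALSE)
  }
  if (!is.numeric(counts)) stop("corrupt image file: ", path, call. = FALSE)
  detector_image(counts, pixel_size, beam_centre, metadata)
}

#' Save a detector frame
#'
#' TIFF frames are written as 16-bit unsigned integers (counts above
#' 65535 are clamped); plain-text frames preserve counts exactly.
#'
#' @param image a [detector_image()].
#' @param path output path; format chosen from the extension.
#' @export
save_image <- function(image, path) {
  stopifnot(inherits(image, "detector_image"))
  ext <- tolower(tools::file_ext(path))
  m <- image$counts[rev(seq_len(nrow(image$counts))), , drop = FALSE]
  if (ext %in% c("tif", "tiff")) {
    mm <- pmin(round(m), 65535L)
    mm[is.na(mm)] <- 65535L
    tiff::writeTIFF(mm / 65535, path, bits.per.sample = 16L)
  } else if (ext %in% c("tsv", "txt", "dat")) {
    utils::write.table(m, path, sep = "\t", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  } else {
    stop("unknown image format '.", ext, "' (supported: .tif/.tiff, ",
         ".tsv/.txt/.dat)", call. = FALSE)
  }
  invisible(path)
}

.full_geometry <- function(geometry) {
  if (!is.finite(geometry$distance) || !is.finite(geometry$pixel_size) ||
      !all(is.finite(geometry$beam_centre))) {
    stop("configuration error: geometry needs distance, beam_centre and ",
         "pixel_size for detector transforms", call. = FALSE)
  }
  geometry
}

#' Flat-detector pixel to (q, chi) transform
#'
#' Exact transform: the scattering angle follows from
#' `tan(2 theta) = r / distance` with `r` the radial distance of the
#' pixel from the beam centre, `q = (4 pi / lambda) sin(theta)`, and the
#' azimuth is `atan2(py - cy, px - cx)` (chi = 0 horizontal, 90 deg
#' vertically up). The beam-centre pixel has q = 0 and undefined chi
#' (`NaN`).
#'
#' @param px,py pixel coordinates (may be vectors); `py` counts from the
#'   detector bottom.
#' @param geometry a fully calibrated [scattering_geometry()].
#' @return list with components `q` (inverse Angstrom) and `chi`
#'   (degrees in `[0, 360)`).
#' @export
pixel_to_q <- function(px, py, geometry) {
  geometry <- .full_geometry(geometry)
  dx <- (px - geometry$beam_centre[1]) * geometry$pixel_size
  dy <- (py - geometry$beam_centre[2]) * geometry$pixel_size
  r <- sqrt(dx^2 + dy^2)
  two_theta <- atan(r / geometry$distance)
  q <- 4 * pi / geometry$wavelength * sin(two_theta / 2)
  chi <- ifelse(r == 0, NaN, (atan2(dy, dx) / .DEG) %% 360)
  list(q = q, chi = chi)
}

#' Cake-style azimuthal regrouping of a detector frame
#'
#' Bins unmasked pixels of the radial annulus `[q_lo, q_hi]` into `n_chi`
#' equal azimuth bins and returns the mean counts per bin (an azimuthal
#' intensity profile of the ring). Optional local background subtraction
#' estimates, per chi bin, the mean counts in two flanking annuli of
#' equal radial width and subtracts their average.
#'
#' @param image a [detector_image()].
#' @param geometry a fully calibrated [scattering_geometry()];
#'   `q_lo < q_ring < q_hi` is required.
#' @param q_lo,q_hi radial annulus bounds in inverse Angstrom; default a
#'   half-width of 0.05 around `q_ring`.
#' @param n_chi number of azimuth bins (>= 36).
#' @param background `"none"` or `"flanking"`.
#' @return an [azimuthal_profile()] at bin centres, with `sigma` the
#'   Poisson standard error of each bin mean, attribute `"n_pixels"`
#'   (pixels per bin; empty bins give `NA` intensity) and attribute
#'   `"sparse"` set `TRUE` when more than half the bins are empty.
#' @export
azimuthal_regroup <- function(image, geometry, q_lo = NULL, q_hi = NULL,
                              n_chi = 360L, background = c("none",
                                                           "flanking")) {
  stopifnot(inherits(image, "detector_image"))
  background <- match.arg(background)
  geometry <- .full_geometry(geometry)
  if (is.null(q_lo)) q_lo <- geometry$q_ring - 0.05
  if (is.null(q_hi)) q_hi <- geometry$q_ring + 0.05
  if (!(q_lo < geometry$q_ring && geometry$q_ring < q_hi)) {
    stop("annulus [q_lo, q_hi] must bracket q_ring", call. = FALSE)
  }
  if (n_chi < 36L) stop("n_chi must be at least 36", call. = FALSE)
  cnt <- image$counts
  px <- matrix(rep(seq_len(ncol(cnt)), each = nrow(cnt)), nrow(cnt))
  py <- matrix(rep(seq_len(nrow(cnt)), ncol(cnt)), nrow(cnt))
  qc <- pixel_to_q(as.numeric(px), as.numeric(py), geometry)
  v <- as.numeric(cnt)
  ok <- is.finite(v)
  bin_means <- function(lo, hi) {
    sel <- ok & qc$q >= lo & qc$q <= hi & is.finite(qc$chi)
    if (!any(sel)) return(NULL)
    b <- pmin(floor(qc$chi[sel] / (360 / n_chi)) + 1L, n_chi)
    n <- tabulate(b, n_chi)
    sums <- numeric(n_chi)
    sums[sort(unique(b))] <- as.numeric(rowsum(v[sel], b))  # rowsum sorts
    list(n = n, sum = sums)
  }
  ann <- bin_means(q_lo, q_hi)
  if (is.null(ann)) stop("empty annulus: no unmasked pixels in [q_lo, ",
                         "q_hi]", call. = FALSE)
  mean_ann <- ifelse(ann$n > 0, ann$sum / ann$n, NA_real_)
  intensity <- mean_ann
  if (background == "flanking") {
    w <- q_hi - q_lo
    inner <- bin_means(q_lo - w, q_lo)
    outer <- bin_means(q_hi, q_hi + w)
    bg <- rep(0, n_chi)
    if (!is.null(inner) || !is.null(outer)) {
      bi <- if (!is.null(inner)) ifelse(inner$n > 0, inner$sum / inner$n,
                                        NA_real_) else rep(NA_real_, n_chi)
      bo <- if (!is.null(outer)) ifelse(outer$n > 0, outer$sum / outer$n,
                                        NA_real_) else rep(NA_real_, n_chi)
      bg <- rowMeans(cbind(bi, bo), na.rm = TRUE)
      bg[is.nan(bg)] <- 0
    }
    intensity <- pmax(mean_ann - bg, 0)
  }
  sigma <- ifelse(ann$n > 0 & is.finite(mean_ann),
                  sqrt(pmax(mean_ann, 1) / pmax(ann$n, 1)), NA_real_)
  chi <- (seq_len(n_chi) - 0.5) * 360 / n_chi
  prof <- azimuthal_profile(chi, intensity, sigma)
  attr(prof, "n_pixels") <- ann$n
  attr(prof, "sparse") <- mean(ann$n == 0) > 0.5
  prof
}
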