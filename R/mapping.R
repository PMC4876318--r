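# Batch fitting of scan grids and export of fibre-orientation maps
# (per-point lamella parameters and renderable glyph descriptions).

#' Fit every point of a scan grid
#'
#' Produces one row per grid point with the fitted 3D orientation
#' parameters of both families, the out-of-plane scale fraction and fit
#' diagnostics. Image scans are regrouped into azimuthal profiles first.
#' Points whose fit fails are flagged (with the error message) but kept,
#' so the map stays aligned with the grid; the call errors only if every
#' point fails. Per-point fits are independent (no spatial
#' regularization); `warm_start = TRUE` optionally seeds each fit's
#' gamma0 multistart from the previous point's solution.
#'
#' @param scan a `waxd_scan` (from [simulate_scan()] or [read_scan()]),
#'   or a directory path.
#' @param geometry a [scattering_geometry()]; defaults to the scan's.
#' @param config a [fit_config()].
#' @param q_window radial half-width for regrouping image scans
#'   (inverse Angstrom).
#' @param n_chi azimuth bins for regrouping image scans.
#' @param warm_start seed each point from its predecessor (off by
#'   default).
#' @return data frame of class `orientation_map`: `x_mm`, `y_mm`, the
#'   per-family parameters (`ip_alpha` ... `op_dgamma0`), `lambda1_frac`,
#'   `lambda2_frac`, `background`, `rss`, `red_chisq`, `converged`,
#'   `ok`, `flags`.
#' @export
fit_scan <- function(scan, geometry = NULL, config = fit_config(),
                     q_window = 0.05, n_chi = 360L, warm_start = FALSE) {
  if (is.character(scan)) scan <- read_scan(scan)
  stopifnot(inherits(scan, "waxd_scan"))
  if (is.null(geometry)) geometry <- scan$geometry
  n <- nrow(scan$points)
  if (n < 1L) stop("scan has no points", call. = FALSE)
  rows <- vector("list", n)
  prev <- NULL
  for (i in seq_len(n)) {
    row <- tryCatch({
      prof <- if (scan$kind == "profile") {
        scan$profiles[[i]]
      } else {
        azimuthal_regroup(scan$images[[i]], geometry,
                          geometry$q_ring - q_window,
                          geometry$q_ring + q_window, n_chi)
      }
      cfg <- config
      if (warm_start && !is.null(prev)) cfg$seed_hint <- prev$par
      fit <- fit_profile(prof, geometry, cfg)
      prev <- fit
      cbind(data.frame(x_mm = scan$points$x_mm[i],
                       y_mm = scan$points$y_mm[i]),
            fit_result_row(fit), ok = TRUE)
    }, error = function(e) {
      data.frame(x_mm = scan$points$x_mm[i], y_mm = scan$points$y_mm[i],
                 ip_alpha = NA_real_, ip_beta = NA_real_,
                 ip_gamma0 = NA_real_, ip_dgamma0 = NA_real_,
                 lambda1_frac = NA_real_, op_alpha = NA_real_,
                 op_beta = NA_real_, op_gamma0 = NA_real_,
                 op_dgamma0 = NA_real_, lambda2_frac = NA_real_,
                 background = NA_real_, rss = NA_real_,
                 red_chisq = NA_real_, converged = FALSE,
                 flags = paste("fit failed:", conditionMessage(e)),
                 ok = FALSE)
    })
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  if (!any(out$ok)) {
    stop("all scan points failed to fit", call. = FALSE)
  }
  class(out) <- c("orientation_map", "data.frame")
  out
}

#' Export an orientation map (and optional lamella glyphs)
#'
#' Writes the map as a delimited table. With `glyphs = TRUE` an
#' additional structured text file describes one lamella glyph per
#' fitted point for external 3D renderers: glyph centre, lamella-plane
#' normal and principal in-plane fibre direction as laboratory-frame
#' unit vectors derived from (alpha, beta, gamma0), and a glyph width
#' proportional to dgamma0.
#'
#' @param map an `orientation_map` from [fit_scan()].
#' @param path output table path.
#' @param format `"tsv"` or `"csv"`.
#' @param glyphs write a glyph mesh file next to the table
#'   (`<path>.glyphs.txt`).
#' @return invisibly, the written path(s).
#' @export
export_map <- function(map, path, format = c("tsv", "csv"),
                       glyphs = FALSE) {
  if (!is.data.frame(map) || nrow(map) == 0L) {
    stop("empty map: nothing to export", call. = FALSE)
  }
  if (!is.character(format) || !all(format %in% c("tsv", "csv"))) {
    stop("unknown format: supported formats are 'tsv' and 'csv'",
         call. = FALSE)
  }
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  utils::write.table(map, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  written <- path
  if (glyphs) {
    gpath <- paste0(path, ".glyphs.txt")
    ok <- map[map$ok %in% TRUE, , drop = FALSE]
    lines <- c("# lamella glyphs: one per fitted scan point",
               paste("# x_mm y_mm z_mm nx ny nz dx dy dz",
                     "width_deg op_fraction"))
    for (i in seq_len(nrow(ok))) {
      a <- ok$ip_alpha[i]
      b <- ok$ip_beta[i]
      g0 <- ok$ip_gamma0[i]
      nrm <- body_to_lab(c(0, 1, 0), a, b)       # lamella-plane normal
      dirv <- body_to_lab(c(cos(g0 * .DEG), 0, -sin(g0 * .DEG)), a, b)
      lines <- c(lines, paste(
        format(c(ok$x_mm[i], ok$y_mm[i], 0,
                 nrm[1, ], dirv[1, ],
                 ok$ip_dgamma0[i], ok$lambda2_frac[i]),
               digits = 8, trim = TRUE), collapse = " "))
    }
    writeLines(lines, gpath)
    written <- c(written, gpath)
  }
  invisible(written)
}

#' @rdname export_map
#' @export
read_map <- function(path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  df <- utils::read.delim(path, sep = if (format == "tsv") "\t" else ",")
  class(df) <- c("orientation_map", "data.frame")
  df
}
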