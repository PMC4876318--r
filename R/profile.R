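# Azimuthal profile container, text I/O and circular peak analysis.

#' Sampled azimuthal intensity profile I(chi)
#'
#' @param chi azimuths in degrees, strictly increasing, spanning at most
#'   360 degrees.
#' @param intensity counts per bin (non-negative; `NA` marks missing bins,
#'   e.g. chi ranges shadowed by detector gaps).
#' @param sigma optional positive count uncertainties.
#' @return an object of class `azimuthal_profile` (also a data frame).
#' @export
azimuthal_profile <- function(chi, intensity, sigma = NULL) {
  stopifnot(is.numeric(chi), is.numeric(intensity),
            length(chi) == length(intensity))
  if (any(diff(chi) <= 0)) {
    stop("invalid profile: chi must be strictly increasing", call. = FALSE)
  }
  if (max(chi) - min(chi) > 360) {
    stop("invalid profile: chi spans more than 360 degrees", call. = FALSE)
  }
  if (any(intensity < 0, na.rm = TRUE)) {
    stop("invalid profile: negative intensities", call. = FALSE)
  }
  if (!is.null(sigma)) {
    stopifnot(length(sigma) == length(chi))
    if (any(sigma <= 0, na.rm = TRUE)) {
      stop("invalid profile: sigma must be positive", call. = FALSE)
    }
  }
  df <- data.frame(chi = as.numeric(chi), intensity = as.numeric(intensity))
  if (!is.null(sigma)) df$sigma <- as.numeric(sigma)
  class(df) <- c("azimuthal_profile", "data.frame")
  df
}

#' @export
print.azimuthal_profile <- function(x, ...) {
  cat(sprintf("Azimuthal profile: %d samples, chi in [%g, %g] deg\n",
              nrow(x), min(x$chi), max(x$chi)))
  invisible(x)
}

#' Read / write azimuthal profiles as delimited text
#'
#' Two columns `chi_deg` and `intensity`, optional third column `sigma`,
#' tab-separated with a header line.
#'
#' @param path file path.
#' @return `read_profile` returns an [azimuthal_profile()].
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop("profile file not found: ", path,
                               call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE)
  if (ncol(df) < 2) stop("profile file needs at least two columns: ", path,
                         call. = FALSE)
  azimuthal_profile(df[[1]], df[[2]],
                    sigma = if (ncol(df) >= 3) df[[3]] else NULL)
}

#' @rdname read_profile
#' @param profile an [azimuthal_profile()] to write.
#' @export
write_profile <- function(profile, path) {
  df <- data.frame(chi_deg = profile$chi, intensity = profile$intensity)
  if (!is.null(profile$sigma)) df$sigma <- profile$sigma
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# minimal signed circular difference a - b in (-period/2, period/2]
circ_diff <- function(a, b, period = 360) {
  d <- (a - b) %% period
  ifelse(d > period / 2, d - period, d)
}

# weighted circular mean of angles (degrees)
circ_mean <- function(x, w = rep(1, length(x)), period = 360) {
  th <- x * 2 * pi / period
  (atan2(sum(w * sin(th)), sum(w * cos(th))) * period / (2 * pi)) %% period
}

# Quadratic (parabolic) sub-bin refinement of a local maximum at index i
# of a circular series. Returns the refined position in chi units.
quad_refine <- function(chi, y, i) {
  n <- length(y)
  im <- if (i == 1L) n else i - 1L
  ip <- if (i == n) 1L else i + 1L
  y0 <- y[im]; y1 <- y[i]; y2 <- y[ip]
  denom <- y0 - 2 * y1 + y2
  frac <- if (abs(denom) < .Machine$double.eps * max(abs(c(y0, y1, y2)), 1)) {
    0
  } else {
    0.5 * (y0 - y2) / denom
  }
  frac <- max(-0.5, min(0.5, frac))
  step <- (max(chi) - min(chi)) / (length(chi) - 1L)
  h <- y1 - 0.25 * (y0 - y2) * frac
  list(position = (chi[i] + frac * step) %% 360, height = h)
}

# Outer-half-maximum width of a lobe: within +/- window of `position`, the
# circular span between the first and last sample at or above half the
# lobe height (interior dips below half, as in the horned limiting
# profile, are bridged).
lobe_width <- function(chi, y, position, height, window = 90) {
  rel <- circ_diff(chi, position)
  sel <- abs(rel) <= window
  rel <- rel[sel]
  ys <- y[sel]
  above <- which(ys >= height / 2)
  if (length(above) == 0L) return(0)
  max(rel[above]) - min(rel[above])
}

#' Detect peaks of a circular azimuthal profile
#'
#' Finds local maxima above a prominence threshold (fraction of the
#' intensity range above the minimum), with wrap-around handling at the
#' 0/360 seam, then merges maxima closer than `min_separation` into one
#' peak — so that the fine double-horn structure the limiting profile
#' develops near the vertical counts as a single lobe. A merged peak's
#' position is the height-weighted circular centroid of its member maxima
#' (exactly the lobe midline for a symmetric pair); a solitary maximum is
#' refined by quadratic sub-bin interpolation. Widths are outer
#' half-maximum widths.
#'
#' @param profile an [azimuthal_profile()], or a numeric vector of
#'   azimuths when `intensity` is given separately.
#' @param intensity intensities if `profile` is a plain chi vector.
#' @param prominence threshold as a fraction of the intensity range.
#' @param min_separation merge radius in degrees.
#' @return data frame with columns `position`, `height`, `width`,
#'   `n_members`, sorted by decreasing height; zero rows if the profile
#'   is flat or no maximum passes the threshold.
#' @export
detect_peaks <- function(profile, intensity = NULL, prominence = 0.05,
                         min_separation = 30) {
  if (inherits(profile, "azimuthal_profile") || is.data.frame(profile)) {
    chi <- profile$chi
    y <- profile$intensity
  } else {
    chi <- profile
    y <- intensity
  }
  keep <- is.finite(y)
  chi <- chi[keep]
  y <- y[keep]
  n <- length(y)
  empty <- data.frame(position = numeric(0), height = numeric(0),
                      width = numeric(0), n_members = integer(0))
  if (n < 5L) return(empty)
  rng <- max(y) - min(y)
  if (rng <= 0) return(empty)
  yl <- y[c(n, seq_len(n - 1L))]
  yr <- y[c(seq.int(2L, n), 1L)]
  cand <- which(y > yl & y >= yr & y >= min(y) + prominence * rng)
  if (length(cand) == 0L) return(empty)
  # cluster candidates, tallest first
  cand <- cand[order(y[cand], decreasing = TRUE)]
  reps <- integer(0)          # cluster representative indices
  members <- list()
  for (i in cand) {
    if (length(reps) > 0L) {
      d <- abs(circ_diff(chi[i], chi[reps]))
      j <- which.min(d)
      if (d[j] < min_separation) {
        members[[j]] <- c(members[[j]], i)
        next
      }
    }
    reps <- c(reps, i)
    members[[length(reps)]] <- i
  }
  pos <- numeric(length(reps))
  hgt <- numeric(length(reps))
  wid <- numeric(length(reps))
  nm <- integer(length(reps))
  for (j in seq_along(reps)) {
    mem <- members[[j]]
    nm[j] <- length(mem)
    if (length(mem) == 1L) {
      r <- quad_refine(chi, y, mem)
      pos[j] <- r$position
      hgt[j] <- r$height
    } else {
      # centre angles on the representative before averaging
      rel <- circ_diff(chi[mem], chi[reps[j]])
      pos[j] <- (chi[reps[j]] +
                   sum(y[mem] * rel) / sum(y[mem])) %% 360
      hgt[j] <- max(y[mem])
    }
    wid[j] <- lobe_width(chi, y, pos[j],
                         hgt[j], window = max(min_separation, 90))
  }
  out <- data.frame(position = pos, height = hgt, width = wid,
                    n_members = nm)
  out[order(out$height, decreasing = TRUE), , drop = FALSE]
}

#' Separation of the two dominant lobes of a profile
#'
#' Detects peaks with a wide merge radius (so each diffraction lobe counts
#' once), keeps the two highest, and returns their circular distance
#' measured from the lower-chi lobe to the higher-chi lobe through
#' increasing chi, together with positions and heights.
#'
#' @param profile an [azimuthal_profile()] or chi vector.
#' @param intensity see [detect_peaks()].
#' @param min_separation merge radius in degrees.
#' @return list with `separation` (degrees), `positions` (increasing chi)
#'   and `heights`; errors if fewer than two lobes are found.
#' @export
peak_separation <- function(profile, intensity = NULL, min_separation = 90) {
  pk <- detect_peaks(profile, intensity, min_separation = min_separation)
  if (nrow(pk) < 2L) {
    stop("fewer than two lobes found in profile", call. = FALSE)
  }
  pk <- pk[1:2, ]
  o <- order(pk$position)
  pk <- pk[o, ]
  list(separation = (pk$position[2] - pk$position[1]) %% 360,
       positions = pk$position, heights = pk$height)
}
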