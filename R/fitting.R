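# Nonlinear estimation of two-family 3D orientation parameters from a
# measured azimuthal profile: peak-based initialization, multistart
# Levenberg-Marquardt (minpack.lm) on the beta-convolved closed form, and
# a coarse exhaustive grid search used as a slow cross-check oracle.

#' Fitting configuration
#'
#' Bounds and controls for [fit_profile()]. Angle bounds reflect the
#' physical roles of the families: in-plane (IP) lamellae are close to the
#' cuticle surface (|beta| <= 45 deg) while out-of-plane (OP) fibres run
#' along the pore canals (60 <= |beta| <= 90 deg, explored as two sign
#' branches). gamma0 is optimised on a wider box and reported wrapped to
#' (-90, 90] (gamma0 and gamma0 + 180 are the same fibril direction).
#'
#' @param alpha_max bound on |alpha| in degrees.
#' @param ip_beta_max bound on IP |beta| in degrees.
#' @param op_beta_abs length-2, allowed range of OP |beta| in degrees.
#' @param dgamma0_range length-2, allowed range of dgamma0 in degrees.
#' @param n_families 1 or 2 fibre families.
#' @param n_starts number of gamma0 multistart seeds.
#' @param max_lm_starts number of most promising starts refined by
#'   Levenberg-Marquardt.
#' @param delta_beta,n_kernel beta-convolution settings of the model, see
#'   [beta_smoothed_profile()].
#' @param maxiter,ftol,ptol Levenberg-Marquardt controls.
#' @param prominence peak-detection prominence used by the initializer.
#' @param seed integer seed fixed at the start of every fit (the fit path
#'   itself is deterministic; the seed makes any downstream resampling by
#'   callers reproducible).
#' @return an object of class `fit_config`.
#' @export
fit_config <- function(alpha_max = 30, ip_beta_max = 45,
                       op_beta_abs = c(60, 90), dgamma0_range = c(3, 90),
                       n_families = 2L, n_starts = 8L, max_lm_starts = 8L,
                       delta_beta = 5, n_kernel = 11L,
                       maxiter = 200L, ftol = 1e-10, ptol = 1e-10,
                       prominence = 0.05, seed = 1L) {
  stopifnot(alpha_max > 0, ip_beta_max > 0,
            length(op_beta_abs) == 2L, op_beta_abs[1] < op_beta_abs[2],
            length(dgamma0_range) == 2L,
            dgamma0_range[1] < dgamma0_range[2], dgamma0_range[1] > 0,
            n_families %in% c(1L, 2L), n_starts >= 1L, max_lm_starts >= 1L)
  structure(list(alpha_max = alpha_max, ip_beta_max = ip_beta_max,
                 op_beta_abs = op_beta_abs, dgamma0_range = dgamma0_range,
                 n_families = as.integer(n_families),
                 n_starts = as.integer(n_starts),
                 max_lm_starts = as.integer(max_lm_starts),
                 delta_beta = delta_beta, n_kernel = as.integer(n_kernel),
                 maxiter = as.integer(maxiter), ftol = ftol, ptol = ptol,
                 prominence = prominence, seed = as.integer(seed)),
            class = "fit_config")
}

# parameter vector layout
.par_names <- function(n_families) {
  if (n_families == 2L) {
    c("ip_alpha", "ip_beta", "ip_gamma0", "ip_dgamma0", "ip_scale",
      "op_alpha", "op_beta", "op_gamma0", "op_dgamma0", "op_scale",
      "background")
  } else {
    c("ip_alpha", "ip_beta", "ip_gamma0", "ip_dgamma0", "ip_scale",
      "background")
  }
}

.model_from_par <- function(par, n_families) {
  ip <- lamella_model(par[1], par[2], par[3], max(par[4], 1e-6), par[5])
  if (n_families == 2L) {
    op <- lamella_model(par[6], par[7], par[8], max(par[9], 1e-6), par[10])
    two_family_model(ip, op, background = max(par[11], 0))
  } else {
    two_family_model(ip, lamella_model(scale = 0),
                     background = max(par[6], 0))
  }
}

.profile_from_par <- function(par, chi, geometry, config) {
  m <- .model_from_par(par, config$n_families)
  two_family_profile(chi, m, geometry, delta_beta = config$delta_beta,
                     n_kernel = config$n_kernel)
}

# box bounds; op beta branch selected by the sign of the start value
.par_bounds <- function(config, op_beta_sign = 1) {
  lo <- c(-config$alpha_max, -config$ip_beta_max, -180,
          config$dgamma0_range[1], 0)
  hi <- c(config$alpha_max, config$ip_beta_max, 180,
          config$dgamma0_range[2], Inf)
  if (config$n_families == 2L) {
    if (op_beta_sign >= 0) {
      ob <- config$op_beta_abs
    } else {
      ob <- -rev(config$op_beta_abs)
    }
    lo <- c(lo, -config$alpha_max, ob[1], -180, config$dgamma0_range[1], 0)
    hi <- c(hi, config$alpha_max, ob[2], 180, config$dgamma0_range[2], Inf)
  }
  list(lower = c(lo, 0), upper = c(hi, Inf))
}

.clamp_start <- function(par, bounds) {
  pmin(pmax(par, bounds$lower + 1e-8), bounds$upper - 1e-8)
}

wrap_gamma0 <- function(g) {
  g <- ((g + 90) %% 180) - 90
  ifelse(g == -90, 90, g)
}

# Keep the best candidates while forcing representation of all three
# alpha regimes around the degeneracy ridge at |alpha| = asin(q/(2k)):
# twin local minima on either side of the ridge can be numerically
# near-identical, so ranking by objective alone strands every start in
# one basin.
.rank_diverse <- function(starts, rss, alpha_vals, ridge, n_per_bucket,
                          n_max) {
  bucket <- findInterval(alpha_vals, c(-ridge, ridge))
  keep <- integer(0)
  for (b in 0:2) {
    idx <- which(bucket == b)
    idx <- idx[order(rss[idx])]
    keep <- c(keep, idx[seq_len(min(n_per_bucket, length(idx)))])
  }
  extra <- setdiff(order(rss), keep)
  keep <- c(keep, extra[seq_len(max(0, n_max - length(keep)))])
  keep[order(rss[keep])]
}

.alpha_ridge <- function(geometry) {
  asin(geometry$q_ring / (2 * wavenumber(geometry))) / .DEG
}

# --- width -> dgamma0 lookup -------------------------------------------

.fibretex_cache <- new.env(parent = emptyenv())

# Forward table of untilted lobe width against dgamma0 at this geometry,
# inverted by interpolation to seed dgamma0 from a measured peak width.
width_to_dgamma0 <- function(width, geometry, delta_beta = 5) {
  key <- paste0("wtab_", signif(geometry$wavelength, 8), "_",
                signif(geometry$q_ring, 8), "_", signif(delta_beta, 4))
  tab <- .fibretex_cache[[key]]
  if (is.null(tab)) {
    dg <- seq(5, 89, by = 4)
    chi <- seq(0, 359.5, by = 0.5)
    wd <- vapply(dg, function(d) {
      y <- beta_smoothed_profile(chi, lamella_model(0, 0, 0, d), geometry,
                                 delta_beta = delta_beta)
      pk <- detect_peaks(chi, y, min_separation = 90)
      pk$width[1]
    }, numeric(1))
    o <- order(wd)
    u <- !duplicated(wd[o])
    tab <- list(width = wd[o][u], dgamma0 = dg[o][u])
    .fibretex_cache[[key]] <- tab
  }
  out <- stats::approx(tab$width, tab$dgamma0, xout = width, rule = 2)$y
  pmin(pmax(out, 3), 89)
}

# --- initialization -----------------------------------------------------

# seed (beta, gamma0, alpha) from a pair of lobes (positions sorted by chi)
.pair_seed <- function(p_lo, p_hi, h_lo, h_hi, geometry, beta_prefer) {
  sep_up <- (p_hi - p_lo) %% 360
  mid <- (p_lo + sep_up / 2) %% 360
  cand <- c(((mid - 180 + 180) %% 360) - 180, ((mid + 180) %% 360) - 180)
  inside <- abs(cand) >= beta_prefer[1] & abs(cand) <= beta_prefer[2]
  beta <- if (any(inside)) cand[inside][1] else cand[which.min(abs(cand))]
  # which lobe is the "up" (chi = 90 + beta side) peak
  d_lo <- abs(circ_diff(p_lo, 90 + beta))
  d_hi <- abs(circ_diff(p_hi, 90 + beta))
  if (d_lo <= d_hi) {
    up <- p_lo; dn <- p_hi; h_up <- h_lo; h_dn <- h_hi
  } else {
    up <- p_hi; dn <- p_lo; h_up <- h_hi; h_dn <- h_lo
  }
  sep <- (dn - up) %% 360
  hh <- (180 - sep) / 2
  qx0 <- -geometry$q_ring^2 / (2 * wavenumber(geometry))
  qp <- sqrt(geometry$q_ring^2 - qx0^2)
  gamma0 <- if (abs(hh) < 0.2) 0 else {
    atan(-qx0 / (qp * sin(hh * .DEG))) / .DEG
  }
  alpha <- if (h_up > h_dn) 2 else -2
  list(beta = beta, gamma0 = wrap_gamma0(gamma0), alpha = alpha)
}

# weighted linear least squares for the family scales and background,
# given fixed angular parameters; negative solutions clamped to zero
.solve_scales <- function(par, chi, obs, sigma, geometry, config) {
  n <- config$n_families
  basis <- list()
  p1 <- par
  p1[5] <- 1
  if (n == 2L) p1[10] <- 0
  p1[length(p1)] <- 0
  basis[[1]] <- .profile_from_par(p1, chi, geometry, config)
  if (n == 2L) {
    p2 <- par
    p2[5] <- 0
    p2[10] <- 1
    p2[length(p2)] <- 0
    basis[[2]] <- .profile_from_par(p2, chi, geometry, config)
  }
  x <- cbind(do.call(cbind, basis), 1) / sigma
  y <- obs / sigma
  coefs <- tryCatch(qr.solve(x, y), error = function(e) rep(0, ncol(x)))
  coefs <- pmax(coefs, 0)
  par[5] <- coefs[1]
  if (n == 2L) {
    par[10] <- coefs[2]
    par[11] <- coefs[3]
  } else {
    par[6] <- coefs[2]
  }
  par
}

#' Heuristic starting model from detected peaks
#'
#' Pairs detected lobes into fibre families (the broad pair becomes the
#' in-plane family, the sharp pair the out-of-plane family), seeds beta
#' from the pair midline, gamma0 from the deviation of the pair
#' separation from 180 degrees through the exact Ewald-offset relation,
#' alpha from the height asymmetry, dgamma0 from the lobe width via a
#' precomputed forward-model lookup, and the scale factors by weighted
#' linear least squares. Falls back to a neutral seed when fewer than two
#' lobes are found.
#'
#' @param profile an [azimuthal_profile()].
#' @param geometry a [scattering_geometry()].
#' @param config a [fit_config()].
#' @return named numeric start vector (see source for layout).
#' @export
initialize_fit <- function(profile, geometry, config = fit_config()) {
  keep <- is.finite(profile$intensity)
  chi <- profile$chi[keep]
  obs <- profile$intensity[keep]
  sigma <- if (!is.null(profile$sigma)) profile$sigma[keep] else
    sqrt(pmax(obs, 1))
  # light circular smoothing for detection only
  n <- length(obs)
  ys <- obs
  if (n >= 9L) {
    kk <- c(1, 2, 3, 2, 1) / 9
    idx <- outer(seq_len(n), -2:2, function(i, j) ((i + j - 1) %% n) + 1)
    ys <- as.numeric(matrix(obs[idx], n, 5) %*% kk)
  }
  pk <- detect_peaks(chi, ys, prominence = config$prominence,
                     min_separation = 30)
  bg0 <- max(min(obs), 0)
  neutral_fam <- c(0, 0, 0, 45, max(stats::median(obs) - bg0, 1e-3))
  nf <- config$n_families
  if (nrow(pk) < 2L) {
    par <- if (nf == 2L) {
      c(neutral_fam, c(0, -85, 0, 10, neutral_fam[5] / 10), bg0)
    } else c(neutral_fam, bg0)
    names(par) <- .par_names(nf)
    return(.solve_scales(par, chi, obs, sigma, geometry, config))
  }
  # pair the tallest lobe with the partner closest to 180 deg away
  make_pair <- function(tab) {
    i <- 1L
    d <- abs(abs(circ_diff(tab$position, tab$position[i])) - 180)
    d[i] <- Inf
    j <- which.min(d)
    list(p = tab[c(i, j), ], rest = tab[-c(i, j), , drop = FALSE])
  }
  # midline-based beta candidate of a pair, in (-90, 90]
  pair_beta <- function(p) {
    o <- order(p$position)
    sep_up <- (p$position[o[2]] - p$position[o[1]]) %% 360
    mid <- (p$position[o[1]] + sep_up / 2) %% 360
    b <- ((mid - 180 + 90) %% 180) - 90
    if (b == -90) 90 else b
  }
  fam_from_pair <- function(p, prefer) {
    o <- order(p$position)
    s <- .pair_seed(p$position[o[1]], p$position[o[2]],
                    p$height[o[1]], p$height[o[2]], geometry, prefer)
    dg <- width_to_dgamma0(mean(p$width), geometry, config$delta_beta)
    c(s$alpha, s$beta, s$gamma0, dg, max(p$height))
  }
  if (nf == 1L) {
    pr <- make_pair(pk)
    par <- c(fam_from_pair(pr$p, c(0, config$ip_beta_max)), bg0)
  } else {
    pr1 <- make_pair(pk)
    pairs <- list(pr1$p)
    if (nrow(pr1$rest) >= 2L) {
      pr2 <- make_pair(pr1$rest)
      pairs[[2]] <- pr2$p
    }
    if (length(pairs) == 2L) {
      # classify by pair midline: IP lamellae lie close to the cuticle
      # surface (|beta| <= 45), OP fibres run along the pore canals
      # (|beta| >= 60); peak width is NOT a reliable discriminator (a
      # near-isotropic family gives sharp peaks)
      betas <- vapply(pairs, pair_beta, numeric(1))
      ip_like <- abs(betas) <= mean(c(config$ip_beta_max,
                                      config$op_beta_abs[1]))
      if (ip_like[1] == ip_like[2]) {
        # ambiguous: taller pair to the class its midline favours,
        # other pair to the remaining class
        idx_ip <- if (ip_like[1]) 1L else 2L
        idx_op <- 3L - idx_ip
      } else {
        idx_ip <- which(ip_like)
        idx_op <- which(!ip_like)
      }
      ip <- fam_from_pair(pairs[[idx_ip]], c(0, config$ip_beta_max))
      op <- fam_from_pair(pairs[[idx_op]], config$op_beta_abs)
      if (abs(op[2]) < config$op_beta_abs[1]) {
        op[2] <- sign(op[2] + 1e-9) * (config$op_beta_abs[1] + 10)
      }
      if (abs(ip[2]) > config$ip_beta_max) {
        ip[2] <- sign(ip[2]) * (config$ip_beta_max - 5)
      }
      par <- c(ip, op, bg0)
    } else {
      ip <- fam_from_pair(pairs[[1]], c(0, config$ip_beta_max))
      par <- c(ip, c(0, -85, 0, 10, ip[5] / 10), bg0)
    }
  }
  names(par) <- .par_names(nf)
  .solve_scales(par, chi, obs, sigma, geometry, config)
}

# --- main fit -----------------------------------------------------------

#' Fit two-family 3D orientation parameters to an azimuthal profile
#'
#' Minimizes the weighted sum of squares between the observed profile and
#' the beta-convolved closed-form model over the 11 parameters (alpha,
#' beta, gamma0, dgamma0, scale per family, plus a constant background;
#' 6 parameters for a single family) by bounded Levenberg-Marquardt with
#' multistart over gamma0 seeds and both out-of-plane beta sign branches.
#' Weights default to the Poisson approximation sigma = sqrt(max(I, 1)).
#'
#' @param profile an [azimuthal_profile()] with at least 36 finite
#'   samples.
#' @param geometry a [scattering_geometry()].
#' @param config a [fit_config()].
#' @return an object of class `fit_result`: the fitted `ip`/`op`
#'   [lamella_model()]s, `background`, `rss`, `red_chisq`, per-parameter
#'   standard errors `se`, `converged`, `op_volume_fraction`, and
#'   `flags` (e.g. near-isotropic families with weakly determined
#'   gamma0).
#' @export
fit_profile <- function(profile, geometry, config = fit_config()) {
  stopifnot(inherits(geometry, "scattering_geometry"),
            inherits(config, "fit_config"))
  keep <- is.finite(profile$intensity)
  chi <- profile$chi[keep]
  obs <- profile$intensity[keep]
  if (length(obs) < 36L) {
    stop("profile has fewer than 36 usable samples", call. = FALSE)
  }
  if (stats::var(obs) == 0) {
    stop("degenerate profile: zero variance", call. = FALSE)
  }
  sigma <- if (!is.null(profile$sigma)) profile$sigma[keep] else
    sqrt(pmax(obs, 1))
  set.seed(config$seed)
  nf <- config$n_families

  resid_fn <- function(par) {
    (.profile_from_par(par, chi, geometry, config) - obs) / sigma
  }

  init <- initialize_fit(azimuthal_profile(chi, obs, sigma), geometry,
                         config)
  # Seed lattice: the peak-based initializer is distorted when a tilt
  # brings the Ewald circle close to the thin diffraction ring (the
  # objective has a ridge near |alpha| ~ asin(q_ring/(2k)) separating
  # basins), so candidate starts vary alpha on both sides of that ridge
  # as well as gamma0 (periodic, weakly seeded for broad distributions)
  # and dgamma0 (width-based seed is biased under tilt).
  g0_seeds <- unique(c(init[3],
                       seq(-90 + 180 / config$n_starts, 90,
                           by = 180 / config$n_starts)))
  a_seeds <- unique(c(init[1], -6, -2, 2, 6))
  a_seeds <- a_seeds[abs(a_seeds) <= config$alpha_max]
  dg_seeds <- unique(c(init[4], 25, 55))
  starts <- list()
  warm <- config$seed_hint
  if (!is.null(warm) && length(warm) == length(init)) {
    starts[[1L]] <- structure(as.numeric(warm), names = names(init))
  }
  for (a in a_seeds) for (s in g0_seeds) for (d in dg_seeds) {
    cand <- init
    cand[1] <- a
    cand[3] <- s
    cand[4] <- d
    starts[[length(starts) + 1L]] <- cand
  }
  if (nf == 2L) {
    # vary the out-of-plane family too: both beta sign branches (the
    # model is NOT invariant under op beta -> -op beta), gamma0 seeds,
    # and a sharp-distribution alternative
    op_b <- unique(c(init[7], -init[7],
                     sign(init[7] + 1e-9) * c(65, 85)))
    op_g0 <- unique(c(init[8], -init[8], seq(-60, 90, by = 30)))
    op_dg <- unique(c(init[9], 12))
    for (b in op_b) for (s in op_g0) for (d in op_dg) {
      cand <- init
      cand[7] <- b
      cand[8] <- s
      cand[9] <- d
      starts[[length(starts) + 1L]] <- cand
    }
  }
  # refine scales and rank candidates by their initial RSS, forcing
  # representation of both sides of the alpha ridge
  starts <- lapply(starts, .solve_scales, chi = chi, obs = obs,
                   sigma = sigma, geometry = geometry, config = config)
  rss0 <- vapply(starts, function(p) sum(resid_fn(p)^2), numeric(1))
  a0 <- vapply(starts, `[`, numeric(1), 1L)
  keep <- .rank_diverse(starts, rss0, a0, .alpha_ridge(geometry),
                        n_per_bucket = 2L, n_max = config$max_lm_starts)
  starts <- starts[keep]

  best <- NULL
  for (start in starts) {
    op_sign <- if (nf == 2L) sign(start[7] + 1e-9) else 1
    bounds <- .par_bounds(config, op_sign)
    start <- .clamp_start(start, bounds)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, lower = bounds$lower,
                         upper = bounds$upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = config$maxiter, ftol = config$ftol,
                           ptol = config$ptol)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    stop("all Levenberg-Marquardt starts failed", call. = FALSE)
  }

  # Block-coordinate refinement: with the stronger family pinned, re-seed
  # and refit the other family's block (its alpha shares the degeneracy
  # ridge, so both sides are seeded), then polish jointly. Skipped when
  # the joint fit already reached the noise floor.
  if (nf == 2L && best$deviance > 1e-8 * length(obs)) {
   for (sweep in 1:3) {
    dev_before <- best$deviance
    for (block in list(6:10, 1:5)) {
      free <- c(block, 11L)
      base <- best$par
      resid_block <- function(pb) {
        p <- base
        p[free] <- pb
        resid_fn(p)
      }
      cand_list <- list()
      a_var <- unique(c(base[block[1]], -25, -20, -15, -10, -6, -2,
                        2, 6, 10, 15, 20, 25))
      a_var <- a_var[abs(a_var) <= config$alpha_max]
      g_var <- unique(c(base[block[3]], -base[block[3]], -45, 0, 45, 90))
      dg_var <- unique(c(base[block[4]], 10, 30, 60))
      for (a in a_var) for (g0 in g_var) for (d in dg_var) {
        p <- base
        p[block[1]] <- a
        p[block[3]] <- g0
        p[block[4]] <- d
        cand_list[[length(cand_list) + 1L]] <-
          .solve_scales(p, chi, obs, sigma, geometry, config)
      }
      r0 <- vapply(cand_list, function(p) sum(resid_fn(p)^2), numeric(1))
      ab <- vapply(cand_list, `[`, numeric(1), block[1])
      keep_b <- .rank_diverse(cand_list, r0, ab, .alpha_ridge(geometry),
                              n_per_bucket = 4L, n_max = 12L)
      cand_list <- cand_list[keep_b]
      op_sign_b <- sign(best$par[7] + 1e-9)
      bounds <- .par_bounds(config, op_sign_b)
      # phase 1: refit the free block from every kept candidate
      block_fits <- list()
      for (p in cand_list) {
        p <- .clamp_start(p, bounds)
        fb <- tryCatch(
          minpack.lm::nls.lm(par = p[free], lower = bounds$lower[free],
                             upper = bounds$upper[free], fn = resid_block,
                             control = minpack.lm::nls.lm.control(
                               maxiter = config$maxiter,
                               ftol = config$ftol, ptol = config$ptol)),
          error = function(e) NULL)
        if (!is.null(fb)) block_fits[[length(block_fits) + 1L]] <- fb
      }
      # phase 2: joint polish of the best block results; a block refit
      # that merely ties the incumbent can still beat it once the pinned
      # family is released
      if (length(block_fits) > 0L) {
        dv <- vapply(block_fits, `[[`, numeric(1), "deviance")
        sel <- union(which(dv < best$deviance),
                     order(dv)[seq_len(min(4L, length(dv)))])
        for (idx in sel[order(dv[sel])]) {
          pfull <- base
          pfull[free] <- block_fits[[idx]]$par
          fj <- tryCatch(
            minpack.lm::nls.lm(par = .clamp_start(pfull, bounds),
                               lower = bounds$lower, upper = bounds$upper,
                               fn = resid_fn,
                               control = minpack.lm::nls.lm.control(
                                 maxiter = config$maxiter,
                                 ftol = config$ftol, ptol = config$ptol)),
            error = function(e) NULL)
          if (!is.null(fj) && fj$deviance < best$deviance) best <- fj
        }
      }
      if (best$deviance <= 1e-8 * length(obs)) break
    }
    if (best$deviance <= 1e-8 * length(obs) ||
        best$deviance > 0.99 * dev_before) break
   }
  }

  # Final polish at tight tolerances: weakly identified directions (e.g.
  # the alpha of a low-fraction broad family) form long flat valleys that
  # the default stopping rule exits early.
  bounds <- .par_bounds(config, if (nf == 2L) sign(best$par[7] + 1e-9) else 1)
  fpol <- tryCatch(
    minpack.lm::nls.lm(par = .clamp_start(best$par, bounds),
                       lower = bounds$lower, upper = bounds$upper,
                       fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 500L, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) NULL)
  if (!is.null(fpol) && fpol$deviance <= best$deviance) best <- fpol

  par <- best$par
  par[3] <- wrap_gamma0(par[3])
  if (nf == 2L) par[8] <- wrap_gamma0(par[8])
  names(par) <- .par_names(nf)
  n_par <- length(par)
  n_obs <- length(obs)
  red_chisq <- best$deviance / max(n_obs - n_par, 1)
  se <- tryCatch({
    v <- diag(solve(best$hessian)) * red_chisq
    sqrt(pmax(v, 0))
  }, error = function(e) rep(NA_real_, n_par))
  names(se) <- names(par)

  model <- .model_from_par(par, nf)
  scales <- c(model$ip$scale, model$op$scale)
  ovf <- if (sum(scales) > 0) unname(scales[2] / sum(scales)) else NA_real_
  flags <- character(0)
  if (par["ip_dgamma0"] > 85) {
    flags <- c(flags, "ip near-isotropic, gamma0 poorly determined")
  }
  if (nf == 2L && par["op_dgamma0"] > 85) {
    flags <- c(flags, "op near-isotropic, gamma0 poorly determined")
  }
  converged <- !is.null(best$info) && best$info %in% 1:4
  if (!converged) flags <- c(flags, "not converged")

  structure(list(ip = model$ip, op = model$op,
                 background = model$background,
                 par = par, se = se, rss = best$deviance,
                 red_chisq = red_chisq, converged = converged,
                 op_volume_fraction = ovf, n_families = nf,
                 flags = flags, method = "lm"),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Fit (%s, %d famil%s): rss = %.4g, reduced chi^2 = %.4g%s\n",
              x$method, x$n_families,
              if (x$n_families == 1L) "y" else "ies",
              x$rss, x$red_chisq,
              if (x$converged) "" else " [NOT CONVERGED]"))
  cat("  IP: ")
  print(x$ip)
  if (x$n_families == 2L) {
    cat("  OP: ")
    print(x$op)
    cat(sprintf("  lambda2/(lambda1+lambda2) = %.3f\n",
                x$op_volume_fraction))
  }
  cat(sprintf("  background = %.4g\n", x$background))
  for (f in x$flags) cat("  flag: ", f, "\n", sep = "")
  invisible(x)
}

#' Out-of-plane volume fraction from fitted scale factors
#'
#' The ratio `lambda2 / (lambda1 + lambda2)` of the fitted family scale
#' factors is proportional to the volume fraction of out-of-plane fibres
#' in the scattering volume.
#'
#' @param result a `fit_result` from [fit_profile()] or [grid_fit()].
#' @return fraction in `[0, 1]`.
#' @export
op_volume_fraction <- function(result) {
  stopifnot(inherits(result, "fit_result"))
  s <- c(result$ip$scale, result$op$scale)
  if (sum(s) <= 0) {
    stop("undefined fraction: both family scales are zero", call. = FALSE)
  }
  unname(s[2] / sum(s))
}

#' Coarse exhaustive grid-search fit (cross-check oracle)
#'
#' Exhaustive search over the angular parameters on regular grids, with
#' the family scale factors and background solved by weighted linear
#' least squares at every node. Slow by construction; used to cross-check
#' [fit_profile()] on small problems, at resolutions of 1 degree or
#' coarser.
#'
#' @param profile an [azimuthal_profile()].
#' @param geometry a [scattering_geometry()].
#' @param grid_resolution grid step in degrees (>= 1).
#' @param config a [fit_config()]; `n_families` is taken from it.
#' @param ranges optional named list overriding individual grid ranges,
#'   entries `alpha`, `beta`, `gamma0`, `dgamma0` (and `op_alpha`, ...,
#'   for the second family), each `c(lo, hi)`.
#' @param max_nodes refusal threshold on the total node count.
#' @return a `fit_result` with `method = "grid"`.
#' @export
grid_fit <- function(profile, geometry, grid_resolution = 5,
                     config = fit_config(n_families = 1L), ranges = list(),
                     max_nodes = 1e7) {
  if (grid_resolution < 1) {
    stop("grid_resolution must be >= 1 degree (use fit_profile for fine ",
         "resolution)", call. = FALSE)
  }
  keep <- is.finite(profile$intensity)
  chi <- profile$chi[keep]
  obs <- profile$intensity[keep]
  sigma <- if (!is.null(profile$sigma)) profile$sigma[keep] else
    sqrt(pmax(obs, 1))
  nf <- config$n_families
  rng <- function(name, default) {
    r <- if (!is.null(ranges[[name]])) ranges[[name]] else default
    seq(r[1], r[2], by = grid_resolution)
  }
  g1 <- list(alpha = rng("alpha", c(-config$alpha_max, config$alpha_max)),
             beta = rng("beta", c(-config$ip_beta_max, config$ip_beta_max)),
             gamma0 = rng("gamma0", c(-85, 90)),
             dgamma0 = rng("dgamma0", config$dgamma0_range))
  nodes1 <- expand.grid(g1, KEEP.OUT.ATTRS = FALSE)
  n_total <- nrow(nodes1)
  if (nf == 2L) {
    g2 <- list(op_alpha = rng("op_alpha",
                              c(-config$alpha_max, config$alpha_max)),
               op_beta = rng("op_beta", c(-90, -60)),
               op_gamma0 = rng("op_gamma0", c(-85, 90)),
               op_dgamma0 = rng("op_dgamma0", config$dgamma0_range))
    nodes2 <- expand.grid(g2, KEEP.OUT.ATTRS = FALSE)
    n_total <- n_total * nrow(nodes2)
  }
  if (n_total == 0) stop("empty grid request", call. = FALSE)
  if (n_total > max_nodes) {
    stop(sprintf(paste0("grid too large: %.3g nodes exceed the %.3g limit; ",
                        "coarsen grid_resolution or narrow ranges"),
                 n_total, max_nodes), call. = FALSE)
  }
  basis_for <- function(a, b, g0, dg) {
    beta_smoothed_profile(chi, lamella_model(a, b, g0, dg, 1), geometry,
                          delta_beta = config$delta_beta,
                          n_kernel = config$n_kernel)
  }
  wy <- obs / sigma
  best <- list(rss = Inf)
  solve_node <- function(bases) {
    x <- cbind(do.call(cbind, bases), 1) / sigma
    cf <- tryCatch(qr.solve(x, wy), error = function(e) NULL)
    if (is.null(cf)) return(NULL)
    cf <- pmax(cf, 0)
    r <- wy - x %*% cf
    list(coefs = cf, rss = sum(r^2))
  }
  if (nf == 1L) {
    for (i in seq_len(nrow(nodes1))) {
      b1 <- basis_for(nodes1$alpha[i], nodes1$beta[i], nodes1$gamma0[i],
                      nodes1$dgamma0[i])
      s <- solve_node(list(b1))
      if (!is.null(s) && s$rss < best$rss) {
        best <- list(rss = s$rss,
                     par = c(nodes1$alpha[i], nodes1$beta[i],
                             nodes1$gamma0[i], nodes1$dgamma0[i],
                             s$coefs[1], s$coefs[2]))
      }
    }
  } else {
    b1_all <- lapply(seq_len(nrow(nodes1)), function(i)
      basis_for(nodes1$alpha[i], nodes1$beta[i], nodes1$gamma0[i],
                nodes1$dgamma0[i]))
    for (j in seq_len(nrow(nodes2))) {
      b2 <- basis_for(nodes2$op_alpha[j], nodes2$op_beta[j],
                      nodes2$op_gamma0[j], nodes2$op_dgamma0[j])
      for (i in seq_len(nrow(nodes1))) {
        s <- solve_node(list(b1_all[[i]], b2))
        if (!is.null(s) && s$rss < best$rss) {
          best <- list(rss = s$rss,
                       par = c(nodes1$alpha[i], nodes1$beta[i],
                               nodes1$gamma0[i], nodes1$dgamma0[i],
                               s$coefs[1],
                               nodes2$op_alpha[j], nodes2$op_beta[j],
                               nodes2$op_gamma0[j], nodes2$op_dgamma0[j],
                               s$coefs[2], s$coefs[3]))
        }
      }
    }
  }
  par <- best$par
  names(par) <- .par_names(nf)
  model <- .model_from_par(par, nf)
  scales <- c(model$ip$scale, model$op$scale)
  structure(list(ip = model$ip, op = model$op,
                 background = model$background, par = par,
                 se = rep(NA_real_, length(par)), rss = best$rss,
                 red_chisq = best$rss / max(length(obs) - length(par), 1),
                 converged = TRUE,
                 op_volume_fraction = if (sum(scales) > 0)
                   scales[2] / sum(scales) else NA_real_,
                 n_families = nf, flags = character(0), method = "grid"),
            class = "fit_result")
}

#' Write fit results as a one-row-per-fit delimited table
#'
#' Columns follow the conventional per-family parameter layout: alpha,
#' beta, gamma0, dgamma0 for the IP and OP families, the scale fractions
#' `lambda1_frac`/`lambda2_frac`, background, and fit diagnostics.
#'
#' @param results a `fit_result` or list of them.
#' @param path output file path.
#' @export
write_fit_results <- function(results, path) {
  if (inherits(results, "fit_result")) results <- list(results)
  rows <- lapply(results, fit_result_row)
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

fit_result_row <- function(r) {
  s <- c(r$ip$scale, r$op$scale)
  fr <- if (sum(s) > 0) s / sum(s) else c(NA_real_, NA_real_)
  data.frame(ip_alpha = r$ip$alpha, ip_beta = r$ip$beta,
             ip_gamma0 = r$ip$distribution$gamma0,
             ip_dgamma0 = r$ip$distribution$dgamma0,
             lambda1_frac = fr[1],
             op_alpha = r$op$alpha, op_beta = r$op$beta,
             op_gamma0 = r$op$distribution$gamma0,
             op_dgamma0 = r$op$distribution$dgamma0,
             lambda2_frac = fr[2],
             background = r$background, rss = r$rss,
             red_chisq = r$red_chisq, converged = r$converged,
             flags = paste(r$flags, collapse = "; "))
}
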