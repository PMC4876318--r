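test_that("initialization seeds the tilts from the detected lobes", {
  g <- std_geometry()
  chi <- chi_grid_1deg()
  cfg <- fit_config(n_families = 1L)
  # beta moves both lobes rigidly; the seed should track it
  y <- beta_smoothed_profile(chi, lamella_model(0, 20, 0, 45, 100), g)
  init <- initialize_fit(azimuthal_profile(chi, y), g, cfg)
  expect_lt(abs(init[["ip_beta"]] - 20), 5)
  # gamma0 closes the peak pair: the seed must carry the right sign
  y2 <- beta_smoothed_profile(chi, lamella_model(0, 0, 30, 45, 100), g)
  init2 <- initialize_fit(azimuthal_profile(chi, y2), g, cfg)
  expect_gt(init2[["ip_gamma0"]], 0)
  y3 <- beta_smoothed_profile(chi, lamella_model(0, 0, -30, 45, 100), g)
  init3 <- initialize_fit(azimuthal_profile(chi, y3), g, cfg)
  expect_lt(init3[["ip_gamma0"]], 0)
  # flat profile: neutral seed
  initf <- initialize_fit(azimuthal_profile(chi, rep(5, length(chi))), g,
                          cfg)
  expect_equal(as.numeric(initf[1:4]), c(0, 0, 0, 45))
})

test_that("single-family noiseless profiles are recovered exactly", {
  g <- std_geometry()
  chi <- chi_grid_1deg()
  truth <- lamella_model(5, 10, 25, 40, scale = 100)
  y <- beta_smoothed_profile(chi, truth, g)
  fit <- fit_profile(azimuthal_profile(chi, y), g,
                     fit_config(n_families = 1L))
  expect_true(fit$converged)
  expect_lt(abs(fit$par[["ip_alpha"]] - 5), 1)
  expect_lt(abs(fit$par[["ip_beta"]] - 10), 1)
  expect_lt(ang_err(fit$par[["ip_gamma0"]], 25, 180), 1)
  expect_lt(abs(fit$par[["ip_dgamma0"]] - 40), 2)
  expect_lt(abs(fit$par[["ip_scale"]] - 100) / 100, 0.01)
})

test_that("fitting is equivariant under profile rotation", {
  g <- std_geometry()
  chi <- chi_grid_1deg()
  base <- lamella_model(0, 5, 20, 45, 100)
  y <- beta_smoothed_profile(chi, base, g)
  fit0 <- fit_profile(azimuthal_profile(chi, y), g,
                      fit_config(n_families = 1L))
  delta <- 20
  y_shift <- beta_smoothed_profile(chi - delta, base, g)
  fit1 <- fit_profile(azimuthal_profile(chi, y_shift), g,
                      fit_config(n_families = 1L))
  expect_equal(fit1$par[["ip_beta"]], fit0$par[["ip_beta"]] + delta,
               tolerance = 0.2)
  expect_lt(ang_err(fit1$par[["ip_gamma0"]], fit0$par[["ip_gamma0"]],
                    180), 0.5)
  expect_equal(fit1$par[["ip_dgamma0"]], fit0$par[["ip_dgamma0"]],
               tolerance = 0.5)
})

test_that("residuals at the optimum satisfy first-order optimality", {
  g <- std_geometry()
  chi <- chi_grid_1deg()
  truth <- lamella_model(2, -15, 35, 55, 100)
  mu <- beta_smoothed_profile(chi, truth, g)
  set.seed(5)
  obs <- stats::rpois(length(mu), mu * 1e4 / max(mu))
  prof <- azimuthal_profile(chi, obs, sqrt(pmax(obs, 1)))
  cfg <- fit_config(n_families = 1L)
  fit <- fit_profile(prof, g, cfg)
  # numeric gradient of the weighted RSS at the optimum ~ 0 relative to
  # its curvature scale
  par <- fit$par
  rss_at <- function(p) {
    m <- two_family_model(lamella_model(p[1], p[2], p[3], p[4], p[5]),
                          lamella_model(scale = 0), max(p[6], 0))
    sum(((two_family_profile(chi, m, g) - obs) / sqrt(pmax(obs, 1)))^2)
  }
  f0 <- rss_at(par)
  h <- 0.02
  for (i in 1:4) {
    up <- par
    up[i] <- up[i] + h
    dn <- par
    dn[i] <- dn[i] - h
    # a stationary point: stepping either way along any parameter axis
    # must not decrease the objective beyond curvature-scale noise
    expect_gte(rss_at(up), f0 - 1e-4 * f0)
    expect_gte(rss_at(dn), f0 - 1e-4 * f0)
  }
})

test_that("grid search agrees with the LM fit on noiseless data", {
  g <- std_geometry()
  chi <- chi_grid_1deg()
  truth <- lamella_model(0, 10, 20, 40, scale = 100)
  y <- beta_smoothed_profile(chi, truth, g)
  prof <- azimuthal_profile(chi, y)
  cfg <- fit_config(n_families = 1L)
  gf <- grid_fit(prof, g, grid_resolution = 5, config = cfg,
                 ranges = list(alpha = c(-5, 5), beta = c(0, 20),
                               gamma0 = c(0, 40), dgamma0 = c(25, 55)))
  fit <- fit_profile(prof, g, cfg)
  # the noiseless truth lies on the grid: both must find it
  expect_lt(abs(gf$par[["ip_beta"]] - fit$par[["ip_beta"]]), 5)
  expect_lt(ang_err(gf$par[["ip_gamma0"]], fit$par[["ip_gamma0"]], 180), 5)
  expect_lt(abs(gf$par[["ip_dgamma0"]] - fit$par[["ip_dgamma0"]]), 5)
  # grid objective cannot beat the continuous optimum
  expect_gte(gf$rss, fit$rss - 1e-8)
  # guardrails
  expect_error(grid_fit(prof, g, grid_resolution = 0.1), ">= 1")
  expect_error(grid_fit(prof, g, grid_resolution = 1, config = cfg,
                        max_nodes = 10), "grid too large")
})

test_that("out-of-plane volume fraction follows the scale ratio", {
  g <- std_geometry()
  chi <- chi_grid_1deg()
  m <- two_family_model(lamella_model(0, 5, 20, 60, 3),
                        lamella_model(0, -85, 0, 10, 3))
  y <- two_family_profile(chi, m, g)
  fit <- fit_profile(azimuthal_profile(chi, y), g,
                     fit_config(n_families = 2L))
  expect_equal(op_volume_fraction(fit), 0.5, tolerance = 0.02)
  # single-family fit: fraction zero
  m1 <- two_family_model(lamella_model(0, 5, 20, 60, 3),
                         lamella_model(scale = 0))
  fit1 <- fit_profile(azimuthal_profile(
    chi, two_family_profile(chi, m1, g)), g, fit_config(n_families = 1L))
  expect_equal(op_volume_fraction(fit1), 0)
})

test_that("degenerate profiles are rejected", {
  g <- std_geometry()
  chi <- chi_grid_1deg()
  expect_error(fit_profile(azimuthal_profile(chi, rep(10, length(chi))),
                           g, fit_config(n_families = 1L)), "variance")
  expect_error(fit_profile(azimuthal_profile(1:10, 1:10), g,
                           fit_config(n_families = 1L)), "36")
})

test_that("fit tables round-trip through write_fit_results", {
  g <- std_geometry()
  chi <- chi_grid_1deg()
  m <- two_family_model(lamella_model(0, 5, 20, 60, 3),
                        lamella_model(scale = 0))
  fit <- fit_profile(azimuthal_profile(
    chi, two_family_profile(chi, m, g)), g, fit_config(n_families = 1L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fit_results(fit, path)
  tab <- utils::read.delim(path)
  expect_equal(nrow(tab), 1L)
  expect_true(all(c("ip_alpha", "ip_beta", "ip_gamma0", "ip_dgamma0",
                    "lambda1_frac", "op_alpha", "op_beta", "op_gamma0",
                    "op_dgamma0", "lambda2_frac", "rss", "red_chisq",
                    "converged") %in% names(tab)))
  expect_equal(tab$ip_beta, fit$par[["ip_beta"]], tolerance = 1e-6)
})

test_that("random single-family draws are recovered from noiseless
           profiles", {
  g <- std_geometry()
  chi <- seq(1, 360, by = 2)
  cfg <- fit_config(n_families = 1L, max_lm_starts = 4L)
  set.seed(202)
  n_draw <- 12
  draws <- data.frame(alpha = stats::runif(n_draw, -12, 12),
                      beta = stats::runif(n_draw, -40, 40),
                      gamma0 = stats::runif(n_draw, -89, 89),
                      dgamma0 = stats::runif(n_draw, 15, 80))
  for (i in seq_len(n_draw)) {
    truth <- lamella_model(draws$alpha[i], draws$beta[i], draws$gamma0[i],
                           draws$dgamma0[i], scale = 100)
    y <- beta_smoothed_profile(chi, truth, g)
    fit <- fit_profile(azimuthal_profile(chi, y), g, cfg)
    expect_lt(abs(fit$par[["ip_alpha"]] - draws$alpha[i]), 1)
    expect_lt(abs(fit$par[["ip_beta"]] - draws$beta[i]), 1)
    expect_lt(ang_err(fit$par[["ip_gamma0"]], draws$gamma0[i], 180), 1)
  }
})
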