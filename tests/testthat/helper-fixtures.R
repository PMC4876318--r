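# Shared fixtures: the beamline geometry used throughout (14 keV
# microfocus WAXD, chitin (110) ring) and the published two-family
# parameter sets for four locations across a telson carina, used as
# ground truth for recovery tests.

std_geometry <- function() chitin_geometry()

# per-location parameters: ip (alpha, beta, gamma0, dgamma0, fraction),
# op (alpha, beta, gamma0, dgamma0, fraction)
carina_locations <- function() {
  list(
    I   = c(0.4, 4.7, 20.0, 83.0, 0.82, 2.2, -87.2, 88.5, 10.0, 0.18),
    II  = c(1.0, 15.1, -40.0, 75.0, 0.66, -0.5, -81.0, 75.0, 10.1, 0.34),
    III = c(0.2, -17.5, -39.1, 89.3, 0.73, 8.5, 80.0, -55.0, 24.0, 0.27),
    IV  = c(1.0, 3.4, -47.6, 50.0, 0.61, -19.0, -86.8, 67.3, 10.2, 0.39))
}

location_model <- function(p, amplitude = 1000) {
  two_family_model(
    lamella_model(p[1], p[2], p[3], p[4], amplitude * p[5]),
    lamella_model(p[6], p[7], p[8], p[9], amplitude * p[10]),
    background = 0)
}

# minimal circular distances for comparing fitted angles
ang_err <- function(a, b, period = 360) {
  d <- (a - b) %% period
  min(d, period - d)
}

# standard 1-degree azimuth grid at bin centres
chi_grid_1deg <- function() seq(0.5, 359.5, by = 1)
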