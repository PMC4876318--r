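# fibretex

Three-dimensional fibre-orientation reconstruction from azimuthal
wide-angle X-ray diffraction (WAXD) intensity profiles.

## The problem

Fibrous biological composites — arthropod cuticle, wood cell walls, bone
lamellae — are built from crystalline nanofibrils arranged in planar
lamellae. In crustacean cuticle the fibrils form twisted-plywood
(Bouligand) stacks of **in-plane (IP)** fibres, threaded by a second
family of **out-of-plane (OP)** fibres running along pore canals. A
scanning microfocus WAXD experiment records, at every grid point, a 2D
diffraction pattern whose azimuthal intensity `I(χ)` around an
equatorial ring (here the α-chitin (110) reflection) encodes the local
3D fibre texture. `fibretex` turns those profiles back into orientation
parameters.

## The model

Under fibre symmetry every fibril contributes a thin ring of (110)
intensity on the reciprocal-space sphere of radius `q₁₁₀`; a lamella of
fibrils whose in-plane angles γ follow a normalized wrapped-Gaussian
distribution

    w(γ; γ₀, Δγ₀) = (1 / (Δγ₀ √π)) · exp(−(γ − γ₀)² / Δγ₀²)

populates that sphere with a band of intensity. The detector sees only
the circle where the Ewald sphere intersects the `q₁₁₀` sphere, with the
exact elastic-scattering curvature offset `q_x = −q₁₁₀²/(2k)` along the
beam. For a lamella tilted by α (laboratory x–y plane) and β (about the
beam axis), the azimuthal profile is

    I(χ) = λ · ∫ w(γ) K(q(χ)·u(γ); a_x) dγ            (integral model)

with `K` a normalized Gaussian ring kernel of width `a_x` and `u(γ)`
the fibril axis. In the high-crystallinity limit `a_x → 0` this
collapses to the closed form

    I(χ) = λ · 2 w(γ_r) / √(q_x² + q_z²),   γ_r = atan2(q_x, q_z),

(body-frame components), which is convolved with a narrow Gaussian
kernel (width Δβ = 5°) to regularize a known artefact near the vertical
and then fitted to measured profiles — two families plus a constant
background, 11 parameters — by bounded Levenberg–Marquardt with
multistart. The ratio λ₂/(λ₁+λ₂) of the fitted family scales is
proportional to the OP fibre volume fraction.

## Worked example

```r
library(fibretex)
geom <- chitin_geometry()          # 0.6888 A, 262.3 mm, 0.172 mm pixels
chi  <- seq(0.5, 359.5, by = 1)

# forward model: an IP family at beta = 10 deg plus a near-vertical OP
# family, as seen in telson cuticle
truth <- two_family_model(ip = lamella_model(2, 8, 30, 50, scale = 1),
                          op = lamella_model(0, -85, 0, 12, scale = 0.3))
img  <- render_image(truth, geom, peak_counts = 1e5, seed = 7)
prof <- azimuthal_regroup(img, geom, background = "flanking")
fit  <- fit_profile(prof, geom, fit_config(n_families = 2))
print(fit)
```

prints

```
Fit (lm, 2 families): rss = 3.886e+04, reduced chi^2 = 111.4
  IP: Lamella: alpha = 2.02411, beta = 8.05217, gamma0 = 29.8919, dgamma0 = 49.7709 deg; scale = 4983.94
  OP: Lamella: alpha = -0.00282854, beta = -85.0186, gamma0 = -0.00222582, dgamma0 = 11.9534 deg; scale = 1527.11
  lambda2/(lambda1+lambda2) = 0.235
  background = 44.78
```

(The reduced chi-square is large relative to 1 because the regrouped
profile's per-bin uncertainties are standard errors of bin means over
hundreds of pixels; the residual structure is the sub-percent mismatch
between the rendered ring and the azimuthal model, not photon noise.)

i.e. starting from a synthetic Pilatus-class frame, the regrouped
profile refits the generating tilts to better than 0.1°, the
distribution widths to better than 0.3°, and the OP scale fraction
0.235 against the true 0.3/1.3 = 0.231. `fit_scan()` applies the same
fit to every point of a mesh scan (e.g. a 7×12 grid at 100 µm spacing)
and `export_map()` writes the per-point parameter table plus lamella
glyphs for external 3D renderers.

A thin command-line wrapper is installed at `inst/cli/fibretex`
(subcommands `simulate`, `integrate`, `fit`, `map`, `check`).

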