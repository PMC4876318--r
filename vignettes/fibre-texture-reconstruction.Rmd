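---
title: "Reconstructing 3D fibre orientation from azimuthal WAXD profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing 3D fibre orientation from azimuthal WAXD profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibretex)
```

## The physical model

Crustacean cuticle — the running example here is the telson (tail
shield) of the mantis shrimp — is a hierarchical composite of α-chitin
nanofibrils wrapped in protein and mineral. At the micron scale the
fibrils are organized in planar lamellae: within a lamella the fibril
long axes lie in one plane, with in-plane angles γ spread around a
principal direction γ₀. Successive lamellae rotate about the surface
normal (the Bouligand, twisted-plywood motif), and a second population
of fibres runs nearly perpendicular to the surface along the pore-canal
network. A focused X-ray beam therefore samples two fibre families at
once: in-plane (IP) and out-of-plane (OP).

Because the chitin unit cell is rotationally averaged about the fibril
axis (fibre symmetry), each fibril's (110) reflection is a thin ring in
reciprocal space, perpendicular to the fibril axis, of radius
q₁₁₀ = 2π/d₁₁₀. All fibril orientations together populate the sphere of
that radius. The detector does not see the whole sphere: it records the
circle where the Ewald sphere intersects it. Working in a laboratory
frame with x along the beam, the intersection circle has a constant
beam-axis component

  q_x = −q₁₁₀² / (2k),  k = 2π/λ,

the exact elastic-scattering curvature offset, and transverse magnitude
√(q₁₁₀² − q_x²). This offset is small (≈ 0.10 Å⁻¹ at 14 keV for
d₁₁₀ = 4.6 Å, about 7.5% of q₁₁₀) but it is the quantity that breaks
the naive 180° peak symmetry and makes the azimuthal profile sensitive
to the in-plane angle γ₀ — without Ewald curvature, rotating the
principal fibre direction within the beam-normal plane would be
invisible.

### Weight function and intensity on the sphere

The in-plane fibril distribution is a normalized Gaussian of width
parameter Δγ₀ (convention f(u) ∝ exp(−u²/a²), i.e. a = √2 σ). Fibrils
are apolar — γ and γ + 180° are the same physical fibril — so the
package wraps the Gaussian with period 180° and normalizes over one
period. For the widths encountered in practice (10°–90°) the wrap terms
matter: at Δγ₀ = 89° the nearest image contributes ~2% of the peak
density. An unwrapped Gaussian summed over both roots of the ring
condition, which is the other reading of the source model, coincides
with the wrapped form whenever the weight is 180°-periodic, which is
why the wrapped form is the default and only behaviour.

A single fibril's ring is modelled as a generalized δ-function band
K(u; a_x) = exp(−u²/a_x²)/(a_x√π) in u = q·u(γ), the component of the
scattering vector along the fibril axis. The width a_x measures
intrafibrillar crystalline alignment; a_x → 0 is the
high-crystallinity limit. The intensity anywhere on the sphere is the
population integral ∫ w(γ) K(q·u(γ)) dγ, evaluated by midpoint
quadrature on a uniform periodic grid (2048 nodes by default, converged
below 1e−6 relative for a_x ≥ 5e−3 Å⁻¹ at this geometry; the rule is
spectrally accurate for periodic integrands).

### Tilts and conventions

The lamella plane is tilted by two angles: α (in the laboratory x–y
plane) and β (about the beam axis). Angle conventions are fixed by the
observable behaviour of I(χ), since they are not uniquely determined by
the printed source material:

* χ is measured counterclockwise from the horizontal (+z) axis, viewed
  from the source; χ = 90° is vertically up.
* β > 0 shifts both peaks rigidly toward larger χ. This shift is exact:
  for α = 0 a β offset is mathematically a rotation of the profile.
* α > 0 strengthens the upper (χ ≈ 90°) peak and weakens the lower one.
* γ₀ ∈ (0°, 90°) pulls the two peaks together (separation < 180°
  measured lower-χ → higher-χ through increasing χ); γ₀ ∈ (−90°, 0°)
  pushes them apart. The fibril axis is u(γ) = (cos γ, 0, −sin γ) in
  the body frame; the opposite sign choice for γ would invert this
  behaviour and contradict the reference phenomenology.

### The closed form and its artefact

In the a_x → 0 limit the kernel collapses to a δ-function and the
population integral evaluates in closed form:

  I(χ) = λ · 2 w(γ_r) / √(q_x² + q_z²),  γ_r = atan2(q_x, q_z) mod 180°,

with body-frame components of the Ewald-circle point. This is the fast
model — no quadrature — that makes Levenberg–Marquardt fitting of scan
grids interactive rather than a day-long brute-force search.

The limit has a known pathology: near the vertical (χ = ±90°) the
denominator approaches its minimum |q_x| while γ_r sweeps rapidly
through 90°, so for moderate Δγ₀ the limiting profile develops a
narrow artefactual minimum at the vertical flanked by two sub-maxima
("horns"). The exact integral at physical a_x shows the same structure
whenever a_x ≲ |q_x|; it is a real feature of the thin-ring model, not
a numerical accident. Two remedies are built in:

1. **Gaussian β-convolution** (width Δβ = 5° by default): physically, a
   narrow fan of principal fibril directions about the beam axis.
   Because a β offset shifts the profile rigidly, the convolution is
   implemented as a one-dimensional circular convolution of I(χ) on a
   fine internal grid (0.25° steps, FFT), then interpolated to the
   requested azimuths. An earlier implementation that summed the closed
   form at 11 discrete β offsets was abandoned: it leaves sub-degree
   1/R spikes in the model, which make the least-squares landscape
   multimodal and stall the optimizer on noiseless data. For α = 0 the
   two constructions are mathematically identical; the convolved form
   is the model used for all fitting.
2. **Denominator floor**: √(q_x²+q_z²) is floored at 1e−6·q₁₁₀ (capped
   and flagged); on the convolution grid the floor is widened to the
   value half a grid step from exact degeneracy, so that a grid point
   landing on the degenerate pole contributes what an honest Riemann
   sum would.

Peak *measurement* must respect the horn structure: the package's peak
detector clusters local maxima within a configurable separation window
(default 30°) so a horned lobe counts once. A clustered lobe's position
is the height-weighted circular centroid of its member maxima — exactly
the lobe midline for the symmetric untilted case — while a unimodal
lobe is refined by quadratic sub-bin interpolation. Comparisons between
the closed form and the integral oracle exclude a flagged degenerate
zone around the vertical (denominator within 3× of its minimum,
roughly ±12° at this geometry).

## Fitting

`fit_profile()` minimizes Σ((I_obs − I_model)/σ)² over 11 parameters
(α, β, γ₀, Δγ₀, λ per family, plus a constant background) with bounded
Levenberg–Marquardt (`minpack.lm`). Key choices:

* **Weights**: σ = √max(I, 1) when the profile carries no
  uncertainties — the Poisson approximation appropriate for
  photon-counting detectors.
* **Bounds**: |α| ≤ 30°, IP |β| ≤ 45°, OP 60° ≤ |β| ≤ 90° (two sign
  branches explored separately, since the model is not symmetric under
  β → −β), Δγ₀ ∈ [3°, 90°], scales ≥ 0. γ₀ is optimised on a wider box
  and reported wrapped to (−90°, 90°], so truth near ±90° is not pinned
  at a bound.
* **Initialization**: lobes are detected, paired by ~180° separation,
  and classified by the pair midline — IP pairs sit near the vertical
  (|β| ≤ ~52°), OP pairs near the horizontal. Peak *width* is
  deliberately not used to classify families: counterintuitively, a
  near-isotropic distribution (Δγ₀ → 90°) produces *sharp* peaks
  (the 1/√(q_x²+q_z²) factor dominates), and a tight distribution
  produces broad ones. β is seeded from the pair midline, γ₀ from the
  deviation of the pair separation from 180° through the exact
  curvature relation, α from the height asymmetry, Δγ₀ from the lobe
  width via a forward-model lookup, and the scales by weighted linear
  least squares.
* **Multistart with ridge diversity**: the objective has a ridge at
  |α| = asin(q₁₁₀/2k) ≈ 4.3°, where the Ewald circle touches the thin
  ring exactly; twin local minima on either side can be numerically
  near-identical (residuals differing by parts in 10⁵ of the data
  scale). Candidate starts therefore vary α on both sides of the ridge
  as well as γ₀ and Δγ₀, and the start ranking is forced to keep
  representatives of all three α regimes rather than ranking by
  objective alone.
* **Block refinement**: after the joint multistart, each family block
  is re-seeded and refit with the other family pinned, sweeping until
  no further improvement (at most 3 sweeps); block results near the
  incumbent get a joint polish, because releasing the pinned family
  can break a tie. A final polish runs at tight tolerances
  (ftol = ptol = 1e−15), since weakly identified directions — e.g. the
  α of a low-fraction, broad family — form long flat valleys that the
  default stopping rule exits early.
* **Flags**: Δγ₀ > 85° marks a family as near-isotropic with weakly
  determined γ₀ (at Δγ₀ = 90° the in-plane direction is formally
  unidentifiable). Non-convergence and failed scan points are flagged,
  never silently dropped.

`grid_fit()` provides the slow cross-check oracle: an exhaustive grid
over the angles (≥ 1° resolution, with a node-count guard at 10⁷) with
the scales solved by weighted linear least squares at every node.

## Synthetic data: what it emulates, and what it does not

The generators produce azimuthal profiles (`simulate_profile`),
Pilatus-class detector frames (`render_image`: azimuthal model ×
radially Gaussian ring + uniform background, Poisson-sampled) and mesh
scans (`simulate_scan`; `carina_param_field()` builds a 7×12 grid at
100 µm spacing whose IP β tilt sweeps linearly from +17.5° on one side
of the ridge to −15.1° on the other, the gradient observed across a
carina). Noise is Poisson throughout (photon counting); all generators
are deterministic under a fixed seed and attach their ground truth as
machine-readable attributes, so recovery tests never hand-copy
parameters.

Real frames differ in ways the generator does not emulate: diffuse
scatter with radial structure (the flat background and optional
flanking-annulus subtraction are first-order stand-ins), detector gaps
and dead zones (masked pixels are supported but not generated by
default), polarization and solid-angle corrections (omitted; hooks
would sit in the regrouping step), sample absorption, and multiple
overlapping reflections. Passing recovery tests on synthetic data
therefore demonstrates the correctness of the geometry, model and
optimizer — not robustness to every instrumental systematic.

## Default parameters

| parameter | default | units | why |
|---|---|---|---|
| d₁₁₀ | 4.6 | Å | α-chitin (110) lattice spacing (literature unit cell); configurable |
| wavelength | 0.6888 | Å | 14 keV microfocus beamline setting |
| distance | 262.3 | mm | typical calibrated sample–detector distance |
| pixel size | 0.172 | mm | Pilatus-class detector |
| a_x | 0.02 | Å⁻¹ | moderate intrafibrillar alignment for integral-model work; the fit uses the a_x → 0 closed form |
| Δβ | 5 | ° | convolution width regularizing the closed form |
| annulus half-width | 0.05 | Å⁻¹ | radial window for regrouping the (110) ring |
| n_chi | 360 | bins | 1° azimuth bins |
| Δγ₀ bounds | [3, 90] | ° | below 3° the lobes alias the bin width; 90° is the isotropy limit |

## Numerical choices and problem sizes

Quadrature: 2048 periodic midpoint nodes for the integral model;
convolution grid 0.25°; spherical maps for power-conservation checks
use a 145×288 mesh with a broad kernel (a_x = 0.15 Å⁻¹) so the band is
resolved by the mesh. The test suite sizes simulations for a default
laptop run: recovery property tests use 12 random single-family draws
on 180-point profiles; the Monte-Carlo noise study uses 50 replicates
at 10⁴ peak counts; the scan tests use small grids (≤ 5 points) for
fitting and the full 84-point mesh for structural checks only. These
sizes are the package's choice of a thorough-but-routine regression
battery; the generators scale to arbitrary sizes.

## Known limitations

* Only equatorial (hk0-type) rings are modelled; meridional (00l)
  reflections require sample-orientation-dependent treatment and are
  out of scope, as is simultaneous multi-ring fitting.
* The family count is user-specified (1 or 2); the package does not
  select it by model comparison.
* Calibration (beam centre, distance) is an input, not refined from
  calibrant rings.
* γ₀ is reported but weakly meaningful for near-isotropic families
  (flagged at Δγ₀ > 85°).
* EDF/HDF5 frame containers are not read in this build; frames are
  accepted as TIFF or plain-text matrices.
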