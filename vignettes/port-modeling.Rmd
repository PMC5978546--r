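---
title: "Modeling the tissue-expander metallic port for photon dose calculation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the tissue-expander metallic port for photon dose calculation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xpanderdose)
```

## The problem

Temporary breast tissue expanders contain a magnetic injection port: a
neodymium magnet (nominally 21 mm x 3.5 mm, 7.4 g/cm^3) in a thin titanium
shell. During postmastectomy radiotherapy the port sits inside the treated
volume, and treatment planning systems handle the resulting high-density
heterogeneity poorly: depending on how the port is contoured and
density-overridden, planned doses near the port can be off by around 10%.
`xpanderdose` implements a radiological model of the port - a homogeneous
tilted disk whose dimensions and density are *calibrated against depth-dose
measurements* rather than taken from the physical part - together with the
synthetic phantoms, dose engine and evaluation tooling needed to exercise and
compare port models end to end.

Three port models are represented by density-override policies:

* **clinical1** - magnet and shell contoured at physical dimensions, nominal
  densities (7.4 / 4.2 g/cm^3), artifacts overridden as water. Tends to
  *overestimate* attenuation.
* **clinical2** - a single artifact-contaminated contour keeping CT-derived
  densities through a conversion table that saturates at a clinical cap
  (3.0 g/cm^3 here). Tends to *underestimate* attenuation.
* **new** - the calibrated disk (17.5 mm x 5 mm at 7.5 g/cm^3), artifacts
  overridden as water.

## Geometry and conventions

World coordinates are right-handed LPS-like millimetres (x left, y posterior,
z superior); axial slices are perpendicular to z; voxel values sit at voxel
centres and the grid extent is half-open. The disk axis starts
anterior-posterior `(0, 1, 0)`; the sagittal tilt (about x) is applied first,
then the transverse tilt (about z), degrees, right-hand rule. No rotation
order or sign convention is claimed from measurements - it is a documented
package choice. "Perpendicular" setup means the beam travels along the disk
axis (central chord = thickness, projected image = the disk circle);
"parallel" means the beam lies in the disk plane (central chord = diameter).

Ray-chord queries are solved analytically (lateral-surface quadratic
intersected with the cap slab). Slice contours exploit convexity of plane
sections of a convex solid: rays from an interior seed are bisected to the
boundary, with the vertex count chosen to keep vertex spacing under 0.5 mm.
Rasterization is a voxel-centre inclusion test; note that grids whose voxel
centres lie exactly on a cap plane count both boundary layers, so analyses
here use half-voxel-offset grids.

The titanium shell is excluded from the default model: its areal density,
`areal_density(0.04, 4.5)` = 0.18 g/cm^2, is below the 0.2 g/cm^2 level that
visibly changes calculated doses. It remains representable via the optional
`shell` spec.

## The dose engine

The engine is a deliberately compact stand-in for a commissioned
collapsed-cone system - accurate enough to reproduce transmission physics,
simple enough to verify against closed forms. Per voxel, the primary dose is

```
fluence x wedge x (SAD / r)^2 x PDD(d) x exp(-mu/rho * max(0, t_rad - d/10))
```

where `d` is the physical depth from the beam's entry into tissue (mm),
`t_rad` the Siddon voxel-traversal radiological path (g/cm^2), and the
`max(0, .)` excess-areal-density term carries all heterogeneity. In
homogeneous water the excess vanishes and the engine *equals* the closed form
`fluence x inverse-square x PDD` - the engine's analytic anchor, held to 1%
in the tests. Inserting a port multiplies the primary dose by exactly
`exp(-mu/rho (rho - 1) chord / 10)`, which the tests check to 3% against the
analytic chord. Densities below water (lung) are clamped by the `max(0, .)`
and treated as water; under-dense corrections are a known limitation.

Key parameters (per energy, `beam_data_table()`):

| parameter | 6 MV | 10 MV | 15 MV | units | role |
|---|---|---|---|---|---|
| `mu_rho` | 0.0493 | 0.0382 | 0.0327 | cm^2/g | effective attenuation |
| `a` | 0.25 | 0.15 | 0.12 | 1/mm | build-up rate |
| `b` | 0.0050 | 0.0042 | 0.0035 | 1/mm | exponential fall-off |
| `dmax` | 15 | 25 | 30 | mm | PDD normalization depth |
| `sigma0`, `sigma_k` | 3, 0.05 | 3, 0.05 | 3, 0.05 | mm, - | scatter width `sigma(d) = sigma0 + k d` |

PDD is `(1 - exp(-a d)) exp(-b (d - dmax))` normalized to 1 at `dmax`, with a
mild field-size factor `b (100 / sqrt(fx fy))^0.05`. Scatter is a unit-mass
lateral Gaussian convolution of the primary grid in planes perpendicular to
the dominant beam axis, with edge-renormalized kernels: broad flat fields are
preserved (the anchor holds with scatter on) while shadow edges smear, which
is the mechanism that washes out thin-port shadows at shallow depths.
`scatter = FALSE` gives the bare primary for oracle tests.

Wedges are modeled as a transmission gradient across the wedged field
direction: unity at the centre and on the thin side, log-linear on the thick
side with slope `(b_eff + 2/1000) tan(theta)` so that the fitted tilt of the
10 cm isodose in water equals the nominal wedge angle (the `2/1000` term is
the inverse-square contribution to the depth fall-off at the nominal SAD
100 cm geometry). A log-linear rather than linear factor is used because the
linear form makes the log-dose gradient - and hence the fitted tilt - drift
~5% across a 10 x 10 field. The (0, 1] clipping means the thin half of the
field is unattenuated; tilt is therefore fitted on the thick side.

Plans are weighted beam sums normalized so the prescription is met at the
isocenter (configurable normalization point); arcs discretize at 10 degrees
by default; IMRT-style beams take fixed fluence grids (no inverse
optimization - out of scope).

## Calibrating the port model

The calibration emulates the measurement loop that produced the 7.5 g/cm^3
model: ion-chamber depth doses at 7-15 cm depth (SSD 85 cm, 10 x 10 cm^2,
port top face 5 cm deep) for parallel and perpendicular setups at 6, 10 and
15 MV, fit by the RMS of relative calculated-vs-measured differences with
equal weights (the objective form is a package choice; only "minimizing the
differences" is prescribed by the source measurements' description).

Depth doses are predicted by an analytic central-axis model
(`ic_depth_dose()`): open-water dose times an observed transmission in which
the chord attenuation deficit is weighted by the fraction of a lateral
Gaussian of width `sigma(d)` covered by the geometric shadow (a disk of the
port diameter for the perpendicular setup; for the parallel setup, a strip of
the port thickness with the chord varying across the diameter, integrated by
an 81-node midpoint rule). This scatter-aware transmission matters for more
than realism: with bare central-ray attenuation, on-axis depth doses depend
on the port only through the products `(rho - 1) x thickness` and
`(rho - 1) x diameter`, and the joint (density, diameter, thickness) fit is
structurally unidentifiable. The depth dependence of the shadow coverage is
exactly what separates dimensions from density - and it reflects the reported
physics (density raises near-port scatter while deepening attenuation).
Synthetic measurements for recovery studies come from the same model with
seeded multiplicative Gaussian noise of stated sigma.

The search is a coarse-to-fine grid (density 4-10 step 0.5; diameter 10-25
step 2.5 mm; thickness 2-8 step 1 mm; two x0.1 refinements; ties toward the
smaller density). Because the objective is nearly flat along
density/dimension trade-off ridges, each refinement zooms around the several
best previous candidates rather than a single argmin, and a bounded
Levenberg-Marquardt polish of the (smooth) relative-residual vector pins the
optimum; the polished point is appended to the diagnostics curve so the
reported optimum always equals the curve minimum. Noise-free joint fits then
recover random ground-truth ports to within one final grid step
(0.005 / 0.025 / 0.01), and with 0.5% noise the median recovered density
stays within 2% of truth.

`fit_port_parameters(..., check_parallel_only = TRUE)` reproduces why
single-setup fitting fails: holding the film-derived thickness (2.5 mm, an
underestimate of the radiological 5 mm) and adjusting density against the
parallel records alone leaves the perpendicular records badly mispredicted,
unlike the joint fit.

## Synthetic phantoms

* **Ion-chamber tank** (`build_ic_phantom()`): water, SSD 85 cm, isocenter at
  15 cm depth, port top face 5 cm deep, sampling 7-15 cm.
* **Anthropomorphic phantoms** (`build_anthro_phantom()`): a water-equivalent
  block (63 mm inflated / 20 mm deflated) over a 10 mm bolus chest wall over
  a wooden lung slab at 0.30 g/cm^3 (the wood density is a configurable
  package choice; no measured value is available). Port centre 20 mm deep;
  lateral half-widths set so the gantry-90/270 SSDs are 90.7 and 95 cm.
  Four TLD points: 1, 2, 4 at 25 mm from the port centre, 3 directly under
  it on its axis (its axial distance, 25 mm, is a documented choice - only
  its lateral position is constrained by the setup drawing). The validation
  design uses 28 TLD packets (24 measurement + 1 background + 3 calibration).
* **Patient-like chest** (`build_patient_like()`): a synthetic half-cylinder
  chest with an expander sphere, the port at its anterior face with seeded
  tilts, a chest-wall PTV wrapping the expander, CT streak artifacts, and
  four evaluation points - two skin points at 12 mm depth on the exit sides
  of the opposed-tangent (307/127 degrees) axis through the port, two
  chest-wall points behind the expander. Deterministic per seed.

Metal artifacts are simulated as seeded alternating bright/dark radial
streaks (`magnitude x cos(n (phi - phi0))`, default 8 streaks at +/-300 HU)
decaying linearly to zero at 8 cm: enough structure to contaminate contours
the way the clinical models require, with no claim of reconstruction physics.

What the generators do *not* emulate: CT noise and beam hardening, anatomical
realism, deformable expander membranes, polyenergetic spectra, electron
contamination. Passing tests therefore demonstrate the correctness of the
geometry, transmission arithmetic and analysis chain - not commissioning-grade
dosimetric accuracy on real patients.

## Evaluation tooling

Percent differences are rounded half away from zero (the convention under
which the published comparison tables reproduce); the phantom TLD table uses
1 decimal and the patient table 2. Recomputing every percent difference from
the shipped dose columns reproduces the patient table exactly; in the phantom
table the dose columns are themselves printed rounded to 0.1 cGy, so 15 of 72
recomputed differences legitimately land one unit of the last printed digit
away. DVHs are cumulative (`V(0) = 100`, non-increasing) with 0.01 Gy bins
for phantoms and 0.5 Gy for the patient-like case. The reduced PTV keeps only
port-containing slices and removes expander and port. FWHM estimation uses a
baseline from the outer 20% of the profile (a package choice; no baseline
rule is prescribed) with linear interpolation at the half level; on box
troughs it is unbiased to within one pixel for spacings up to 0.5 mm. TLD
calibration is an ordinary least-squares line (reading to dose) inverted for
lookup.

## Numerical choices and degenerate inputs

* Problem sizes: on-axis engine checks use narrow 1-2 mm water grids
  (~0.5 M voxels); rasterization oracles use 0.25 mm grids over the port
  bounding box; calibration recovery uses 50 random ports (tests) and 10
  (acceptance script); the patient demo runs 2-beam plans on a 2 x 2 x 2.5 mm
  grid. These sizes keep every check comfortably reproducible on one CPU.
* Chord queries: rays parallel to the axis or in the cap plane are handled as
  degenerate slabs; zero-norm directions error.
* Contouring of grazing sections falls back to progressively finer interior
  scans before declaring no intersection.
* `density = 0` candidates are accepted in calibration (a vacuum port
  attenuates nothing: `max(0, rho - 1)` in the exponent).
* Dose grids must be entered by the beam to score dose; rays that never meet
  tissue score zero with a warning.
* All randomness (artifacts, patient phantom, synthetic noise) flows through
  seeded, state-restoring generators; identical seeds give identical volumes.

## Known limitations

The engine is not a collapsed-cone or Monte Carlo system: no polyenergetic
spectra, no electron transport, no lateral electron disequilibrium in lung,
under-dense media treated as water in the primary term. The analytic IC model
and the 3D grid engine share the transmission physics but are not numerically
identical (separable Gaussian vs in-plane convolution). Whether the engine
reproduces the specific shallow-depth perpendicular discrepancies reported
for the commercial system is deliberately not asserted. DICOM export is not
provided; NRRD/MetaImage and JSON structure sets are the interchange formats.
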