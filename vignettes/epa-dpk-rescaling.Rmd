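---
title: "Equivalent-path-length rescaling of electron dose point kernels around gold nanoparticles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equivalent-path-length rescaling of electron dose point kernels around gold nanoparticles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanodpk)
```

## The problem

Gold nanoparticles (GNPs) taken up by tumour cells act as radiosensitizers:
keV photons interact strongly with gold (photoelectric cross-sections scale
roughly as Z^4–5), releasing short-ranged secondary electrons that deposit
a highly localized extra dose in the first nanometres to micrometres of
surrounding tissue. Resolving that dose with a general-purpose Monte Carlo
transport code is expensive — nanometre voxels, billions of histories — so
hybrid methods are attractive: compute one electron **dose point kernel**
(DPK, the radial dose around an isotropic point electron source in water)
and superpose it analytically over the nanoparticle geometry.

The complication is that the kernel is a *water* kernel, while part of each
source-to-tally path runs through gold, where electrons lose energy roughly
an order of magnitude faster per unit length. The **equivalent path length
approximation** (EPA) absorbs this heterogeneity into a single dimensionless
factor `alpha >= 1`:

```
MPL = GPL + (alpha - 1) * DTI
```

where GPL is the geometric distance from a source point (SP) inside the
particle to a tally point (TP) in water, DTI is the distance traversed
inside the particle along that segment, and the water kernel is evaluated
at the modified path length MPL. This package implements that method
end-to-end for nanospheres, nanorods, and pixelated two-dimensional
cluster geometries, together with the tooling around it: secondary-electron
spectrum generation, the four standard rescaling factors, a simplified
transport oracle for validation, and MAPE-based profile comparison.

## Rescaling factors

Four choices of `alpha` are provided (`factor_unity()`, `factor_tsp()`,
`factor_lrr()`, `factor_pdr()`):

* **unity** — `alpha = 1`; geometry-based rescaling only. The kernel is
  evaluated at the plain GPL.
* **TSP** — the secondary-electron-spectrum-weighted ratio of linear total
  stopping powers, `sum(w_i E_i TSP_Au(E_i)) / sum(w_i E_i TSP_w(E_i))`,
  over the occupied spectrum bins with centers `E_i` and weights `w_i`.
* **LRR** — the spectrum-weighted linear range ratio
  `sum(w_i E_i CSDA_w(E_i)) / sum(w_i E_i CSDA_Au(E_i))`.
* **PDR** — the physical density ratio, 19.3 for gold/water; a pure
  material property and the upper bound of the family.

Three conventions here were genuinely open and are package decisions:

1. **Linear, not mass, quantities.** The defining equations do not say
   whether stopping powers and ranges are mass or linear quantities. We use
   linear (per-length) values: the EPA rescales *path lengths*, and the
   density-ratio factor — a pure ratio of linear scales — is its limiting
   case. With mass quantities the PDR would be unity, contradicting its
   published value.
2. **Bin centers.** `E_i` is taken at the center of each occupied
   spectrum bin; with the default 0.1 keV bins the center/edge difference
   is far below every other uncertainty in the chain.
3. **Log-log interpolation, no extrapolation.** Stopping-power and range
   tables are interpolated log-log (both quantities are near power laws in
   energy); energies outside the tabulated grid raise an error rather than
   extrapolate.

## Secondary-electron spectra

`secondary_electron_spectrum()` implements a deliberately simple
first-interaction model: photons sampled from the line spectrum eject
photoelectrons of energy `E_gamma - B` from shells chosen among the
energetically allowed ones with fixed relative probabilities, plus
fixed-energy Auger electrons per vacancy. Compton scattering and pair
production are omitted — at the 50–310 keV energies of a Yb-169 source
interacting with gold, photoelectric absorption dominates — and the
spectrum is an *input* to the factor computation, so any externally
computed spectrum can be substituted via `electron_spectrum()` or the CSV
reader. Default bin width is 0.1 keV, the convention for keV brachytherapy
sources; 1 keV suits megavoltage spectra.

The bundled gold shell data (`gold_shells()`, `gold_auger()`) and the
gold/water stopping-power tables (`gold_table()`, `water_table()`) are
labelled *synthetic*: the shell probabilities are fixed simplifications of
standard X-ray data, and the material tables are computed from the
relativistic Bethe collision formula with an approximate radiative term
(`data-raw/stopping_tables.R`) rather than taken from an evaluated
database. They are accurate at the ~10% level above ~10 keV — adequate for
spectrum-weighted ratios, not for reference dosimetry. With these inputs
the Yb-169 factors computed by `scripts/acceptance.R` land close to the
values reported for this source class (TSP near 8, LRR near 10, PDR 19.3
exactly).

## Kernels and profiles

`kernel_from_deposits()` builds a DPK by histogramming point energy
deposits into uniform concentric shells and dividing by shell mass and
source count; the energy-conservation identity
`sum(dose * mass * n_source) = sum(e_dep)` holds to floating-point error by
construction and is property-tested. `kernel_value()` interpolates linearly
between shell centers, returns the first shell's value below the first
center, and 0 beyond the last center (electrons have finite range). The
interpolation rule at an arbitrary MPL is a package decision; no published
convention exists.

`profile_sphere()` and `profile_rod()` estimate shell-averaged dose
profiles by pair sampling: SP uniform in the particle, a distance bin
chosen uniformly (stratified, so distant bins are not starved), the TP
placed in that bin's scoring shell, and the kernel accumulated at the MPL.
The per-bin mean of kernel values is the profile. This estimator is a
package decision; it is chosen because it reproduces the homogeneous
kernel exactly in the point-source limit (verified to MAPE < 2% per
million pairs) and matches volume-averaged shell scoring semantics. TP
placement is uniform in distance within a bin rather than volume-weighted;
over nanometre bins the difference is negligible.

For nanorods (axis along z, radius `r`, half-length `h`) exterior space is
partitioned by the long-axis cone (`tan(omega) = r/h`) and short-axis cone
(`tan(theta) = h/r`); profiles are scored in two cone frustums beyond the
caps (long axis) or the cone-bounded hollow cylinder beyond the side
(short axis). Boundary points, where the defining inequalities become
equalities, classify as "neither" and are not scored — the strict
inequalities of the printed conditions. The closed-form scoring volumes
are validated against rejection-sampling Monte Carlo estimates in the test
suite. `dti_rod()` computes the exact first exit over the full rod
boundary (caps and lateral surface) rather than assuming the exit surface
from the TP's region: an SP–TP segment can leave through a cap even when
the TP lies in the short-axis region.

## The pixelated 2D cluster method

For clusters segmented from microscopy images, `grid_from_image()` labels
a pixel gold when its mean RGB value falls below a global threshold
(default 0.4). Each gold pixel is an isotropic point source at its center;
`dose_map()` superposes the kernel over all water pixels, with the DTI
obtained by Bresenham traversal: the count of gold pixels *strictly
between* the endpoints times the pixel size (endpoint handling is
unspecified in the published method; excluding both endpoints is the
package's decision, and exact chord-length traversal is a possible
extension). Gold pixels score no dose. `normalize_relative()` rescales to
the maximum water-pixel dose for display. `synth_cluster()` generates
random disc-cluster grids as a synthetic stand-in for TEM segmentations,
which are rarely deposited alongside publications.

## The transport oracle, and what validation does and does not show

`transport_homogeneous()` and `transport_sphere_source()` implement
straight-line continuous-slowing-down transport: no multiple scattering,
no bremsstrahlung escape, no secondaries; energy is deposited at step
midpoints and the sub-cutoff remainder locally, so conservation is exact
(tested to 1e-9 relative). The default 0.25 keV cutoff mirrors the
conventional 250 eV nanodosimetry threshold; steps are capped at
`max_step` and at 2% energy loss, and inside a particle also at the
remaining distance to the boundary, so each step sees one material.

This oracle deliberately shares its physics with nothing but the package
itself. What it *can* validate: the geometry engine, the path
decomposition, kernel construction, and the estimator — with matched
physics, any discrepancy between the rescaled profile and the oracle is
attributable to the EPA itself. What it *cannot* show: agreement with
condensed-history Monte Carlo (scattering, energy straggling, delta rays),
which is the published method's actual reference.

One result of this validation deserves emphasis. Under straight-line
physics the exact dose at a tally point can be written in closed form:
the electron's residual energy at the TP is what it would have after a
water path of length MPL, but its fluence has diluted over the geometric
sphere of radius GPL, so the exact dose is `K(MPL) * (MPL/GPL)^2` — not
`K(MPL)`. The plain EPA estimate therefore carries an intrinsic low bias
that grows with `(alpha - 1) * DTI / GPL`. The test suite verifies the
corrected closed form against the oracle to within Monte Carlo noise
(a few percent), while the plain `K(MPL)` method — implemented exactly as
published — shows MAPEs rising from under 20% at a 5 nm sphere radius to
roughly 60% at 100 nm under gold-like contrast (`alpha ~ 10`), as
recomputed by `scripts/acceptance.R`. We keep the published form as the
method (the solid-angle factor is part of *this* limit's exact solution,
not necessarily of scattering-dominated transport, where lateral diffusion
redistributes fluence) and surface the bias here so users can judge it.

## Toy fixtures and problem sizes

The matched-physics validation uses `toy_material_tables()`: analytic
power-law stopping powers (`S = s0 (E/10 keV)^-p`) whose CSDA ranges are
the exact integrals, so interpolation and range are mutually consistent.
The default pair has gold-like linear contrast (about 10 at 10 keV, the
realistic gold/water magnitude for keV spectra) with slightly different
exponents, making the spectrum-weighted factor a genuine average. The
validation spectrum is flat over 8–12 keV, giving toy-water ranges of
1.2–2 µm so that the first micrometre of profile is fully populated.

Default problem sizes — 1e4–2e4 oracle electrons, 3e5–1e6 sampled pairs,
20 nm comparison bins over 1 µm — were chosen as the package's desk-scale
defaults: they hold per-bin Monte Carlo noise near or below a percent,
comfortably below the effects being measured. Every stochastic routine
takes an explicit seed and is bit-reproducible; all randomness in the
acceptance script derives from its single `--seed` argument.

## Known limitations

* The secondary-spectrum model is photoelectric-only with fixed shell
  ratios; Compton recoil electrons (relevant above ~200 keV) and cascade
  detail are absent.
* The bundled stopping-power tables are Bethe-formula synthetics, weak
  below ~10 keV where shell corrections matter.
* The transport oracle's straight tracks understate lateral spread;
  validation against it bounds implementation error, not physical error.
* The 2D cluster method is genuinely two-dimensional (distances between
  pixel centers in the plane); the out-of-plane extent of a real specimen
  is not modelled.
* `dose_map()` is an exact O(gold x water) double loop; fields much beyond
  ~10^4 pixels with `alpha > 1` call for patience or coarser grids.
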