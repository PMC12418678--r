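---
title: "Multipole refinement against theoretical structure factors: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multipole refinement against theoretical structure factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcfit)
```

## The problem

Transferable pseudo-atom databanks store averaged multipole-model
parameters per atom type. To generate such parameters one fits a
Hansen–Coppens multipole model (MM) to *theoretical* static structure
factors: a molecule is placed in a large pseudo-cubic cell, the Fourier
transform of its valence electron density is sampled on the reciprocal
lattice, and the MM parameters are refined against those complex
amplitudes with the scale factor fixed at 1 and no thermal motion. The
quality of the resulting charge density is then judged not only by the
crystallographic R factor but by real-space electrostatics: correlation
of electrostatic-potential (ESP) grids, QTAIM atomic electron
populations integrated over *unified* basins, and the ESP averaged over
iso-density molecular surfaces.

`hcfit` implements this entire loop, replacing the quantum-chemical
wavefunction stage with a synthetic reference generator so that every
stage is testable offline with known ground truth.

## The pseudo-atom model

Each atom contributes

$$\rho_a(\mathbf r) = P_c\,\rho_{core}(r)
  + P_v\,\kappa^3 \rho_{val}(\kappa r)
  + \sum_{l=0}^{l_{max}} \kappa'^3 R_l(\kappa' r)
    \sum_{m,\pm} P_{lm\pm}\, d_{lm\pm}(\theta,\varphi),$$

with $r$ measured from the nucleus in the atom's local frame.

* $\rho_{core}$, $\rho_{val}$ are spherical Slater-type *density*
  expansions $\sum_i c_i r^{n_i} e^{-\zeta_i r}$ taken from a
  radial-function databank. The stored shells integrate to their
  electron counts; $P_v$ multiplies the unit-normalized valence shape,
  so its value is an electron count.
* $R_l(r) = \frac{\zeta_l^{n_l+3}}{(n_l+2)!} r^{n_l} e^{-\zeta_l r}$ is
  the normalized single-Slater deformation radial function
  ($\int R_l r^2 dr = 1$).
* $d_{lm\pm}$ are density-normalized real spherical harmonics
  ($\int |d_{lm}| d\Omega = 2$ for $l\ge1$), so $P_{lm}$ measures
  electrons moved between lobes. The normalization constants are
  computed once by piecewise-exact quadrature between the roots of the
  associated Legendre factors.
* $\kappa$ and $\kappa'$ are the radial expansion–contraction
  parameters of the spherical and aspherical valence density; one
  $\kappa'$ per atom shared across all $l$.

Truncation follows standard practice for this kind of refinement:
hexadecapoles ($l\le4$) for non-hydrogens, quadrupoles ($l\le2$) for
hydrogens, and hydrogens carry only bond-oriented $m=0$ terms in a
frame whose local $z$ points along the X–H bond. Chemically identical
hydrogens share $\kappa,\kappa'$; symmetry-equivalent atoms (the six
waters of the hexaaqua-magnesium built-in, the two water hydrogens)
share their full parameter set. $P_c$ is fixed at 1 and never refined.
An $l=0$ deformation population exists in the schema but is off by
default — it is degenerate with $(P_v, \kappa)$ in least squares.

The shipped databank (`builtin_databank("slater-rules")`) is a
*synthetic* bank for H, C, N, O, Mg, Cl whose shell exponents follow
Slater screening rules. It is structurally interchangeable with
Clementi–Roetti-like or relativistic banks through the documented
plain-text schema, but its coefficients are not a reproduction of any
published table; shipping those is out of scope.

## Scattering and refinement

Structure factors use the crystallographic convention
$F(\mathbf H) = \int \rho(\mathbf r) e^{+2\pi i \mathbf H\cdot\mathbf
r_{frac}} dV$ on the cubic metric $s = |\mathbf{hkl}|/(2a)$. The
reciprocal lattice excludes the origin strictly and includes the upper
resolution bound; the full sphere is available, and a Friedel-unique
hemisphere is provided for economy (for real densities complex
amplitudes on a hemisphere carry the same information).

Radial transforms $\langle j_l\rangle(q)$ are evaluated in closed form
from the termwise Laplace transform of the spherical Bessel kernels,
switching to an ascending series below $q = 0.2\,\zeta$ where the
termwise form cancels catastrophically; both paths agree to $10^{-10}$
and an adaptive-quadrature mode cross-checks them in the tests.

Refinement minimizes $\sum |F_{target} - k\,F_{model}|^2$ (complex
residuals by default — theoretical phases are known; a modulus mode
fits $|F|$ as conventional refinement programs do, and both are
tested). Populations enter linearly, so their Jacobian columns are
exact; $\kappa$-type parameters get central finite-difference columns
on the affected atom only. Steps are Levenberg-damped Gauss–Newton
with rejection, so the residual norm never increases; $\kappa$-type
parameters are clipped to (0.5, 2). Constraint ties are enforced by
parameter elimination (tied parameters occupy one slot of the packed
vector), so they hold exactly at every iterate. Unit weights are used
throughout: theoretical static data carry no experimental sigma.

With $F(000)$ excluded by $0 < s$, the total electron count is almost
unconstrained. The refiner therefore offers an optional
electroneutrality constraint (a stiff pseudo-observation pinning
$\sum P_v$), off by default in `fit_multipole_model()`. The comparison
pipeline turns it on: on targets the MM cannot represent exactly, an
unpinned monopole absorbs ~0.05–0.1 e of spurious charge whose $q/r$
tail dominates every far-field ESP comparison.

## The synthetic reference

`synthetic_spec()` + `generate_case()` emulate production inputs. The
built-in geometries are idealized (water, ammonia, an alanine molecule
assembled from literature-typical bond lengths and angles, and an
octahedral hexaaqua-magnesium dication with all six waters
symmetry-equivalent); X–H distances are reset to typical
neutron-diffraction averages (C–H 1.089, N–H 1.015, O–H 0.967 Å).
Ground-truth parameters are drawn through one seeded RNG: valence
populations uniform within ±0.2 e of neutrality (then shifted so the
total electron count is exact), multipole populations uniform within
±0.06 e, $\kappa,\kappa' \sim U(0.9, 1.1)$ — magnitudes typical of
refined organic-molecule multipole models.

The "wavefunction-like" gap between a reference density and the best
MM is emulated by charge-neutral Gaussian bond bumps: +0.05 e at each
bond midpoint, −0.025 e at the two bonded atoms, width 0.3 bohr —
the scale of residual bond-density features seen in deformation maps.
Pairing positive and negative parts keeps each atom's local charge
roughly neutral, so far-field ESP remains comparable between truth and
reference, as for real wavefunction-vs-MM pairs. Their structure
factors are added analytically (Gaussian transform), so the target is
exact rather than grid-limited.

What the generator does *not* emulate: basis-set-specific wavefunction
differences, core polarization, and cusp behaviour at nuclei. A green test suite
therefore demonstrates the correctness of the fitting and comparison
machinery, not the physics of any particular wavefunction.

## Grids, fields, ESP

Grids follow the Gaussian-cube convention: isotropic step, x slowest /
z fastest, edge $= (n-1)\cdot step$. The production-scale reference
grid — 270 points per axis at 0.094486 bohr, 19 683 000 points,
edge 25.416734 bohr — is representable and checked, but desk-scale
work uses 48³–96³ grids. Density and ESP grids for the MM and IAM are
built with core electrons re-expanded, mirroring the valence-only
refinement followed by full-density grid work.

The ESP is evaluated analytically per pseudo-atom through the
inside/outside radial-moment decomposition
$V_{lm}(r) \propto r^{-l-1}\int_0^r R\,s^{l+2}ds + r^l\int_r^\infty
R\,s^{1-l}ds$, which for single-Slater radial functions reduces to
incomplete-gamma closed forms; a finite-difference Poisson check
($\nabla^2 V = -4\pi\rho$) guards the implementation. A grid point
within $10^{-6}$ bohr of a nucleus gets the nuclear term evaluated at
a $10^{-6}$ bohr offset — deterministic and affecting at most isolated
points. For oracle grids that tile a periodic cell, densities are
evaluated under the minimum-image convention (with a full
corner-image sum for diffuse shells), so the FFT of the samples
differs from the analytic transform only by reciprocal-space aliasing.

## Comparison statistics

* **R factor** $\sum||F_o| - k|F_c||/\sum|F_o|$ with $k$ fixed at 1.
* **Pearson correlation** of ESP grids over all points.
* **Unified basins**: QTAIM basins are generated once on the
  *reference* density by near-grid steepest ascent (26-neighbour
  slopes, deterministic lexicographic tie-break), then both densities
  are integrated over the same basins, so $\Delta N$ is untouched by
  boundary-definition differences and is exactly zero for a field
  against itself. Two corrections make the grid method faithful:
  attractor fragments within 2.5 steps are merged (discretized flat
  maxima), and boundary plus low-density voxels
  ($\rho < 10^{-3}$ e bohr⁻³, where 26-direction quantization drifts
  over long flat chains) are re-assigned by Heun trajectories on the
  trilinearly interpolated **log**-density gradient — parallel to the
  density gradient but numerically faithful in exponential tails.
  Voxels below $10^{-10}$ e bohr⁻³ are assigned to the nearest
  attractor so the partition conserves the grid sum exactly. Hydrogen
  attractors in X–H bonds are shallow (the dip between H and its heavy
  atom is a few 0.01 e bohr⁻³ deep); resolving them needs steps
  ≲ 0.12 bohr, which is why production grids use steps near 0.09 bohr.
* **Iso-density surfaces** at 0.1, 0.05, 0.01, 0.001, 0.0001 a.u. by
  marching tetrahedra (six-tetrahedra cube decomposition, linear edge
  interpolation). The surface-averaged ESP is the area-weighted mean
  over triangle centroids (a discrete surface integral divided by
  area); an unweighted point-sampled mode exists for cross-checking
  and agrees on smooth cases. Errors between a system and the
  reference on the same surface are summarized as ME/MAE/RMSE.

## Problem sizes and defaults

Tests and the acceptance script run at desk scale, chosen as the
smallest sizes at which each property is cleanly measurable:
parameter-recovery refinements use the 30 Å pseudo-cubic cell
truncated at $s \le 0.7$ Å⁻¹ on a Friedel-unique hemisphere (155 088
reflections); FFT-oracle comparisons use 96³ grids on an 8.5 Å cell at
$s \le 0.5$ (the small cell pushes reciprocal aliasing of the sharpest
valence shells below $10^{-3}$ e); pipeline comparisons use a 15 Å
cell (so that low-order reflections constrain the monopole) with 64³
to 96³ grids. The full production resolution ($s \le 1.1$) and grid
(270³) are supported but not exercised by default.

## Known limitations

* A multipole model refined with unit weights against complex
  amplitudes optimizes the *density*, not the far-field potential.  On
  references with sharp non-representable bond features the fit can
  contract hydrogen deformation functions to their sanity bound and
  end up with a surface-ESP error on the lowest-density surfaces
  (0.001–0.0001 a.u.) *larger* than the spherical-atom baseline, even
  while beating it five-fold in R factor and on the high-density
  surfaces.  This ordering inversion on far-field surfaces is a known
  behaviour of the fitting protocol, not an artifact of this
  implementation; it appears for some seeds (e.g. the ammonia test
  case) and not others.

* The shipped databank is schematic; quantitative agreement with
  published pseudo-atom parameters requires loading a real bank
  through the file format.
* Grid-based basin populations inherit quadrature error of sharp core
  densities on coarse grids; the 1s cores need steps near 0.1 bohr for
  percent-level population accuracy.
* No thermal smearing, no coordinate refinement, no anomalous
  dispersion, non-cubic cells unsupported — all outside the modelled
  workflow.
* Periodic (lattice-summed) ESP and Ewald sums are not implemented;
  molecules are treated as isolated in a large cell.
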