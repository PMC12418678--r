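# hcfit

Hansen–Coppens multipole-model refinement against theoretical static
structure factors, with a full charge-density comparison suite.

## What it is for

Transferable pseudo-atom databanks (and any study of how well a
multipole model can represent a quantum-chemical electron density) rest
on one workflow: place an isolated molecule in a large pseudo-cubic
cell, compute *static* valence-only structure factors from a reference
electron density, fit the Hansen–Coppens pseudo-atom expansion

    rho_a(r) = P_c rho_core(r) + P_v k^3 rho_val(k r)
             + sum_l k'^3 R_l(k' r) sum_m P_lm d_lm(theta, phi)

to those amplitudes by constrained least squares (scale fixed at 1, no
thermal motion, hexadecapoles on heavy atoms, bond-oriented quadrupoles
on hydrogens), and then ask how close the fitted model's charge density
comes to the reference in real space: crystallographic R factor,
Pearson correlation of electrostatic-potential (ESP) grids, QTAIM
atomic electron populations integrated over *unified* basins
(basins generated once on the reference grid and applied to both
densities), and ESP averaged over iso-density molecular surfaces
(0.1 … 0.0001 a.u.) with ME/MAE/RMSE error summaries.

`hcfit` implements every stage in R: Slater-type radial-function
databanks (documented plain-text schema), analytic aspherical
scattering factors with closed-form Fourier–Bessel transforms and an
independent grid-FFT oracle, damped Gauss–Newton refinement with exact
population Jacobians and constraint ties, density/ESP grids in
Gaussian-cube format, near-grid basin integration with
trajectory refinement, marching-tetrahedra iso-surfaces, and a
seedable synthetic reference generator that stands in for the
wavefunction stage by adding small charge-neutral bond-density
features a multipole model cannot represent.

## Worked example

```r
library(hcfit)

## a seeded synthetic case: ground-truth multipole model for water plus
## non-representable bond bumps, valence-only structure factors on a
## 15 Angstrom pseudo-cubic cell truncated at s <= 0.7 1/A
cs  <- generate_case(synthetic_spec("water", seed = 2),
                     a = 15, s_max = 0.7, friedel_unique = TRUE)

## refine from the independent-atom model and compare on 96^3 grids
rep <- run_comparison(cs, grid_n = 96L, grid_pad = 6)
rep
#> comparison_report [water-seed2]
#>   R(MM) = 6.931e-03   R(IAM) = 1.887e-01
#>   ESP correlation: CC(MM) = 0.99997126  CC(IAM) = 0.99886723
#>   max |dN| (MM): 0.003477 e
#>   surface-ESP MAE (a.u.) per level:
#>         0.1: MM 7.426e-03  IAM 2.556e-02
#>        0.05: MM 8.936e-03  IAM 2.889e-02
#>        0.01: MM 5.735e-03  IAM 1.716e-02
#>       0.001: MM 1.229e-03  IAM 9.972e-03
#>      0.0001: MM 3.362e-04  IAM 5.891e-03
```

Reading: the refined multipole model reproduces the reference
amplitudes to R = 0.7% where the spherical-atom baseline sits at 19%;
its ESP grid correlates with the reference at 0.99997; unified-basin
atomic populations agree within 0.0035 e; and the ESP mapped on every
iso-density surface is 3–20 times more accurate than the IAM's, with
the advantage largest far from the nuclei. On a case generated
*without* the non-representable bumps the same pipeline recovers the
generating parameters to ~1e-10 and R < 1e-11.

Individual stages are exported (`generate_hkl`, `structure_factors`,
`fft_oracle`, `fit_multipole_model`, `density_field`, `esp_field`,
`assign_basins`, `integrate_basins`, `extract_isosurface`,
`surface_average_esp`, `write_cube`, `write_report`, …), and
`inst/scripts/hcfit-cli.R` wraps case generation and the end-to-end
run for shell use.

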