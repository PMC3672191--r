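# fcshydro

Fluorescence correlation spectroscopy (FCS) measures the diffusion of
fluorescent molecules through a femtolitre observation volume by
autocorrelating intensity fluctuations. From the fitted diffusion
coefficient one can infer hydrodynamic size — and, when a molecule slows
down without growing, hydrodynamic *shape*. `fcshydro` is an R package
for that inference chain, written for biophysicists studying
conformational change (e.g. pH-induced unfolding of globular proteins)
with FCS and molecular-dynamics simulations.

It provides:

* **FCS forward model** — one/two-species autocorrelation for a 3D
  Gaussian observation volume,
  `G(τ) = G∞ + (1/N) Σᵢ fᵢ (1+τ/τ_Dᵢ)⁻¹ (1+τ/(s²τ_Dᵢ))⁻¹ᐟ²`, with
  one- and two-photon diffusion-time relations `τ_D = ω₀²/(4D)` and
  `ω₀²/(8D)`, and beam calibration against a reference dye
  (rhodamine 110, D = 300 µm²/s).
* **Fitting** — weighted bounded Levenberg–Marquardt with multi-start,
  parsimony-based one- vs two-species selection, residual-resampling
  bootstrap intervals; broom-style `tidy()` / `glance()` / `augment()`.
* **Hydrodynamics** — Stokes–Einstein radius `R = kT/(6πηD)`, the
  empirical native-protein scaling `R_N = 4.75 N^0.29` Å, and the Perrin
  prolate-ellipsoid model relative to the equal-volume sphere,
  `F(p) = √(1−p²) / (p²ᐟ³ ln[(1+√(1−p²))/p])`, inverted by bisection at
  fixed volume.
* **Synthetic data** — noisy analytic curves, Brownian-dynamics photon
  traces through a squared-Gaussian (two-photon) detection profile with
  Poisson counting, a multi-tau correlator, pH-titration curve sets with
  known truth, and toy trajectories with planted cluster structure.
* **Trajectory statistics** — MSD and Einstein-relation diffusion
  (`D = slope/6`), Kabsch-superposed RMSD, radius of gyration, Daura
  conformational clustering, Cα PCA and `−ln(P/Pmax)` free-energy
  landscapes.

## Worked example

Fit a noisy two-species curve (a 97/3 mixture of a slowed protein at
44 µm²/s and aggregates at 15 µm²/s), select the model, and interpret the
dominant coefficient as a shape change at fixed native volume:

```r
library(fcshydro)

beam  <- beam_geometry(omega0_um = 0.4, z0_um = 2.0)   # two-photon, s = 5
truth <- fcs_model(c(44, 15), fraction = c(0.97, 0.03), occupancy = 5)
curve <- simulate_curve(truth, beam, noise_cv = 0.02,
                        lag_s = lag_grid(1e-6, 1, 512), seed = 42)

fit1 <- fit_correlation(curve, 1, beam)
fit2 <- fit_correlation(curve, 2, beam)
compare_models(fit1, fit2)
#> # A tibble: 1 × 5
#>   selected    chi2_red_1 chi2_red_2 improvement minor_fraction
#>   <chr>            <dbl>      <dbl>       <dbl>          <dbl>
#> 1 two-species       1.17      0.943       0.197         0.0521

tidy(fit2)
#> # A tibble: 4 × 3
#>   term      estimate std.error
#>   <chr>        <dbl>     <dbl>
#> 1 occupancy    5.00    0.00850
#> 2 D1          44.7     1.69
#> 3 D2          18.5     6.42
#> 4 F1           0.948   0.0552

hydro_shape(tidy(fit2)$estimate[2], volume_A3 = sphere_volume(29))
#> # A tibble: 1 × 6
#>   D_um2_s R_sph_A   a_A   b_A      p D_model_um2_s
#>     <dbl>   <dbl> <dbl> <dbl>  <dbl>         <dbl>
#> 1    44.7    54.9  196.  11.2 0.0571          44.7
```

Reading the output: the second species is accepted (reduced χ² improves
by 20% and the minor fraction, 5%, clears the 0.5% floor); the dominant
coefficient 44.7 ± 1.7 µm²/s would correspond to an implausibly large
55 Å sphere, but is consistent with a strongly elongated prolate
ellipsoid (axial ratio ≈ 0.06) of the same ~10⁵ Å³ volume as a compact
29 Å native sphere (`stokes_einstein_radius(84)` → 29.2 Å). The last
column verifies the inversion: the shape's model-implied coefficient
reproduces the input.

The same chain runs over a whole titration with
`titration_scenario()` → `run_titration()` → `autoplot()`, and
`write_titration_report()` saves a CSV plus a JSON provenance block
(config, seeds, package version) so identical runs are byte-identical.

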