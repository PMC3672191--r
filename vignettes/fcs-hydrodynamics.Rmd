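---
title: "From correlation curves to molecular shape: the models behind fcshydro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From correlation curves to molecular shape: the models behind fcshydro}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcshydro)
```

## What the package models

Fluorescence correlation spectroscopy (FCS) watches the intensity
fluctuations produced by fluorescent molecules diffusing through a
femtolitre observation volume. The normalised autocorrelation of those
fluctuations decays on the timescale a molecule needs to cross the volume,
so its shape encodes the translational diffusion coefficient and its
amplitude the mean number of molecules in the volume. `fcshydro`
implements the standard analysis chain for such experiments —

1. an analytic forward model for the autocorrelation of one or two freely
   diffusing species in a 3D Gaussian observation volume,
2. weighted nonlinear least-squares fitting with parsimony-based model
   comparison and bootstrap uncertainties,
3. conversion of fitted diffusion coefficients into hydrodynamic size
   (Stokes–Einstein) and shape (Perrin prolate ellipsoid under an
   equal-volume constraint),

— together with a synthetic-data generator that stands in for the
instrument, and the standard post-processing statistics used on molecular-
dynamics trajectories (MSD/Einstein diffusion, superposed RMSD, radius of
gyration, Daura conformational clustering, C$\alpha$ PCA and free-energy
landscapes). The motivating application is pH-unfolding studies of
globular proteins, where the diffusion coefficient of a labelled protein
is tracked across a pH titration and its changes interpreted as changes of
molecular shape, but every component is generic.

## The autocorrelation model

For a 3D Gaussian detection profile with radial $1/e^2$ radius $\omega_0$
and axial radius $z_0$ (structure parameter $s = z_0/\omega_0 \ge 1$), the
autocorrelation of $n$ freely diffusing species is

$$G(\tau) = G_\infty + \frac{1}{N}\sum_{i=1}^{n} f_i
\left(1+\frac{\tau}{\tau_{D,i}}\right)^{-1}
\left(1+\frac{\tau}{s^2\,\tau_{D,i}}\right)^{-1/2},$$

with occupancy $N$ (mean molecule number in the volume, so
$G(0^+)-G_\infty = 1/N$), amplitude fractions $f_i$ summing to 1, and
per-species diffusion times $\tau_{D,i}$. The package supports one or two
species; no triplet/photophysics term is included (the baseline
$G_\infty$, fixed at 0 by default, is the only additive degree of
freedom). Fractions are amplitude fractions under an equal-brightness
assumption.

The diffusion time is linked to the diffusion coefficient by the beam
geometry:

$$\tau_D = \frac{\omega_0^2}{4D} \;(\text{one-photon}), \qquad
  \tau_D = \frac{\omega_0^2}{8D} \;(\text{two-photon}).$$

Two-photon excitation is the default: quadratic dependence on the
illumination intensity squares the detection profile, which halves the
effective residence time for the same waist. `calibrate_beam()` inverts
this relation to obtain $\omega_0$ from the fitted diffusion time of a
reference fluorophore; the conventional reference is rhodamine 110 with
$D = 300\ \mu m^2/s$. The effective volume
$V_\mathrm{eff} = \pi^{3/2}\omega_0^2 z_0$ is a reporting convention only
— concentrations depend on it, diffusion coefficients never do.

Units are fixed throughout: lag times in seconds, $D$ in $\mu m^2/s$, beam
radii in $\mu m$, hydrodynamic radii in Å, temperature in K, viscosity in
cP (converted internally to Pa·s).

## Fitting and model comparison

`fit_correlation()` minimises
$\sum_k \left[(g_k - G(\tau_k))/\sigma_k\right]^2$ with bounded
Levenberg–Marquardt (minpack.lm), using $\sigma_k = 1$ when no
uncertainties are given. Because the two-species objective is multimodal,
every fit is restarted from several log-spaced diffusion-time
initialisations derived from the curve's half-decay point, plus — for two
species — the one-species solution placed at the $f_1 = 1$ boundary. That
last start guarantees the nested-model property: adding a species can
never raise the minimised $\chi^2$. Species are always reported sorted by
descending $D$, so `F1` refers to the faster species. Default bounds are
$D \in [0.1, 1000]\ \mu m^2/s$ and occupancy $\in (0, 10^4]$.

`compare_models()` prefers the two-species model only when it improves the
reduced $\chi^2$ by more than 10% *and* assigns the minor species more
than 0.5% of the amplitude; both thresholds are configuration keys. This
mirrors the visual practice of accepting a second component only when it
clearly improves the fit. `bootstrap_uncertainty()` resamples fit
residuals with replacement and reports 16/84 percentile intervals,
deterministic under a fixed seed.

**A resolution caveat.** Two diffusing species can only be separated
cleanly when their coefficients differ by roughly a factor of two or more
and the minor fraction is not too small. Near that limit the likelihood
develops a second minimum in which the major species is split into two
nearby components; with 2% per-point noise this alternative minimum can
genuinely become the global one for an appreciable fraction of noise
realisations, and no optimiser can undo that. Recovery of a 3% slow
component at $D_1/D_2 \approx 3$ is reliable on information-rich curves
(512 log-spaced channels: mean recovered $F_1$ within 0.01 of truth over
200 replicates) but visibly biased on sparse ones (96 channels). The
package's simulation studies therefore use 512-channel curves, the upper
end of what hardware/software correlators deliver; the general-purpose
default of `lag_grid()` remains 96 channels. At the extremes of the
titration scenario, where $D_1/D_2$ falls below about 2.3 and the
aggregate fraction reaches 8–10%, the fitted decomposition occasionally
trades amplitude between the species; the dominant-species coefficient is
then recovered to ~10% typically, worse in unlucky realisations. This is
a property of the measurement, not of the optimiser.

## From diffusion to size and shape

The Stokes–Einstein relation gives the radius of the hydrodynamically
equivalent sphere, $R = k_BT / (6\pi\eta D)$; defaults are water at 25 °C
($T = 298.15$ K, $\eta = 0.89$ cP). The empirical native-protein scaling
$R_N = 4.75\,N^{0.29}$ Å (`wilkins_native_radius()`) provides an
independent expectation from the residue count alone; its coefficients
are configurable and no uncertainty propagation is attempted.

When a measured $D$ is too small for a plausible sphere, a shape change
can explain it. The Perrin model gives the friction of a prolate spheroid
with semi-axes $a \ge b$ relative to the sphere of equal volume:

$$F(p) = \frac{\sqrt{1-p^2}}{p^{2/3}\,
\ln\!\frac{1+\sqrt{1-p^2}}{p}}, \qquad p = b/a \in (0,1],$$

with $F(1) = 1$ and $F$ strictly decreasing toward the sphere, so
$D_E = D_\mathrm{sphere}(R_\mathrm{eq})/F(p)$ with
$R_\mathrm{eq} = (ab^2)^{1/3}$. `invert_prolate()` solves
$F(p) = D_\mathrm{sphere}/D_\mathrm{meas}$ by bisection on $p$ (relative
tolerance $10^{-10}$, at most 200 iterations; bisection is preferred to
derivative methods because $F$ is monotone and smooth). The semi-axes
$a = R_\mathrm{eq}p^{-2/3}$, $b = pa$ conserve the imposed volume
exactly. Axial ratios below $10^{-4}$ are refused as out-of-model;
$D_\mathrm{meas}$ above the spherical bound has no prolate solution.

Note that the equal-volume constraint is aggressive: a protein whose $D$
halves while conserving volume must elongate enormously (at
$V \approx 10^5\ \text{Å}^3$, $D = 44\ \mu m^2/s$ needs $p \approx 0.056$,
i.e. $a \approx 200$ Å). Literature tables sometimes report much milder
semi-axes for comparable $D$ values; those cannot be reproduced by the
equal-volume Perrin relation — their implied volume is smaller than
stated and the standard friction factor at their axial ratio cannot halve
$D$. `fcshydro` implements the self-consistent model: the forward and
inverse operations round-trip to $10^{-8}$ and volume is conserved to
$10^{-10}$, which the test suite asserts.

## The synthetic-data generator

Because raw instrument data are rarely shareable, every input the
pipeline needs can be generated:

* `simulate_curve()` applies multiplicative Gaussian noise with constant
  coefficient of variation to the analytic curve and records the true
  per-point standard deviation. This is a deliberate simplification —
  real correlator noise is lag-correlated and heteroscedastic in a more
  complicated way (Koppel theory); constant-CV noise is sufficient to
  exercise weighted fitting and model comparison, so passing tests show
  estimator correctness under the stated noise model, not robustness to
  real detector artefacts.
* `simulate_photon_trace()` is a physical ground truth: point emitters
  take Brownian steps (per-axis variance $2D\,dt$, enforced
  $dt \le \tau_D/20$) in a periodic box of at least $10\,\omega_0$
  (periodic re-entry preserves concentration, unlike reflecting walls),
  and per-bin counts are Poisson draws around
  $\beta\,dt\,e^{-4(x^2+y^2)/\omega_0^2 - 4z^2/z_0^2}$ — the *square* of
  the Gaussian illumination for two-photon excitation (exponent 2 for
  one-photon). The per-bin loop is compiled (Rcpp) but draws from R's
  RNG, so a seed makes traces bit-reproducible.
* `multitau_correlate()` computes
  $G(\tau) = \langle\delta I\,\delta I_\tau\rangle/\langle I\rangle^2$ on
  the quasi-logarithmic multi-tau grid (m = 16 channels per level, bin
  width doubling per level, matching common correlator hardware), with
  symmetric normalisation to suppress finite-length bias. The grid covers
  lags from one bin width to about a quarter of the trace.
* `titration_scenario()` emulates a pH titration: the dominant $D$
  follows a piecewise-linear template (25 $\mu m^2/s$ at pH 2 rising to
  50 at pH 4.5, plateau to pH 6, peak of 84 at pH 7, decline to 31 at
  pH 10) and a slow aggregate species ($D_2 = 15\ \mu m^2/s$) carries
  2–10% of the amplitude, peaking at the extremes and absent at pH 7,
  where the native protein is a clean single species.
* `toy_trajectory()` builds trajectories with planted structure: a rigid
  body on a Brownian centre-of-mass walk of known $D$ (1 $\mu m^2/s$ =
  $10^{-6}$ nm²/ps), a deterministic two-state alternation with Gaussian
  jitter (every $1/f$-th frame is the minor state, so cluster sizes are
  exact by construction), or a static conformation.

All generators are pure functions of their parameters and a seed.

## Trajectory statistics

* **MSD / Einstein relation.** `msd()` averages squared displacements over
  the selected atoms and over *all* time origins (sliding window), a
  deliberate variance-reducing divergence from the textbook
  "displacement from the initial frame". `einstein_diffusion()` fits an
  ordinary least-squares line over a lag window (default 10–90% of the
  curve) and returns $D = \mathrm{slope}/6$. Because MSD estimates at
  long lags are strongly correlated and noisy, restricting the MSD to
  short lags (`max_lag_frac` of 0.02–0.05) gives markedly more stable
  estimates; with $10^4$ frames and 20 seeds the generator's $D$ is
  recovered to well within 5%.
* **RMSD.** `kabsch_rmsd()` superposes by the optimal least-squares
  rotation (Kabsch, via SVD, with the determinant correction against
  improper rotations) before measuring; mass-weighting is off by default.
  `rmsd_trajectory()` gives the classic stability trace against the
  starting structure.
* **Radius of gyration** is geometric (unweighted) by default with an
  optional mass-weighted mode.
* **Daura clustering.** The greedy neighbour-counting algorithm: the
  frame with most neighbours within the RMSD cutoff (MD practice: 0.25
  nm) becomes a centre, its neighbourhood is removed, repeat. Equal
  neighbour counts are broken toward the lowest frame index — the
  original formulation leaves ties open, and a deterministic rule makes
  runs reproducible. `daura_from_dist()` exposes the same greedy core on
  any precomputed distance matrix; the test suite checks it against a
  brute-force enumeration oracle on small instances.
* **PCA / free-energy landscapes.** Frames are superposed onto their mean
  structure (two refinement passes), the covariance of the flattened
  C$\alpha$ coordinates is eigendecomposed, and projections on the
  orthonormal modes feed `free_energy_landscape()`:
  $\Delta G = -\ln(P/P_\mathrm{max})$ in $k_BT$ over a 2D histogram
  (default 32×32 bins). The most occupied bin is exactly 0 and bins never
  visited are reported as `NA` rather than given an arbitrary cap —
  "unvisited" and "high energy" are different statements.

## Numerical choices and degenerate inputs

* Constant curves are refused by the fitter (nothing to fit); identically
  zero photon traces make the correlator's normalisation undefined and
  raise an error; all-identical projections make the free-energy
  histogram degenerate.
* The bisection in `invert_prolate()` and the LM restarts in
  `fit_correlation()` are deterministic; all stochastic components
  (curve noise, photon traces, bootstrap, toy trajectories) consume an
  explicit seed and restore the RNG state afterwards.
* Fit standard errors come from the weighted-Jacobian normal matrix
  scaled by the reduced $\chi^2$; when only relative uncertainties are
  supplied this is the standard rescaled-covariance convention.
* Coordinates are nanometres internally; the XYZ reader/writer converts
  from/to ångströms on request.

## Problem sizes used by the shipped studies

The package's own simulation studies (test suite and acceptance script)
use: 200 replicate curves of 512 channels for the two-species recovery
study; 10 photon traces of 2 s at 10 µs bins with 64 emitters for the
simulator-to-fit cross-validation (recovering $D = 84\ \mu m^2/s$ to
within 10%); 20 Brownian trajectories of $10^4$ frames for the
Einstein-relation contract; and a nine-point pH grid for the end-to-end
titration. These sizes were chosen so each study's Monte-Carlo error is
comfortably below the tolerance it checks.

## Known limitations

* Amplitude fractions assume equal molecular brightness; a brighter
  aggregate would be over-weighted.
* No triplet kinetics, afterpulsing, photobleaching, flow or
  cross-correlation modes.
* Oblate ellipsoids, rotational diffusion and hydration corrections are
  out of scope of the shape model; only the prolate branch is inverted.
* The synthetic noise model is uncorrelated across lags; real correlator
  noise is not, so real-data $\chi^2$ values are only comparable
  relatively, not absolutely.
* The trajectory tools are post-processing statistics; the package does
  not integrate equations of motion beyond the toy Brownian generator.
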