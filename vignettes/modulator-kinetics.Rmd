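---
title: "Mechanistic analysis of Abeta42 aggregation modulators from ThT kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanistic analysis of Abeta42 aggregation modulators from ThT kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amylokin)
```

## The model

Amyloid formation by the 42-residue amyloid-beta peptide (Abeta42)
under quiescent conditions is well described by three microscopic
processes: primary nucleation of new aggregates from free monomer
(rate constant $k_n$, reaction order $n_c$), secondary nucleation of
new aggregates on the surface of existing fibrils (rate constant
$k_2$, order $n_2$, proportional to fibril mass), and elongation of
fibril ends by monomer addition (rate constant $k_+$). Tracking the
fibril number concentration $P$ and fibril mass concentration $M$,
with free monomer $m = m_{tot} - M$, gives the two-moment system

$$\frac{dP}{dt} = k_n m^{n_c} + k_2 m^{n_2} M,
  \qquad \frac{dM}{dt} = 2 k_+ m P.$$

`integrate_moments()` solves this with a stiff-capable adaptive
integrator (`deSolve::lsoda`, relative tolerance $10^{-10}$, absolute
tolerance $10^{-12} m_{tot}$, which keeps even the stiffest parameter
sets the tests draw within $10^{-6}$ of an independent Radau
reference). No fragmentation term is
included: the assays this package emulates are quiescent, where
fragmentation is negligible. Saturation of elongation or secondary
nucleation, and length distributions beyond the two moments, are out
of scope.

Two combined rates summarize the kinetics:
$\lambda = \sqrt{2 k_+ k_n m_{tot}^{n_c}}$ (proliferation through
primary nucleation) and
$\kappa = \sqrt{2 k_+ k_2 m_{tot}^{n_2+1}}$ (through secondary
nucleation). For unseeded reactions `analytical_mass_fraction()`
provides the standard closed-form fixed-point solution; it is an
optional fast path that must agree with the integrator to 2% RMS in
the secondary-dominated regime ($\kappa \ge 10\lambda$) before use,
and the fitting machinery always uses the integrator.

An important identifiability fact drives the package's reporting
conventions: unseeded normalized curves are exactly invariant under
$(k_+, k_n, k_2) \to (c k_+, k_n/c, k_2/c)$, so only the products
$k_+ k_n$ and $k_+ k_2$ are identifiable from an unseeded experiment.
All unseeded fits therefore hold $k_+$ at a nominal value and report
the products.

### Reaction orders

The reaction orders default to $n_c = 2$ and $n_2 = 2$, the standard
choice for Abeta42 in master-equation analyses of ThT data; both are
configurable in `kinetic_params()`.

## The half-time statistic and the screen

The screen's summary statistic is the half-time $t_{1/2}$: the
earliest time at which the baseline-subtracted ThT signal crosses half
of the baseline-subtracted plateau, linearly interpolated between
samples (`halftime()`). Baseline and plateau are means of the first
and last $k = 5$ samples (configurable). The statistic is invariant
under affine transforms of the fluorescence, so whether a screen is
analyzed on raw or normalized signal does not matter. Curves that do
not plateau (signal still rising over the final 15% of the window by
more than 5% of the total rise) or that are flat are rejected with
classed conditions; `screen_halftimes()` converts those into
excluded-with-reason rows rather than dropping wells silently.

`call_hits()` compares each condition's replicate half-times to the
vehicle control with Dunnett's many-to-one procedure on a one-way
ANOVA and classifies conditions at adjusted $p \le \alpha$ as
inhibitors (longer half-time) or accelerators (shorter). In the
balanced case (equal replication everywhere) the many-to-one t
statistics are equicorrelated with $\rho = 1/2$ and the adjusted
p-values are computed by the classical deterministic double
quadrature over the shared control variate and the pooled-variance
chi scale (`dunnett_p_balanced()`, accurate to ~$10^{-4}$ and
cross-checked against `mvtnorm` in the tests); unbalanced designs
fall back to `multcomp::glht` with a pinned quadrature stream. Ties and equal means stay `no-effect`: conservative
screening. Calibration is assessed family-wise — the probability that
a screen of truly null compounds produces any call — because that is
the error Dunnett's procedure controls at $\alpha$; the per-comparison
rate under a many-to-one adjustment is by construction far below
$\alpha$.

## What the synthetic generator emulates

`generate_screen()`, `generate_dose_series()` and
`generate_mixture()` produce plate-reader-like datasets with known
ground truth. Defaults were chosen once, as plausible study
conditions, and are not tuned per analysis:

* **Kinetics.** 2 uM monomer; $k_+ = 10^4\,\mathrm{\mu M^{-1} h^{-1}}$
  (about $3 \times 10^6\,\mathrm{M^{-1} s^{-1}}$, the literature
  regime for Abeta42 elongation), $k_n = 1.1 \times 10^{-6}$,
  $k_2 = 7 \times 10^{-4}$ in uM/h units. This gives an unseeded
  half-time of about 0.77 h, $\kappa/\lambda \approx 35$
  (secondary-dominated, as for Abeta42), and a 0.2x-inhibited well
  still plateaus inside a 4 h window.
* **Modulators.** Multiplicative, dose-dependent factors
  $(f_n, f_2, f_+)$ on the rate constants. Screen-style qualitative
  effects map to $(0.2, 0.2, 1)$ for inhibition and $(5, 5, 1)$ for
  acceleration — directions are what a qualitative screen reports;
  the sizes are the package's own choice, large enough to be
  unambiguous at triplicate scale. `retinoid_like()` is a
  dose-dependent nucleation inhibitor ($f_n = f_2 = 0.1^{d/10}$,
  elongation touched only at the top dose, $f_+ = 0.5$ at 10 ME).
  `tocopherol_like()` is a micellar-switch amphiphile: a monomeric
  inhibitor below its critical assembly concentration (default 0.3
  ME) and an accelerator above it, phenomenological only — no micelle
  physics is modelled.
* **Seeding.** Seed mass fractions 2% (low) and 30% (high), with
  fibril number $P_0 = M_0 / L$ for mean seed length $L = 500$
  monomers.
* **Noise.** Per-well lognormal amplitude spread (CV 5%), additive
  Gaussian per-point noise (SD 2% of plateau), a baseline offset and
  a slow linear drift (0.002 a.u./h). Replicates are independent
  draws; a fixed seed reproduces a dataset bit-for-bit.
* **Time grids.** Screens use 0-4 h at a 2-min cycle (plateau sampled
  by 4 h for unseeded 2 uM reactions). Unseeded dose series use
  0-10 h so that strongly inhibited top doses still plateau.
  High-seed plates use a fast kinetic cycle (5 s over 0.3 h): at
  realistic $k_+$, elongation of 30% preformed seeds completes within
  minutes, and — holding the unseeded products fixed — any slower
  elongation constant would let secondary nucleation on the seed mass
  contaminate the early window beyond the 2% curvature budget of the
  slope estimator. This is an assay-design point, not a numerical
  convenience: early-slope elongation assays genuinely require dense
  early sampling.

What the generator does **not** emulate: vendor export formats,
spatial plate effects, evaporation, temperature gradients,
ThT-binding nonlinearity, or compound fluorescence interference.
Passing tests on synthetic data therefore demonstrate the estimators'
correctness against the stated generative model, not robustness to
every artefact of real plates.

## Fitting and mechanism decomposition

`fit_control()` fits $(k_n, k_2)$ (log-space, L-BFGS-B, eight
multi-starts from a log-uniform Latin hypercube around a data-driven
guess; the best-so-far objective is non-increasing by construction)
jointly across replicates with equal weights per time point. The
residual model is the measurement equation itself: per trace the data
are compared to $a + c t + b \cdot M(t)/m_{tot}$, with the affine and
drift nuisances $(a, c, b)$ profiled out in closed form. Profiling the
measurement layer, rather than anchoring the curve on noisy
first/last-window means, keeps window noise out of the residuals and
makes the fit exactly affine invariant. A fit is declared failed (classed condition) when the data
show no transition or no start reaches a residual RMS below 0.1.

`fit_dose_series()` refits each dose independently with the reaction
orders and nominal $k_+$ held at the baseline and reports
$r_{primary} = (k_+ k_n)_d / (k_+ k_n)_0$ and
$r_{secondary} = (k_+ k_2)_d / (k_+ k_2)_0$.

A caution on precision: at a single monomer concentration with
triplicates and 2% point noise, the primary product sits on a narrow
$\lambda$-$\kappa$ ridge (a small steepness error trades against a
large lag-position error), so its per-dose uncertainty is several
times that of the secondary product — recovery to within
15% at every dose holds for most random datasets but not all. The
secondary product is much better identified (2-7%). Global fitting
across monomer concentrations, which breaks this ridge, is how the
combined constants are pinned down in practice; it is outside this
package's scope.

The seeded analyses decouple the products:

* `elongation_from_high_seed()` uses the early growth rate of
  high-seeded wells, where $dM/dt(0) = 2 k_+ m(0) P_0$, so with equal
  seed preparations the slope ratio against dose 0 estimates the
  $k_+$ ratio. The early window keeps points below 30% of the
  normalized rise and before half the half-time (at least 5 points);
  each well is scaled by plateau minus the early fit's intercept at
  $t = 0$, because a seeded trace grows from the first sample and a
  first-window mean would overstate the baseline. The slope is fitted
  on $-\log(1 - \hat y)$: seeded elongation-only growth follows
  $\hat y = 1 - e^{-2 k_+ P_0 t}$, so this ordinate is linear in time
  and the estimate is free of monomer-depletion curvature, which at
  realistic elongation rates would otherwise bias a raw-signal slope
  by far more than the estimator's 2% curvature budget. A dose is flagged
  `affected` only when $|r_+ - 1|$ exceeds both 0.25 and twice its
  standard error — requiring the deviation to be substantial *and*
  significant keeps noise-level wobbles at small SE from being called
  elongation effects.
* `secondary_from_low_seed()` fits $k_2$ alone to 2%-seeded curves
  (one-dimensional, golden-section search), with $k_n$ and $k_+$
  fixed at baseline — but refuses to fit any dose whose elongation is
  flagged, since the low-seeded assay cannot then separate $k_2$ from
  $k_+$. Relative $k_2$ is reported against the dose-0 low-seed fit:
  normalizing within the seeded arm cancels the systematics that the
  fixed baseline parameters impose on every dose alike.
* `attribute_mechanism()` divides $r_+$ out of the combined products
  where decoupling is valid and reports which of $(k_n, k_2, k_+)$
  changed (threshold: ratio deviating from 1 by more than 0.25), or
  marks the dose not-decoupled.

## Mixture analysis

`mixture_halftime_grid()` reduces a two-compound dose grid to
replicate-mean half-times per cell and `zero_net_region()` returns the
cells within a relative tolerance (default 0.10, boundary inclusive)
of the control half-time — the operational definition of a near-zero
net effect. The detector is deliberately phenomenological: the
generator cancels multiplicatively on rate constants, but the region
is defined on half-times alone so that no mechanistic assumption is
imported into the measurement. Cells missing from the data are
reported, never imputed, and never in the region.

## Numerical and degenerate-input policy

* Integration failures name the offending parameter set; mass is
  clipped to $[0, m_{tot}]$ only within integrator jitter.
* The closed form switches to overflow-safe log evaluation
  ($\log(B + C e^{\kappa t}) = \kappa t + \log(C + B e^{-\kappa t})$)
  so late-time values are finite at any horizon.
* Flat curves raise degenerate-curve conditions; truncated sigmoids
  raise not-converged; both are carried as per-well exclusion reasons
  in screens.
* Ties at the half crossing take the earliest crossing; equal means in
  hit calling stay no-effect.

## Problem sizes used by the tests

The packaged checks run the screen at its full size (18 compounds + 2
controls, triplicate), the dose series at 6 doses x 3 seeding arms x 3
replicates, 500 null screens for caller calibration, 100 seeded
mixture grids (4 x 4, triplicate) for zero-sum recovery, and 20 random
parameter sets for integrator cross-validation. These sizes were
chosen to estimate each rate or error against a tolerance meaningfully
tighter than the effect sizes involved.

## A worked example

```{r, eval = FALSE}
ann <- read_metabolite_annotations()
ds <- generate_screen(ann, seed = 1)
res <- analyze_screen(ds, control = "DMSO", alpha = 0.05)
subset(as.data.frame(res), call != "no-effect",
       select = c(compound, mean_halftime, delta, p_adj, call))
```

## Known limitations

* Absolute $k_+$ is not estimable (it would require the absolute seed
  number concentration); all elongation results are ratios.
* Single-concentration unseeded data cannot separate $k_+ k_n$ from
  $k_+ k_2$ noise-robustly along the ridge discussed above.
* The micellar switch is a threshold phenomenology; real
  amphiphile assembly is gradual and concentration-history dependent.
* The Dunnett caller assumes approximately normal, homoscedastic
  half-times within a screen; heavy-tailed well failures should be
  excluded upstream (the QC path does this for non-plateauing wells).
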