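---
title: "Models and methods behind hydrotrait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hydrotrait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydrotrait)
```

This vignette documents the models the package implements, the assumptions
behind them, the tunable parameters and their defaults, the numerical choices
made where the standard methods leave room, and what the synthetic-data
generator does and does not emulate. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## Anatomy-derived hydraulic indices

The hydraulically weighted vessel diameter is the fourth-power mean
$D_h = (\sum_i D_i^4 / N)^{1/4}$, which weights each vessel by its
Hagen–Poiseuille conductance contribution ($\propto D^4$). It is never
smaller than the arithmetic mean (power-mean inequality), which the tests
exercise as a property. Elliptical lumina are converted to an equivalent
circular diameter area-preservingly, $d = \sqrt{d_{long} d_{short}}$
(`equivalent_diameter()`), because an ellipse with those axes has the same
cross-sectional area as that circle.

Theoretical conductivity assumes ideal Hagen–Poiseuille flow through open
tubes — no end walls, no pits, laminar flow:

$$K_{th} = \frac{\pi \rho}{128\,\eta}\, \mathrm{VF}\, D_h^4 .$$

Units are converted internally (VF mm⁻² → m⁻², $D_h$ µm → m). The default
constants are water at 20 °C: $\rho = 998.2$ kg m⁻³ and
$\eta = 1.002\times10^{-9}$ MPa s. Viscosity is expressed in MPa s (not the
more common Pa s) so that $K_{th}$ comes out directly in
kg m⁻¹ MPa⁻¹ s⁻¹, the unit in which xylem conductivities are reported in
this field; dimensional analysis fixes this choice. Both constants are
overridable through `physical_constants()`. Because $D_h$ and VF are
computed from the same vessel set, $K_{th}$ is algebraically identical to
the brute-force per-vessel sum $(\pi\rho/128\eta)\sum d_i^4/A$; a test
asserts this to $10^{-9}$ relative.

Pit shape ratios ($R_{pa}$, $R_{pit}$) are computed **per pit and then
averaged** by default. Computing them from mean diameters instead is
available via `ratio_mode = "of_means"`, since which convention a given
dataset used is often unknowable; the two differ whenever shape varies among
pits. Pit density pools counts over walls ($\sum n / \sum A_{wall}$) rather
than averaging per-wall densities, weighting each wall by the area actually
examined. The "packing position" $D_p \cdot A_{pit}$ is the fraction of
intervessel wall covered by pit membranes; 1 is complete coverage, a
geometric upper bound that serves as a defined reference point for how close
a sample sits to the packing limit.

Stomatal counting follows the standard tile-safe rule: stomata visible along
the top and left borders are included, bottom and right discarded, so tiled
fields count each stoma exactly once. "Visible along" is operationalised as
the centroid lying within `border_tol` of the edge; callers supply the pixel
size of their images as the tolerance. A property test checks that the rule
is irrelevant for fields whose stomata all sit away from the borders.

## Minimum diffusive conductance

After stomata close, residual (mostly cuticular) conductance is estimated
from a bench drying curve as

$$g_{min} = \frac{WL \cdot P_{atm}}{VPD},$$

with the water-loss rate $WL$ the OLS slope of mass (g) on time (s),
converted to mmol s⁻¹ (molar mass 18.015 g mol⁻¹) and normalised by either
single-sided projected area (g_min,area) or dry mass (g_min,mass). The two
normalisations obey the exact identity
$g_{min,area} \cdot A = g_{min,mass} \cdot m_{dry}$, which is asserted in
the tests. VPD uses the Arden Buck saturation vapour pressure and is
averaged over the per-weighing values within the fitted window, since
temperature and humidity are recorded at each weighing but the slope is a
single number. The projected area is deliberately single-sided (not
doubled).

Two fit windows are offered. `"full"` (default) uses all weighings —
appropriate for organs that dry linearly from the start, as organs with few
or no stomata do. `"auto"` searches every contiguous window of at least 5
points for the one maximising $r^2$ (preferring longer windows on ties),
for organs whose early drying still contains a stomatal phase. Both modes
are exposed because how many of the ~10 weighings to use is a judgement
call that should be inspectable.

If air is effectively saturated over the window (mean VPD < 10⁻⁶ kPa) the
conductance is undefined and the function stops rather than returning an
unstable ratio. A mass series that increases over the window yields a
flagged non-positive loss rate with a warning.

## Pressure–volume parameters

PV analysis uses the classic transform: against cumulative water deficit
(saturated mass minus observed mass), $-1/\Psi$ is linear after turgor loss,
with intercept $-1/\Psi_{sft}$ at zero deficit. All parameters are expressed
on a **dry-mass basis** (capacitance in mol kg⁻¹ MPa⁻¹) because petal area
is not measurable after wilting, so an area basis would silently break for
flowers.

Numerical choices, in order of appearance:

* **Saturated mass** defaults to the maximum observed mass. The optional
  correction (`plateau_correct`/`saturated_mass(correct = TRUE)`)
  extrapolates the initial linear mass-vs-Ψ region to Ψ = 0: leading points
  lying above that line are treated as an oversaturation plateau (excess
  surface or intercellular water) and dropped (up to 3, until the initial
  fit reaches r² ≥ 0.995); the extrapolated intercept replaces the maximum
  whenever a plateau was dropped or the intercept exceeds the maximum
  (undersaturated sampling). With fewer than 3 usable initial points the
  correction falls back to the maximum, flagged.
* **Breakpoint search** is exhaustive over all splits leaving at least 3
  points per segment. A bare argmax of post-segment r² is biased toward
  short, lucky segments near the dry end, because every subset of the true
  post-turgor-loss points fits the same line and shorter subsets have noisier
  r². The rule therefore estimates the measurement noise from the
  best-fitting split and then takes the **most hydrated** split whose
  residual variance is statistically consistent with that noise (5%
  F-criterion). On noiseless data this reduces to "most hydrated among exact
  ties". A brute-force reimplementation of the rule guards the production
  code in the tests.
* **Degenerate curves**: if the whole series is linear in the transform
  (r² ≥ 1 − 10⁻⁹) and no split improves it, the curve is treated as purely
  osmotic — breakpoint flagged at the first point, $\Psi_{sft}$ from the
  whole-series intercept.
* **$\Psi_{tlp}$** is read off the fitted post-breakpoint line at the
  deficit midway between the last pre-breakpoint and first post-breakpoint
  observations. The true turgor loss point lies between those two samples,
  so the midpoint halves the worst-case discretisation bias relative to
  evaluating at the first post-breakpoint point. A guard enforces
  $\Psi_{tlp} \le \Psi_{sft}$ against floating-point excess; the recovery
  tests verify the inequality holds on every fit.
* **Capacitance** $C_T$ is the slope of water content (mol per kg dry mass)
  against Ψ over the **pre**-breakpoint segment — capacitance at full
  turgor, the regime in which buffered organs actually operate. Whether a
  published $C_T$ is pre-TLP, post-TLP or whole-curve is frequently
  unstated; the post-TLP slope is therefore also reported (`c_t_post`), and
  an apoplastic-fraction estimate is exposed as a diagnostic rather than a
  headline output.
* A fit whose osmotic line extrapolates to a non-positive $-1/\Psi$
  intercept has no physical interpretation and raises an error carrying the
  post-segment r² as a diagnostic.

## Phylogenetic independent contrasts

`pic_contrasts()` implements Felsenstein's pruning: at each internal node
the contrast is $(x_i - x_j)/\sqrt{v_i + v_j}$, the ancestral value is the
variance-weighted daughter mean, and the ancestral branch is inflated by
$v_i v_j/(v_i + v_j)$. Under Brownian motion the $n-1$ contrasts are iid
normal; the tests verify the standardisation by checking
$A C A^\top = I$ with $C$ the shared-path-length covariance computed by
brute force, and by comparison against an independent reference
implementation.

Contrast correlations are fitted **through the origin**. The sign of each
contrast depends on an arbitrary child order, and only the through-origin
fit is invariant to those sign flips; its $r^2$ uses the through-origin
total sum of squares and the t-test has $n_{contrasts} - 1$ degrees of
freedom. An intercept mode exists purely for sensitivity analysis.
Polytomies are accepted with a warning and resolved arbitrarily into
zero-length bifurcations, which leaves the contrast variances well defined
while flagging that some "contrasts" are then not unique.

## Comparative statistics

Paired flower-vs-leaf tests pair by species (two-sided, $n-1$ df) and are
identical to a one-sample t on the differences — asserted as an identity
test. ANOVA + LSD follows the protected convention: pairwise LSD tests on
the pooled mean square are only interpreted when the omnibus F is itself
significant at $\alpha$ (default 0.05, two-sided throughout); unprotected
mode is switchable. The compact letter display uses insert-and-absorb, and a
test checks the display is invariant to group input order. SMA regression
uses the closed form (slope $= \mathrm{sign}(r)\, s_y/s_x$) with the
correlation test for significance; the identities $|b| = s_y/s_x$,
$b_{xy} b_{yx} = 1$ and $b_{SMA} = b_{OLS}/|r|$ are asserted on random
data. PCA runs on centred, scaled data (correlation matrix); rows with
missing values in the selected traits are dropped and reported, because
astomatous petals genuinely lack stomatal traits and silent imputation would
distort the ordination. PC signs are fixed by making the largest-magnitude
loading positive. Hull overlap is intersection-over-union of the two
organs' convex hulls in PC1–PC2, with the convex intersection computed by
Sutherland–Hodgman clipping; collinear (zero-area) groups are flagged
degenerate.

## What the synthetic generator emulates — and what it does not

`study_design()` fixes the study conditions: 10 species × 2 organs × 23
traits. Trait medians are illustrative values realistic for subtropical
woody angiosperms — flowers leakier (higher $g_{min}$), with higher SWC and
capacitance and less negative water potentials, slightly smaller pits and
vessels in peduncles than petioles — and are documented as such, not as
measurements. Positivity-constrained traits are generated as lognormals
(water potentials as negated lognormals). Cross-trait correlation comes
from a two-factor loading model (a xylem/pit-size axis and a water-economy
axis), which guarantees a positive semidefinite correlation matrix by
construction. Species deviations evolve as correlated Brownian motion on a
unit-depth coalescent tree and are **shared between the organs of a
species**, which is what makes between-organ contrast correlations
non-trivial; organ identity enters as a fixed log-scale offset, plus
independent lognormal measurement noise (default sd 0.1 log units, a ~10%
error on a species-organ mean; among-species CV defaults to 0.3).

Drying curves invert the conductance equation at 10-minute intervals with
Gaussian weighing noise (default 10⁻⁴ g, a 0.1 mg balance). PV curves come
from a closed-form model: osmotic component $\Psi_s = \Psi_{sft}/R_s$ in
symplastic relative water content $R_s$, and a turgor component that is
maximal ($-\Psi_{sft}$, so the total starts at 0) at full hydration and
declines to zero at the turgor loss point $R_s = r_{tlp}$ (default 0.85),
shaped by an elastic exponent (default 1, linear). The implied true turgor
loss point is $\Psi_{sft}/r_{tlp}$. Sampling starts at $R_s = 0.99$ —
equivalent to the usual practice of starting PV curves near −0.1 MPa — and
extends 0.25 below $r_{tlp}$ over 12 points, within the usual 8–15 range.

What passing tests therefore demonstrate: the estimators recover known
parameters under lognormal trait variation, Brownian evolution, constant
microclimate and Gaussian measurement noise at realistic magnitudes. What
they do not demonstrate: robustness to non-Brownian evolution (selection,
rate shifts), drifting bench microclimate, balance drift, partially closed
stomata that never reach a linear phase, osmotic adjustment during the PV
measurement, or operator-dependent anatomical annotation. Real data violate
these assumptions to unknown degrees; the generator is a correctness
harness, not a claim about nature.

## Problem sizes and tolerances in the test suite

The suite sizes were chosen to make the stochastic checks statistically
meaningful while staying quick: 500 replicates for conductance recovery
(asserting every replicate within 5% of truth at 0.1 mg noise), a 36-point
generating grid × 5 replicates for PV recovery (median $|\Psi_{sft}|$ error
< 0.05 MPa, median $|\Psi_{tlp}|$ error < 0.1 MPa at 0.02 MPa noise), 1000
replicates for the contrast-regression type-I calibration (nominal 0.05,
accepted within [0.035, 0.065], about ±2 binomial standard errors), 100
random datasets for the SMA identities (10⁻¹⁰), 200-tip trees for contrast
correlation consistency (bias < 0.05), and 60 full synthetic studies for the
end-to-end organ-contrast direction check (≥ 95% recovery). Deterministic
identities are asserted at 10⁻⁹–10⁻¹² relative; frozen formula constants at
10⁻⁶ against independently computed values.

## Known limitations

* The pipeline treats species-organ means as observations; no hierarchical
  error propagation from individual samples to species means.
* No multiple-testing correction across the many trait-pair regressions and
  contrast correlations (deliberate — results are reported as a table, and
  correction policy is the analyst's choice).
* SMA inference uses the correlation test; confidence intervals for SMA
  slopes are not implemented.
* The PV breakpoint assumes a single regime change; curves with rehydration
  artefacts mid-series will fit poorly (and show up in `r2_post`).
* Polytomy resolution is arbitrary; contrast values at resolved nodes are
  order-dependent even though regression statistics are not.
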