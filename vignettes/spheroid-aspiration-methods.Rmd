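---
title: "Methods: spheroid aspiration analysis with spheromech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spheroid aspiration analysis with spheromech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spheromech)
```

## The measurement and the model

In chip-based micropipette aspiration, a spheroid sits in a pocket and
blocks a square aspiration channel; a hydrostatic step pressure ΔP pulls a
tissue tongue into the channel. The tongue length over time, $L(t)$, is the
creep response to a constant stress. `spheromech` models it with the
four-element modified Maxwell network — a dashpot $\xi_t$ in series with a
spring $k_1$ that is in parallel with a $k_2$–$\xi_c$ branch:

$$L(t) = \delta\left(1 - \beta e^{-t/\tau_c}\right) + \dot L_\infty\, t,$$

with four fitted parameters:

| parameter | meaning | units |
|---|---|---|
| $\delta = f/k_1$ | elastic deformation: intercept of the long-time linear flow extrapolated to $t=0$ | µm |
| $\beta = k_2/(k_1+k_2)$ | fraction of $\delta$ reached through the delayed (rather than instantaneous) elastic response; $L(0) = \delta(1-\beta)$ | — |
| $\tau_c$ | rising time of the delayed elastic deformation | s |
| $\dot L_\infty = f/\xi_t$ | long-time viscous flow velocity | µm/s |

The model assumes a constant step stress (valid only once every pocket is
clogged, see the network section), a tongue long enough for the
semi-infinite aspiration geometry, and volume conservation of the spheroid.

Aspiration force and mechanics use the circular-pipette relations with an
effective radius for the square channel:

$$f = \pi R_\mathrm{eff}^2 (\Delta P - \Delta P_c), \qquad
E = \frac{R_\mathrm{eff}(\Delta P - \Delta P_c)}{\delta}, \qquad
\eta = \frac{R_\mathrm{eff}(\Delta P - \Delta P_c)}{3\pi \dot L_\infty},$$

and $\tau = \eta/E$. $R_\mathrm{eff}$ is the radius of the circular duct
with the same Poiseuille conductance as the rectangular channel,

$$R_\mathrm{eff} = \left(\tfrac{2}{3\pi} f^*(a)\, W_{\max} H_{\min}^3\right)^{1/4},
\qquad
f^*(a) = 1 - \frac{192}{\pi^5} a \sum_{n\,\mathrm{odd}}
\frac{\tanh(n\pi/2a)}{n^5},$$

with $a = H_{\min}/W_{\max} \le 1$. For the 50 µm square channel this gives
27.35 µm, i.e. the conventionally quoted 27 µm at µm precision. The package
keeps full precision internally; `channel_geometry(r_eff_um = 27)` lets you
reproduce derivations that use the rounded value. The series is truncated
once terms fall below $10^{-12}$ (terms are bounded by $n^{-5}$, so this is
essentially exact); the factor is symmetric in $W$ and $H$ by construction.

## Tunable parameters

* `delta_p` (Pa): the applied step; 700 Pa for the soft HEK293T preset,
  1500 Pa for the stiffer lines, matching the measurement conditions of
  each preset.
* `delta_p_c` (Pa, default 0): the critical pressure below which surface
  tension blocks aspiration. The chip cannot measure the retraction curves
  needed to estimate it, so it defaults to zero; glass-pipette work places
  it at 50–150 Pa, which at a 500 Pa step shifts $E$ and $\eta$ by exactly
  $\Delta P_c/\Delta P$ = 10–30%. It is exposed so users with an external
  estimate can apply it.
* `delta_p_error` (20 Pa) and `dimension_error_um` (5 µm): instrument
  1-sigma errors (ruler reading in 0.2 cmH₂O graduations; profilometry of
  the channel cross-section). They enter the delta-method propagation
  below.
* Tracking: `pixel_size_um` (default 1.3 µm ≈ 6.5 µm camera pixel / 5×
  objective), `frame_interval_s` (5 s), exclusion tolerances
  (`max_spread_px` 10, `max_retreat_px` 5, circularity ≥ 0.85, area drift
  ≤ 10%). The defaults encode the manual curation rules as reproducible
  thresholds; they are configurable because real illumination and
  magnification vary.

## Error propagation

`propagate_uncertainty()` combines, in quadrature assuming independence,
the fit standard errors of $\delta$ and $\dot L_\infty$ (from the NLS
covariance), the pressure-reading error, and the channel-dimension error
(pushed through $R_\mathrm{eff}$ by central differences). Because $E$ and
$\eta$ are products and ratios of their inputs, relative variances add.
The suite checks the result against a $10^4$-draw Monte-Carlo resampling
oracle. Independence is an assumption: no correlation model between error
sources is available.

## Fitting: numerical choices

* **Optimizer.** `stats::nls(algorithm = "port")` with box constraints
  $\delta > 0$, $\beta \in [0,1]$, $\tau_c > 0$, $\dot L_\infty \ge 0$.
  Plain unweighted least squares.
* **Initialization.** A straight line through the final third of the
  record gives $\dot L_\infty^0$ (slope) and $\delta^0$ (intercept) — the
  graphical definition of $\delta$; $\beta^0 = 1 - L(0)/\delta^0$ clipped
  to $[0.05, 0.95]$; $\tau_c^0 = 5\,\mathrm{d}t$. The fit is deterministic
  given the curve.
* **Onset.** Recordings may start before the pressure step.
  `detect_onset()` declares the onset at the first frame exceeding the
  running baseline mean by 3 baseline SDs, requiring the next frame to
  exceed the threshold too (a single noisy baseline frame cannot trigger;
  the genuine elastic jump always persists). Times are re-zeroed at the
  onset.
* **Goodness of fit.** $R^2$ is the coefficient of determination against
  the mean of post-onset lengths.
* **Model comparison.** `fit_nested_models()` fits pure Maxwell,
  Kelvin–Voigt, standard-linear-solid and the full model. The full model
  nests the others; to guarantee that ordering numerically its fit is also
  started from each sub-model's optimum (with $\beta$ or $\dot L_\infty$
  at the matching bound) and the lowest residual sum of squares wins.
* **Degenerate inputs.** Fewer than 10 post-onset points is an error
  (4 parameters + 6); solver failure from every start returns a flagged,
  non-converged result rather than an error, and such records are skipped
  by `derive_mechanics()`. Zero-variance groups in the t-test follow the
  p = 1 convention, flagged `degenerate`.

## The synthetic-data generator

`generate_cohort()` encodes the study conditions used throughout the test
suite: per-spheroid $E_i, \eta_i$ drawn lognormally **around the preset
means** (HEK293T 210 Pa / 12 kPa·s at 700 Pa, n = 80; NIH3T3 780 / 67 at
1500 Pa, n = 75; MCF10A 770 / 67 at 1500 Pa, n = 34) with a 20%
between-spheroid coefficient of variation; creep parameters obtained by
inverting the mechanics relations, $\delta_i = R_\mathrm{eff}\Delta P/E_i$,
$\dot L_{\infty,i} = R_\mathrm{eff}\Delta P/(3\pi\eta_i)$; shared shape
parameters $\beta = 0.6$, $\tau_c = 10$ s (not reported by the published
tables; recovery of $E$ and $\eta$ does not depend on their exact values);
61 frames at 5 s; 2 µm i.i.d. Gaussian frame noise. The CV and noise level
were chosen once so that cohort SEMs sit at the scale of the published
ones (±5 Pa on 210 Pa at n = 80). Spheroid radii are drawn uniformly in
60–125 µm and never enter the creep law, making the size-independence
check true by construction.

Two consequences of this design are worth knowing. The lognormal draw is
mean-preserving in $E$ and $\eta$, so cohort-mean recovery of those is
unbiased; the cohort-mean of $\delta_i \propto 1/E_i$ then carries the
reciprocal-moment factor $1 + \mathrm{CV}^2 \approx 1.04$ relative to the
point inversion at the preset. And with CV 20%, a cohort mean at n = 34–80
has a 2–3.5% standard error: individual seeds can land a couple of percent
off the preset without any defect in the pipeline.

The renderer (`render_stack()`) draws flat-fronted binary tongues on up to
8 vertical channels (lengths rounded to whole pixels) and emits the exact
front rows, plus per-spheroid mask series for the shape checks. Artifact
modes inject a detaching blob ahead of a front (`break_off`), a 2:1
ellipse mask (`non_round`), or a mask losing 20% area (`shrinking`).

What the generator does **not** emulate: brightfield texture and uneven
illumination, meniscus curvature of real fronts, sub-pixel edge blur,
spheroid motion inside the pocket, pressure ramping before full clogging,
or correlated (drift-like) measurement noise. Passing tests therefore
demonstrate the correctness of the computational chain — tracking is
pixel-exact, fitting recovers known parameters, mechanics invert
consistently — not robustness to every optical artifact of real
microscopy.

## The hydraulic network

The chip only applies the nominal step pressure once all 8 pockets are
clogged; before that, the considerable resistance of the 60 cm outlet tube
(300 × 300 µm cross-section) takes up most of the drop. `chip_network()` /
`solve_network()` model this as a lumped resistor network — inlet,
8 parallel pocket+channel branches, outlet tube — solved by flow
conservation at the two manifolds, replacing 3D finite-element simulation.
Duct resistances use the same rectangular-duct series as the geometry
module ($R = 12\mu L / (W H^3 f^*)$, verified against a finite-difference
velocity-profile oracle). The aspiration-channel length is not a published
number; the default (300 µm) was chosen once so that the all-open
per-channel drop is a few tens of Pa for a 700 Pa step, the scale the 3D
simulations report, and the model is asserted only for its robust
qualitative content: strict monotone growth of the open-channel drop as
pockets clog (tens → low hundreds of Pa), the full step on every channel
once all are clogged, and flow conservation to $10^{-9}$. Entrance
effects, 3D velocity fields and spheroid deformation coupling are out of
scope, as is the (negligible, per the source study) effect of slab
misalignment — a lumped model cannot resolve it.

## Statistics

`summarize_group()` reports mean ± SEM (sample SD/√n) over non-excluded
converged fits, with viscosity in kPa·s. `two_sample_t_test()` defaults to
the classical equal-variance Student test, two-tailed, α = 0.05 (a Welch
variant is available); no multiple-testing correction is applied.
`size_independence_check()` reports Pearson correlations of $E$ and $\eta$
against radius with a permutation p-value (analytic t-approximation
alongside).

## Problem sizes and reproducibility

The test suite simulates cohorts at the published sizes (80/75/34, plus
56/24 for the pressure comparison) and renders 8-channel stacks of 61
frames (about 130 × 460 px), which keeps the full suite under half a
minute on a single core. Every stochastic step takes an explicit seed and
restores the caller's RNG state; the acceptance script derives per-cohort
seeds deterministically from its single `--seed` argument.

## Known limitations

* $\Delta P_c = 0$ by default biases absolute $E$ and $\eta$ upward by an
  estimated 10–30% when the true critical pressure is 50–150 Pa; relative
  comparisons between cell lines are unaffected.
* The front tracker takes the first foreground pixel from the top;
  detached debris above the front shadows it, which is exactly what the
  stability check is there to catch — curation is automated, not
  infallible.
* Otsu thresholding replaces the original manual threshold choice; on
  low-contrast frames a manual threshold may still be preferable.
* $\xi_c$ (the friction coefficient of the delayed branch) is not
  reported separately — only $\tau_c$ — because its defining relation to
  the spring constants is not recoverable from the creep curve alone.
* Tissue surface tension is not computed: it requires retraction
  measurements the chip geometry cannot provide.
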