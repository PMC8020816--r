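---
title: "A minimal model of glucagon kinetics during an OGTT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A minimal model of glucagon kinetics during an OGTT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glucakin)
```

## The model

During an oral glucose tolerance test (OGTT), glucose-induced insulin
secretion suppresses glucagon release from the pancreatic alpha cells
("intra-islet" inhibition). `glucakin` implements a deliberately minimal
description of this process, suitable for fitting to a single subject's
sampled curves. Plasma C-peptide — co-secreted equimolarly with insulin but
not degraded by the liver — serves as the marker of insulin secretion and is
treated as a measured input, not a state.

Two linear compartments are modelled. Suprabasal C-peptide first transits a
compartment *remote* from plasma, which delays its action:

$$\frac{d\,\Delta CP_{remote}}{dt}
  = -K_{\Delta CPREM}\,\Delta CP_{remote}(t)
  + \bigl(CP_{plasma}(t) - Cp_b\bigr),
  \qquad \Delta CP_{remote}(0) = 0,$$

and plasma glucagon is eliminated at rate $K_{GLUCA}$ while being suppressed
in proportion to the *rate of change* of remote C-peptide, through the
time-varying alpha-cell insulin sensitivity $S_{GLUCA}(t)$:

$$\frac{d\,Gluca}{dt}
  = -K_{GLUCA}\,Gluca(t)
  - S_{GLUCA}(t)\,\frac{d\,\Delta CP_{remote}}{dt},
  \qquad Gluca(0) = Gluca_b.$$

Units: glucagon in ng/L, C-peptide in nmol/L, rates in 1/min,
$S_{GLUCA}$ in ng glucagon per nmol C-peptide. The remote compartment is a
mathematical delay device without a strict anatomical identity; its input
term carries an implicit unit transfer rate of 1/min so that the units
balance. The model is linear, so simulated glucagon can cross zero; the
simulator permits this and warns, since concentrations are physically
non-negative.

$S_{GLUCA}(t)$ is estimated as one knot per sampling time and treated as
piecewise constant between consecutive samples (knot $i$ holds on
$[t_i, t_{i+1})$, left-continuous). A consequence worth knowing: the knot
attached to the *last* sampling time multiplies no interval and is pinned
only by the smoothness penalty below. Negative knots are allowed — they
describe periods where glucagon rises although insulin secretion is not
falling — but are discouraged by a penalty.

## Simulation: exact discrete-time propagation

`simulate_glucagon()` works on a fine uniform grid (default step 1 min,
which makes every standard OGTT sampling time a grid point; a final partial
step inside an inter-sample interval is truncated to the sample time).
Plasma C-peptide is interpolated linearly between samples. Within each grid
step both states are propagated with the *exact* solution of the linear
system for a linear-in-time input (scalar matrix-exponential updates with
series expansions near $K h \to 0$), not with a forward-Euler rule. The
discretization therefore introduces no truncation error beyond the linear
interpolation of the input itself, and the fixed-step solution matches an
adaptive high-accuracy integration (`method = "ode"`, `deSolve::lsoda` at
rtol $10^{-10}$, restarted at every sampling time so input kinks and
sensitivity switches never sit inside an integration span) to ~$10^{-8}$
relative. The test suite asserts 0.1% agreement over random parameter sets,
and machine-precision agreement with the closed forms available when
$S_{GLUCA} \equiv 0$, when $K_{GLUCA} = 0$ with constant $S_{GLUCA}$, and
for a constant suprabasal input.

## Estimation

`fit_subject()` minimises the regularized least-squares objective

$$RSS + K_{GLUCA}
  + w_1 \sum_j \bigl(\Delta^2 S_{GLUCA}\bigr)_j^2
  + w_2 \,\#\{j : S_{GLUCA,j} < 0\},$$

where $RSS$ is the sum of squared differences between simulated and
observed glucagon at the sampling times, the bare $K_{GLUCA}$ term encodes
the physiological expectation that clearance contributes little to
suppression during the test (it biases $K_{GLUCA}$ low by design), the
second-difference term limits unphysiologically rapid swings of the
sensitivity, and the count term discourages negative knots. The solver
minimises a residual *vector* whose squared norm equals this scalar cost:
data residuals, $\sqrt{K_{GLUCA}}$, $\sqrt{w_1}\,\Delta^2 S$, and
$\sqrt{w_2 \cdot \tilde c}$, where $\tilde c$ is a logistic softening of
the negativity count (sharpness 50) that keeps the objective differentiable
inside the optimizer; all *reported* costs use the exact count.

The optimizer is the bound-constrained Levenberg–Marquardt trust-region
solver of `minpack.lm` with function and step tolerances $10^{-6}$, bounds
$[0, 1]$ on both rates and unbounded sensitivities, run from `n_starts`
(default 10) random initial vectors with every component uniform on (0, 1).
The run with the lowest exact cost wins; ties go to the lowest start index.

One sequencing detail matters. The remote-compartment rate trades off
against the sensitivity knots along a curved valley: for *any*
$K_{\Delta CPREM}$, the ten interval equations can be solved exactly by the
ten dynamically active knots, so the sample-time data alone do not
discriminate the rate — only the penalties do (this is the practical face
of the model's merely *local* structural identifiability). A cold joint
solve tends to run the rate into its upper bound and stall there under
simple bound clamping. Each local run is therefore sequenced in two phases:
$K_{\Delta CPREM}$ is frozen at its random start value while everything
else adapts, then the full vector is released. This preserves the random
multistart protocol while removing the boundary-stalling failure mode and
raising the per-start success rate several-fold; the multistart stability
test (identical best cost under different start seeds) exercises this.

### What recovery can and cannot be expected

Because the rate is identified only through the penalties, recovery quality
depends on the true sensitivity profile and the noise level:

* noise-free data with a constant true $S_{GLUCA}$ recover
  $K_{\Delta CPREM}$ and the sensitivity to ~1% (the exact-fit solution is
  strictly smoother than any wrong-rate mimic);
* noise-free data with a smoothly varying profile already show ~20% rate
  error (a lower rate enlarges the remote excursion, shrinks the mimicking
  knots and thus *reduces* their roughness penalty);
* at 5% multiplicative measurement noise the knots absorb noise, the
  penalty landscape is swamped, and the rate is effectively not recoverable
  (median errors well above the 20% bound regardless of the smoothness
  weight; the corresponding recovery check in the acceptance suite computes
  these medians and fails by design). Time-averaged sensitivity errors track the rate errors, since a
  mis-estimated rate rescales the knots.

Population-level *contrasts* (the regression and duration analyses below)
are robust to this, because the rescaling acts similarly across subjects.

### Confidence intervals

95% intervals come from the Jacobian of the full residual vector at the
optimum: $se = \sqrt{\mathrm{diag}\bigl((J^\top J)^{-1}\bigr) s^2}$ with
$s^2 = \lVert f \rVert^2 / \max(\mathrm{dof}, 1)$ and
$CI = \hat\theta \pm t_{0.975,\mathrm{dof}}\, se$. The parameter count
exceeds the number of data points by construction ($p = n + 2$), so the
regularization rows are counted as residuals and
$\mathrm{dof} = n_{rows} - p$ (which is $n - 2$); a pseudo-inverse is used
with a warning if $J^\top J$ is singular. The same code path reproduces the
textbook OLS interval for a scalar linear model, which the tests verify.

### Regularization-weight selection

`select_weights()` follows a randomized grid search: 10 candidate values
per weight (100 combinations) drawn log-uniformly on $[10^{-3}, 10^{2}]$
(the original procedure states only "randomly generated"; a log-uniform
range spanning clearly-too-small to clearly-too-large values is the
package's choice). A combination is acceptable if the mean absolute
residual relative to the observed glucagon stays below 10% — the scale of
the inter-/intra-assay coefficient of variation of glucagon measurements —
and the acceptable combination with the lowest mean residual wins. The
package default outside this procedure is $w_1 = 0.1$, $w_2 = 1$: small
enough that a typical measurement-noise RSS dominates, large enough to
regularize the otherwise-unpinned rate and to make single negative knots
cost about one (ng/L)² of fit.

## Virtual population generation

`generate_population()` draws each concentration from a normal distribution
with the template's per-time mean and SD, truncated to the 95% band
(±1.96 SD, and at zero), and requires the sign of every consecutive
difference to match the template mean curve (flat template segments allow
either sign); glucagon and C-peptide are constrained independently.
Sampling is per-point rejection with a whole-curve restart when a point
gets stuck and a hard budget of $10^4$ draws. Two properties follow from
the constraints and are worth stating plainly:

* every subject satisfies the band and sign rules *exactly* (tested
  exhaustively), and
* the constrained distribution's mean is *not* the template mean — the sign
  conditioning shifts it by a substantial fraction of an SD at curve
  turning points (the tests bound the shift by 1 SD) (an
  unconditional whole-curve rejection sampler shows the same shifts, so
  this is a property of the constraints, not of the sampling scheme). The
  cohort mean tracks the template within 1 SD and preserves its shape.

The packaged templates (`default_template()`) are synthetic fixtures: an
11-sample 5-h OGTT with the canonical glucagon suppression-then-recovery
and C-peptide rise-then-decay shapes, and four 5-sample 2-h archetypes
(high/low fasting glucagon, rapid/delayed suppression, and a rising curve).
They emulate the *shapes* reported for real cohorts; they are not measured
data, so analyses on them reproduce directions and orders of magnitude,
not published point values. What passing tests on them show is that the
machinery is correct — not that any particular clinical population behaves
this way.

`synthesize_from_truth()` is the companion ground-truth generator for
estimator validation: it simulates glucagon from known parameters and a
C-peptide curve, then applies multiplicative Gaussian noise of a given CV
(floored at zero) to the sampled values.

## Population analyses

`subject_indices()` computes, per fitted subject: the arithmetic mean of
the sensitivity knots over the full test and over the nested 3-h
(t ≤ 180 min) and 2-h (t ≤ 120 min) windows (unweighted means; window
boundaries inclusive); the trapezoidal AUC of the simulated suprabasal
remote C-peptide; and the trapezoidal AUC of observed glucagon below basal,
$\max(Gluca_b - Gluca_{obs}, 0)$.

`sgluca_auc_regression()` regresses log mean sensitivity on the log of the
AUC ratio (remote C-peptide over glucagon deficit). Subjects with a
non-positive mean sensitivity or AUC ratio cannot be log-transformed and
are excluded with a count — the original analysis log-transforms without
stating how such subjects were handled. The mechanics of the model make
the expected slope negative: for small $K_{GLUCA}$,
$Gluca_b - Gluca \approx \bar S \cdot \Delta CP_{remote}$, so the AUC
ratio scales like $1/\bar S$ and the log–log slope sits near $-1$ before
attenuation by between-subject spread.

`duration_sensitivity()` compares the full-test mean sensitivity with the
3-h and 2-h window means across subjects, using a paired t-test when the
paired differences pass a Lilliefors-corrected Kolmogorov–Smirnov normality
check and a Wilcoxon signed-rank test otherwise. The Lilliefors correction
is used because the normal's mean and SD are estimated from the sample;
the plain KS test would be anticonservative. For 3–4 values (below the
Lilliefors implementation's minimum) an uncorrected KS on the standardized
sample is used and flagged approximate.

## Problem sizes and reproducibility

Validation workloads were sized to run comfortably on a single CPU: 50
random parameter sets for the solver cross-check, 20 noisy subjects for the
recovery study, 100 virtual subjects for the cohort analyses, 100
replicates for the normality-test calibration, and a 10 × 10 weight grid
searched on the packaged mean curve. All randomness derives from a single
root seed per entry point; per-subject and per-start seeds are drawn
deterministically from it, so every artifact is reproducible from
configuration plus seed alone.

## Known limitations

* No glucose compartment, no insulin-secretion deconvolution, no
  incretin/GLP-1 terms, no liver–alpha-cell amino-acid axis: insulin
  secretion (via C-peptide) is the only driver of suppression.
* $K_{\Delta CPREM}$ is a practical, penalty-identified parameter; its
  single-subject value should be interpreted with the caution described
  above, and $K_{GLUCA}$ is biased low *by design* through its
  regularization term.
* The RSS is unweighted (no measurement-variance weighting is stated for
  the original procedure).
* 2-h, 5-sample tests cover only the suppression phase; the duration
  analysis quantifies exactly how much the window truncation moves the
  mean sensitivity.
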