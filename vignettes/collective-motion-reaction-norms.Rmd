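---
title: "Collective-motion metrics and group-level reaction norms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collective-motion metrics and group-level reaction norms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shoalmotion)
```

## The problem

Small groups of social fish — the motivating system is shoals of eight
three-spined sticklebacks tested repeatedly in an open arena — show
*collective personality*: stable between-group differences in how aligned,
cohesive and fast their collective movement is. They may also show
*collective plasticity*: groups can differ in how their collective motion
changes over time, both within a testing session and across days of repeated
testing. shoalmotion implements the full analysis chain for this question:
from raw per-frame tracking coordinates to six interval-level
collective-motion statistics, and from those statistics to a reaction-norm
mixed-model layer that asks (i) do groups differ on average (random
intercepts), (ii) do groups differ in their temporal trends (random slopes),
and (iii) does between-group variance grow or shrink over time.

## Preprocessing

Tracking output is ingested as a long CSV (`group, day, trial, frame, id, x,
y`) at a known frame rate (default 25 fps) and pixel scale (default 2.7
px/mm); all internal computation is in mm and seconds. The preprocessing
chain is applied in a fixed order, and the order matters:

1. **Complete-frame filter.** A frame enters group-level analysis only if
   all `N` individuals were tracked at it.
2. **Speed-outlier filter** on *raw* positions: any frame where an
   individual's per-frame displacement exceeds 50 px/frame (about 46 cm/s at
   2.7 px/mm and 25 fps — several body lengths per frame) is treated as a
   tracking error and excluded whole. The filter must precede smoothing,
   which would smear the spike below threshold.
3. **Savitzky–Golay smoothing**, window 13 frames (about 0.5 s) and degree
   3, applied per individual and coordinate over contiguous valid runs only.
   Only interior points with a full window are replaced; run edges, and runs
   shorter than the window, pass through unsmoothed. No values are ever
   fabricated across tracking gaps, and smoothing never changes the validity
   mask. Velocities are central first differences of the smoothed positions
   (one-sided at run edges).
4. **Interval segmentation** into the five 2.5-min analysis windows of a
   trial (configurable); windows retaining less than 30 s of valid
   trajectory are dropped and logged with a reason code.

## The six collective-motion statistics

Per interval, one analysis row is computed:

* **Polarization** — the order parameter $P = \lVert \tfrac1N \sum_i
  \mathbf{u}_i \rVert$ over unit headings $\mathbf{u}_i$; 0 = no alignment,
  1 = complete alignment. Headings come from smoothed velocities; an
  individual slower than `min_heading_speed` (default $10^{-6}$ mm/frame)
  contributes no heading, and a frame needs at least two defined headings.
  The interval value is the median over frames (the per-frame distribution
  is right-skewed).
* **Centroid speed** — median over frames of $\lVert \mathbf{c}_t -
  \mathbf{c}_{t-1}\rVert \cdot \mathrm{fps}$, consecutive valid frames only
  (mm/s).
* **Convex hull area** — median over frames of the area of the convex
  polygon spanned by the group (mm²); an inverse-cohesion measure.
* **Transition rate** — the number of changes between polarized
  ($P > 0.65$) and unpolarized states across consecutive valid frames,
  divided by the number of valid frames. A frame at exactly the threshold
  counts as unpolarized.
* **Maximum speed cross-correlation** — for each focal fish, the Pearson
  cross-correlation between its speed series and its nearest neighbour's
  (nearest neighbour recomputed every frame, ties to the lowest id),
  maximized over lags $\tau \in [-300, 300]$ frames (±12 s), then averaged
  over individuals. Computed on the longest contiguous valid run so no
  correlation is estimated across gaps. A proxy for information transfer.
* **Leadership switch rate** — at each polarized frame, fish are ranked by
  the projection of their centroid-relative position onto the direction of
  group motion; the front rank is the leader. For each fish, the number of
  changes in leader status across consecutive polarized frame pairs is
  divided by the number of such pairs, and the mean over fish is returned.

Choices the definitions leave open were resolved as follows: the direction
of group motion is the centroid displacement to the next frame (a
mean-heading alternative is available via `metric_config()`); the leadership
denominator is the number of polarized consecutive frame pairs, the unit in
which switches are countable; cross-correlation lags run symmetrically; and
smoothed speeds are used for all metrics, for internal consistency.

## The reaction-norm statistical layer

Each metric is modelled with within-trial interval (1–5) and day (1–12) as
continuous fixed effects. Candidate random structures for group identity
are: none; a random intercept; intercept + interval slope; intercept + day
slope (with the intercept–slope correlation estimated). Gaussian responses
use `lme4`; convex hull area is square-root transformed. The leadership
switch rate, a rate in (0, 1), uses a beta-family mixed model with logit
link fitted by adaptive Gauss–Hermite quadrature (15 nodes by default; the
marginal likelihood is stable to well below $10^{-6}$ against a 41-node
rule). Responses exactly at 0 or 1 are rejected with the offending rows
named; an optional squeeze transform was considered and deliberately left
out — boundary values indicate a degenerate interval that should be
inspected, not silently squeezed.

Model comparison follows an information-criterion protocol. All compared
models are fitted by maximum likelihood. Mixed Gaussian models are scored by
**conditional AIC** in the Vaida–Blanchard form
$\mathrm{cAIC} = -2\,\ell_{\text{cond}} + 2(\rho + 1)$, where
$\ell_{\text{cond}}$ is the conditional log-likelihood at the BLUPs and
$\rho$ is the trace of the hat matrix mapping observations to fitted values
at the estimated variance parameters (computed via the Woodbury identity;
the `+1` counts the residual variance). As the between-group variance
shrinks to zero, $\rho$ falls to the fixed-effect count and cAIC converges
to the AIC of the fixed-effects model. Models without random effects (and
all beta-family models, for which cAIC is not defined here) are scored by
**AICc**. A structure is supported when the alternative sits more than 2
criterion units above the best model. A fit whose random-effect correlation
is estimated at the ±1 boundary — or cannot be estimated because a variance
collapsed — is overfitted: it is flagged unreliable, reported without a
criterion value and excluded from ranking.

Fixed effects in Gaussian mixed models are tested with Satterthwaite
denominator-df F-tests (`lmerTest`). This is a deliberate substitution for
the Kenward–Roger adjustment: at this design size the two agree closely, and
Satterthwaite avoids the specialised covariance correction. Beta-family
covariates are tested by likelihood-ratio tests.

With a random slope the between-group variance is a function of where the
covariate is centred:
$\operatorname{Var}(a_g + s_g c) = \sigma^2_{\text{int}} +
2c\,\rho\,\sigma_{\text{int}}\sigma_{\text{slope}} + c^2\sigma^2_{\text{slope}}.$
`variance_at_covariate()` evaluates this closed form (it equals the
intercept variance of a re-centred refit, a property the tests verify) and
attaches parametric-bootstrap percentile CIs: responses are simulated from
the fitted model, the model refitted, the variance recomputed (default 1000
replicates, seeded). Coverage calibration uses REML point fits, since the
downward bias of ML variance estimates centres the bootstrap too low.
`predict_reaction_norms()` returns per-group conditional predictions (fixed
effects + BLUPs) along one covariate with the others held at their means.

## The synthetic-data generators

No raw tracking data ship with the package, so validation rests on two
generators with known truth.

**Metric-level generator** (`simulate_metric_table()`): draws interval-level
responses directly from the reaction-norm model — fixed plane plus bivariate
normal (intercept, day-slope) group effects, optional interval slopes, and
Gaussian (or, through an inverse-logit map, beta) noise. Because it *is* the
model the fitting layer assumes, it gives exact ground truth for parameter
recovery and model-selection calibration. Default parameters
($\beta_0 = 0.7$, $\beta_{\text{interval}} = -0.01$,
$\beta_{\text{day}} = -0.015$, $\sigma_{\text{int}} = 0.05$,
$\sigma_{\text{slope,day}} = 0.01$, $\sigma_{\text{res}} = 0.05$, 12 groups
× 12 days × 5 intervals) are on the scale of a polarization-like trait with
a declining day trend and group heterogeneity in both level and slope.

**Trajectory-level generator** (`simulate_school()`, `simulate_study()`): a
zonal (three-ring) agent-based schooling model — repulsion inside 30 mm,
alignment to 150 mm, attraction to 450 mm — in a 1335 × 720 mm elliptical
arena, with bounded turning (0.4 rad/frame), wrapped-normal heading noise,
and wall handling by steering along the ellipse tangent within a boundary
layer (reflection would create artefactual polarization spikes). A zonal
model rather than a Vicsek-type model because it produces every regime the
metrics must discriminate: swarm/polarized transitions, cohesion changes,
and a leadership structure. The social (alignment + attraction) response of
group $g$ is weighted by an effective sociability
$\omega_g(d, i) = \omega_0 + a_g + (b + b_g)(d-1) + c\,(i-1)$, giving each
group a baseline personality ($a_g$) and its own day slope ($b_g$).
Speeds carry AR(1) fluctuations partially matched to the nearest
neighbour's, with matching strength proportional to sociability, so
information transfer (speed cross-correlation) also declines as groups
become less social; preferred speed itself declines across days.

The defaults were calibrated once so that baseline median polarization sits
near 0.7 — straddling the 0.65 threshold, which keeps the transition rate
informative — with $\omega_0 = 0.27$, heading noise SD 0.55 rad/frame,
$\mathrm{sd}(a_g) = 0.04$, $b = -0.008$/day, $\mathrm{sd}(b_g) = 0.004$,
and a within-trial drift of $-0.004$/interval. In this regime the
polarization response to sociability is steep
($\partial P/\partial \omega \approx 1.8$), so group differences and day
trends in $\omega$ map visibly onto all six metrics.

What the simulator does *not* emulate: body shape and collision mechanics,
3-D motion, individual heterogeneity within groups, tracking noise and
identity swaps, variable inter-presentation spacing, or individual
replacement between trials. Passing end-to-end tests on this generator shows
the chain recovers structure *of the kind assumed*, not that real tracking
data meet those assumptions.

## Problem sizes used in the test suite

The validation suite runs the statistical checks at deliberately reduced
but informative sizes, chosen as the smallest designs at which each
property is stable: parameter recovery at the study design size (12 groups
× 60 observations; 100 replicates) and at doubled replication (24 groups)
for bias; model-selection calibration over 100 replicates; bootstrap
coverage over 100 simulations with 200 bootstrap replicates; and the
end-to-end trajectory study at 6 groups × 6 days × 3 intervals with 1500
frames (60 s) per interval.

## Numerical and degeneracy conventions

* Polarization is undefined (and excluded from the interval median) at
  frames with fewer than two defined headings; an all-invalid series leaves
  the affected metric missing and the row flagged `qc_ok = FALSE`.
* Hull areas of degenerate point sets (collinear, < 3 distinct points) are 0.
* Zero-variance speed series contribute no cross-correlation and are
  excluded from the across-individuals mean.
* Gaussian mixed fits: `lme4` defaults with derivative checks disabled;
  non-convergence is reported on the fit, not raised.
* Beta GLMM: BFGS on $(\beta, \log\phi, \log\sigma)$ with per-group
  posterior-mode adaptation of the quadrature grid; group modes are located
  by golden-section search on a wide bracket and curvature by central
  differences.
* Ties in nearest-neighbour distance go to the lowest individual id;
  a polarization exactly at the threshold is unpolarized.

## Known limitations

* cAIC values are comparable only within a response/transform; the absolute
  values depend on the data scale.
* The beta layer supports a single random intercept (one-dimensional
  quadrature); random slopes for beta responses are out of scope, mirroring
  the analysis design it implements.
* The percentile bootstrap for variance components is approximate at 12
  groups; coverage is calibrated in the test suite rather than assumed.
* Repeatability is deliberately not reported: with random slopes it varies
  with the covariate level, so the variance-trend curve replaces it.
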