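---
title: "Methods: BACI occupancy analysis of forest owls under wildfire and invasive predator removal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BACI occupancy analysis of forest owls under wildfire and invasive predator removal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(owlbaci)
```

This vignette is the package's account of its science: the models it
fits, the assumptions they make, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the places where
the design was genuinely open and a choice had to be made.

## The study design being modeled

A regional passive acoustic monitoring program surveys a fixed grid of
non-contiguous 400-ha hexagonal cells, each holding two autonomous
recording units (ARUs) at least 500 m apart, across four breeding seasons.
Two disturbances partition the design into a Before-After-Control-Impact
(BACI) structure: severe wildfires (cells whose home-range buffers
intersect high-severity burn footprints) and an experimental lethal
removal of invasive barred owls (cells whose buffers intersect removal
home ranges). Species with small home ranges (flammulated owl, 50 ha;
pygmy owl, 300 ha) are analysed at the ARU level; the wide-ranging great
horned owl (700-ha buffer) at the hexagon level, because its calls reach
both ARUs of a cell.

## Detector score calibration

An automated detector emits a prediction score in [0, 1] every few
seconds. To turn scores into detection/non-detection data without
swamping the occupancy models with false positives, a per-species score
threshold is selected as follows:

1. Hour-long validation samples (default 200 per species-year, mirroring
   the minimum amount of audio reviewed manually) are labelled 1 if they
   contain at least one confirmed true positive.
2. For each threshold on the ladder 0.1, 0.2, …, 0.9, 0.91, …, 0.99, a
   logistic regression of false-positive status (1 = hour contains no
   true positive) on the number of predictions at or above the threshold
   gives an hourly false-positive probability FP.
3. FP is scaled to a weekly secondary sampling period as
   `1 − (1 − FP)^n`, with `n = 84` h (12 nocturnal survey hours × 7
   nights).
4. The smallest threshold with expected weekly rate below the 1% target
   is selected — smallest, because it maximizes retained detections
   subject to the bound; ties cannot occur on a strict ladder.

Two details are under-determined by the procedure's usual description and
were fixed here:

* **Reference count.** The logistic model must be evaluated at some
  predictor value to yield "the" hourly FP probability. We evaluate at
  count = 1, the minimal hour that produces a detection at that
  threshold; `ref = "mean"` evaluates at the mean observed count instead.
  With the slope constrained to zero the estimate reduces exactly to the
  observed false-positive fraction, which the tests use as an oracle.
* **Separation.** At high thresholds the validation sample typically
  contains *no* false-positive hour with any prediction above the
  threshold, so the maximum-likelihood fit diverges. We then use a
  ridge-penalized fit with a deliberately small penalty (λ = 1e-5) and
  flag the result. The small penalty matters: it lets the slope grow
  until fitted probabilities in the separated region are numerically
  zero, which is the honest answer there — a heavier penalty would park
  the decision boundary between the classes and report a fabricated
  mid-range rate. The penalized path uses Newton iterations with step
  halving, so it is monotone and deterministic.

## Encounter histories

The season is divided into 11 half-open 7-day bins anchored at May 7
00:00; eleven whole weeks end exclusively on July 23 00:00. (An inclusive
reading of "ending July 23" would give 78 days, incompatible with 11
whole weeks — the half-open convention is forced.) Only nocturnal events
(20:00–08:00) count. A period with zero recording effort is missing, not
a non-detection; a partly covered period keeps its data, with recorded
hours entering the detection model as a covariate. At hexagon level the
two ARUs' detections are unioned and their effort hours summed (bounded
by 336 h/week); a max-effort rule is available but the sum is the
default, since both ARUs listen independently.

Closure is assumed within each season. Across seasons, histories are
*stacked*: each unit-season is a row, with year and site random effects
absorbing the repeated structure rather than modeling
colonization/extinction dynamics.

## Covariates

* **Buffers.** Circular home-range buffers with radius `sqrt(area/π)`;
  areas 50/300/700/2004 ha for flammulated, pygmy, great horned, and
  barred owl respectively.
* **Severe fire.** The binary `burn` indicator and the continuous
  high-severity fraction of the buffer (cell-center inclusion at the grid
  resolution; simple and unbiased at 10–50 m cells). Prefire rows carry
  zeros. `burn1`–`burn3` distribute the fraction by years postfire and
  are fraction-valued; the fire-by-removal interaction terms are binary
  indicators. The asymmetry is deliberate and matches the models'
  definitions exactly.
* **Removals.** A site is a removal site iff its buffer strictly
  intersects a removal buffer (tangency, a measure-zero case, counts as
  non-overlap). `lethal1`, `lethal2`, `lethal3plus` code 1, 2, and ≥3
  years post-removal.
* **Terrain ruggedness.** Mean over buffer cells (390 m radius) of each
  cell's mean absolute elevation difference to its 8 neighbors; no edge
  extrapolation — a buffer touching the grid border is an error rather
  than a silently truncated value.
* **Seral forest.** Fraction of buffer cells classified
  intermediate-to-late seral (the synthetic layer is generated directly
  as a binary field; the thresholds it stands in for are QMD ≥ 25 cm and
  canopy cover > 40%).
* **Collinearity.** Pairwise Pearson correlations among predictors are
  reported and warned about at |r| ≥ 0.6.

Continuous *detection* covariates (date, effort, ruggedness) and the
niche covariates are z-standardized. Occupancy covariates are kept on
their natural scale: they are indicators and fractions bounded in [0, 1],
and the model coefficients are interpreted per unit of proportion burned,
which standardization would obscure.

## Occupancy models and sampler

The marginalized single-season likelihood per unit-season row is

* any detection: `ψ · Π_t p_t^y (1−p_t)^(1−y)`,
* no detection: `ψ · Π_t (1−p_t) + (1−ψ)`,

with missing periods contributing nothing. This function is a first-class
tested artifact: the suite checks it against brute-force enumeration over
the latent state for every 2–4 period history, including missing
patterns.

Priors are weakly informative: Normal(0, 2.5²) on occupancy and detection
coefficients, half-Normal(0, 1) on the random-effect SDs — the common
default class for occupancy packages, chosen because the models
themselves state no priors.

The sampler is an adaptive Metropolis-within-Gibbs:

* coordinate-wise random-walk updates for β and α;
* jointly vectorized elementwise updates for year and site effects (valid
  because years and sites each partition the rows, so the acceptance
  decisions are independent);
* random-walk updates of log σ against prior terms only;
* proposal scales adapt in batches of 50 toward 44% acceptance during
  burn-in *only*, so the retained chain is a valid Markov chain;
* chain seeds derive deterministically from the master seed — same seed,
  bit-identical draws.

Defaults are 4 chains × 2600 iterations with half discarded, summaries as
posterior means with 85% equal-tailed credible intervals (the level is
conventional in this literature and configurable), convergence by the
Gelman–Rubin statistic with the usual 1.1 rule.

Prediction at a covariate profile marginalizes the random effects by
drawing fresh year and site effects from their posterior SDs per draw
(describing a new site in a new year); `re = "zero"` conditions on average
units instead. The choice matters for the absolute level of ψ and is
exposed rather than hidden.

## Goodness of fit

The MacKenzie–Bailey test is run as a posterior predictive check: for a
thinned set of draws, the Pearson chi-square over encounter-history
frequencies is computed on the data and on a replicate simulated from the
same draw, and the p-value is the fraction of replicates with a statistic
at least as large. Rows are cohorted by missingness pattern; cohorts with
fewer than 2 rows are merged into the nearest pattern (Hamming distance)
and compared on their jointly observed periods, keeping expected counts
away from zero. All never-observed histories contribute their pooled
expectation.

Two properties are verified by simulation, with the check design chosen
deliberately:

* **Calibration** (p approximately uniform under the generating model) is
  checked at 150 sites × 2 seasons with 5 weekly periods. Fewer periods
  than the survey's 11 are used so that encounter histories repeat;
  with 11 periods nearly every history is unique and the statistic is
  dominated by sparse-cell noise.
* **Power.** Logit-normal per-row detection heterogeneity is only weakly
  detectable by this statistic — the fit partially mimics it with lower ψ
  and higher p (the known ψ–p mixture near-non-identifiability), and the
  generator exposes that knob (`p_extra_sd`) precisely so users can see
  the weakness. The power check instead uses site-level random slopes on
  the seasonal date term (`p_slope_sd = 3`: sites detectable early vs
  late in the season), a form of site heterogeneity the shared seasonal
  trend cannot absorb and that the test rejects decisively.

## Contrasts and niche analysis

Removal effects are assessed by the overlap of the posterior densities of
the occupancy linear predictor at removal sites before (β₀ + β_site-type)
and after (adding the post-removal term) removals, on the logit scale.
The overlap index is `∫ min(f_a, f_b)` from Gaussian kernel density
estimates with plug-in (Sheather–Jones) bandwidths on a shared 512-point
grid spanning both samples ± 3 bandwidths; overlap below 15% is flagged
as a meaningful difference. The index is symmetric and invariant to
common shifts, and reproduces the closed-form overlap of two unit-variance
normals two SDs apart (2Φ(−1) ≈ 0.317) within the suite's tolerance.

The invader's occurrence is modeled by maximum-likelihood logistic
regression on standardized elevation, ruggedness and seral fraction —
appropriate for a species surveyed without repeat visits and with high
seasonal detection probability — with average marginal effects
`mean(β_j p(1−p))` verified against numerical differentiation. Niche
breadth and segregation use 85% standard ellipses: center at the sample
mean, shape from the sample covariance scaled by the χ²₂(0.85) quantile,
area `π χ²₂(0.85) √det Σ`. Ellipse intersection is computed by
Sutherland–Hodgman clipping of 512-vertex boundary polygons (relative
area error well below 0.1%, verified against the closed-form circular
lens), and the overlap fraction normalizes by the smaller ellipse.
Breadth and overlap are reported per covariate pair, with no aggregation
across pairs. Native-species niche inputs are first-season detections
only (conditions before removals and fires); invader inputs add the
removal locations.

## The synthetic-data generator

The generator is first-class, tested code. It emulates: a planar
landscape (meters, no geodesy) with a smoothed Gaussian random-field
elevation (so ruggedness varies realistically; smoothing scale
configurable), clumped binary seral stands, circular fire footprints
whose realized high-severity fraction matches the request up to cell
rounding; a hexagonal survey lattice with non-contiguous sampled cells
(edge-sharing candidates rejected), two ARUs ≥ 500 m apart per cell, and
the two deployment protocols (three 1-week pulses with ≥ 14-day gaps vs
five continuous weeks); removal locations placed preferentially in
high-seral, flatter cells (uniform placement available); latent
occupancy drawn once per unit-season from any of the six models with year
and site random effects; weekly detections from the five-predictor
detection model only where effort is positive; detection events
materialized as nocturnal timestamps inside deployment intervals; and
hourly detector score streams with planted true positives (dispersed
high scores) and false positives (bounded low scores).

Default scale is 60 hexagons × 4 seasons — desk-runnable — against the
real program's 265; the tests use smaller sizes still, stated per test.
What the generator does *not* emulate: audio itself, spatial
autocorrelation in occupancy beyond the random effects, animal movement,
and observer-level review error. Passing tests therefore demonstrate the
*estimators* are correct under the stated generative assumptions, not
that real acoustic data meet those assumptions.

The bounded false-positive score support deserves a note: an overfit
detector's spurious predictions concentrate at low confidence, so the
default profile bounds them at 0.35. This gives the threshold ladder a
regime where false positives are strictly absent — which is exactly the
regime in which a <1% weekly bound is certifiable at all from a
200-hour validation sample; an unbounded heavy upper tail would make the
1% target unreachable at any threshold and the selection procedure would
(correctly) error out.

## Numerical choices and degenerate inputs

* Likelihood evaluations use `log1p`/`plogis(log.p = TRUE)` forms; the
  no-detection row probability is computed in probability space (it is
  bounded away from underflow by `1 − ψ`).
* An all-missing history contributes probability 1 (no information).
* Constant occupancy design columns produce a warning, not an error: in
  small BACI subsets a treatment arm can be empty and the prior then
  dominates that coefficient.
* Degenerate validation samples (a single label class) and zero-variance
  posterior draw vectors are errors, not silent NaNs.
* `weekly_fp` saturates at 1 in double precision for hourly rates above
  ~5% with n = 84; the monotonicity property is exact on the operating
  range of interest (rates ≪ 1%).
* Collinear niche points are an error for ellipse construction (the
  covariance is singular).
* All stage and chain seeds derive from one master seed by a fixed
  integer schedule, kept below 2³¹.

## Problem sizes used by the checks

Parameter recovery runs at 250 sites × 2 seasons (500 stacked rows) with
the fire model's generating coefficients (−1, 0.5, −3) and random-effect
SDs 0.3; interval coverage uses 50 replicates at a reduced chain length
(900 iterations, single chain), which the pilot calibration showed is
enough for nominal-range coverage. The calibration operating bound is
re-simulated over ≥ 1000 independent 84-hour weeks. These sizes are the
package's own choice of desk-scale study conditions.

## Known limitations

* The stacked design estimates regional occupancy patterns, not turnover;
  colonization/extinction dynamics are out of scope.
* Detection-year effects are fixed effects independent of the
  occupancy-year random effect; the alternative (shared effects) is not
  implemented.
* The MacKenzie–Bailey test has intrinsically low power against smooth
  detection heterogeneity (see above); a clean p-value is weak evidence
  of homogeneous detection.
* The hexagon-level effort sum treats the two ARUs as independent ears;
  if their detection ranges overlap substantially the effective effort is
  overstated.
* Ellipse overlap is 2-D per covariate pair; no 3-D ellipsoids.
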