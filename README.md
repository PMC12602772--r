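# owlbaci

Before-After-Control-Impact (BACI) occupancy analysis of forest owl
responses to severe wildfire and invasive barred owl (*Strix varia*)
removal, driven by passive acoustic monitoring.

Regional acoustic surveys of the Sierra Nevada forest owl assemblage —
flammulated owl (*Psiloscops flammeolus*), northern pygmy owl
(*Glaucidium californicum*), and great horned owl (*Bubo virginianus*) —
bracket two megafires and a lethal barred owl removal experiment. This
package implements the full analysis chain for that design, together with a
synthetic-data generator that emulates the acoustic-grid study (hexagonal
400-ha survey cells, two recording units per cell, weekly secondary
sampling periods, fire footprints, removal home-range buffers, and
detector prediction-score streams), so the entire pipeline runs with no
downloads and with known ground truth for testing.

## What it computes

**Detector calibration.** Hour-long validation samples are labelled true
or false positive; a logistic model of false-positive status on the number
of detector predictions above a candidate score threshold gives an hourly
false-positive probability FP, scaled to a weekly secondary sampling
period as `1 − (1 − FP)^n` with `n = 84` survey hours. The smallest
threshold with an expected weekly rate below 1% is selected.

**Encounter histories.** Detection events and deployment records become
site-by-week detection/non-detection matrices over 11 one-week periods
(May 7 – July 23), with recorded hours per period as a detection
covariate and unsurveyed periods treated as missing.

**Occupancy models.** Six Bayesian stacked single-season occupancy models
with the MacKenzie et al. marginalized likelihood,

    logit ψ_i = β₀ + β·x_i + μ₁[year_t] + μ₂[site_i]

where `x_i` is, by model: burn status and high-severity fraction
(time-constant or split by years postfire); removal-site status and
post-removal indicators (time-constant or by years post-removal); or
fire-by-removal interactions. Detection is a five-predictor logit model
(ordinal date, survey year, terrain ruggedness, weekly survey hours,
barred owl presence). Inference is by an adaptive Metropolis-within-Gibbs
sampler written in this package (4 chains × 2600 iterations, half
burn-in, 85% credible intervals), with Gelman–Rubin convergence checks
and a MacKenzie–Bailey posterior-predictive goodness-of-fit test.

**Contrasts and niche segregation.** Pre- vs post-removal effects are
compared by the overlap of posterior densities on the logit scale
(kernel-density estimate of `∫ min(f_a, f_b)`; overlap below 15% is
treated as a meaningful difference). Habitat niche segregation uses a
logistic occurrence model for the invader, average marginal effects, and
85% standard ellipses (area `π · χ²₂(0.85) · √det Σ`) with pairwise
overlap by polygon clipping.

## Worked example

```r
library(owlbaci)

# 1. calibrate a score threshold against the <1% weekly false-positive target
profile <- species_profile()
stream  <- simulate_scores(profile, n_hours = 200, seed = 1)
cal     <- calibrate(stream, target = 0.01, n_hours = 84)
cal
#> <owl_calibration> 18 thresholds, target 0.01/week (n = 84 h): selected 0.30

# 2. fit the removal (time-constant) occupancy model to synthetic data
sim   <- simulate_occupancy_data("bo_tc", n_sites = 150, n_seasons = 2, seed = 2)
draws <- sample_posterior(sim$design, chains = 2, iters = 800, burn = 400, seed = 3)
summary(draws)[1:3, ]
#>            parameter  mean   sd lower upper rhat
#> 1   beta_(Intercept) -1.23 0.96 -3.02  0.23    1
#> 2     beta_site_type -0.26 0.37 -0.84  0.29    1
#> 3 beta_allpostlethal  0.87 0.45  0.18  1.53    1

# 3. pre- vs post-removal contrast on the logit scale
removal_contrast(draws, "allpostlethal")
#> <owl_overlap> 53.6% overlap (not a meaningful difference at <15%)

predict_occupancy(draws, c(site_type = 1, allpostlethal = 0), re = "zero")$mean
# removal-site occupancy pre 0.23 (85% CI 0.04-0.55) vs post 0.38 (85% CI 0.08-0.70)
```

The generating truth here was β = (−1, −0.6, 0.9): the post-removal
effect (0.87, 85% CI excluding zero) and the occupancy increase at
removal sites are recovered; at this desk scale (150 sites) the posterior
overlap stays well above the 15% rule, as expected for the reduced sample
size.

`run_pipeline(owl_config(seed = 1), "out/")` executes the whole chain —
simulate → calibrate → build → fit → contrast → niche — writing plain
CSV/JSON artifacts per stage.

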