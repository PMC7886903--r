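# recer

Regression analysis of radiocarbon-dated event counts under chronological
uncertainty: Radiocarbon-dated Event Count Ensembles (RECEs) and
hierarchical negative-binomial regression, in R.

## The problem

Did late-Pleistocene North American megafauna decline because human
populations grew, because climate changed, or both? Questions of this
shape are usually asked of radiocarbon-date databases, and usually
answered with summed probability density functions (SPDFs) — the pointwise
sum of calibrated date densities, read as a population proxy. SPDFs
conflate *process variation* (how many dated events happened per year)
with *chronological uncertainty* (how poorly each event is dated), which
can badly mislead a regression.

`recer` implements the event-count alternative. Each dated record is
calibrated into a calendar-year density; each ensemble member draws one
probable year per record from the 98% highest-density region of its
density and counts events per year, giving M probable count sequences (a
RECE). Every member sequence `y_m` is then a separate negative-binomial
regression,

    y_mt ~ NB(mu_mt, phi),    log mu_mt = beta_0m + sum_k beta_km * x_kmt ,

whose member-level coefficients are pooled under top-level normals
`beta_km ~ N(B_k, sigma_k)`. The hyper-means `B_k` carry each covariate's
effect across all probable event histories; a covariate matters when the
equal-tailed 95% credible interval of its `B_k` excludes zero. Covariates
are member-paired, so a covariate that is itself a dated-event record (a
human-activity RECE, a tephra-based taphonomic RECE) or an uncertain
climate series propagates its own chronological uncertainty into the
posterior. The MCMC sampler is implemented in C++ (adaptive
Metropolis-within-Gibbs with interweaved non-centred hyper-parameter
moves) and is byte-reproducible under a seed.

The package also generates complete synthetic study inputs with known
ground truth (`make_scenario()`), so the full pipeline is testable without
any external downloads.

## Worked example

Simulate a scenario in which climate drives megafauna event counts
(coefficient +0.1 in standardized units) and humans do not, then run the
whole pipeline — calibration, 50-member ensembles on the 15.0–11.7 ka
window, decadal thinning, and the mixed (humans + climate + taphonomy)
model:

```r
library(recer)
sc  <- make_scenario("climate_driven_humans_null", seed = 42)
fit <- fit_scenario(sc, family = "mixed", M = 50, iterations = 3000,
                    warmup = 1000, chains = 2, seed = 43)
fit
#> Hierarchical NB event-count regression (50 ensemble members, 331 retained years)
#> Covariates: humans, climate, taphonomy
#> Top-level coefficient means (posterior mean [95% CrI]):
#>   beta0             -2.4489 [ -2.5120,  -2.3924]
#>   beta_humans        0.0218 [ -0.0360,   0.0741]
#>   beta_climate       0.0686 [  0.0139,   0.1196]
#>   beta_taphonomy    -0.1013 [ -0.2769,  -0.0024]
#> Dispersion phi: 42.451
#> Max split R-hat 1.032; min ESS 72

significance(fit, "climate")$decision
#> [1] "significant_positive"
significance(fit, "humans")$decision
#> [1] "not_significant"
```

Reading the output: `beta_climate` recovers the generating +0.1 effect
(posterior mean 0.069, interval excluding zero — climate "significant
positive"), while `beta_humans` straddles zero, matching the generating
truth. The intercept fixes the mean count level and is never tested.
`beta_taphonomy` (generating truth 0) lands just past the interval edge
here — a reminder that a 95% rule produces marginal calls at rate 5%, and
why the decision comes with the full interval rather than a star.
`summary(fit)` adds hyper-sds, dispersion, split R-hat and effective
sample sizes per parameter; `plot(fit)` draws the posterior densities
with the zero reference line, and `plot_rece_heatmap()` draws the
member-agreement heat map of any ensemble.

`run_analysis_suite()` repeats this over taxon/region subsets and the
three model families (humans-only, climate-only, mixed) and returns one
tidy results table.

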