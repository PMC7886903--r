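---
title: "Event-count regression under chronological uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-count regression under chronological uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Radiocarbon-dated records — megafauna fossils, archaeological charcoal,
tephra layers — are commonly turned into through-time abundance proxies.
The conventional device is the summed probability density function (SPDF):
add up the calibrated date densities and read the sum as population size.
The SPDF, however, conflates two very different things: *process variation*
(how many events actually happened per year) and *chronological
uncertainty* (how poorly each event is dated). A century-wide calibrated
density contributes a century-wide smear to the SPDF even if the event
itself was instantaneous, and regressing an SPDF on a covariate treats
that smear as if it were signal.

`recer` implements the alternative this package is built around: treat the
true event history as unknown, sample many *probable* event-count
sequences consistent with the dated record, and carry the whole ensemble
through the regression. The result is a posterior for each covariate
effect that reflects chronological uncertainty without mistaking it for
process variation.

## From dates to count ensembles

Each conventional radiocarbon age `a ± s` (RCYBP) is calibrated against a
curve `(c14_mean(t), c14_sigma(t))` on an annual calendar grid: the
posterior mass at year `t` is proportional to the normal density of `a` at
mean `c14_mean(t)` and standard deviation `sqrt(s^2 + c14_sigma(t)^2)`,
normalised over the grid (`calibrate()`). We use a normal (not Student-t)
measurement model — the simplest standard calibration likelihood — and
linear interpolation of the curve onto the annual grid. The calendar
convention everywhere is integer years cal BP, stored oldest-first; total
unnormalised mass below 1e-300 is reported as a degenerate density rather
than silently renormalised.

A Radiocarbon-dated Event Count Ensemble (RECE, `build_rece()`) is built
by drawing, for each ensemble member, one calendar year per dated record
from the 98% highest-density region (HDR) of its calibrated density, in
proportion to the density, and histogramming the draws into annual bins of
the analysis window. The HDR (`hdr()`) is the smallest set of years,
accumulated in descending mass order, reaching the level; ties at the
cut-off are all included. Sampling is independent across records and
members; draws landing outside the window are dropped from that member, so
member row sums can differ near window edges — the window restriction is
applied after sampling. The default ensemble size for the full analysis
configuration is M = 50, and count sequences are thinned to every 10th
year (`thin_rece()`) before fitting: thinning *selects* annual bins, it
never aggregates them, because a "count" is defined per calendar year. We
thin after windowing; the alternative order is not distinguishable from
the analysis description we follow and makes no difference away from
window edges.

`build_spdf()` is provided as the comparison baseline only.

## The hierarchical negative-binomial regression

Each ensemble member `m` is one probable count sequence `y_mt` and gets
its own log-linear negative-binomial regression,

```
y_mt ~ NB(mu_mt, phi),   log mu_mt = beta_0m + sum_k beta_km x_kmt ,
```

and the member-level coefficients are pooled under top-level normals,
`beta_km ~ N(B_k, sigma_k)`. The hyper-means `B_k` are the quantities of
interest: they summarise a covariate's effect across all probable event
histories. A covariate is deemed important when the equal-tailed 95%
credible interval of its hyper-mean excludes zero (`significance()`). We
use equal-tailed rather than highest-posterior-density intervals as the
simplest reproducible reading of a "95% credible region"; the intercept is
reported but never tested, since it only fixes the mean count level.

Member pairing is structural: covariate member `j` always enters
regression `j`. Covariates can therefore themselves be ensembles — a human
event-count RECE, a tephra-based taphonomic RECE (`build_taphonomic_rece()`,
sampling each event age from its central 98% normal region, which equals
the HDR for symmetric unimodal densities), or a climate-series ensemble —
so their chronological uncertainty propagates into the posterior alongside
the response's.

Choices the analysis description leaves open, fixed here as package
defaults (all overridable):

* **Priors** (`recm_priors()`): `B_k ~ N(0, 10)`, `sigma_k ~ half-N(1)`,
  and a half-normal(5) prior on `1/phi`. These are weakly informative on
  the standardized-covariate scale where effects of interest are ~0.1.
* **Dispersion** `phi` is shared across members within one fit; sharing
  stabilises fits on sparse (mostly 0/1) annual counts, and the dispersion
  mostly absorbs the temporal spread injected by chronological
  uncertainty. A fixed `dispersion` can be supplied (large values give the
  Poisson limit, which we exploit for oracle testing).
* **Standardization**: every covariate is z-scored over the window, per
  member, so coefficients are comparable across proxies; whether the
  original analysis standardized its covariates is not stated, and
  reported coefficients here always refer to standardized units. Constant
  member slices (e.g. an all-zero covariate draw) are centred to zero
  rather than rejected — such a member simply contributes no information
  about that covariate.

## Sampling and diagnostics

The posterior is explored with an adaptive Metropolis-within-Gibbs sampler
written in C++ (`src/recm_sampler.cpp`): componentwise random-walk moves
on each member coefficient, conjugate Gibbs draws for the hyper-means,
log-scale random-walk moves for the hyper-sds and dispersion, and — the
step that matters most — an interweaved *non-centred* update of each
`(B_k, sigma_k)` pair holding the standardized member offsets fixed.
Centred updates alone cannot traverse the funnel that opens when members
agree closely (small `sigma_k`); the interweaved move walks straight
through it. Proposal scales adapt by Robbins-Monro during warmup (target
acceptance 0.44) and are frozen afterwards. The sampler uses R's RNG, so
a seed makes entire fits byte-reproducible; chains `c` use `seed + c - 1`.

Convergence is summarised by split R-hat (computed in-package, so single
chains are supported) and effective sample size (via `coda`), with fits
flagged — never suppressed — when max split R-hat exceeds 1.05. On the
desk-scale problems in the test-suite the sampler reaches R-hat below
1.03 and ESS in the hundreds within 2000–3000 iterations. An independent
cross-check against a general-purpose MCMC engine (rjags) on a shared
small fixture is part of the test-suite.

## Climate covariates under uncertainty

The ice-core oxygen-isotope proxy enters either as a 50-year running-mean
record (`smooth_running_mean()`, centred window, truncated at the edges)
or, for the extended analysis mode, as an ensemble that re-projects the
record's chronological and measurement uncertainty from the time axis onto
the measurement axis (`reproject_uncertainty()`). Each ensemble member
evaluates the record under one age-model realisation built as a cumulative
sum of independent Gaussian increments whose running variance matches the
accumulated counting-uncertainty profile, sorted to enforce monotonicity,
then re-interpolated and perturbed with independent measurement noise.
This is the simplest scheme consistent with layer-counted age
uncertainties; the envelope contract — pointwise 2.5/50/97.5 percentiles
whose 95% band covers a truth generated under the same error model at
~95% — is what the tests pin down, not any particular published
re-projection algorithm. Two geometric facts shape how that coverage is
verified: the band is nominal only where age uncertainty dominates
measurement noise (members add fresh measurement noise to an
already-noisy record, so at negligible age error the band over-covers),
and the age-error path of any one record is a single autocorrelated
random walk, so coverage must be aggregated across many independent
records rather than many years of one record. Ice-core ages on the b2k datum (before 2000 CE)
are converted to cal BP by subtracting 50 years (`to_cal_bp()`).

## The synthetic-data generator

`make_scenario()` generates every input with known ground truth: a
monotone wiggly calibration curve, a millennial-scale quasi-stadial
climate series with measurement noise and accumulating age uncertainty,
a growth-ramp human event history, uniform tephra events, and a megafauna
event history drawn from the same negative-binomial log-linear process
the regression assumes, with stated coefficients (scenario
`climate_driven_humans_null` sets `beta_climate = +0.1`,
`beta_humans = 0`; `null_null` and `humans_driven` cover the competing
hypotheses). Defaults mirror the real records' order of magnitude at desk
scale: ~300 megafauna events and ~600 human events on a 15.0–11.7 ka
window, M = 20, 80 14C-yr measurement errors, NB dispersion 10. A
full-scale preset (432 cleaned events plus 89 flagged duplicate rows,
938 human dates, 14 Canada-labelled rows) uses fixed-total multinomial
event sampling so file-level record counts are exact.

Because the generator matches the analysis model by construction, recovery
failures in the test-suite indicate implementation faults rather than
model misspecification. The flip side is what passing does *not* show:
the generator has no research-effort bias, no spatial site structure, no
realistic calibration-curve plateau statistics, and its taphonomic decay
option is off by default — so green tests say the machinery is faithful,
not that the model is adequate for any particular real record.

One property of the method worth stating plainly: a single simulated
history of ~300 events carries sampling noise of roughly 0.06 on its
realised log-linear slope, and the hyper-mean credible interval quantifies
chronological uncertainty, not that generative sampling error. Parameter
recovery is therefore assessed on the mean posterior estimate across
replicate histories in the test-suite, and interval coverage of the truth
is checked per replicate rather than assumed.

## Problem sizes used by the tests and acceptance script

Unit tests run on toy grids (tens to hundreds of bins). The statistical
acceptance checks use: 110+ random densities for the HDR oracle; M = 2000
members for the count-expectation link; 20 replicate null fits (M = 20,
~300 events, 1500 iterations) for interval coverage of a zero human
effect; 8 replicate recovery fits for the +0.1 climate effect; one
M = 50 mixed fit for the qualitative decision pattern; and 200 replicate
records (10^4 interior grid years in total) for envelope coverage. The acceptance
script fits the full-scale emulation (432 cleaned events, M = 50,
decadal thinning, 15.0–11.7 ka) with 3000 iterations on 2 chains.

## Known limitations

No reservoir corrections, marine curves, or age-depth modelling; no
model-comparison machinery (WAIC/LOO); no spatial random effects; no
threshold/non-linear climate response; regional labels are taken as given
input, never derived from coordinates; and the human/taphonomy covariate
RECEs are thinned identically to the response, which the analysis
description implies but does not state.
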