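---
title: "Methods: hierarchical discrete-choice resource selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical discrete-choice resource selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coveysel)
```

## The design and the model

Fall/winter telemetry of covey-living bobwhite yields one used location per
relocation. Pairing each used location with three available locations
sampled at 50–400 m (uniform distance, uniform azimuth) forms a choice set:
four alternatives of which exactly one was selected. The conditional
multinomial logit models the probability of the selected alternative as the
softmax of linear utilities over standardized covariates. Two properties of
this likelihood shape everything else:

* only *within-set contrasts* are identified — a covariate constant within
  every choice set contributes nothing (tested explicitly);
* the softmax is shift-invariant, so utilities are computed with
  max-subtraction and are immune to overflow.

Coefficients vary by covey and season: `beta[k, c, s] ~ N(mu[k, s],
sigma[k, s]^2)`. The season split is binary (November = fall = 0,
December–January = winter = 1; other months are rejected), and the
population mean and sd are season-specific, so each covey–season
combination present in the data carries its own coefficient vector. Each
selection event is assumed independent given the coefficients; serial
autocorrelation of relocations is out of scope.

## Priors and their interpretation

The population means take Normal(0, sd 10) priors. Samplers in the BUGS
family write this as `dnorm(0, 0.01)` — a *precision* of 0.01 — and we
follow that reading because the analysis this package operationalizes calls
its priors vague; interpreting 0.01 as a variance would instead be strongly
informative at sd 0.1. The population sds take half-Normal(sd 5) priors, a
weakly informative default that admits anything from near-pooling to very
heterogeneous coveys; both scales are `mcmc_config()` knobs, and fits with
prior sds of 5–20 on the means move the large-effect posteriors by far less
than one CRI half-width.

## Sampler

`fit_dcm()` runs an adaptive Metropolis-within-Gibbs sampler (compiled
code), with four move types per iteration:

1. random-walk updates of each covey–season coefficient (only that group's
   sets are re-evaluated, incrementally);
2. exact conjugate Gibbs draws of each population mean given its
   coefficients and sd;
3. a *translation* move shifting a population mean and all of its season's
   coefficients together (the coefficient prior is invariant, so only the
   likelihood and the mean's prior enter);
4. a *scale* move multiplying a population sd and rescaling its
   coefficients about the mean (the prior and Jacobian terms cancel).

Moves 3 and 4 are what make the hierarchy mix: without them the mean can
only drift at speed `sigma/sqrt(n_groups)` per iteration and the classic
sd–coefficient funnel appears. With them, four chains of 5,000 iterations
(burn-in 1,000, thin 5) reach Gelman–Rubin values below 1.05 on
population-level parameters at the default study scale; the conservative
default configuration (100,000 iterations, burn-in 10,000, thin 50, giving
1,800 retained draws per chain) matches the field's customary settings.
Proposal scales adapt toward 44% acceptance in batches of 50 during burn-in
only. Chains start over-dispersed (means from N(0, 2), sds from U(0.3, 2))
and run sequentially under one seed, so fits are exactly reproducible;
non-finite states at initialization trigger a bounded re-draw of initials.
The Gelman–Rubin statistic uses the classic (non-split) potential
scale-reduction formula; convergence failures are reported and flagged,
never silently accepted.

## Numerical conventions

* **Standardization** pools *all* alternatives (used and available) across
  all sets, once; within-set contrasts keep their meaning, and prediction
  axes are back-transformed through the stored parameters. The NG-by-PG
  interaction is formed on the raw scale, then standardized as its own
  column.
* **Credible intervals** are equal-tailed, by default 85% (7.5th/92.5th
  percentiles), computed with R's default type-7 linear-interpolation
  quantile rule.
* **VIF** is `1/(1 - R^2)` from an intercept-included OLS regression of
  each covariate on the others over the pooled alternatives; combinations
  pass below 2.5. Exact collinearity reports `Inf` and fails rather than a
  large finite number.
* **WAIC** uses the variance form of the effective-parameter penalty
  (pWAIC2), with the choice set as the pointwise unit. The filter removes a
  competitive model (dWAIC < 2) when a *strictly smaller* competitive model
  shares at least one term with it.
* **Landscape metrics**: cover classes come from half-open height
  thresholds (shrub [0.7, 3.5) m, tree [3.5, 40] m, the 3.5 m boundary
  belonging to trees; taller than 40 m is open), buffers use the
  cell-center-in-disc rule, edge density counts interior woody/non-woody
  boundaries whose midpoints fall in the disc (an isolated 3.6-m cell in a
  50-m buffer gives 14.4 m / 0.7854 ha ≈ 18.33 m/ha), and distance-to-tree
  is measured to cell centers — GIS tools that polygonize the tree layer
  can differ by up to half a cell diagonal. Native-grass and management
  layers enter as caller-supplied masks; the raster pathway is optional and
  the models consume covariates directly.

## The synthetic generator

`generator_config()` encodes the emulated study conditions: 67 coveys, 650
choice sets, a ~40/60 fall/winter split, covariate marginals bounded and
calibrated to the field ranges (percent covers and visual obstruction as
truncated Normals; stem counts negative-binomial capped at 1,000; the
50-m-buffer proportions as Beta; distance-to-tree as a truncated
exponential; edge density as a truncated Normal up to 2,100 m/ha), and
truth population means seeded from the reported fall/winter posterior means
of the motivating analysis so that recovery tests run in that effect-size
regime. The population sd defaults to 0.5 everywhere — modest covey
heterogeneity; no reported value exists for it.

Alternatives within a set are *not* independent in the field: they lie
50–400 m apart and their landscape covariates are computed over overlapping
50-m buffers, so most covariate variance is between sets. The generator
reproduces this with a Gaussian copula whose set-level factor carries 80%
of the latent variance (`within_set_cor = 0.8`). This matters more than it
looks: with independent alternatives and effects of magnitude 3–4 on the
standardized scale, the simulated choices become nearly deterministic, the
coefficient *magnitude* loses identification, and the posterior drifts
toward the prior scale — conditions under which no analysis (this one or
the field's) could have produced the finite, narrow intervals that motivate
the default truth values. The knob is exposed and documented rather than
claimed to be field-accurate.

What the generator does **not** emulate: spatially explicit movement,
serial dependence between a covey's successive choice sets, measurement
error in the vegetation readings, and covey detection/availability
processes. Passing recovery tests therefore demonstrate correctness of the
estimator under its own assumptions, not robustness to these field
realities.

## Known limitations

* At the emulated study scale a covey–season group has ~4–6 choice sets
  informing 6 group-level coefficients. Many groups are perfectly separable
  (the within-group likelihood increases without bound along some
  coefficient ray), so group coefficients inherit the small-sample
  magnitude bias of conditional-logistic estimation, the population sd is
  pulled up, and population means for large effects overshoot truth by
  roughly 15–25% — the fall season, with fewer sets per group, more than
  winter. The package's recovery tests compute and expose exactly this:
  equal-tailed 85% intervals cover large-magnitude truths less often than
  nominal at that scale, while small effects are covered at or above
  nominal and non-hierarchical fits recover truth essentially unbiased.
  Users planning designs of this shape should expect magnitude inflation in
  covey-level hierarchies, or fit fewer random slopes per group.
* In the far tails of a selection curve the draw distribution of the
  relative probability is extremely skewed; the pointwise posterior *mean*
  curve can there lie outside the equal-tailed band (the median never
  does). Curves are therefore best read by their bands.
* Quadratic terms are supported (`model_spec(..., quadratic = )`) but off
  by default; at sparse study scales such models typically fail to
  converge, and non-convergence is reported rather than repaired.
* Curve uncertainty propagates population-mean draws only — these are
  population-level selection curves, not covey-specific predictions with
  sd-level uncertainty added.

## Problem sizes used by the shipped tests

The test suite exercises the estimator at the emulated study scale (67
coveys, 650 sets) with the reduced sampler configuration (4 chains x 5,000
iterations, burn-in 1,000, thin 5) across five replicate fits, the oracle
comparisons at 200 sets, and the landscape metrics on rasters up to 50 x 50
cells; the acceptance script mirrors these sizes. These are the package's
standard verification sizes; the full-length sampler configuration behaves
identically, only more precisely.
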