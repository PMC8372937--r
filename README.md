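# coveysel

Hierarchical Bayesian discrete-choice resource selection for grouped
wildlife telemetry data.

## The problem

In fall and winter, northern bobwhite (*Colinus virginianus*) live in social
groups — coveys — and a covey's choice of location reflects trade-offs among
vegetation structure, woody cover and landscape management. A standard way to
quantify this is a **used-versus-available discrete-choice design**: each time
a covey is located, the used location is paired with three available
locations sampled 50–400 m away, forming a *choice set*. Modelling the choice
within each set (rather than pooling used and available points globally)
controls for everything that varies between sets — time, place, availability —
and isolates the within-set covariate contrasts that actually drove
selection.

`coveysel` implements the full analysis pipeline for this design:
choice-set assembly and validation, landscape covariates from
vegetation-height rasters, covariate standardization and a
variance-inflation-factor (VIF) screen, a hierarchical Bayesian conditional
multinomial-logit estimator, convergence diagnostics, WAIC model comparison,
and relative-probability-of-selection curves. A synthetic-data generator
with complete truth records supports parameter-recovery testing of the whole
pipeline. It is aimed at quantitative wildlife ecologists analysing telemetry
data with paired availability samples.

## The model

The utility of alternative *j* in choice set *i* of covey *c* during season
*s* is linear in standardized covariates
(e.g. percent grass GS, visual obstruction VO, woody stem count SC,
proportion native grass NG, distance to tree TD, woody edge density WE):

    U_icj = β_1cs z_ij1 + … + β_Kcs z_ijK

and the probability that alternative *j* is chosen from the four offered is
the conditional-logit softmax

    P_i(j) = exp(U_icj) / Σ_k exp(U_ick).

Covey-level coefficients are drawn from season-specific population
distributions (the covey random effect):

    β_kcs ~ Normal(μ_ks, σ_ks²),

with vague Normal(0, sd 10) priors on each population mean μ (precision
0.01) and half-Normal(sd 5) priors on each population sd σ. Posteriors are
sampled with an adaptive Metropolis-within-Gibbs algorithm (conjugate Gibbs
draws for μ, random-walk updates for β and log σ, plus joint
translation/scale moves that decorrelate the hierarchy), by default 4 chains
of 100,000 iterations including a 10,000-iteration burn-in, thinned by 50.
Reported per parameter: posterior mean (PM), equal-tailed 85% credible
interval (CRI), the proportion of the posterior that is positive/negative,
and the Gelman–Rubin statistic (converged when < 1.1). Candidate models are
compared by WAIC; competitive models (ΔWAIC < 2) that are more complex than
a simpler competitive model sharing a term are flagged as uninformative.

## Worked example

Simulate a dataset with known truth (20 coveys, 200 choice sets; true
population means seeded from a reported fall/winter bobwhite analysis, e.g.
GS fall −3.77, VO winter 4.59), screen for collinearity, fit, and compare
against the null model:

```r
library(coveysel)

cfg <- generator_config(n_coveys = 20, n_sets = 200,
                        covariates = c("GS", "VO", "SC"),
                        mu = matrix(c(-3.77, 2.48, 2.67,
                                      -0.25, 4.59, 3.35), 3, 2),
                        seed = 42)
sim <- simulate_choice_data(cfg)

vif_screen(sim$data, c("GS", "VO", "SC"))
#> VIF screen (threshold 2.5):
#>    GS    VO    SC
#> 1.019 1.005 1.017
#> PASS - max VIF = 1.019

fit <- fit_dcm(sim$data, model_spec(c("GS", "VO", "SC")),
               mcmc_config(n_chains = 4, n_iterations = 5000,
                           burn_in = 1000, thin = 5, seed = 7))
summarize_posterior(fit)[1:6, ]
#>       parameter     PM lower upper prop_pos prop_neg support rhat
#> 1   mu[GS,fall] -3.744 -5.02 -2.61    0.000    1.000       - 1.00
#> 2   mu[VO,fall]  3.146  2.14  4.28    1.000    0.000       + 1.01
#> 3   mu[SC,fall]  3.417  2.11  4.97    1.000    0.000       + 1.00
#> 4 mu[GS,winter] -0.491 -1.15  0.17    0.133    0.867       - 1.00
#> 5 mu[VO,winter]  5.125  4.03  6.32    1.000    0.000       + 1.00
#> 6 mu[SC,winter]  3.430  2.43  4.52    1.000    0.000       + 1.00
```

The fall GS mean is recovered at −3.74 (truth −3.77) with an 85% CRI of
(−5.02, −2.61) and the posterior is entirely negative — coveys select
against grassy locations in fall. All Gelman–Rubin values are at 1.01 or
below. Model comparison and a selection curve:

```r
w1 <- compute_waic(fit)
w0 <- compute_waic(fit_dcm(sim$data, model_spec(character(0))))
rank_models(list(w1, w0), names = c("m1", "null"))
#>   model    terms    waic   dwaic competitive removed reason
#> 1    m1 GS+VO+SC 314.589   0.000        TRUE   FALSE
#> 2  null   (null) 554.518 239.929       FALSE   FALSE

plot(relative_probability_curve(fit, "VO", "winter"))
```

The generating model beats the null by ~240 WAIC units; the curve shows the
relative probability of selection rising with visual obstruction in winter,
passing exactly through 0.25 at the covariate mean (four identical
alternatives are chosen uniformly).

Landscape covariates from a vegetation-height raster (3.6 m resolution,
shrubs 0.7–3.5 m, trees 3.5–40 m):

```r
h <- read_ascii_grid("heights.asc", "height")
cov <- classify_heights(h)
landscape_covariates(cov, points, radius = 50)   # pct covers, WE, TD
```

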