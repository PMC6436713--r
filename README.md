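# spordinal

Bayesian hierarchical **sp**atial **ordinal** regression for facility-based
health surveys: a proportional-odds (cumulative logit) model for patients
nested in facilities nested in counties, with unstructured, intrinsic CAR,
and convolution (BYM-type) county random effects, estimated by
Metropolis-within-Gibbs MCMC and compared by DIC.

The package was built around a concrete use case: modeling whether
post-abortion care patients leave a facility with no contraceptive method,
a less effective method, or a highly effective method, where uptake
clusters within facilities and varies smoothly across a county map. The
original survey microdata are not publicly deposited, so the package ships
a first-class synthetic-data generator that reproduces the survey's
structure (47 counties on a connected adjacency graph, 281 facilities,
2,568 patients, three-level ordinal outcome, missing-as-category coding)
with recorded ground truth for simulation studies.

## The model

For patient $i$ in facility $j(i)$ and county $c(i)$:

$$\Pr(y_i = k) = \mathrm{logit}^{-1}(\kappa_k - \eta_i) -
                 \mathrm{logit}^{-1}(\kappa_{k-1} - \eta_i), \qquad
  \eta_i = x_i^\top \beta + f_{j(i)} + u_{c(i)} + \phi_{c(i)},$$

with ordered cutpoints $\kappa$ (no intercept — the cutpoints absorb it),
facility effects $f_j \sim N(0, 1/\tau_v)$, unstructured county effects
$u_c \sim N(0, 1/\tau_h)$, and an intrinsic CAR prior
$p(\phi \mid \tau_c) \propto \exp\{-\frac{\tau_c}{2}\sum_{c\sim c'}
(\phi_c - \phi_{c'})^2\}$ on the county adjacency graph. Reported effects
are odds ratios $e^{\beta}$ with equal-tailed credible intervals; county
surfaces are the odds multipliers $e^{u_c + \phi_c}$. Model choice uses
$\mathrm{DIC} = \bar D + p_D$, $p_D = \bar D - D(\hat\theta)$.

See `vignettes/spatial-ordinal-models.Rmd` for the full account of priors,
sampler design, identification of the intrinsic CAR, and the generator's
assumptions.

## Worked example

```r
library(spordinal)

# survey design weight: sampling fraction 0.1233, response rate 0.94
compute_sampling_weight(0.1233, 0.94)
#> [1] 8.627979

# simulate a survey-structured dataset with known truth
sc  <- simulation_config(n_counties = 12, n_facilities = 40,
                         n_patients = 1200, seed = 2)
adj <- generate_adjacency(12, "random-planar", seed = 2)
tr  <- make_truth(sc, adj)
sim <- generate_dataset(sc, tr, adj)
sim$dataset
#> Ordinal dataset: 1200 patients, 40 facilities, 12 counties, 3 outcome categories
#> Covariates: age_2, age_3, wanted_2, wanted_3, wanted_9, public_2,
#>   maternity_2, method_count, unmetneedfp
#> Outcome counts: 1:547  2:503  3:150

# fit the convolution model and summarize as odds ratios
fit <- run_mcmc(sim$dataset, adj, model_spec("convolution"),
                mcmc_config(n_draws = 500, burnin = 600, seed = 9))
summarize_draws(fit)[, c("parameter", "or_mean", "or_sd", "or_l95", "or_u95")]
#>      parameter or_mean or_sd or_l95 or_u95
#> 1        age_2   1.657 0.287  1.278  2.259
#> 2        age_3   1.806 0.314  1.342  2.400
#> ...

compute_dic(fit, sim$dataset)
#> DIC = 2207.7  (D_bar = 2174.1, D_at_mean = 2140.4, pD = 33.6)

# posterior county odds multipliers exp(u + phi) for mapping
head(export_county_effects(fit, adj), 2)
#>   county_id mean_multiplier median_multiplier lower upper
#> 1         1           1.050             1.037 0.880 1.298
#> 2         2           0.980             0.989 0.827 1.101
```

An odds ratio above 1 means higher odds of a more effective contraceptive
category; a county multiplier above 1 with an interval excluding 1 marks a
county with elevated uptake after adjusting for the covariates. Posterior
means at this size carry sds of roughly 0.1–0.2 on the log-odds scale, so
single-replicate estimates scatter around the generating values
accordingly (`tr$beta` holds the truth).

The full pipeline — weights, weighted descriptives, 85%-credibility
covariate screening with forced-in covariates, the
unstructured/structured/convolution model sequence, DIC comparison, and
county surfaces — runs from one config:

```r
res <- run_full_analysis(list(
  seed = 5,
  simulate = list(n_counties = 12, n_facilities = 40, n_patients = 1200),
  survey = list(ps = 0.1233, pr = 0.94),
  candidates = c("age", "wanted", "maternity", "method_count", "unmetneedfp"),
  forced = "public"))
```

A command-line wrapper (`inst/scripts/spordinal.R`) exposes `simulate`,
`fit` and `run-all` for shell use.

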