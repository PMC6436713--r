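---
title: "Hierarchical spatial ordinal models for facility-based contraceptive uptake"
author: "spordinal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical spatial ordinal models for facility-based contraceptive uptake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spordinal)
```

## The problem

Post-abortion care (PAC) programmes aim to provide every treated patient
with family-planning counseling and, ideally, a highly effective
contraceptive method (implant, IUCD or sterilization) before discharge.
Uptake is recorded on an ordinal scale — no method (1), a less effective
method (2), a highly effective method (3) — for patients who are nested in
health facilities, which in turn sit in counties. Facilities cluster
patients; counties cluster facilities; and neighbouring counties tend to
resemble each other because referral patterns, staffing, commodity supply
and social norms vary smoothly in space.

`spordinal` implements this analysis as a reusable package: a
proportional-odds (cumulative logit) likelihood with facility and county
random effects; unstructured, intrinsic conditional autoregressive (CAR),
and convolution (BYM-type) county-effect structures; a Metropolis-within-
Gibbs sampler; DIC model comparison; survey-weight handling for
descriptives; a covariate-screening and model-sequence workflow; and a
synthetic-data generator with recorded ground truth, because the original
facility survey microdata are not publicly deposited.

## The model

For patient $i$ in facility $j(i)$ and county $c(i)$, with outcome
$y_i \in \{1, \dots, K\}$ ($K = 3$ here, implemented for general $K \ge 2$):

$$\Pr(y_i = k) = \frac{1}{1+e^{-(\kappa_k - \eta_i)}} -
                 \frac{1}{1+e^{-(\kappa_{k-1} - \eta_i)}},$$

with $\kappa_0 = -\infty$, $\kappa_K = +\infty$ and increasing interior
cutpoints $\kappa_1 < \dots < \kappa_{K-1}$. The linear predictor is

$$\eta_i = x_i^\top\beta + f_{j(i)} + u_{c(i)} + \phi_{c(i)},$$

where $f_j \sim N(0, 1/\tau_v)$ are facility effects,
$u_c \sim N(0, 1/\tau_h)$ unstructured county effects, and $\phi$ carries
the intrinsic CAR prior
$p(\phi \mid \tau_c) \propto \exp\{-\tfrac{\tau_c}{2}
\sum_{c \sim c'} (\phi_c - \phi_{c'})^2\}$, the sum running over unordered
neighbour pairs of the county adjacency graph (equivalently
$-\tfrac{\tau_c}{2}\phi^\top L \phi$ with $L$ the graph Laplacian). The
`unstructured` structure uses $u$ only, `structured` uses $\phi$ only, and
`convolution` uses both. There is no intercept: the cutpoints absorb it,
which is also why the data loader rejects constant design columns.
Cutpoints are stored as a free first cutpoint and strictly positive
increments ($\kappa_1 = g_1$, $\kappa_2 = g_1 + g_2$), so ordering holds by
construction in every draw.

Priors follow the conventions of the original model code: coefficients get
mean-zero normal priors by block — patient characteristics ($b$, precision
$10^{-3}$) and the facility-binary ($s$), county-continuous ($q$) and mixed
($m$) blocks (precision $10^{-6}$); $g_1 \sim N(0, 1/0.01)$;
$g_2 \sim \mathrm{Gamma}(0.001, 0.001)$;
$\tau_h, \tau_c \sim \mathrm{Gamma}(0.5, 0.0005)$ and
$\tau_v \sim \mathrm{Gamma}(0.001, 0.001)$, all shape–rate. All of these
are overridable through `prior_spec()`.

### Identification of the intrinsic CAR

The intrinsic CAR is improper: it is flat along the constant vector (one
flat direction per connected component). Two standard fixes are used and
tested. In *simulation*, `sample_car_effects()` draws on the sum-to-zero
subspace through the spectral decomposition of $L$, giving a proper
distribution whose covariance is the generalized inverse of $\tau_c L$. In
*estimation*, $\phi$ is recentred to mean zero after every sweep, and the
Gibbs update for $\tau_c$ uses the rank-corrected shape increment
$(n - c)/2$, $c$ the number of connected components.

## The sampler

`run_mcmc()` is a Metropolis-within-Gibbs scheme:

* joint random-walk Metropolis per coefficient block, and for
  $(g_1, \log g_2)$ with the log-transform Jacobian;
* simultaneous coordinate-wise Metropolis for $f$ and for $u$. This is a
  valid product kernel because, conditionally on everything else, the
  target factorizes across facilities (and across counties for $u$): the
  priors are iid and each unit's likelihood block is disjoint;
* sequential single-site Metropolis for $\phi$ (the CAR prior couples
  neighbours, so these sites are visited one at a time with the local
  pairwise prior term), followed by exact recentring;
* conjugate Gamma Gibbs draws for $\tau_h$, $\tau_v$, $\tau_c$.

Proposal scales adapt toward a 30% acceptance rate (Robbins–Monro, window
of 50 iterations) during burn-in only, so the post-burn-in kernel is fixed
and the chain is a valid time-homogeneous MCMC over the retained draws.
`n_draws` is the retained sample size: the chain runs
`burnin + n_draws * thinning` iterations. One master seed drives
deterministically derived per-chain streams; identical seeds give
bit-identical draws.

Running with an empty (0-row) dataset suppresses the likelihood entirely,
so the chain targets the prior. The test suite uses this to verify the
sampler against the analytic priors (Kolmogorov–Smirnov distance on
coefficient and precision marginals). One caveat discovered there: the
facility precision's Gamma(0.001, 0.001) prior places roughly half of its
probability mass below the smallest positive double, so no floating-point
sample can represent its lower half and a KS check against it is
meaningless; its Gibbs conditional is instead verified analytically (it
reduces exactly to the prior when no information is present).

### DIC

`compute_dic()` reports $\bar D$ (posterior mean deviance),
$D(\hat\theta)$ (deviance at the posterior mean of *all* parameters,
random effects included — the focused, BUGS-style plug-in),
$p_D = \bar D - D(\hat\theta)$ and $\mathrm{DIC} = \bar D + p_D$. Both
components are stored so any other plug-in convention can be recovered.

## The synthetic-data generator

The generator stands in for a facility survey of 2,568 PAC patients in 281
facilities across 47 counties — the default dimensions of
`simulation_config()`. What it emulates:

* a connected county adjacency graph — `"random-planar"` (Gabriel graph of
  random points; planar, connected by construction, irregular like a
  county map) or `"lattice"` (near-square grid, rook neighbours);
* nesting — every county seeded with one facility and every facility with
  one patient, remaining units allocated by multinomial draws with
  configurable (default uniform) sizes; the survey gives no allocation
  rule, so uniform is the neutral choice;
* covariates at all three levels: patient-level categoricals (one with a
  distinct missing-as-category code 9 at a default rate of 10%, exercising
  the missing-category coding path), facility binaries, a standardized
  continuous facility measure, and a continuous county measure;
* outcomes drawn from the exact model probabilities at the stored latent
  $\eta$, which is returned for clustering diagnostics.

Ground-truth values are recorded in a `truth_record` for recovery studies.
Default generating values, chosen once as a realistic scenario: cutpoints
$(-0.19, 2.30)$, which reproduce the 45/46/9 percent marginal outcome mix
observed in the motivating survey at $\eta = 0$; coefficient magnitudes
between 0.2 and 0.8 in absolute value (odds ratios roughly 0.45–2);
county-unstructured sd 0.25 ($\tau_h = 16$), facility sd $\approx 0.3$
($\tau_v = 10$), and CAR precision $\tau_c = 8$ (marginal sd around 0.3 on
typical planar graphs). Area-level heterogeneity of this size — odds
multipliers mostly between 0.6 and 1.7 — is what BYM-type analyses of
service-uptake outcomes typically report; facility-level variation is set
somewhat larger than county variation, as in the motivating setting.

What the generator does *not* emulate: the joint distribution of the real
covariates (only their structure — levels, nesting, missing coding),
informative facility sampling, item nonresponse beyond the single
missing-category covariate, and any within-facility patient correlation
beyond the shared facility effect. Passing recovery tests therefore show
that the estimation machinery is correct under the assumed model, not that
the model is adequate for any particular real survey.

## Survey weights

The facility design weight is $sw = 1/(p_s \cdot p_r)$ — with the
motivating survey's printed sampling fraction $p_s = 0.1233$ and response
rate $p_r = 0.94$ this is $8.62798$ (printed there, truncated, as 8.6279).
`normalize_weights()` rescales weights to mean one over the analysis
sample, a single global rescaling that preserves all (including
within-stratum) weight ratios and is idempotent. Weighted descriptive
tables come from `weighted_tabulate()`. The MCMC likelihood is
deliberately unweighted, matching the original Bayesian model code;
weights enter modeling only as a descriptive diagnostic.

## The analysis workflow

`run_full_analysis()` chains the stages: data (load or simulate) →
weights → weighted descriptives → bivariate screening → model sequence →
DIC comparison → county surface, writing every artifact plus an MD5
manifest under one output directory; the same config and seed reproduce
identical checksums.

*Screening* (`screen_covariates()`) fits one bivariate model per candidate
using the unstructured county + facility structure and retains candidates
whose 85% equal-tailed credible interval for the odds ratio excludes 1 —
the interval-excludes-one rule is this package's operationalization of
"significant at 85% credibility" (on the OR scale; equivalent to the
coefficient interval excluding 0). Forced-in covariates (ownership, in the
motivating study) are retained regardless, labelled `"forced"`. By
construction a pure-noise covariate should pass in about 15% of
replicates; the test suite checks this calibration.

*The model sequence* (`fit_model_sequence()`) fits the unstructured,
structured and convolution structures on identical data and seed and
flags the lowest DIC. A caution from this package's own simulations: the
three structures can reproduce each other's county-effect patterns (iid
effects can fit a smooth field; a weak-precision CAR mimics iid effects),
so their DICs typically differ by only a few points and the DIC ranking
identifies the generating structure unreliably — an insensitivity worth
keeping in mind when reading any single DIC comparison between these
structures.

*County surfaces* (`export_county_effects()`) summarize
$\exp(u_c + \phi_c)$ per county — posterior mean, median and credible
interval. These are odds multipliers (the model is ordinal-logit), not
risk ratios, and are exported as CSV or GeoJSON (polygon geometry is
caller-supplied; no map data are bundled).

## Numerical choices and limitations

* Category probabilities are differences of logistic CDFs; probabilities
  are clamped at $10^{-300}$ before logs, so likelihoods stay finite.
* Tie-break on empty screening selections: the model sequence falls back
  to all covariates.
* Initialization: cutpoints from empirical cumulative outcome frequencies
  (clamped to [0.05, 0.95]); everything else from zero; precisions at 1.
* Problem sizes in the shipped tests are the package's own choices for a
  desk-scale simulation study: recovery runs use the survey's full
  dimensions with 5 replicates and 2,000 retained draws (thin 2, burn-in
  2,500); the structure-selection and screening-calibration studies use
  reduced dimensions (about 1,000 patients, 25 counties; 600 patients, 12
  counties) with matched, fixed seeds.
* Not implemented (out of scope by design): proper-CAR/Leroux priors,
  partial proportional odds, design-based (Rao–Scott) test statistics,
  quadrature ML estimation, and styled cartography.
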