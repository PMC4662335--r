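---
title: "Methods: hierarchical occupancy models for nested monitoring designs"
author: "nestocc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical occupancy models for nested monitoring designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Regional monitoring programs for pond-breeding amphibians (and many other
taxa) rarely sample a region at random.  Instead they use a nested design: a
handful of protected areas are enrolled, many wetlands are subsampled within
each area, and each wetland is visited several times per breeding season so
that imperfect detection can be separated from true absence.  Wetlands within
an area share managers, weather and habitat, so their occupancy dynamics are
dependent; treating them as independent overstates the effective sample size
and produces spuriously confident regional conclusions.

`nestocc` fits two hierarchical occupancy models designed for exactly this
structure, on detection-history tables with one row per
(area, wetland, year, visit):

* a **static trend model**, for estimating linear occupancy trends at the
  area and regional level, with an among-area random trend and a
  latitude-on-trend covariate; and
* a **dynamic model**, in which occupancy follows a two-state Markov chain
  governed by colonization and persistence probabilities that carry crossed
  area and year random effects.

## Detection model (shared by both)

The probability of detecting the species on visit $k$ to an occupied wetland
in area $i$, year $j$ is

$$\operatorname{logit}(p_{ijk}) = \alpha + \beta\,\mathrm{date}_{ijk} + \delta_{ij},
\qquad \delta_{ij} \sim \mathrm{Normal}(0, \sigma_p),$$

where the visit date (integer day-of-year, no scaling) is centered to mean 0
*within each area*, so the date effect absorbs only within-area variation in
survey timing, and $\delta_{ij}$ soaks up area-year differences (water
levels, observer crews).  $\delta_{ij}$ is defined only for sampled
area-years; elsewhere it has no likelihood contribution.  Detections are
conditionally independent Bernoulli draws given occupancy and $\delta_{ij}$.

## Model 1: occupancy trend

Occupancy in area $i$, year $j$ is

$$\operatorname{logit}(\psi_{ij}) = \alpha_i + (\beta_L L_i + \delta_i)\,Y_j,
\qquad \delta_i \sim \mathrm{Normal}(\mu, \sigma),$$

with $Y_j$ the year covariate centered to mean 0 over each area's *sampled*
years (so $\alpha_i$ is mid-study occupancy; the same centering is reused if
predictions are made into unsampled years), and $L_i$ latitude centered to
mean 0 across areas.  $\mu$ is the mean trend, $\sigma$ the among-area trend
spread, and $\beta_L$ the latitude-on-trend effect.  The area intercepts
$\alpha_i$ get independent Uniform(0, 1) priors on the probability scale (no
hyperprior — the stated prior list treats them as fixed effects).

The **non-nested variant** (`nested = FALSE`, and `nonnested_variant()` for
parameter objects) removes $\delta_i$, $\mu$ and $\sigma$, leaving a single
shared slope plus the latitude regression.  It treats every wetland as an
independent sample of the region and is fit only for comparison
(`compare_nesting()`): on data with genuine among-area variation it produces
a narrower interval for $\beta_L$ and more extreme evidence of a latitude
gradient — the signature of ignoring the nesting.  The detection random
effect is retained in both variants, so the comparison isolates the trend
nesting.

## Model 2: colonization and persistence

Only initial occupancy $\psi_{i1}$ (first *global* year; independent
Uniform(0, 1) per area, no hyperparameters) is estimated directly.
Thereafter

$$\operatorname{logit}(\phi_{ij}) = \alpha^\phi + \delta^\phi_i + \theta^\phi_j,
\qquad
\operatorname{logit}(\gamma_{ij}) = \alpha^\gamma + \delta^\gamma_i + \theta^\gamma_j,$$

with $\delta_i \sim \mathrm{Normal}(0, \sigma_\delta)$ and $\theta_j \sim
\mathrm{Normal}(0, \sigma_\theta)$, each transition parameter having its own
effect set (colonization is formulated the same way as persistence but
shares nothing with it).  Year effects are indexed by the transition's
origin year on the global calendar and are shared across areas even when an
area skipped that year — that sharing is what lets a sparsely sampled area
borrow strength from the rest of the network.

Derived quantities (`occupancy_by_area_year()`, `regional_occupancy()`):
$\psi_{i,j+1} = \psi_{ij}\phi_{ij} + (1-\psi_{ij})\gamma_{ij}$, computed per
posterior draw for *every* year of the global span.  For unsampled years
the chain simply runs forward without an emission, so estimates exist there
too, with credible intervals that widen as the gap since the last sample
grows (until they saturate at the width of the chain's stationary
distribution — a short one- or two-year hole costs little precision).  The
regional mean is the unweighted average of the area-level $\psi_{ij}$ per
draw, treating the enrolled areas as representative of the region's public
lands; `weights = "wetlands"` provides a wetland-count-weighted alternative
but is not the default inference target.

## Priors

As printed in the reference protocol: logit-scale intercepts
($\alpha_i$, detection $\alpha$, transition $\alpha$, $\operatorname{logit}\psi_{i1}$)
are Uniform(0, 1) on the probability scale (a logistic density on the logit
scale); slopes and hyper-means ($\beta$, $\beta_L$, $\mu$) are
Normal(0, sd = 100); random-effect SDs are Gamma(0.1, 0.1).  The SD prior
wording is ambiguous between the SD itself and the BUGS precision
convention; the package follows the literal reading and places
Gamma(0.1, 0.1) on the SD by default, with
`prior_convention = "precision"` switching to a Gamma(0.1, 0.1) prior on
$1/\sigma^2$ (change-of-variables Jacobians included).  "Normal(0, 100)" is
read as standard deviation 100.

## Likelihood: marginalizing the latent states

Rather than Gibbs-sampling the latent occupancy states (the usual BUGS
data-augmentation), both likelihoods integrate them out analytically:

* static: each wetland-year contributes the zero-inflated Bernoulli form
  $\log[\psi \prod_k p_k^{y_k}(1-p_k)^{1-y_k} + (1-\psi)\,I(\text{all } y_k = 0)]$;
* dynamic: each wetland contributes a two-state forward-algorithm pass over
  the global year span, with an all-ones emission for unobserved years and
  the transition matrix $[[1-\gamma, \gamma], [1-\phi, \phi]]$ between
  years.

The posterior is identical to the data-augmented formulation, mixing is
better (no latent-state/parameter coupling), and — the deciding argument —
the likelihood code can be verified against brute-force enumeration of every
latent configuration, which the test suite does to $10^{-10}$ in log space
for instances with up to $2^{10}$ configurations.

Because $\psi$, $\phi$, $\gamma$ and $p$ depend on the wetland only through
its area (and the visit date), wetlands with identical histories within an
area are collapsed to one weighted likelihood term before sampling.  This is
exact and makes the 14-area design (about 15,000 visit records) cheap to
iterate over.

## MCMC

`run_mcmc()` uses blocked adaptive random-walk Metropolis, one parameter at
a time, with each update recomputing only the cached likelihood slice it
can affect (an area's profiles, an area-year's records, or the full table
for global detection parameters).  Proposal scales adapt by Robbins–Monro
toward a target acceptance of 0.30 during burn-in and are frozen at
burn-in's end, so the post-burn-in chain is a valid time-homogeneous
Metropolis sampler.  Hyperparameters ($\mu$, all SDs) touch only their
prior terms and are nearly free to update.

Intercepts and their random-effect blocks are deliberately confounded
ridges ($\beta_L$ with the $\delta_i$, transition intercepts with
$\delta_i$/$\theta_j$, detection $\alpha$ with $\delta_{ij}$), which cripples
one-at-a-time proposals.  The sampler therefore adds *translation moves*:
shift the global parameter by $\varepsilon$ and counter-shift every effect
in its block so all linear predictors — hence the likelihood — are exactly
unchanged, accepting on the prior ratio alone.  These moves cost no
likelihood evaluations and restore healthy mixing along the ridges
(effective sizes for $\beta_L$ improve by more than an order of magnitude).

Defaults follow the reference protocol — 3 chains, 20,000 retained samples,
5,000 burn-in — and everything is overridable.  Initialization: logit
intercepts at 0 (the prior median), slopes and effects at 0, SDs at 0.5.
Per-chain seeds are fixed offsets from one master seed and all randomness
flows through R's RNG, so runs are bit-reproducible.  `fit_summary()`
reports means, SDs, the 2.5/25/50/75/97.5% quantiles, $P(>0)$, the classic
between/within-chain Gelman–Rubin $\widehat{R}$ (warning above 1.1, the
community default — the protocol names the diagnostic without a threshold)
and an effective sample size (Geyer initial-positive-sequence; reported as
an extra diagnostic with no pass/fail rule, since the protocol reports
none).  The fixed-effects dynamic variant is fit area by area (the areas
are independent given no hyperdistributions) and the chains are
column-bound with area-tagged names.

## Synthetic data

`simulate_static()` / `simulate_dynamic()` draw from exactly the generative
structure above, record every latent state and realized random effect in a
truth object, and emit observations only for sampled area-years (latent
occupancy is simulated for the whole global span, so unsampled-year
predictions can be checked against truth).  `table1_design()` reproduces the
motivating 14-area network: 11–111 wetlands per area, subsets of 2004–2013,
latitudes 39.0–45.1°N.  Two stand-ins are documented because the published
design summary does not pin them down: visit counts default to 3 per
area-year (the midpoint of the stated 2–4; overridable per area-year), and
visit dates are drawn uniformly in a configurable day-of-year window
(default 75–135, spring breeding), shared by all wetlands surveyed in the
same area-year visit — survey crews sweep an area's pools in a short window,
and the shared dates are also what makes the exact history-collapse
effective.  Missing visits are absent rows, never sentinel codes.

Default generator parameters are the package's reference conditions: trend
model $\mu = 0$, $\sigma = 0.15$, $\beta_L = 0.05$, detection intercept
$\operatorname{logit}(0.7)$, date slope $-0.02$/day, $\sigma_p = 0.5$;
dynamic model colonization mean 0.119 and persistence mean 0.896 (typical
wood-frog vernal-pool values, stationary occupancy
$\gamma/(\gamma + 1 - \phi) \approx 0.53$), area/year effect SDs 0.3,
$\psi_{i1} = 0.5$.  One RNG sub-stream per area (derived deterministically
from the master seed) keeps an area's draws stable under edits to the rest
of the design.

What the generator does *not* emulate: spatial autocorrelation among
wetlands beyond the shared random effects, observer heterogeneity,
hydroperiod or habitat covariates, and trend-dynamics coupling (the static
model's data are truly trend-generated, the dynamic model's truly
Markovian).  Passing recovery tests therefore demonstrate correctness of
the inference machinery under the models' own assumptions, not robustness
to their violation on field data.

## Cross-validation

`crossval()` implements k-fold (default 5) cross-validation with predictive
deviance, comparing the random-effects dynamic model against the per-area
fixed-effects model (no hyperdistributions anywhere: transition, initial
occupancy and detection parameters all independent per area, no area-year
detection effect).  Three choices the published description leaves open are
made explicit here and are switchable rather than claimed as "the"
original method:

* **Unit**: the wetland — an entire detection history is held out together.
  Predicting a new wetland from its area's parameters is the model's actual
  prediction task, and holding out whole histories prevents leakage through
  a wetland's own past.  Folds are stratified by area so every area appears
  in every training set (areas with fewer wetlands than folds are spread as
  evenly as possible, with a warning).
* **Holdout parameters**: held-out wetlands inherit the training posterior
  of their area's effects.  A never-seen area can only be predicted under
  the random-effects model, by drawing its effects from the fitted
  hyperdistribution.
* **Aggregation**: each history's predictive probability is the posterior
  average of its marginal likelihood on the *probability* scale (log of
  mean, not mean of log), i.e. the proper posterior-predictive density;
  deviance is $-2$ times the summed logs, and fold deviances add to the
  total by construction.

## Numerical choices

* Forward recursion renormalizes the two-component state vector whenever its
  sum drops below $10^{-12}$, accumulating the log; underflow is impossible
  for any realistic design.
* All logistic quantities go through `log1p`/`plogis(log.p = TRUE)`-style
  guarded forms; site likelihoods combine the occupied and empty branches
  by log-sum-exp.
* A detection in a site-year forces the empty branch to drop out exactly
  ($\psi = 0$ with a detection gives $-\infty$, as it must).
* Degenerate inputs: an area with a single sampled year gets a zero year
  covariate (warned); zero-row tables are valid (likelihood 0, the sampler
  reproduces the prior); ties in fold assignment are broken by the seeded
  permutation.

## Problem sizes used by the checks

The test suite runs the full protocol's structure at reduced chain lengths,
chosen as the smallest sizes at which the checks are stable: trend-model
recovery uses 20 replicate simulations of the 14-area design with 3 chains
of 4,000 retained draws after 1,000 burn-in (95% intervals for $\mu$,
$\sigma$, $\beta_L$ cover truth in ≥ 90% of parameter-replicate pairs);
dynamic recovery uses one full-design fit (3 × 2,500 + 500) within ±0.03 of
the realized mean transition probabilities and a 5-area × 20-wetland ×
6-year design within ±0.05; the nesting comparison uses 10 paired
replicates (and, for the $\sigma = 0$ agreement check, a high-information
design of 80 wetlands × 10 years × 4 visits per area, where the among-area
variance is actually resolvable — at the field design's scale the nested
interval legitimately stays wider even when the true $\sigma$ is 0, because
the $\sigma$ posterior cannot concentrate at zero); the cross-validation
comparison uses 10 replicates of a 6-area × 10-wetland × 5-year design with
effect SDs of 0.5.

## Known limitations

* The Gamma(0.1, 0.1) SD prior has infinite density at 0; with very few
  groups the $\sigma$ posterior is prior-sensitive near the origin (the
  funnel), and the sampler's one-at-a-time updates mix slowly if the data
  truly pin $\sigma$ at 0.
* No covariates on occupancy (trend model) or on $\phi$/$\gamma$; no
  multi-species or multi-state structure; no spatial correlation beyond the
  area blocking.
* The non-nested comparison and CV comparison are implemented for the
  purposes above, not as general model-selection machinery (no WAIC/LOO).
* Whether the regional mean should weight areas by wetland count is a
  genuine modeling choice; both are exposed, the unweighted mean is the
  default.
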