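# nestocc

Hierarchical Bayesian occupancy models for **nested monitoring designs**:
many wetlands subsampled within a few protected areas, repeat visits within
years, imperfect detection.  Built for analysts of regional amphibian (or
other pond-breeding species) monitoring networks who need trend and
turnover estimates at both the area and regional level without pretending
that wetlands inside the same protected area are independent samples of the
region.

## Models

Detection, shared by both models, for visit *k* to an occupied wetland in
area *i*, year *j*:

    logit(p_ijk) = α + β·date_ijk + δ_ij,   δ_ij ~ Normal(0, σ_p)

with the visit date centered per area.

**Static trend model** (`run_mcmc(..., model = "static")`):

    logit(ψ_ij) = α_i + (β_L·L_i + δ_i)·Y_j,   δ_i ~ Normal(μ, σ)

Y_j is the year covariate centered within each area's sampled years, L_i the
area's centered latitude; μ is the regional mean trend, σ the among-area
trend spread, β_L the latitude-on-trend effect.  A non-nested variant
(`nested = FALSE`) drops δ_i and treats every wetland as independent;
`compare_nesting()` fits both and shows how ignoring the nesting shrinks the
interval on β_L and overstates the evidence for a latitudinal gradient.

**Dynamic model** (`model = "dynamic"`): occupancy follows a two-state
Markov chain with initial occupancy ψ_i1 (Uniform(0,1) per area) and
transition probabilities

    logit(φ_ij) = α_φ + δ_i^φ + θ_j^φ     (persistence)
    logit(γ_ij) = α_γ + δ_i^γ + θ_j^γ     (colonization)

with crossed area and year random effects per parameter.  Derived annual
occupancy ψ_ij is produced for every year of the study span — including
years an area skipped — plus regional means and average transition
probabilities.  `crossval()` compares this random-effects model with
per-area fixed-effects fits by 5-fold predictive deviance, holding out
whole wetland histories stratified by area.

Latent occupancy states are marginalized out of both likelihoods
(zero-inflated Bernoulli; two-state forward algorithm), which lets the test
suite verify the likelihood code against exhaustive latent-state
enumeration.  Sampling is blocked adaptive random-walk Metropolis written in
C++, with likelihood-invariant translation moves along the
intercept/random-effect ridges; draws are bit-reproducible given a seed.

Priors follow the reference protocol: Uniform(0,1) on the probability scale
for intercepts, Normal(0, sd = 100) for slopes and hyper-means,
Gamma(0.1, 0.1) for random-effect SDs (on the SD as written by default;
`prior_convention = "precision"` for the BUGS convention).

## Worked example

The package ships the motivating 14-area design (11–111 wetlands per area,
subsets of 2004–2013) and a generator with known truth, so the whole
pipeline runs without any field data:

```r
library(nestocc)
design <- table1_design()                      # 14 areas, 605 wetlands

sim <- simulate_static(design, static_gen_params(), seed = 42)
fit <- run_mcmc(sim$detections, design, model = "static",
                chains = 3, iter = 4000, burnin = 1000, seed = 7)
fit_summary(fit, params = c("mu", "sigma", "beta_lat"))
#>   parameter  mean    q2.5 q97.5 rhat p_gt0
#> 1        mu 0.030 -0.0638  0.13    1  0.75
#> 2     sigma 0.159  0.0919  0.27    1  1.00
#> 3  beta_lat 0.057  0.0034  0.11    1  0.98
```

The generating truth was μ = 0, σ = 0.15, β_L = 0.05: the regional trend is
correctly found to be indistinguishable from zero (P(μ > 0) = 0.75), the
among-area spread and the latitude effect are recovered inside their 95%
intervals, and R-hat of 1 says the three chains agree.

```r
dyn  <- simulate_dynamic(design, dynamic_gen_params(), seed = 42)
dfit <- run_mcmc(dyn$detections, design, model = "dynamic",
                 chains = 3, iter = 2500, burnin = 500, seed = 7)
mean_transition_summary(dfit)
#>      parameter mean     sd q2.5 q97.5
#> 1 colonization 0.14 0.0102 0.12  0.16
#> 2  persistence 0.89 0.0093 0.87  0.91
head(regional_occupancy(dfit), 3)
#>   year mean q2.5  q50 q97.5
#> 1 2004 0.53 0.47 0.53  0.59
#> 2 2005 0.54 0.49 0.54  0.58
#> 3 2006 0.54 0.50 0.54  0.58
```

Colonization ≈ 0.14 and persistence ≈ 0.89 recover the generating means
(0.119 and 0.896 plus realized year/area noise): occupied pools almost
always stay occupied, empty ones are colonized rarely, and regional
occupancy sits near the implied stationary value γ/(γ+1−φ) ≈ 0.53.
`occupancy_by_area_year(dfit)` adds per-area trajectories with a `sampled`
flag for the interpolated years.

A thin command-line wrapper for batch use lives at `inst/cli/nestocc`
(subcommands `simulate`, `fit`, `crossval`).

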