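# anctrend

Bayesian hierarchical trend and projection models for antenatal-care (ANC)
coverage among adolescent mothers in low- and middle-income countries.

National household surveys (DHS, MICS) yield a handful of coverage estimates
per country scattered over 2000–2019, while programme targets are phrased
per country and year out to 2030. `anctrend` fits a three-level Gaussian
hierarchy to logit-transformed coverage of at least one (ANC1) or at least
four (ANC4) antenatal visits,

```
y ~ N(b0[k] + b1[k]·(year−2000) + b2[k]·SDI + b3[k]·HRH, τ²)
beta[country k] ~ N(beta[region j], σ_j²)    (per coefficient)
beta[region j]  ~ N(beta,           σ²)      (per coefficient)
beta ~ N(0, 10000),  σ_j, σ ~ Gamma(0.001, 0.001),  τ ~ Uniform(0, 1000)
```

so country estimates borrow strength within regions and globally, then
projects coverage with 95 % credible intervals to 2030 and computes the
equity summaries practitioners report: the slope index of inequality (SII)
across wealth quintiles, urban–rural gaps, 80 %-coverage target flags, and
annualized rates of change. A companion hierarchical logistic model
estimates individual-level determinants of ANC use as odds ratios with
credible intervals. Posterior sampling is a bespoke Metropolis-within-Gibbs
algorithm (compiled core) with collapsed updates designed for the
near-improper Gamma-on-sd priors; see the methods vignette
(`vignettes/anctrend-methods.Rmd`) for the model, sampler and design
decisions.

Because the real survey microdata are registration-gated, the package ships
a first-class synthetic-data generator (`anc_scenario()`,
`simulate_anc_data()`) that emulates the multi-country survey structure —
sparse noisy logit-scale survey points, rising SDI/HRH covariates, pro-rich
quintile gradients, urban/rural offsets, individual records with known
log-odds effects — and retains its ground truth for recovery testing.

## Worked example

```r
library(anctrend)

sim <- simulate_anc_data(anc_scenario(seed = 42))      # 4 regions x 5 countries
fit <- anc_trend(sim$observations, sim$covariates,
                 control = sampler_config(seed = 3))   # 10000 x 3 chains
summary(fit)
```

```
Hierarchical ANC coverage trend model (ANC1, ages 15-19, national stratum)
  100 observations; 20 countries in 4 regions; covariates: year + SDI + HRH
  sampler: 3 chains x 10000 iterations (burn-in 2000, thin 10) -> 2400 retained draws
  posterior mean global coefficients: intercept=0.81, year=0.119, sdi=-0.3, hrh=0.01

Posterior summaries (95% credible intervals):
                   mean     sd   lower   upper
beta[intercept]  0.8099 0.2090  0.4067  1.1870
beta[year]       0.1186 0.0159  0.0869  0.1500
beta[sdi]       -0.2997 0.0938 -0.4874 -0.1156
beta[hrh]        0.0100 0.0531 -0.0997  0.1079
tau              0.2482 0.0203  0.2110  0.2906

Gelman-Rubin: max point estimate 1.002 (upper 1.016) at sigma_region[R1,year]
```

`beta[year]` is the global per-year trend on the logit scale (here ≈ 0.12,
i.e. steadily rising coverage; within-country SDI moves almost in lockstep
with calendar year, so the year and SDI coefficients share the trend between
them — projections are unaffected). `tau` recovers the generator's 0.25
logit-scale survey noise. From the fit:

```r
proj  <- project_coverage(fit, years = 2000:2030)      # % coverage + CrIs
flag_threshold(proj, threshold = 80, target_year = 2030)
rate_of_change(proj, from = 2000, to = 2030)           # pp per year

qfit <- anc_trend(sim$strata, sim$covariates, stratum = "quintile",
                  control = sampler_config(seed = 4))
sii_table(project_coverage(qfit, years = c(2000, 2030), keep_draws = TRUE))
```

A typical run prints SII values around 25–30 percentage points (pro-rich) in
2000 shrinking towards 10 by 2030 as national coverage saturates — the
qualitative pattern the wealth-gradient generator encodes. The
individual-level model:

```r
ind  <- generate_individuals(sim$truth, anc_scenario(seed = 42), 20000)
dfit <- anc_determinants(ind, "anc4")
summarize_odds_ratios(dfit)   # OR table; richest-vs-poorest near the true 1.76
```

File-driven runs go through `run_pipeline("simulate" | "fit" | "project" |
"equity" | "determinants" | "diagnose", config)` with a YAML or list config;
a thin command-line wrapper is installed at `inst/cli/anc-pipeline`.

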