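---
title: "Hierarchical trend and projection modelling of antenatal-care coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical trend and projection modelling of antenatal-care coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anctrend)
```

## The problem

Coverage of antenatal care (ANC) among adolescent mothers in low- and
middle-income countries is observed only where and when a household survey
(DHS or MICS) was fielded: a country typically contributes a handful of
survey estimates scattered over 2000–2019, while policy questions are posed
about every country and every year up to 2030. `anctrend` estimates and
projects coverage of at least one (ANC1) and at least four (ANC4) antenatal
visits from such sparse series by borrowing strength across countries within
a region and across regions globally, and then derives the equity summaries
practitioners report: wealth-based inequality (slope index of inequality,
SII), urban–rural gaps, 80 %-coverage target flags and rates of change.

## The model

Let $y_{ijkl}$ be the logit of the survey coverage estimate from observation
$i$ in year $l$ for country $k$ in region $j$. The model is a three-level
Gaussian hierarchy on the logit scale:

$$
\begin{aligned}
y_{ijkl} &\sim \mathrm{N}(\hat y_{jkl},\ \tau^2),\\
\hat y_{jkl} &= \beta_{0,jk} + \beta_{1,jk}\,\mathrm{year}_l
  + \beta_{2,jk}\,\mathrm{SDI}_{kl} + \beta_{3,jk}\,\mathrm{HRH}_{kl},\\
\beta_{jk} &\sim \mathrm{N}(\beta_j,\ \sigma_j^2), \qquad
\beta_j \sim \mathrm{N}(\beta,\ \sigma^2), \qquad
\beta \sim \mathrm{N}(0,\ 10\,000),\\
\sigma_j,\ \sigma &\sim \mathrm{Gamma}(0.001,\ 0.001), \qquad
\tau \sim \mathrm{Uniform}(0,\ 1000),
\end{aligned}
$$

with a country-specific coefficient vector (intercept, per-year slope,
Socio-demographic Index effect, health-workforce-density effect), one
hierarchical standard deviation per coefficient at each level, and a single
homoscedastic observation noise sd $\tau$. Each indicator (ANC1/ANC4), age
group and stratum system is fitted independently.

Conventions the data do not fix, chosen once and documented here:

* **Year coding.** Year enters as calendar year minus 2000, unscaled, so the
  slope reads "per year on the logit scale".
* **Covariate scaling.** SDI and HRH are z-standardized with constants
  estimated from the fitting data and stored in the fit; projections for
  2020–2030 reuse them unchanged. This is numerically convenient and leaves
  the model's function space unchanged.
* **Gamma prior on standard deviations.** The Gamma(0.001, 0.001) prior is
  placed on the *standard deviations*, not the precisions, and is
  non-conjugate. It is extremely concentrated near zero (about 98 % of its
  mass lies below $10^{-6}$) with a heavy flat tail — effectively a
  spike-and-slab on each sd. Its support is truncated below at $10^{-9}$, a
  pure floating-point floor: sds below any data resolution are statistically
  indistinguishable, and untruncated draws underflow double precision.
* **Boundary proportions.** Survey proportions of exactly 0 or 1 (possible
  in small strata) are clamped at `eps = 1e-3` before the logit, keeping
  every outcome finite without discarding data. Countries with a single data
  point are flagged by `validate_dataset()` but retained.
* **Effective sample sizes.** An `ess` column is accepted and carried
  through, but the likelihood is homoscedastic and unweighted, matching the
  model displayed above.

### The wealth-quintile extension

For quintile-specific series the national predictor gains country-by-quintile
offsets on the intercept and the year slope,

$$\hat y_{jkl q} = \hat y_{jkl} + a_{kq} + b_{kq}\,\mathrm{year}_l,
\qquad a_{kq} \sim \mathrm{N}(0, \sigma_a^2),\quad
b_{kq} \sim \mathrm{N}(0, \sigma_b^2),$$

with separate shrinkage sds for the intercept and slope offsets, each under
the same Gamma sd prior. A single shared sd is tempting but wrong here: the
two families live on different scales (logit units versus logit per year),
and a shared scale under the spike-at-zero prior collapses to the smaller
one, crushing a genuine wealth gradient into observation noise — an effect
that is easy to reproduce on synthetic data with a known ±0.6-logit
gradient. The offsets are
identified by a sum-to-zero constraint across the five quintiles within each
country, enforced by a centering sweep: after each Gibbs update the
per-country offset means are transferred into the country intercept and year
slope (the linear predictor is unchanged by the sweep). This is the standard
hierarchical-recentering device; the chain then explores the identified,
sum-to-zero parameterization.

## Posterior computation

The sampler is a bespoke Metropolis-within-Gibbs algorithm (compiled core in
`src/sampler.cpp`), designed around two failure modes of naive conditional
updating under the spike-and-slab-like sd prior:

1. **Funnels.** When an sd approaches zero its child coefficients are pinned
   to their parent mean, and conditional updates cannot escape. Each
   hierarchical sd is therefore updated by a random-walk Metropolis step on
   the log scale (with the Jacobian correction) against the *marginal*
   likelihood in which both coefficient levels are integrated out
   analytically — everything is Gaussian, so the marginals reduce to
   $p \times p$ factorizations through a thin-QR/Woodbury identity that is
   cancellation-free and positive-semidefinite by construction.
2. **Cross-level coupling.** The location parameters are then redrawn in one
   exact blocked pass down the hierarchy: the global coefficient vector from
   its conditional with region and country coefficients integrated out, the
   region means with country coefficients integrated out, and finally the
   country vectors from their full conditionals. By the chain rule this
   triple is a single exact blocked Gibbs draw, so the levels never drag on
   each other.

Observation noise $\tau$ uses an ordinary log-scale random-walk Metropolis
step on its full conditional (it is well identified); the two quintile
shrinkage sds are updated against their marginal likelihood with the offsets
integrated out per country-quintile cell (the same anti-funnel device),
followed by an exact joint draw of each cell's offset pair.
Step sizes adapt toward 44 % acceptance (Robbins–Monro) during burn-in only
and are frozen afterwards, preserving detailed balance in retained draws.
Chains are initialized from per-country ordinary least squares (pooled where
a country has too few points), sds at 0.5, and $\tau$ at the pooled residual
sd. All randomness flows through R's RNG, so runs are reproducible from the
configured seed; each chain derives its own stream.

Default settings retain $(10\,000 - 2\,000)/10 = 800$ draws per chain across
3 chains. A pure-R reference implementation of a (differently blocked,
partially collapsed) sampler for the same posterior is kept internally; the
compiled sampler was validated against a closed-form conjugate posterior
(single country, fixed scales) and against long runs of the reference
sampler, whose posterior quantiles agree.

The individual-level determinant model — Bernoulli-logit outcome on the
standard dummy-coded household covariates with a country random intercept —
has no usable conjugacy, so every block is Metropolis: the fixed effects
move in one joint random-walk step shaped by the Cholesky factor of the
maximum-likelihood covariance (scaled $2.38/\sqrt{p}$, globally adapted),
country intercepts by scalar walks with their mean swept into the global
intercept, and the random-intercept sd on the log scale.

## Diagnostics and summaries

* **Gelman–Rubin.** Classic PSRF,
  $\sqrt{((n-1)/n\,W + B/n)/W}$, with the 97.5 % F-quantile correction for
  the upper limit. Identical chains give exactly $\sqrt{(n-1)/n}$; the
  statistic is deliberately not clamped at 1.
* **DIC.** $\mathrm{DIC} = \bar D + p_D$ with
  $p_D = \bar D - D(\bar\theta)$; validated against the closed-form
  effective-parameter count of a known-variance Normal mean model.
* **Credible intervals.** Equal-tailed 2.5/97.5 empirical percentiles with
  linear-interpolation quantiles (R type 7).
* **Projections.** Per retained draw, coverage
  $= 100\,\mathrm{logit}^{-1}(\hat y)$ for every country-year(-stratum),
  summarized by the mean, median, 95 % and 50 % intervals. Future SDI/HRH
  values come from per-country linear extrapolation clipped to valid ranges;
  observed years pass through unchanged.
* **SII.** Weighted least squares of quintile coverage on ridit scores
  (cumulative-share midpoints; 0.1, 0.3, …, 0.9 at equal shares); the SII is
  the fitted difference between rank 1 and rank 0, i.e. the slope, in
  percentage points, computed per posterior draw and summarized. Because the
  raw WLS slope can exceed 100 in magnitude for extreme patterns (e.g.
  coverages (0, 0, 0, 100, 100) give 150) while the index is defined on
  $[-100, 100]$, the returned value is clamped to that range. Shares are
  configurable; a logistic-scale SII variant is deliberately out of scope.
* **Rates of change.** Absolute annualized change in percentage points per
  year and the relative annualized rate
  $(p_{to}/p_{from})^{1/(to-from)} - 1$ (undefined at a zero baseline).
* **Sensitivity.** Two harness variants refit the model with (1) the SDI/HRH
  columns removed and (2) half-Cauchy(1) priors replacing the Gamma sd
  priors, comparing posterior-mean coverage per country-year over the full
  projection span and reporting the median absolute difference and DIC per
  variant.

## What the synthetic generator emulates — and what it does not

`anc_scenario()` defines the study conditions: by default 4 regions × 5
countries, 3–8 survey points per country over 2000–2019, Normal logit-scale
noise `obs_sd = 0.25` (roughly the sampling error of a survey estimate of a
mid-range proportion at an effective sample size of a few hundred), rising
logistic SDI trajectories inside [0, 1], linear-plus-noise HRH clipped at 0,
an ordered pro-rich quintile gradient (±0.6 logit between extreme
quintiles), urban/rural offsets of ±0.5 logit, and global coefficients
(intercept 0.2, year slope 0.06, SDI effect 1.0 per SDI unit, HRH effect
0.05) that move national coverage from roughly 55–70 % in 2000 to 85–95 % by
2030 — the magnitudes reported for ANC1 in multi-country compilations.
Individual-level records use log-odds effects taken from published
odds-ratio tables for ANC determinants (e.g. richest-vs-poorest 1.42 for
ANC1 and 1.76 for ANC4), uniform category frequencies and a 0.3-sd country
random intercept. A 54-country configuration (`n_regions = 6,
countries_per_region = 9`) reproduces the scale of the real multi-country
analyses and is used where identification at scale matters (the
covariate-exclusion sensitivity check).

The generator retains its ground truth (`anc_truth`), so recovery tests can
ask whether credible intervals cover the generating values. Three caveats
bound what passing tests demonstrate about real data. First, the generator
draws from the model family itself (plus raw-scale covariate coding, an
affine reparameterization), so recovery shows correctness of inference, not
robustness to survey-design artifacts, recall bias, or non-Normal
measurement error. Second, ANC1 and ANC4 outcomes are generated
independently by default, matching the two-independent-models assumption;
real nesting (four visits implies one) can be switched on with `nest_anc4`
but is off by default. Third, survey weights and cluster designs are not
simulated: the generator emulates already-weighted survey estimates.

## Problem sizes and numerical choices

Test and validation runs use deliberately modest problem sizes chosen as the
smallest that make the statistical property visible: the conjugate oracle
uses 5 000 retained draws (agreement within 3 Monte-Carlo standard errors);
slope recovery uses 10 replicates of the default 20-country scenario at
3 chains × 4 000 iterations (burn-in 1 000, thin 5); determinant recovery
uses 10 replicates of 20 000 individuals; the sensitivity check uses the
54-country scale where null covariate effects are well identified. Remaining
numerical conventions: Cholesky factorizations carry an escalating
scale-aware jitter for the transient near-singular precisions that arise
while a weakly identified sd explores the prior's heavy tail; ties in
quantiles follow R's default type-7 interpolation; degenerate SII inputs
(zero variance in ridit ranks) return 0.

## Known limitations

* The Gaussian logit-scale likelihood ignores the varying precision of
  survey estimates; an `ess`-weighted likelihood would be a natural
  extension but is deliberately not fitted.
* Quintile offsets shrink toward zero with a single shared sd; strongly
  asymmetric inequality patterns may be over-shrunk in sparse countries.
* Covariate futures are linear extrapolations; structural breaks after 2019
  are outside the model.
* The determinant model pools all countries with a random intercept only;
  survey-round effects and interactions are out of scope.
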