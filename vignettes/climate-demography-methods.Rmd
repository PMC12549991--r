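---
title: "Models and methods: climate effects on sage-grouse demography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: climate effects on sage-grouse demography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`grousepop` implements the two modelling frameworks used to relate greater
sage-grouse (*Centrocercus urophasianus*) demography to climate and landcover
variation: a hierarchical state-space model of lek-count population growth,
and logistic-exposure models of daily survival for three reproductive life
stages (nests, broods, and adults/yearlings during the Mar–Aug reproductive
season). Both are fitted by MCMC with JAGS through `rjags`. This vignette
documents the models, their assumptions, the tunable parameters, the
synthetic-data generator used to verify them, and the numerical and design
choices that were genuinely open.

## The population state-space model

Annual maximum male counts $y_{i,t}$ at lek $i$ in year $t$ index local
abundance. The latent process is a stochastic Gompertz model on the log
scale:

$$\log N_{i,t+1} = \log N_{i,t} + r_{i,t}, \qquad
  r_{i,t} \sim \mathrm{Normal}(\mu_{r_{i,t}}, \sigma^2_{r_i}),$$

with Poisson observation $y_{i,t} \sim \mathrm{Poisson}(N_{i,t})$ and drift

$$\mu_{r_{i,t}} = \alpha_R + X'_{i,t}\beta_R + \theta_R \log N_{i,t},$$

where $R$ indexes the region containing lek $i$. Region intercepts and
coefficients are exchangeable draws from range-wide hypermeans,
$\alpha_R \sim \mathrm{Normal}(\mu, \sigma^2)$ and
$\beta_{k,R} \sim \mathrm{Normal}(\mu_{\beta_k}, \sigma^2_{\beta_k})$, so
reporting can focus on the grand means while regional imbalance in lek
numbers is absorbed by the hierarchy.

Assumptions worth stating plainly: counts are unbiased indices of abundance
(no trend in detection or lek attendance); observation error is Poisson on
the natural scale with the continuous latent $N$ as its rate; missing counts
contribute no observation term but the latent state is still propagated; and
density dependence is Gompertz, i.e. linear in *log* abundance.

**Density-dependence form.** Whether the density term multiplies
$\log N$ or $N$, and whether the log abundance is centred, are genuinely
open choices. The default is $\theta_R \log N_{i,t}$ — the standard Gompertz
state-space form, acting on the abundance at the start of the transition
$t \to t+1$ (the prior year relative to the resulting count). A centred
variant (`density = "gompertz_centered"`), which decorrelates $\alpha_R$ and
$\theta_R$, and a density-independent variant (`density = "none"`) are
available.

**Priors.** Hypermeans and $\theta_R$ get vague Normal(0, sd 5) priors; all
standard deviations get half-Normal(0, 1); the latent initial state is
anchored weakly at the first observed count,
$\log N_{i,1} \sim \mathrm{Normal}(\log(y_{i,\text{first}}+1), 1)$,
which avoids improper starts at zero counts. These are documented stand-ins
chosen to be vague on the scale of log growth rates (which rarely exceed
$\pm 0.5$ in this system).

**Sampling.** The JAGS program parameterizes the latent path by the states
$\log N_{i,t}$ rather than the increments $r_{i,t}$. The two are equivalent
in distribution, but the state parameterization gives each node local graph
dependencies only, which is substantially faster and mixes better. A fit
refuses to `summary()` quietly when any top-level R-hat is $\ge 1.1$ (draws
are still returned). Note that $\alpha_R$ and $\theta_R$ are strongly
negatively correlated a posteriori (the classic Gompertz ridge), so these
parameters need the longest chains.

**Derived quantities.** The finite rate of change is $\lambda = e^r$;
`derive_lambda()` summarizes it per lek, region, or globally, and converts a
coefficient $b$ on the growth-rate scale into the marginal percent change in
$\lambda$ per unit covariate change, $100(e^b - 1)$.

## Logistic-exposure survival models

Each life-stage dataset is a set of exposure intervals: a unit (nest, brood,
or individual) enters an interval of $t$ days and either survives it
($y = 1$) or fails during it ($y = 0$, terminating its history). Daily
survival is inverse-logit of a linear predictor in standardized covariates,
and interval survival compounds it:

$$\mathrm{DSR}_i = \mathrm{logit}^{-1}(\beta_0 + \beta_1 x_1 + \dots),
  \qquad S_i = \mathrm{DSR}_i^{t_i}, \qquad y_i \sim \mathrm{Bernoulli}(S_i).$$

This makes unequal revisit intervals innocuous: a $t$-day interval is
exactly equivalent to $t$ unit intervals with the same covariates (a tested
likelihood identity). Stage horizons for cumulative survival are 38 days
(nest incubation), 50 days (brood-rearing), and 167 days (the day-75 to
day-242 reproductive season for adults). Brood interval success means at
least one chick alive — chick-level survival is not modelled. Covariates for
broods and adults describe the window preceding each observed location.

All non-intercept coefficients receive a Laplace (double-exponential)
shrinkage prior with density $\propto \exp(-\Lambda|\beta|)$, with
$\Lambda \sim \mathrm{Uniform}(0.01, 10)$ unless pinned. The intercept gets
Normal(0, sd 5). Indicator covariates (sex, hen age, transmitter type,
translocation status) stay 0/1; everything else is z-scored with the
centre/scale pair stored for prediction. Derived daily survival is reported
at the reference point — standardized covariates at 0, indicators at their
reference level — which is consistent with the inverse-logit of the
intercept; the cumulative value is computed per posterior draw so the
identity $S = \mathrm{DSR}^{\text{horizon}}$ holds draw-wise, not merely for
summary statistics. There are no site/year random effects by default:
hierarchical structure is carried by the shrinkage prior, matching the
fixed-effects-plus-$\Lambda$ reporting convention.

**Numerical guard.** The linear predictor is clipped to $\pm 35$ before
inverse-logit. At double precision this changes nothing beyond $10^{-15}$;
it only prevents overflow in pathological inputs.

## Covariate engineering

Landscape covariates are summarized in circular moving windows around a
focal location (`moving_window_mean()`: mean of cells whose centres fall
within the radius; edge cells are excluded from both numerator and
denominator rather than padded). Candidate radii are 2.5, 5 and 10 km for
population analyses and 75, 167, 260, 370, 439 and 1451 m for life-stage
analyses, reflecting generalized movement distances; 1439 m is accepted as
an alias of the largest radius, which appears under both printed values in
the source materials. Proximity to features (wetlands, mesic areas) uses
exponential distance decay $e^{-d/\alpha}$ with $\alpha$ drawn from the same
life-stage set. Coarse (4 km) climate grids are sampled at the focal
location with no moving window — they are not scale-dependent.

Climate series are aggregated over named lag windows. For a response in
year $t$ (the spring count), "previous" windows resolve as: previous
calendar year = 14 Mar $t{-}1$ to 14 Mar $t$; water year = 1 Oct $t{-}2$ to
30 Sep $t{-}1$; growing season (1 Apr–31 Oct), spring, summer and fall are
those seasons of $t{-}1$; winter = 1 Dec $t{-}1$ through end of February of
$t$. The exact calendar mapping of lag labels to years is not uniquely
determined by the source descriptions; this mapping, which spans lags of
0–1.5 years consistent with prior-year moisture driving current-year
abundance, is fixed here and surfaced in configuration. Two deliberate
conventions: the winter window ends 29 Feb in leap years (no data loss,
despite the conventional "28 Feb" label), and survival-model concurrent
windows ("current month", "previous month", Mar–May spring) resolve on the
interval's midpoint date, since start-vs-midpoint is unstated in the field
protocols. Precipitation aggregates default to the mean of monthly totals
for comparability across unequal windows; a cumulative-sum mode exists
because per-cm effect statements imply totals.

All covariates are z-scored (sample SD, $n-1$); the transformation is
idempotent and the stored centre/scale pair is reused verbatim for
prediction inputs.

## Two-stage variable and scale selection

The published selection procedure is described only in outline, so the
reconstruction here is explicit and configurable:

1. **Grouping.** Candidates are partitioned by the connected components of
   the graph joining pairs with $|r| \ge 0.65$. Transitivity is intentional:
   if A–B and B–C are strongly correlated, all three are assessed together
   even when A–C is not.
2. **Screening.** Each group is fitted one at a time under the shrinkage
   prior with all scale variants of its members as alternative columns. Per
   candidate, the scale with maximal probability of direction (pd) wins,
   ties broken toward the smaller (more local) scale for determinism;
   candidates with pd $\ge 0.80$ are retained. A candidate whose
   coefficient sign flips between the group fit and a solo fit is flagged
   confounded and dropped — the analogue of omitting covariates confounded
   with the rest of the candidate set.
3. **Final fit.** Retained covariates enter a joint fit with independent
   Laplace priors, rate $\Lambda \sim \mathrm{Uniform}(0.01, 10)$.

The 0.65/0.80/(0.01, 10) constants are defaults consistent with reported
$\Lambda$ posteriors spanning roughly 4–10 (suggesting an upper prior bound
near 10); each is a `run_config()` knob. Under an all-null truth, the
expected per-covariate retention rate at pd $\ge 0.80$ is roughly 0.4 — the
screen is deliberately permissive, with stage 2's shrinkage doing the final
regularization.

## The synthetic-data generator

Because the real lek database and telemetry data are not redistributable,
every input the pipeline consumes is simulated by `gen_lek_counts()` and
`gen_encounter_histories()` at a known truth (`sim_truth()`), and
correctness is demonstrated by parameter recovery rather than by
reproducing field estimates. Defaults mirror the study's shape at desk
scale: 3 regions × 60 leks × 20 years, three standardized covariates, and
300 nests / 200 broods / 400 adults. Generative values are chosen to be
biologically realistic: $\mu_\alpha = 0.5$ with $\theta = -0.1$ puts the
Gompertz equilibrium at $e^5 \approx 148$ males per lek; process SD 0.15 on
log growth gives interannual count fluctuations of the size seen in lek
series; stage intercepts sit at the logit of daily survivals 0.969 / 0.989 /
0.9982, i.e. cumulative stage survivals near 0.31, 0.57 and 0.75; covariate
effects of 0.10–0.15 per SD are moderate, detectable but not dominant.
Nests are revisited every 4 days; brood and adult intervals are uniform on
1–14 days, echoing telemetry revisit variability; adult histories span days
of year 75–242.

What the generator deliberately does **not** emulate: spatial structure in
covariates or rasters (covariates are exchangeable standardized draws), lek
attendance and detection processes beyond Poisson error, nest-fate
misclassification, left truncation of nests found after initiation, and
chick-level detection. Passing recovery tests therefore demonstrates that
the estimation machinery is correct for the stated generative model — not
that the model is adequate for any particular field dataset.

The closed-form limits used as checks: with no noise the latent state
converges to $\log N^* = -\alpha/\theta$; with noise, writing
$\log N_{t+1} = \alpha + (1+\theta)\log N_t + \varepsilon$, the stationary
SD of $\log N$ is $\sigma_r / \sqrt{1 - (1+\theta)^2}$.

## Diagnostics and reporting

Posterior summaries follow the standard table format: mean, SD, 2.5th, 50th
and 97.5th draw percentiles, R-hat, and pd. Conventions:

- **R-hat** is the classic non-split potential scale reduction factor
  (between/within chain variances), with a split-chain option for detecting
  within-chain drift; it is undefined (reported `NA`) when the within-chain
  variance is zero. The in-package implementation is cross-checked against
  `coda::gelman.diag` in the tests.
- **pd** is defined relative to the sign of the posterior *median* (the
  primary convention); a mean-referenced variant exists because summary
  tables sometimes define it against the mean — the two differ only for
  heavily skewed posteriors.
- **Credible intervals** are equal-tailed with linear-interpolation
  (type 7) quantiles, for bit-stable results. Evidence categories: "strong"
  when the 95% CRI excludes 0, "moderate" when it overlaps 0 but
  pd > 0.85.
- **Bayesian p-values** compare a discrepancy between observed and
  replicated data across posterior draws: chi-square for Poisson counts,
  Bernoulli deviance for exposure intervals. Values near 0 or 1 imply lack
  of fit; on self-simulated data the statistic stays comfortably inside
  (0.05, 0.95).

## Problem sizes and sampler settings

Two sampler profiles exist. The `"paper"` profile preserves the full-scale
settings (50,000 iterations, 25,000 burn-in, thin 10; the selection-stage
population model doubles these). The `"desk"` profile, used throughout the
tests and the acceptance script, runs 2 chains with a few thousand
iterations — e.g. 3,000 kept after 1,500 burn-in (thin 3) for the
state-space model and roughly half that for exposure models — which is
sufficient for R-hat < 1.1 on the default simulated-study sizes and keeps a
full recovery experiment (5 replicates of each model class) in the
minutes range. Recovery experiments exclude and count any replicate with a
top-level R-hat $\ge 1.1$.

## Known limitations

- Regions are abstract labels; no spatial autocorrelation between leks.
- The Poisson observation model cannot absorb attendance-driven
  overdispersion; posterior-predictive p-values are the guard.
- The selection procedure is a documented reconstruction, not a published
  algorithm; its constants are configurable and logged.
- $\alpha_R$/$\theta_R$ posterior correlation makes the density-dependence
  strength the slowest-mixing quantity; use the centred variant or longer
  chains when it matters.
- Exposure models assume covariates constant within an interval and exact
  fate dates at interval ends.
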