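# grousepop

Hierarchical Bayesian models of greater sage-grouse (*Centrocercus
urophasianus*) demography and its relationship to climate and landcover
variation, for population ecologists working with lek-count time series and
telemetry-based encounter histories.

The package implements two modelling frameworks and the machinery around
them:

**Population state-space model.** Annual maximum male counts $y_{i,t}$ at
lek $i$ index abundance through a Poisson observation model,
$y_{i,t} \sim \mathrm{Poisson}(N_{i,t})$, while latent log-abundance follows
a stochastic Gompertz process,

$$\log N_{i,t+1} = \log N_{i,t} + r_{i,t}, \quad
  r_{i,t} \sim \mathrm{Normal}\!\left(\alpha_R + X'_{i,t}\beta_R +
  \theta_R \log N_{i,t},\ \sigma^2_{r_i}\right),$$

with region-varying intercepts and covariate effects drawn from range-wide
hypermeans ($\beta_{k,R} \sim \mathrm{Normal}(\mu_{\beta_k},
\sigma^2_{\beta_k})$, $\alpha_R \sim \mathrm{Normal}(\mu, \sigma^2)$) and a
Gompertz density-dependence coefficient $\theta_R < 0$ for regulated
dynamics. The finite rate of change is $\lambda = e^r$.

**Logistic-exposure survival models.** Nest, brood and adult daily survival
are modelled from exposure intervals of $t$ days:

$$\mathrm{DSR}_i = \mathrm{logit}^{-1}(\beta_0 + \beta_1 x_1 + \cdots),
  \quad S_i = \mathrm{DSR}_i^{t_i}, \quad y_i \sim \mathrm{Bernoulli}(S_i),$$

with Laplace (double-exponential) shrinkage priors of rate $\Lambda$ on all
covariate effects, and cumulative survival reported at the stage horizon
(38-day nests, 50-day broods, 167-day adult reproductive season).

Around these sit lag-window climate covariate engineering (water year,
growing season, seasonal windows; circular moving-window means; exponential
distance decay), two-stage Bayesian variable and scale selection,
convergence and posterior-predictive diagnostics (R-hat, probability of
direction, Bayesian p-values), and a forward simulator that generates every
input with known ground truth so each stage is verifiable by parameter
recovery. MCMC runs in JAGS via `rjags`.

## Worked example

Simulate a desk-scale study (3 regions × 60 leks × 20 years with three
standardized covariates; 10% of counts missing), fit the state-space model,
and summarize growth-rate effects:

```r
library(grousepop)

truth <- sim_truth(seed = 1)                       # known generative truth
sim <- gen_lek_counts(truth, seed = 1, missing_frac = 0.1)

cfg <- run_config(iterations = 3000, burn_in = 1500, thin = 3, chains = 2,
                  adapt = 500, seed = 1)
fit <- fit_ssm(build_ssm(sim$series, sim$design,
                         density = "gompertz_centered", config = cfg))
fit
#> Lek-count state-space model fit
#>   60 leks, 20 years, 3 regions, 3 covariates (density: gompertz_centered)
#>   converged: TRUE  (max R-hat 1.024)

subset(summary(fit), grepl("^mu_|^theta", parameter))
#>     parameter     mean     sd    q2.5       q50   q97.5 rhat    pd
#> 13   mu_alpha -0.00133 0.0380 -0.0708  4.06e-07  0.0686    1 0.500
#> 14 mu_beta_x1  0.16222 0.1288 -0.0870  1.60e-01  0.4365    1 0.941
#> 15 mu_beta_x2 -0.07062 0.0557 -0.1598 -7.08e-02  0.0127    1 0.970
#> 16 mu_beta_x3  0.07597 0.1257 -0.1583  7.57e-02  0.3495    1 0.869
#> 21   theta[1] -0.08693 0.0143 -0.1164 -8.71e-02 -0.0583    1 1.000
#> 22   theta[2] -0.14511 0.0154 -0.1750 -1.45e-01 -0.1153    1 1.000
#> 23   theta[3] -0.05849 0.0156 -0.0920 -5.71e-02 -0.0302    1 1.000
```

The covariate hypermeans recover their generating values (0.15, −0.10,
0.05), and every $\theta_R$ is credibly negative — the simulated populations
are density-regulated. In the centred parameterization `mu_alpha` is the
mean log growth rate at average abundance, which is ~0 for a stationary
population. Growth-rate summaries convert to the λ scale:

```r
lam <- derive_lambda(fit, scope = "global")
lam$lambda
#>    scope  mean   q2.5   q50 q97.5
#> 1 global 0.998 0.9959 0.998     1
round(lam$percent_effects, 2)
#>    x1    x2    x3
#> 17.61 -6.82  7.89
```

i.e. the population is on average stationary ($\hat\lambda \approx 1$), and
one SD of covariate `x1` raises λ by about 18% (truth: $100(e^{0.15}-1) =
16.2\%$). A nest-survival model from simulated encounter histories:

```r
nests <- gen_encounter_histories(truth, "nest", seed = 1)
nest_fit <- fit_stage_model(build_stage_model("nest", nests,
                                              main = c("x1", "x2"),
                                              config = run_config(
                                                iterations = 1500, burn_in = 700,
                                                thin = 2, chains = 2,
                                                adapt = 300, seed = 1)))
summary(nest_fit)
#>     parameter     mean      sd    q2.5      q50 q97.5  rhat    pd
#> 1 (Intercept)  3.47534 0.07291  3.3441  3.47264 3.627 0.999 1.000
#> 2          x1  0.21237 0.07530  0.0649  0.21266 0.363 1.000 0.999
#> 3          x2 -0.00953 0.06235 -0.1339 -0.00664 0.120 1.000 0.554
#> 4      Lambda  6.27310 2.33402  1.7406  6.41936 9.821 1.001 1.000
#> 5         DSR  0.96991 0.00211  0.9659  0.96990 0.974    NA    NA
#> 6         S38  0.31417 0.02608  0.2677  0.31305 0.369    NA    NA

bayesian_pvalue(nest_fit, seed = 1, max_draws = 300)
#> [1] 0.4166667
```

The reference daily survival rate (`DSR`, the inverse logit of the
intercept) is 0.970 and 38-day cumulative nest survival (`S38 = DSR^38`,
held as a per-draw identity) is 0.314, against a generating truth of 0.969
and 0.308; the Bayesian p-value near 0.5 indicates no lack of fit, as
expected for self-simulated data.

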