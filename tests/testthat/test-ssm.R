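# 2-lek, 3-year toy with 2 regions and one covariate, used for the
# log-posterior oracle
toy_ssm <- function(density = "gompertz_logN") {
  series <- data.frame(
    lek_id = rep(c("L1", "L2"), each = 3),
    region_id = rep(c("R1", "R2"), each = 3),
    year = rep(2001:2003, 2),
    count = c(10L, 12L, NA, 40L, 35L, 38L))
  design <- data.frame(
    lek_id = rep(c("L1", "L2"), each = 2),
    year = rep(2002:2003, 2),
    x1 = c(0.5, -0.2, 1.0, 0.3))
  build_ssm(validate_lek_series(series), design, density = density)
}

toy_state <- function() {
  list(logN = matrix(c(2.3, 2.4, 2.5, 3.7, 3.6, 3.65), 2, 3, byrow = TRUE),
       alpha = c(0.4, 0.5), theta = c(-0.1, -0.12),
       beta = matrix(c(0.2, 0.15), 2, 1),
       sigma_r = c(0.2, 0.25),
       mu_alpha = 0.45, sigma_alpha = 0.1,
       mu_beta = 0.18, sigma_beta = 0.05)
}

test_that("SSM log-posterior equals a term-by-term hand-summed oracle", {
  m <- toy_ssm()
  st <- toy_state()
  # independent oracle: write out every density term explicitly
  X <- c(L1_2002 = 0.5, L1_2003 = -0.2, L2_2002 = 1.0, L2_2003 = 0.3)
  lp <- 0
  # initial conditions anchored at log(first observed count + 1)
  lp <- lp + dnorm(2.3, log(10 + 1), 1, log = TRUE)
  lp <- lp + dnorm(3.7, log(40 + 1), 1, log = TRUE)
  # process terms: r = diff(logN), mean alpha_R + beta_R x + theta_R logN_t
  lp <- lp + dnorm(2.4 - 2.3, 0.4 + 0.2 * X[["L1_2002"]] + (-0.1) * 2.3, 0.2, log = TRUE)
  lp <- lp + dnorm(2.5 - 2.4, 0.4 + 0.2 * X[["L1_2003"]] + (-0.1) * 2.4, 0.2, log = TRUE)
  lp <- lp + dnorm(3.6 - 3.7, 0.5 + 0.15 * X[["L2_2002"]] + (-0.12) * 3.7, 0.25, log = TRUE)
  lp <- lp + dnorm(3.65 - 3.6, 0.5 + 0.15 * X[["L2_2003"]] + (-0.12) * 3.6, 0.25, log = TRUE)
  # Poisson observations (missing count contributes nothing)
  lp <- lp + dpois(10, exp(2.3), log = TRUE) + dpois(12, exp(2.4), log = TRUE)
  lp <- lp + dpois(40, exp(3.7), log = TRUE) + dpois(35, exp(3.6), log = TRUE) +
    dpois(38, exp(3.65), log = TRUE)
  # priors
  lp <- lp + sum(log(2) + dnorm(c(0.2, 0.25), 0, 1, log = TRUE))   # half-normal sigma_r
  lp <- lp + sum(dnorm(c(0.4, 0.5), 0.45, 0.1, log = TRUE))        # alpha_R | hyper
  lp <- lp + dnorm(0.45, 0, 5, log = TRUE)                         # mu_alpha
  lp <- lp + log(2) + dnorm(0.1, 0, 1, log = TRUE)                 # sigma_alpha
  lp <- lp + sum(dnorm(c(0.2, 0.15), 0.18, 0.05, log = TRUE))      # beta_R | hyper
  lp <- lp + dnorm(0.18, 0, 5, log = TRUE)                         # mu_beta
  lp <- lp + log(2) + dnorm(0.05, 0, 1, log = TRUE)                # sigma_beta
  lp <- lp + sum(dnorm(c(-0.1, -0.12), 0, 5, log = TRUE))          # theta_R
  expect_equal(m$logpost(st), as.numeric(lp), tolerance = 1e-10)
})

test_that("with zero covariates the drift reduces to the region intercept", {
  series <- validate_lek_series(data.frame(
    lek_id = rep(c("L1", "L2"), each = 3),
    region_id = rep(c("R1", "R2"), each = 3),
    year = rep(2001:2003, 2),
    count = c(10L, 12L, NA, 40L, 35L, 38L)))
  design0 <- data.frame(lek_id = rep(c("L1", "L2"), each = 2),
                        year = rep(2002:2003, 2), x1 = 0)
  m <- build_ssm(series, design0)
  st1 <- toy_state()
  st2 <- st1
  st2$beta <- matrix(c(0.9, -0.4), 2, 1)
  # beta no longer enters the likelihood: logpost differs only by the prior
  prior_diff <- sum(dnorm(st2$beta, st2$mu_beta, st2$sigma_beta, log = TRUE)) -
    sum(dnorm(st1$beta, st1$mu_beta, st1$sigma_beta, log = TRUE))
  expect_equal(m$logpost(st2) - m$logpost(st1), prior_diff, tolerance = 1e-10)
})

test_that("log-posterior is invariant to permuting data rows", {
  m1 <- toy_ssm()
  series2 <- data.frame(
    lek_id = c("L2", "L1", "L2", "L1", "L2"),
    region_id = c("R2", "R1", "R2", "R1", "R2"),
    year = c(2003, 2001, 2001, 2002, 2002),
    count = c(38L, 10L, 40L, 12L, 35L))
  design2 <- data.frame(
    lek_id = c("L2", "L1", "L2", "L1"),
    year = c(2003, 2002, 2002, 2003),
    x1 = c(0.3, 0.5, 1.0, -0.2))
  m2 <- build_ssm(validate_lek_series(series2), design2)
  st <- toy_state()
  expect_equal(m2$logpost(st), m1$logpost(st), tolerance = 1e-12)
})

test_that("model construction validates covariate completeness and regions", {
  series <- validate_lek_series(data.frame(
    lek_id = rep("L1", 3), region_id = "R1", year = 2001:2003,
    count = c(5L, 6L, 7L)))
  design <- data.frame(lek_id = "L1", year = 2002, x1 = 0.1)  # 2003 missing
  expect_error(suppressWarnings(build_ssm(series, design)), "no covariate row")
  expect_warning(build_ssm(series, NULL), "single region")
  expect_error(build_ssm(series[series$year < 2003, ], NULL), "3 years")
})

test_that("density-independent fit recovers the mean log-count difference", {
  # with theta = 0 and no covariates the model is a random walk with drift:
  # on dense data the posterior of alpha tracks the mean observed log diff
  tr <- suppressWarnings(sim_truth(n_regions = 1, n_leks = 15, n_years = 15,
                                   n_covs = 0, mu_alpha = 0.08, sigma_alpha = 0,
                                   theta = 0, process_sd = 0.05))
  sim <- gen_lek_counts(tr, seed = 41, init_logn = rep(5, 15))
  suppressWarnings(m <- build_ssm(sim$series, NULL, density = "none",
                                  config = fast_config(41)))
  fit <- fit_ssm(m)
  y <- matrix(sim$series$count, nrow = 15, byrow = TRUE)
  empirical <- mean(diff(t(log(y))))
  a <- fit$summary[fit$summary$parameter == "alpha[1]", ]
  expect_lt(abs(a$mean - empirical), 0.03)
})

test_that("posterior predictive counts match observed means on simulated data", {
  tr <- sim_truth(n_covs = 0, n_leks = 20, n_years = 12)
  sim <- gen_lek_counts(tr, seed = 42)
  m <- build_ssm(sim$series, NULL, config = fast_config(42))
  fit <- fit_ssm(m)
  obs_mean <- mean(sim$series$count, na.rm = TRUE)
  post_mean <- mean(exp(fit$logN))
  expect_equal(post_mean, obs_mean, tolerance = 0.1)
  expect_s3_class(fit, "lek_ssm_fit")
  expect_output(print(fit), "state-space")
})

test_that("lambda derivations: identity at r = 0 and percent effects", {
  fake <- list(
    logN = array(3, dim = c(50, 4, 6)),   # constant latent state -> r = 0
    model = list(regions = c("R1", "R2"), region_index = c(1, 1, 2, 2),
                 leks = paste0("L", 1:4)),
    draws = list())
  class(fake) <- "lek_ssm_fit"
  lam <- derive_lambda(fake, "global")
  expect_equal(lam$lambda$mean, 1)
  expect_equal(lam$lambda$q2.5, 1)
  lam_r <- derive_lambda(fake, "region")
  expect_equal(nrow(lam_r$lambda), 2)
  # a growth-rate coefficient of 0.00608 is a 0.61% increase in lambda
  expect_equal(percent_lambda_effect(0.00608), 0.61, tolerance = 1e-2)
})
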