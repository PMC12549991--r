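test_that("inverse logit reproduces the printed daily survival rates", {
  expect_equal(inv_logit(0), 0.5)
  # stage intercepts -> derived DSRs
  expect_equal(inv_logit(3.460), 0.96953, tolerance = 1e-5)
  expect_lt(abs(inv_logit(3.460) - 0.969), 6e-4)
  expect_lt(abs(inv_logit(4.470) - 0.989), 1e-3)
  expect_equal(inv_logit(6.350), 0.99826, tolerance = 1e-5)
  expect_lt(abs(inv_logit(6.350) - 0.9982), 1e-3)
  # monotone, stabilized at extremes
  expect_true(all(diff(inv_logit(seq(-50, 50, 1))) >= 0))
  expect_true(inv_logit(1e6) < 1 && inv_logit(-1e6) > 0)
})

test_that("interval survival is the product of daily survivals", {
  expect_equal(interval_survival(0.87, 1), 0.87)
  expect_equal(interval_survival(0.9, 3), 0.9 * 0.9 * 0.9)
  # brood-style week: repeated-multiplication oracle
  prod7 <- Reduce(`*`, rep(0.9, 7))
  expect_equal(interval_survival(0.9, 7), prod7)
  expect_equal(interval_survival(0.9, 7), 0.4783, tolerance = 1e-4)
  # cumulative stage survivals implied by the printed DSRs
  expect_lt(abs(interval_survival(0.96953, 38) - 0.308), 1e-3)
  expect_error(interval_survival(1.2, 3), "dsr")
  expect_warning(s <- interval_survival(0.9, 0), "trivially 1")
  expect_equal(s, 1)
})

test_that("exposure log-likelihood matches hand-computed single intervals", {
  b0 <- qlogis(0.9)
  X <- matrix(1, 1, 1)
  expect_equal(exposure_loglik(b0, X, t = 3, y = 1), log(0.729))
  expect_equal(exposure_loglik(b0, X, t = 3, y = 0), log(1 - 0.729))
  expect_error(exposure_loglik(c(1, 2), X, t = 3, y = 1), "match")
})

test_that("exposure log-likelihood is additive over intervals and equals the oracle", {
  set.seed(21)
  for (i in 1:25) {
    k <- sample(1:4, 1)
    n <- sample(1:8, 1)
    beta <- c(rnorm(1, 3, 1), rnorm(k - 1, 0, 0.5))
    X <- cbind(1, matrix(rnorm(n * (k - 1)), n, k - 1))
    t <- sample(1:14, n, replace = TRUE)
    y <- rbinom(n, 1, 0.8)
    expect_equal(exposure_loglik(beta, X, t, y), loglik_oracle(beta, X, t, y),
                 tolerance = 1e-12)
    # additivity over the rows
    per_row <- sapply(seq_len(n), function(j) {
      exposure_loglik(beta, X[j, , drop = FALSE], t[j], y[j])
    })
    expect_equal(sum(per_row), exposure_loglik(beta, X, t, y), tolerance = 1e-12)
  }
})

test_that("a t-day interval equals t unit intervals with identical covariates", {
  set.seed(22)
  beta <- c(3.2, 0.4, -0.3)
  x <- rnorm(2)
  X1 <- matrix(c(1, x), 1, 3)
  t <- 9L
  # survived interval: identical likelihood either way
  Xt <- X1[rep(1, t), , drop = FALSE]
  expect_equal(exposure_loglik(beta, X1, t, 1),
               exposure_loglik(beta, Xt, rep(1L, t), rep(1L, t)),
               tolerance = 1e-12)
})

test_that("increasing a coefficient with a positive covariate raises DSR", {
  x <- 0.7
  dsr <- function(b1) inv_logit(3.0 + b1 * x)
  b <- seq(-1, 1, 0.1)
  expect_true(all(diff(sapply(b, dsr)) > 0))
})

test_that("stage design matrices have the reported coefficient counts", {
  set.seed(23)
  n <- 120
  mk <- function(nms) {
    df <- data.frame(unit_id = sprintf("U%03d", seq_len(n)), site_id = "S1",
                     interval_start_doy = 100L, interval_end_doy = 104L,
                     exposure_days = 4L, outcome = 1L)
    for (v in nms) df[[v]] <- rnorm(n)
    df
  }
  # nest: 7 covariates, no interactions -> 8 coefficients incl. intercept
  nest_covs <- c("day_of_season", "sagebrush", "annual_forb_grass",
                 "bare_ground", "non_sage_shrub", "topo_roughness", "vpd")
  mn <- build_stage_model("nest", validate_encounter_histories(mk(nest_covs), "nest"),
                          main = nest_covs)
  expect_equal(length(mn$coef_names), 8)

  # brood: 13 mains + 5 interactions -> 19 coefficients
  brood_covs <- c("sagebrush", "non_sage_shrub", "bare_ground", "tree",
                  "topo_roughness", "aspect", "wetland_prox", "tmin",
                  "spi_mm", "spi_sn", "day_of_season", "hen_age", "brood_age")
  brood_int <- list(c("sagebrush", "brood_age"), c("bare_ground", "brood_age"),
                    c("wetland_prox", "brood_age"), c("tmin", "brood_age"),
                    c("spi_sn", "day_of_season"))
  mb <- build_stage_model("brood", validate_encounter_histories(mk(brood_covs), "brood"),
                          main = brood_covs, interactions = brood_int,
                          indicators = "hen_age")
  expect_equal(length(mb$coef_names), 19)

  # adult: 12 mains + 1 interaction -> 14 coefficients
  adult_covs <- c("non_sage_shrub", "perennial_forb_grass", "bare_ground",
                  "tree", "topo_position", "mesic_prox", "wet_meadow_prox",
                  "vpd", "swe", "spei_ngs", "day_of_season", "sex")
  df <- mk(adult_covs); df$interval_start_doy <- 100L; df$interval_end_doy <- 104L
  ma <- build_stage_model("adult", validate_encounter_histories(df, "adult"),
                          main = adult_covs,
                          interactions = list(c("spei_ngs", "day_of_season")),
                          indicators = "sex")
  expect_equal(length(ma$coef_names), 14)
  expect_equal(ma$horizon, 167)
  expect_equal(mn$horizon, 38)
  expect_equal(mb$horizon, 50)

  expect_error(build_stage_model("nest", validate_encounter_histories(mk("a"), "nest"),
                                 main = "a", interactions = list(c("a", "b"))),
               "absent")
})

test_that("short MCMC fit recovers exposure coefficients on simulated nests", {
  tr <- sim_truth()
  h <- gen_encounter_histories(tr, "nest", n_units = 250, seed = 31)
  cfg <- fast_config(seed = 31)
  fit <- fit_stage_model(build_stage_model("nest", h, main = c("x1", "x2"),
                                           config = cfg))
  expect_true(fit$converged)
  s <- fit$summary
  truth <- c(`(Intercept)` = tr$exposure$nest$beta0, x1 = 0.15, x2 = -0.10)
  for (p in names(truth)) {
    row <- s[s$parameter == p, ]
    expect_lt(abs(row$mean - truth[[p]]), 2.5 * row$sd)
  }
  # per-draw identity: cumulative survival is DSR^horizon exactly
  expect_equal(fit$cum_draws, fit$dsr_draws^38, tolerance = 1e-15)
  # derived rows present with the stage horizon
  expect_true(all(c("DSR", "S38", "Lambda") %in% s$parameter))
  # coef/predict methods
  expect_equal(names(coef(fit)), c("(Intercept)", "x1", "x2"))
  pr <- predict(fit, data.frame(x1 = c(0, 2)))
  expect_gt(pr$dsr[2], pr$dsr[1])   # positive coefficient, larger covariate
})
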