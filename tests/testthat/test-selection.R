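test_that("correlation grouping forms transitive components", {
  trip <- correlated_triplet()   # cor(A,B)=.9, cor(B,C)=.7, cor(A,C)=.63
  g <- group_covariates(trip, threshold = 0.65)
  # A-C edge is below threshold, but B links them: one group by transitivity
  expect_equal(length(g), 1)
  expect_setequal(g[[1]], c("A", "B", "C"))
  # at a higher threshold the weak B-C edge drops out
  g2 <- group_covariates(trip, threshold = 0.8)
  expect_equal(sort(sapply(g2, paste, collapse = "")), sort(c("AB", "C")))
})

test_that("independent columns form singletons; near-1 threshold always does", {
  set.seed(51)
  d <- as.data.frame(matrix(rnorm(500 * 3), 500, 3))
  names(d) <- c("u", "v", "w")
  expect_equal(lengths(group_covariates(d, 0.65)), c(1, 1, 1))
  trip <- correlated_triplet()
  expect_equal(lengths(group_covariates(trip, 0.999)), c(1, 1, 1))
})

test_that("grouping is a partition invariant to column order", {
  trip <- correlated_triplet()
  d <- cbind(trip, D = rnorm(nrow(trip)))
  g1 <- group_covariates(d, 0.65)
  g2 <- group_covariates(d[, c("D", "C", "A", "B")], 0.65)
  canon <- function(g) sort(sapply(g, function(x) paste(sort(x), collapse = "+")))
  expect_equal(canon(g1), canon(g2))
  expect_setequal(unlist(g1), names(d))        # exhaustive
  expect_equal(anyDuplicated(unlist(g1)), 0)   # disjoint
  d$E <- 1
  expect_error(group_covariates(d, 0.65), "constant column 'E'")
})

# stub fitter: returns pinned pd/mean tables so the selection logic can be
# checked without MCMC
stub_fit <- function(table) {
  function(cols) table[table$parameter %in% cols, , drop = FALSE]
}

test_that("stage-1 screening selects the max-pd scale, ties toward smaller", {
  set.seed(52)
  n <- 80
  h <- data.frame(unit_id = sprintf("U%02d", 1:n), site_id = "S1",
                  interval_start_doy = 100L, interval_end_doy = 104L,
                  exposure_days = 4L, outcome = 1L,
                  ppt_75 = rnorm(n), ppt_370 = rnorm(n), vpd = rnorm(n))
  h <- validate_encounter_histories(h, "nest")
  tab <- data.frame(parameter = c("ppt_75", "ppt_370", "vpd"),
                    mean = c(0.1, 0.3, -0.2), pd = c(0.7, 0.95, 0.95))
  rep <- screen_stage1(h, list(ppt = c("ppt_75", "ppt_370"), vpd = "vpd"),
                       config = run_config(), fit_fun = stub_fit(tab))
  expect_equal(rep$scores$chosen[rep$scores$candidate == "ppt"], "ppt_370")
  expect_true(all(rep$scores$retained))
  expect_equal(unname(rep$retained), c("ppt_370", "vpd"))
  # tie in pd -> the smaller (earlier-listed) scale wins
  tab2 <- tab; tab2$pd <- c(0.95, 0.95, 0.95)
  rep2 <- screen_stage1(h, list(ppt = c("ppt_75", "ppt_370"), vpd = "vpd"),
                        config = run_config(), fit_fun = stub_fit(tab2))
  expect_equal(rep2$scores$chosen[rep2$scores$candidate == "ppt"], "ppt_75")
  # below the screening threshold the candidate is dropped
  tab3 <- tab; tab3$pd <- c(0.6, 0.7, 0.95)
  rep3 <- screen_stage1(h, list(ppt = c("ppt_75", "ppt_370"), vpd = "vpd"),
                        config = run_config(), fit_fun = stub_fit(tab3))
  expect_false(rep3$scores$retained[rep3$scores$candidate == "ppt"])
  expect_equal(names(rep3$retained), "vpd")
})

test_that("single candidate with single scale passes through with its pd", {
  h <- validate_encounter_histories(
    data.frame(unit_id = c("U1", "U2", "U3"), site_id = "S1",
               interval_start_doy = 100L, interval_end_doy = 104L,
               exposure_days = 4L, outcome = 1L,
               vpd = c(0.2, -0.4, 0.1)), "nest")
  tab <- data.frame(parameter = "vpd", mean = -0.3, pd = 0.88)
  rep <- screen_stage1(h, list(vpd = "vpd"), config = run_config(),
                       fit_fun = stub_fit(tab))
  expect_equal(rep$scores$pd, 0.88)
  expect_equal(unname(rep$retained), "vpd")
})

test_that("sign instability between group and solo fits flags confounding", {
  trip <- correlated_triplet(n = 80)
  h <- data.frame(unit_id = sprintf("U%02d", 1:80), site_id = "S1",
                  interval_start_doy = 100L, interval_end_doy = 104L,
                  exposure_days = 4L, outcome = 1L,
                  A = trip$A, B = trip$B, C = trip$C)
  h <- validate_encounter_histories(h, "nest")
  # A flips sign when fitted alongside its group
  fit_fun <- function(cols) {
    if (length(cols) == 1L && cols == "A") {
      data.frame(parameter = "A", mean = -0.2, pd = 0.9)
    } else {
      data.frame(parameter = c("A", "B", "C"), mean = c(0.3, 0.4, 0.1),
                 pd = c(0.9, 0.95, 0.85))
    }
  }
  rep <- screen_stage1(h, list(A = "A", B = "B", C = "C"),
                       config = run_config(), fit_fun = fit_fun)
  expect_true(rep$scores$confounded[rep$scores$candidate == "A"])
  expect_false(rep$scores$retained[rep$scores$candidate == "A"])
  expect_false("A" %in% names(rep$retained))
})

test_that("larger shrinkage rates pull null coefficients toward zero", {
  tr <- sim_truth()
  tr$exposure$nest$beta <- c(x1 = 0.3, x2 = 0, x3 = 0, x4 = 0)
  h <- gen_encounter_histories(tr, "nest", n_units = 150, seed = 53)
  cfg <- fast_config(seed = 53, iterations = 800, burn_in = 400, thin = 1)
  fits <- lapply(c(0.5, 8), function(lam) {
    fit_stage_model(build_stage_model("nest", h, main = paste0("x", 1:4),
                                      lambda_fixed = lam, config = cfg))
  })
  null_mean <- function(f) {
    s <- f$summary
    mean(abs(s$mean[s$parameter %in% c("x2", "x3", "x4")]))
  }
  expect_lt(null_mean(fits[[2]]), null_mean(fits[[1]]))
})

test_that("stage-2 fit estimates Lambda inside its prior support", {
  tr <- sim_truth()
  h <- gen_encounter_histories(tr, "nest", n_units = 150, seed = 54)
  cfg <- fast_config(seed = 54, iterations = 800, burn_in = 400, thin = 1)
  out <- fit_stage2(c(x1 = "x1", x2 = "x2"), h, stage = "nest", config = cfg)
  lam <- out$fit$summary[out$fit$summary$parameter == "Lambda", ]
  expect_gt(lam$q2.5, cfg$shrink_lower)
  expect_lt(lam$q97.5, cfg$shrink_upper)
  expect_error(fit_stage2(character(0), h), "empty")
})
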