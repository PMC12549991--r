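#' Ground-truth parameter set for forward simulation
#'
#' Bundles every generative parameter of the simulated study: the state-space
#' process (region intercepts, covariate coefficients, Gompertz
#' density-dependence terms, per-lek process SDs, hypermeans/hyper-SDs) and
#' the per-stage logistic-exposure coefficients. Defaults mirror the study's
#' shape at desk scale: 3 regions, 60 leks, 20 years, 3 standardized
#' covariates; stage intercepts placed at the logit of realistic daily
#' survival rates (nest 0.969, brood 0.989, adult 0.9982). With
#' `alpha = 0.5` and `theta = -0.1` the Gompertz equilibrium abundance is
#' `exp(5) ~ 148` males per lek, a realistic large-lek count.
#'
#' @param n_regions Number of regions.
#' @param n_leks Total number of leks (assigned to regions in equal blocks).
#' @param n_years Number of count years.
#' @param n_covs Number of lek-level covariates.
#' @param mu_alpha,sigma_alpha Hypermean and hyper-SD of region intercepts.
#' @param mu_beta,sigma_beta Hypermeans (length `n_covs`) and common hyper-SD
#'   of region coefficients.
#' @param theta Gompertz density-dependence coefficient (one per region or a
#'   scalar; must be negative for stationary dynamics, flagged otherwise).
#' @param process_sd Per-lek process SD (scalar or length `n_leks`).
#' @param corr Covariate correlation matrix (default identity).
#' @param seed Seed used to realize region-level parameters.
#' @return A list of class `sim_truth`.
#' @export
sim_truth <- function(n_regions = 3, n_leks = 60, n_years = 20, n_covs = 3,
                      mu_alpha = 0.5, sigma_alpha = 0.05,
                      mu_beta = c(0.15, -0.10, 0.05)[seq_len(n_covs)],
                      sigma_beta = 0.05,
                      theta = -0.1, process_sd = 0.15,
                      corr = diag(n_covs), seed = 1) {
  stopifnot(length(mu_beta) == n_covs)
  if (any(theta >= 0)) {
    warning("theta >= 0: simulated dynamics are non-stationary")
  }
  check_correlation(corr)
  set.seed(seed)
  alpha_R <- stats::rnorm(n_regions, mu_alpha, sigma_alpha)
  beta_R <- matrix(stats::rnorm(n_regions * n_covs, rep(mu_beta, each = n_regions),
                                sigma_beta),
                   n_regions, n_covs)
  truth <- list(
    ssm = list(n_regions = n_regions, n_leks = n_leks, n_years = n_years,
               n_covs = n_covs, alpha_R = alpha_R, beta_R = beta_R,
               theta_R = rep(theta, length.out = n_regions),
               process_sd = rep(process_sd, length.out = n_leks),
               mu_alpha = mu_alpha, sigma_alpha = sigma_alpha,
               mu_beta = mu_beta, sigma_beta = rep(sigma_beta, n_covs)),
    exposure = list(
      nest = list(beta0 = stats::qlogis(0.969), beta = c(x1 = 0.15, x2 = -0.10),
                  interactions = list(), n_units = 300, horizon = 38L),
      brood = list(beta0 = stats::qlogis(0.989), beta = c(x1 = 0.15, x2 = -0.10),
                   interactions = list(), n_units = 200, horizon = 50L),
      adult = list(beta0 = stats::qlogis(0.9982), beta = c(x1 = 0.10, x2 = -0.10),
                   interactions = list(), n_units = 400, horizon = 167L)),
    corr = corr, seed = seed)
  class(truth) <- "sim_truth"
  truth
}

check_correlation <- function(corr) {
  corr <- as.matrix(corr)
  if (nrow(corr) == 0L) return(invisible(corr))
  if (!isSymmetric(unname(corr)) || any(abs(diag(corr) - 1) > 1e-8)) {
    stop("corr must be a symmetric correlation matrix with unit diagonal")
  }
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) stop("corr must be positive definite")
  invisible(corr)
}

#' Generate standardized correlated covariates
#'
#' Multivariate-normal draws with the requested correlation structure, then
#' column z-scored; empirical correlations approach `corr` as `n_units` grows.
#'
#' @param n_units Number of rows.
#' @param n_covs Number of columns.
#' @param corr Correlation matrix (positive definite).
#' @param seed Integer seed.
#' @return A data.frame of standardized covariates `x1..xk`.
#' @export
gen_covariates <- function(n_units, n_covs, corr = diag(n_covs), seed = 1) {
  check_correlation(corr)
  set.seed(seed)
  Z <- MASS::mvrnorm(n_units, mu = rep(0, n_covs), Sigma = corr)
  Z <- matrix(Z, n_units, n_covs)
  Z <- apply(Z, 2L, function(x) as.numeric(standardize(x)))
  df <- as.data.frame(Z)
  names(df) <- paste0("x", seq_len(n_covs))
  df
}

#' Forward-simulate region-structured lek-count series
#'
#' Runs the state-space process forward: latent log abundance follows
#' `log N[i, t+1] = log N[i, t] + r[i, t]` with drift
#' `alpha_R + X' beta_R + theta_R log N[i, t]` and per-lek process noise, and
#' observed counts are Poisson draws from the latent abundance. Initial log
#' abundances are drawn around the Gompertz equilibrium. An optional
#' missingness mask blanks a fraction of counts afterwards (never an entire
#' lek).
#'
#' @param truth A [sim_truth()].
#' @param seed Integer seed.
#' @param missing_frac Fraction of lek-years with the count masked to `NA`.
#' @param init_logn Optional length-`n_leks` initial log abundances; default
#'   draws `Normal(equilibrium, 0.3)`.
#' @return A list: `series` (a `lek_series` data.frame), `design` (covariate
#'   table aligned to response years), `latent` (true `logN` and `r`
#'   matrices), and `truth`.
#' @export
gen_lek_counts <- function(truth, seed = 1, missing_frac = 0, init_logn = NULL) {
  s <- truth$ssm
  nl <- s$n_leks; ny <- s$n_years; K <- s$n_covs
  if (ny < 3L) stop("n_years must be >= 3")
  region <- rep(seq_len(s$n_regions), length.out = nl)
  region <- sort(region)
  set.seed(seed)
  X <- array(stats::rnorm(nl * (ny - 1L) * K), dim = c(nl, ny - 1L, K))
  if (K > 1L && any(truth$corr[upper.tri(truth$corr)] != 0)) {
    L <- chol(truth$corr)
    flat <- matrix(X, ncol = K)
    X <- array(flat %*% L, dim = dim(X))
  }
  if (is.null(init_logn)) {
    eq <- -s$alpha_R[region] / ifelse(s$theta_R[region] == 0, NA, s$theta_R[region])
    eq[is.na(eq)] <- log(100)
    init_logn <- stats::rnorm(nl, eq, 0.3)
  }
  logN <- matrix(NA_real_, nl, ny)
  r <- matrix(NA_real_, nl, ny - 1L)
  logN[, 1L] <- init_logn
  for (t in seq_len(ny - 1L)) {
    drift <- s$alpha_R[region] + s$theta_R[region] * logN[, t]
    if (K > 0L) {
      for (k in seq_len(K)) drift <- drift + X[, t, k] * s$beta_R[region, k]
    }
    r[, t] <- drift + stats::rnorm(nl, 0, s$process_sd)
    logN[, t + 1L] <- logN[, t] + r[, t]
  }
  if (any(logN > 20)) {
    stop("latent abundance overflow (unstable dynamics); use theta_R < 0")
  }
  y <- matrix(stats::rpois(nl * ny, exp(logN)), nl, ny)
  if (missing_frac > 0) {
    for (i in seq_len(nl)) {
      n_drop <- min(ny - 1L, stats::rbinom(1L, ny, missing_frac))
      if (n_drop > 0L) y[i, sample.int(ny, n_drop)] <- NA
    }
  }
  lek_ids <- sprintf("L%03d", seq_len(nl))
  years <- 2000L + seq_len(ny) - 1L
  series <- data.frame(
    lek_id = rep(lek_ids, each = ny),
    region_id = rep(paste0("R", region), each = ny),
    year = rep(years, nl),
    count = as.vector(t(y)), stringsAsFactors = FALSE)
  series <- validate_lek_series(series[!is.na(series$count), , drop = FALSE])
  design <- data.frame(
    lek_id = rep(lek_ids, each = ny - 1L),
    year = rep(years[-1L], nl), stringsAsFactors = FALSE)
  for (k in seq_len(K)) design[[paste0("x", k)]] <- as.vector(t(X[, , k]))
  list(series = series, design = design,
       latent = list(logN = logN, r = r, region = region, years = years,
                     lek_ids = lek_ids),
       truth = truth)
}

#' Forward-simulate encounter histories from the exposure process
#'
#' Generates per-unit interval histories: each interval's daily survival rate
#' is the inverse logit of the stage's linear predictor evaluated at
#' interval-specific covariates, the interval is survived with probability
#' `DSR^t`, and a failure terminates the unit's history. Histories run to the
#' stage horizon (38 days for nests, 50 for broods, 167 for adults by
#' default). Nests are revisited on a fixed spacing; brood and adult interval
#' lengths are drawn uniformly from 1-14 days, echoing telemetry revisit
#' variability. Adult histories lie within days of year 75-242.
#'
#' @param truth A [sim_truth()].
#' @param stage `"nest"`, `"brood"`, or `"adult"`.
#' @param n_units Number of units; defaults to the stage's value in `truth`
#'   (300 nests, 200 broods, 400 adults).
#' @param seed Integer seed.
#' @param visit_spacing Nest revisit interval in days (default 4).
#' @param interval_range Range of brood/adult interval lengths (default 1-14).
#' @return A validated `encounter_history` data.frame with covariate columns
#'   and attribute `stage`.
#' @export
gen_encounter_histories <- function(truth, stage = c("nest", "brood", "adult"),
                                    n_units = NULL, seed = 1,
                                    visit_spacing = 4L, interval_range = c(1L, 14L)) {
  stage <- match.arg(stage)
  ex <- truth$exposure[[stage]]
  if (is.null(n_units)) n_units <- ex$n_units
  if (visit_spacing < 1L || any(interval_range < 1L)) {
    stop("interval lengths must be positive")
  }
  set.seed(seed)
  horizon <- ex$horizon
  start0 <- switch(stage,
    nest = sample(100:150, n_units, replace = TRUE),
    brood = sample(130:170, n_units, replace = TRUE),
    adult = rep(75L, n_units))
  covs <- names(ex$beta)
  min_len <- if (stage == "nest") visit_spacing else interval_range[1]
  cap <- n_units * (horizon %/% min_len + 1L)
  unit <- istart <- ilen <- out <- integer(cap)
  xs <- matrix(NA_real_, cap, length(covs))
  n_rec <- 0L
  for (u in seq_len(n_units)) {
    doy <- start0[u]
    end_doy <- if (stage == "adult") 242L else start0[u] + horizon
    elapsed <- 0L
    repeat {
      len <- if (stage == "nest") visit_spacing else
        sample(seq(interval_range[1], interval_range[2]), 1L)
      len <- min(len, horizon - elapsed, end_doy - doy)
      if (len <= 0L) break
      x <- stats::rnorm(length(covs))
      eta <- ex$beta0 + sum(x * ex$beta)
      for (it in ex$interactions) {
        eta <- eta + it$coef * prod(x[match(it$pair, covs)])
      }
      dsr <- inv_logit(eta)
      alive <- stats::runif(1) < dsr^len
      n_rec <- n_rec + 1L
      unit[n_rec] <- u; istart[n_rec] <- doy; ilen[n_rec] <- len
      out[n_rec] <- as.integer(alive); xs[n_rec, ] <- x
      doy <- doy + len
      elapsed <- elapsed + len
      if (!alive || elapsed >= horizon || doy >= end_doy) break
    }
  }
  keep <- seq_len(n_rec)
  unit <- unit[keep]; istart <- istart[keep]; ilen <- ilen[keep]
  out <- out[keep]; xs <- xs[keep, , drop = FALSE]
  df <- data.frame(
    unit_id = sprintf("%s%05d", toupper(substr(stage, 1, 1)), unit),
    site_id = paste0("S", 1L + (unit %% 10L)),
    interval_start_doy = istart, interval_end_doy = istart + ilen,
    exposure_days = ilen, outcome = out, stringsAsFactors = FALSE)
  for (j in seq_along(covs)) df[[covs[j]]] <- xs[, j]
  validate_encounter_histories(df, stage)
}

#' Parameter-recovery harness
#'
#' Repeatedly simulates data at a known truth, fits the model, and reports
#' per-parameter mean bias, RMSE, and empirical coverage of 95% credible
#' intervals. Replicates with any top-level R-hat >= 1.1 are excluded from
#' the tallies and counted.
#'
#' @param truth_values Named numeric vector of true parameter values; names
#'   must match `parameter` entries of the fitted summaries.
#' @param sim_fun Function `(replicate_seed) -> data`.
#' @param fit_fun Function `(data) -> data.frame` with columns `parameter`,
#'   `mean`, `q2.5`, `q97.5`, `rhat`.
#' @param n_replicates Number of replicates.
#' @param seed Base seed; replicate r uses `seed * 1000 + r`.
#' @return A list with `per_parameter` (bias, RMSE, coverage), `coverage`
#'   (pooled across parameters and replicates), `n_excluded`, and
#'   `n_replicates_used`.
#' @export
recovery_harness <- function(truth_values, sim_fun, fit_fun,
                             n_replicates = 5, seed = 1) {
  covered <- est <- matrix(NA_real_, n_replicates, length(truth_values),
                           dimnames = list(NULL, names(truth_values)))
  excluded <- 0L
  for (rep in seq_len(n_replicates)) {
    rep_seed <- (seed * 1000L + rep) %% 2147483647L
    data <- sim_fun(rep_seed)
    summ <- fit_fun(data)
    rhats <- summ$rhat[summ$parameter %in% names(truth_values)]
    if (any(!is.na(rhats) & rhats >= 1.1)) {
      excluded <- excluded + 1L
      next
    }
    idx <- match(names(truth_values), summ$parameter)
    if (anyNA(idx)) {
      stop("fit summary is missing parameters: ",
           paste(names(truth_values)[is.na(idx)], collapse = ", "))
    }
    est[rep, ] <- summ$mean[idx]
    covered[rep, ] <- truth_values >= summ$q2.5[idx] & truth_values <= summ$q97.5[idx]
  }
  used <- stats::complete.cases(est)
  per_param <- data.frame(
    parameter = names(truth_values),
    truth = as.numeric(truth_values),
    bias = colMeans(est[used, , drop = FALSE]) - truth_values,
    rmse = sqrt(colMeans((est[used, , drop = FALSE] -
                            matrix(truth_values, sum(used), length(truth_values),
                                   byrow = TRUE))^2)),
    coverage = colMeans(covered[used, , drop = FALSE]),
    stringsAsFactors = FALSE)
  rownames(per_param) <- NULL
  list(per_parameter = per_param,
       coverage = mean(covered[used, , drop = FALSE]),
       n_excluded = excluded,
       n_replicates_used = sum(used))
}
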