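#' Build the lek-count population state-space model
#'
#' Constructs the hierarchical Gompertz state-space model of lek counts.
#' Latent log-abundance follows a random walk with drift,
#' `log N[i, t+1] = log N[i, t] + r[i, t]` with
#' `r[i, t] ~ Normal(mu_r[i, t], sigma_r[i]^2)`, counts are Poisson draws from
#' the latent abundance on the natural scale, and the drift is
#' `mu_r[i, t] = alpha_R + X'[i, t] beta_R + theta_R * log N[i, t]`
#' with region-varying intercepts and coefficients drawn from common
#' hypermeans (`beta[k, R] ~ Normal(mu_beta[k], sigma_beta[k]^2)`,
#' `alpha_R ~ Normal(mu, sigma^2)`). Density dependence acts through the
#' log-abundance at the start of each transition (Gompertz form); a centred
#' variant and a density-independent variant are available. Missing counts
#' contribute no observation term (the latent state is still propagated).
#'
#' Priors: Normal(0, sd 5) on hypermeans and on `theta_R`; half-Normal(sd 1)
#' on all standard deviations; the latent initial condition is
#' `log N[i, 1] ~ Normal(log(y[i, first] + 1), sd 1)`. With a single region
#' the hierarchical priors collapse (with a warning) to the vague priors
#' directly on `alpha` and `beta`.
#'
#' @param data A `lek_series` data.frame (see [read_lek_counts()]).
#' @param design Optional covariate table: data.frame with `lek_id`, `year`
#'   and numeric covariate columns, one row per lek-year; the drift of the
#'   transition into year t+1 uses the row for response year t+1. Covariates
#'   are assumed already standardized. `NULL` fits a covariate-free model.
#' @param density Density-dependence form: `"gompertz_logN"` (default;
#'   `theta_R * log N[i, t]`), `"gompertz_centered"` (log N centred at the
#'   mean observed log count), or `"none"` (theta omitted).
#' @param config A [run_config()].
#' @return An object of class `lek_ssm` holding the JAGS specification, the
#'   prepared data arrays, and `logpost(state)`, an R evaluator of the
#'   unnormalized log-posterior used for verification.
#' @export
build_ssm <- function(data, design = NULL,
                      density = c("gompertz_logN", "gompertz_centered", "none"),
                      config = run_config()) {
  density <- match.arg(density)
  leks <- sort(unique(data$lek_id))
  years <- seq(min(data$year), max(data$year))
  nl <- length(leks); ny <- length(years)
  if (ny < 3L) stop("need at least 3 years of data")
  region_of <- tapply(data$region_id, data$lek_id, function(r) r[1])[leks]
  regions <- sort(unique(region_of))
  nr <- length(regions)
  hierarchical <- nr > 1L
  if (!hierarchical) {
    warning("single region: hierarchical priors collapse to vague priors")
  }
  y <- matrix(NA_real_, nl, ny, dimnames = list(leks, years))
  y[cbind(match(data$lek_id, leks), match(data$year, years))] <- data$count

  K <- 0L
  X <- NULL
  cov_names <- character(0)
  if (!is.null(design)) {
    cov_names <- setdiff(names(design), c("lek_id", "region_id", "year"))
    K <- length(cov_names)
    X <- array(0, dim = c(nl, ny - 1L, K))
    ii <- match(design$lek_id, leks)
    tt <- match(design$year, years) - 1L   # transition index: drift into year t+1
    ok <- !is.na(ii) & !is.na(tt) & tt >= 1L & tt <= ny - 1L
    for (k in seq_len(K)) {
      X[cbind(ii[ok], tt[ok], k)] <- design[[cov_names[k]]][ok]
    }
    # every observed lek-year beyond the first must have a covariate row
    obs <- which(!is.na(y[, -1L, drop = FALSE]), arr.ind = TRUE)
    have <- matrix(FALSE, nl, ny - 1L)
    have[cbind(ii[ok], tt[ok])] <- TRUE
    missing_row <- obs[!have[obs], , drop = FALSE]
    if (nrow(missing_row)) {
      stop("no covariate row for observed lek-year (",
           leks[missing_row[1, 1]], ", ", years[missing_row[1, 2] + 1L], ")")
    }
  }

  first_obs <- apply(y, 1L, function(r) r[which(!is.na(r))[1]])
  if (anyNA(first_obs)) stop("lek with no observed counts: ",
                             leks[which(is.na(first_obs))[1]])
  logn1_mean <- log(first_obs + 1)
  center <- if (density == "gompertz_centered") mean(log(y[!is.na(y)] + 1)) else 0
  jags_data <- list(nl = nl, ny = ny, y = y, region = match(region_of, regions),
                    logn1_mean = logn1_mean)
  if (hierarchical) jags_data$nr <- nr
  if (K > 0L) { jags_data$X <- X; jags_data$K <- K }
  if (density == "gompertz_centered") jags_data$center <- center

  model <- list(
    leks = leks, years = years, regions = regions,
    region_index = match(region_of, regions),
    y = y, X = X, cov_names = cov_names, K = K,
    density = density, center = center, hierarchical = hierarchical,
    logn1_mean = logn1_mean,
    jags_data = jags_data,
    jags_code = ssm_jags_code(K, hierarchical, density),
    config = config)
  model$logpost <- function(state) ssm_logpost(model, state)
  class(model) <- "lek_ssm"
  model
}

ssm_jags_code <- function(K, hierarchical, density) {
  dens_term <- switch(density,
    gompertz_logN = " + theta[region[i]] * logN[i, t]",
    gompertz_centered = " + theta[region[i]] * (logN[i, t] - center)",
    none = "")
  cov_term <- if (K > 0L) " + inprod(X[i, t, ], beta[region[i], ])" else ""
  theta_prior <- if (density == "none") "" else
    "    theta[R] ~ dnorm(0, 0.04)\n"
  if (hierarchical) {
    region_block <- paste0(
      "  for (R in 1:nr) {\n",
      "    alpha[R] ~ dnorm(mu_alpha, tau_alpha)\n",
      theta_prior,
      if (K > 0L) "    for (k in 1:K) { beta[R, k] ~ dnorm(mu_beta[k], tau_beta[k]) }\n" else "",
      "  }\n",
      "  mu_alpha ~ dnorm(0, 0.04)\n",
      "  sigma_alpha ~ dnorm(0, 1) T(0,)\n",
      "  tau_alpha <- pow(sigma_alpha, -2)\n",
      if (K > 0L) paste0(
        "  for (k in 1:K) {\n",
        "    mu_beta[k] ~ dnorm(0, 0.04)\n",
        "    sigma_beta[k] ~ dnorm(0, 1) T(0,)\n",
        "    tau_beta[k] <- pow(sigma_beta[k], -2)\n",
        "  }\n") else "")
  } else {
    region_block <- paste0(
      "  alpha[1] ~ dnorm(0, 0.04)\n",
      if (density != "none") "  theta[1] ~ dnorm(0, 0.04)\n" else "",
      if (K > 0L) "  for (k in 1:K) { beta[1, k] ~ dnorm(0, 0.04) }\n" else "")
  }
  # logN is parameterized as the stochastic node (equivalent to sampling r
  # and accumulating): each state then has only local graph dependencies
  paste0(
    "model {\n",
    "  for (i in 1:nl) {\n",
    "    logN[i, 1] ~ dnorm(logn1_mean[i], 1)\n",
    "    for (t in 1:(ny - 1)) {\n",
    "      mu_r[i, t] <- alpha[region[i]]", cov_term, dens_term, "\n",
    "      logN[i, t + 1] ~ dnorm(logN[i, t] + mu_r[i, t], tau_r[i])\n",
    "    }\n",
    "    for (t in 1:ny) {\n",
    "      N[i, t] <- exp(logN[i, t])\n",
    "      y[i, t] ~ dpois(N[i, t])\n",
    "    }\n",
    "    sigma_r[i] ~ dnorm(0, 1) T(0,)\n",
    "    tau_r[i] <- pow(sigma_r[i], -2)\n",
    "  }\n",
    region_block,
    "}\n")
}

half_normal_logpdf <- function(x, sd) {
  if (any(x < 0)) return(-Inf)
  sum(log(2) + stats::dnorm(x, 0, sd, log = TRUE))
}

# unnormalized log-posterior of the SSM at a pinned parameter state.
# state: list(logN [nl x ny], alpha, theta, beta [nr x K], sigma_r [nl],
#             mu_alpha, sigma_alpha, mu_beta [K], sigma_beta [K])
ssm_logpost <- function(model, state) {
  nl <- nrow(model$y); ny <- ncol(model$y)
  reg <- model$region_index
  lp <- sum(stats::dnorm(state$logN[, 1L], model$logn1_mean, 1, log = TRUE))
  for (t in seq_len(ny - 1L)) {
    mu_r <- state$alpha[reg]
    if (model$K > 0L) {
      for (k in seq_len(model$K)) {
        mu_r <- mu_r + model$X[, t, k] * state$beta[reg, k]
      }
    }
    if (model$density != "none") {
      mu_r <- mu_r + state$theta[reg] * (state$logN[, t] - model$center)
    }
    r <- state$logN[, t + 1L] - state$logN[, t]
    lp <- lp + sum(stats::dnorm(r, mu_r, state$sigma_r, log = TRUE))
  }
  obs <- !is.na(model$y)
  lp <- lp + sum(stats::dpois(model$y[obs], exp(state$logN)[obs], log = TRUE))
  lp <- lp + half_normal_logpdf(state$sigma_r, 1)
  if (model$hierarchical) {
    lp <- lp + sum(stats::dnorm(state$alpha, state$mu_alpha, state$sigma_alpha, log = TRUE))
    lp <- lp + stats::dnorm(state$mu_alpha, 0, 5, log = TRUE)
    lp <- lp + half_normal_logpdf(state$sigma_alpha, 1)
    if (model$K > 0L) {
      for (k in seq_len(model$K)) {
        lp <- lp + sum(stats::dnorm(state$beta[, k], state$mu_beta[k],
                                    state$sigma_beta[k], log = TRUE))
        lp <- lp + stats::dnorm(state$mu_beta[k], 0, 5, log = TRUE)
      }
      lp <- lp + half_normal_logpdf(state$sigma_beta, 1)
    }
  } else {
    lp <- lp + sum(stats::dnorm(state$alpha, 0, 5, log = TRUE))
    if (model$K > 0L) lp <- lp + sum(stats::dnorm(state$beta, 0, 5, log = TRUE))
  }
  if (model$density != "none") {
    lp <- lp + sum(stats::dnorm(state$theta, 0, 5, log = TRUE))
  }
  lp
}

#' Fit the lek-count state-space model by MCMC
#'
#' Samples the posterior of a [build_ssm()] specification with JAGS. R-hat is
#' computed for every top-level parameter (region intercepts, coefficients,
#' density-dependence terms, hypermeans, hyper-SDs); `summary()` warns when
#' any R-hat is >= 1.1 (the convergence gate), but draws are always returned.
#'
#' @param model A `lek_ssm` specification.
#' @param config A [run_config()]; defaults to the one stored in the model.
#' @return Object of class `lek_ssm_fit`: `draws` (top-level parameters as
#'   iterations x chains matrices), `logN` (array draw x lek x year of latent
#'   log-abundance), `summary`, `converged`, and the `model`.
#' @export
fit_ssm <- function(model, config = model$config) {
  stopifnot(inherits(model, "lek_ssm"))
  top <- c("alpha")
  if (model$density != "none") top <- c(top, "theta")
  if (model$K > 0L) top <- c(top, "beta")
  if (model$hierarchical) {
    top <- c(top, "mu_alpha", "sigma_alpha")
    if (model$K > 0L) top <- c(top, "mu_beta", "sigma_beta")
  }
  jm <- rjags::jags.model(textConnection(model$jags_code),
                          data = model$jags_data,
                          n.chains = config$chains, n.adapt = config$adapt,
                          inits = jags_inits(config), quiet = TRUE)
  stats::update(jm, config$burn_in, progress.bar = "none")
  samp <- rjags::coda.samples(jm, c(top, "logN"), n.iter = config$iterations,
                              thin = config$thin, progress.bar = "none")
  vars <- coda::varnames(samp)
  is_latent <- startsWith(vars, "logN[")
  top_draws <- draws_to_matrices(samp[, vars[!is_latent], drop = FALSE])
  names(top_draws) <- rename_ssm_params(names(top_draws), model)
  nl <- nrow(model$y); ny <- ncol(model$y)
  lat <- do.call(rbind, lapply(samp, function(ch) as.matrix(ch)[, vars[is_latent], drop = FALSE]))
  idx <- do.call(rbind, lapply(strsplit(gsub("logN\\[|\\]", "", colnames(lat)), ","),
                               as.integer))
  logN <- array(NA_real_, dim = c(nrow(lat), nl, ny))
  for (j in seq_len(ncol(lat))) logN[, idx[j, 1L], idx[j, 2L]] <- lat[, j]
  summ <- posterior_summary(top_draws)
  converged <- all(is.na(summ$rhat) | summ$rhat < 1.1)
  fit <- list(model = model, draws = top_draws, logN = logN,
              summary = summ, converged = converged, config = config)
  class(fit) <- "lek_ssm_fit"
  fit
}

rename_ssm_params <- function(nm, model) {
  # single-element nodes lose their bracket in JAGS; restore it
  nm[nm == "alpha"] <- "alpha[1]"
  nm[nm == "theta"] <- "theta[1]"
  nm[nm == "beta"] <- "beta[1,1]"
  if (model$K > 0L) {
    m <- regmatches(nm, regexec("^beta\\[(\\d+),(\\d+)\\]$", nm))
    for (i in seq_along(nm)) {
      if (length(m[[i]])) {
        nm[i] <- paste0("beta_", model$cov_names[as.integer(m[[i]][3])],
                        "[", m[[i]][2], "]")
      }
    }
    m2 <- regmatches(nm, regexec("^(mu_beta|sigma_beta)\\[(\\d+)\\]$", nm))
    for (i in seq_along(nm)) {
      if (length(m2[[i]])) {
        nm[i] <- paste0(m2[[i]][2], "_", model$cov_names[as.integer(m2[[i]][3])])
      }
    }
  }
  nm
}

#' @export
print.lek_ssm_fit <- function(x, ...) {
  cat("Lek-count state-space model fit\n")
  cat(sprintf("  %d leks, %d years, %d regions, %d covariates (density: %s)\n",
              nrow(x$model$y), ncol(x$model$y), length(x$model$regions),
              x$model$K, x$model$density))
  cat("  converged:", x$converged,
      sprintf(" (max R-hat %.3f)\n", max(x$summary$rhat, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.lek_ssm_fit <- function(object, ...) {
  if (!object$converged) {
    warning("summarizing an unconverged fit (some R-hat >= 1.1)")
  }
  object$summary
}

#' @export
coef.lek_ssm_fit <- function(object, ...) {
  stats::setNames(object$summary$mean, object$summary$parameter)
}

#' Derive population rate-of-change summaries
#'
#' The finite rate of change is `lambda = exp(r)` for each latent growth rate
#' draw `r[i, t] = log N[i, t+1] - log N[i, t]`. Summaries are computed per
#' lek, per region, or globally (growth rates averaged within each posterior
#' draw before exponentiating). Also reports, for each covariate hypermean,
#' the marginal percent change in lambda per unit (1 SD) covariate change,
#' `100 * (exp(mu_beta_k) - 1)`.
#'
#' @param fit A `lek_ssm_fit`.
#' @param scope `"global"`, `"region"`, or `"lek"`.
#' @return A list with `lambda` (summary data.frame for the chosen scope) and
#'   `percent_effects` (named vector, empty without covariates).
#' @export
derive_lambda <- function(fit, scope = c("global", "region", "lek")) {
  scope <- match.arg(scope)
  r <- fit$logN[, , -1L, drop = FALSE] - fit$logN[, , -dim(fit$logN)[3], drop = FALSE]
  groups <- switch(scope,
    global = list(global = seq_len(dim(r)[2])),
    region = {
      g <- split(seq_len(dim(r)[2]), fit$model$regions[fit$model$region_index])
      g
    },
    lek = split(seq_len(dim(r)[2]), fit$model$leks))
  rows <- lapply(names(groups), function(g) {
    lam <- exp(apply(r[, groups[[g]], , drop = FALSE], 1L, mean))
    data.frame(scope = g, mean = mean(lam),
               q2.5 = stats::quantile(lam, 0.025, names = FALSE),
               q50 = stats::median(lam),
               q97.5 = stats::quantile(lam, 0.975, names = FALSE),
               stringsAsFactors = FALSE)
  })
  eff <- numeric(0)
  mu_names <- grep("^mu_beta_", names(fit$draws), value = TRUE)
  if (length(mu_names)) {
    eff <- vapply(mu_names, function(p) {
      percent_lambda_effect(mean(as.numeric(fit$draws[[p]])))
    }, numeric(1))
    names(eff) <- sub("^mu_beta_", "", mu_names)
  }
  list(lambda = do.call(rbind, rows), percent_effects = eff)
}

#' Percent change in lambda per unit covariate change
#'
#' A coefficient `b` on the log growth rate corresponds to a multiplicative
#' change `exp(b)` in lambda per unit covariate change, i.e.
#' `100 * (exp(b) - 1)` percent.
#'
#' @param b Coefficient value(s) on the growth-rate scale.
#' @return Percent change(s) in lambda.
#' @export
percent_lambda_effect <- function(b) 100 * (exp(b) - 1)

#' @export
bayesian_pvalue.lek_ssm_fit <- function(fit, statistic = "chi_square",
                                        seed = NULL, max_draws = 500L, ...) {
  obs <- which(!is.na(fit$model$y))
  nd <- dim(fit$logN)[1]
  keep <- if (nd > max_draws) round(seq(1L, nd, length.out = max_draws)) else seq_len(nd)
  N <- exp(matrix(fit$logN[keep, , ], nrow = length(keep)))[, obs, drop = FALSE]
  bayesian_pvalue.default(
    list(observed = fit$model$y[obs], expected = N,
         simulate = function(mu) stats::rpois(length(mu), mu)),
    statistic = statistic, seed = seed)
}
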