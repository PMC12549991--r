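#' Inverse logit link
#'
#' `exp(eta) / (1 + exp(eta))`, numerically stabilized by clipping `eta` to
#' +/- 35 before exponentiation (no effect beyond 1e-15 at double precision).
#'
#' @param eta Linear predictor value(s).
#' @return Probability value(s) in (0, 1).
#' @export
inv_logit <- function(eta) {
  eta <- pmin(pmax(eta, -35), 35)
  1 / (1 + exp(-eta))
}

#' Cumulative survival over an exposure interval
#'
#' Survival over `t` days at daily survival rate `dsr` is `dsr^t`, the product
#' of `t` daily survivals.
#'
#' @param dsr Daily survival probability in (0, 1].
#' @param t Exposure days (non-negative integer).
#' @return `dsr^t`. A zero-day interval returns 1 with a warning.
#' @export
interval_survival <- function(dsr, t) {
  if (any(dsr <= 0) || any(dsr > 1)) stop("dsr must be in (0, 1]")
  if (any(t < 0)) stop("exposure days must be non-negative")
  if (any(t == 0)) warning("zero-day exposure interval: survival is trivially 1")
  dsr^t
}

# stage horizons (days) for cumulative survival
stage_horizon <- function(stage) {
  switch(stage, nest = 38L, brood = 50L, adult = 167L,
         stop("unknown stage '", stage, "'"))
}

#' Logistic-exposure log-likelihood
#'
#' Bernoulli log-likelihood of interval outcomes under the logistic exposure
#' model: for each interval, survival probability is `DSR^t` with
#' `DSR = inv_logit(X beta)`, and the contribution is
#' `y log(DSR^t) + (1 - y) log(1 - DSR^t)`.
#'
#' @param beta Coefficient vector (intercept first), aligned to `X`.
#' @param X Design matrix (one row per interval, intercept column included).
#' @param t Exposure days per interval.
#' @param y Interval outcomes (1 = survived, 0 = failed).
#' @return The summed log-likelihood (finite for DSR strictly inside (0,1)).
#' @export
exposure_loglik <- function(beta, X, t, y) {
  X <- as.matrix(X)
  if (ncol(X) != length(beta)) {
    stop("length(beta) = ", length(beta), " does not match ncol(X) = ", ncol(X))
  }
  stopifnot(length(t) == nrow(X), length(y) == nrow(X))
  dsr <- inv_logit(drop(X %*% beta))
  S <- dsr^t
  S <- pmin(pmax(S, 1e-300), 1 - 1e-16)
  sum(y * log(S) + (1 - y) * log1p(-S))
}

#' Build a stage-specific logistic-exposure model
#'
#' Assembles the design matrix and JAGS specification for one life stage.
#' Continuous main effects are z-scored (the centre/scale pairs are stored for
#' prediction); indicator covariates (e.g. sex, hen age, transmitter type,
#' translocation status) are left 0/1. Interaction columns are products of the
#' named (standardized) main-effect columns, and every interaction must
#' reference mains present in the model. All non-intercept coefficients get a
#' Laplace (double-exponential) shrinkage prior with rate Lambda, itself given
#' a Uniform prior over the configured bounds; the intercept gets a vague
#' Normal(0, sd 5) prior.
#'
#' @param stage `"nest"`, `"brood"`, or `"adult"` (sets the cumulative-survival
#'   horizon: 38, 50, 167 days).
#' @param histories An `encounter_history` data.frame (see
#'   [read_encounter_histories()]).
#' @param main Character vector of main-effect covariate columns.
#' @param interactions Optional list of length-2 character vectors naming
#'   interacting mains.
#' @param indicators Character subset of `main` to leave unstandardized (0/1).
#' @param lambda_fixed Optional fixed value for the shrinkage rate (used for
#'   shrinkage-path diagnostics); when `NULL` (default) Lambda is estimated.
#' @param config A [run_config()].
#' @return An object of class `exposure_model`.
#' @export
build_stage_model <- function(stage, histories, main = covariate_names(histories),
                              interactions = NULL, indicators = character(),
                              lambda_fixed = NULL, config = run_config()) {
  stage <- match.arg(stage, c("nest", "brood", "adult"))
  miss <- setdiff(main, names(histories))
  if (length(miss)) stop("covariates not found: ", paste(miss, collapse = ", "))
  for (pair in interactions) {
    if (length(pair) != 2L || !all(pair %in% main)) {
      stop("interaction {", paste(pair, collapse = " x "),
           "} references a main effect absent from the model")
    }
  }
  centers <- scales <- stats::setNames(numeric(0), character(0))
  cols <- list(`(Intercept)` = rep(1, nrow(histories)))
  for (v in main) {
    x <- histories[[v]]
    if (v %in% indicators) {
      cols[[v]] <- as.numeric(x)
    } else {
      z <- standardize(x, name = v)
      centers[v] <- attr(z, "center")
      scales[v] <- attr(z, "scale")
      cols[[v]] <- as.numeric(z)
    }
  }
  for (pair in interactions) {
    cols[[paste(pair, collapse = ":")]] <- cols[[pair[1]]] * cols[[pair[2]]]
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  model <- list(
    stage = stage,
    horizon = stage_horizon(stage),
    X = X,
    days = histories$exposure_days,
    y = histories$outcome,
    coef_names = colnames(X),
    centers = centers,
    scales = scales,
    interactions = interactions,
    lambda_fixed = lambda_fixed,
    config = config,
    jags_code = exposure_jags_code(ncol(X), fixed_lambda = !is.null(lambda_fixed))
  )
  class(model) <- "exposure_model"
  model
}

exposure_jags_code <- function(K, fixed_lambda = FALSE) {
  shrink <- if (K > 1L) {
    "  for (k in 2:K) { beta[k] ~ ddexp(0, lambda) }\n"
  } else {
    ""
  }
  lambda_prior <- if (fixed_lambda) "" else "  lambda ~ dunif(shrink_lower, shrink_upper)\n"
  paste0(
    "model {\n",
    "  for (j in 1:n) {\n",
    "    eta[j] <- inprod(X[j, ], beta[])\n",
    "    dsr[j] <- ilogit(eta[j])\n",
    "    S[j] <- pow(dsr[j], days[j])\n",
    "    y[j] ~ dbern(S[j])\n",
    "  }\n",
    "  beta[1] ~ dnorm(0, 0.04)\n",
    shrink, lambda_prior,
    "}\n")
}

#' Fit a logistic-exposure model by MCMC
#'
#' Samples the posterior of an [build_stage_model()] specification with JAGS,
#' computes R-hat for all coefficients and the shrinkage rate, and derives the
#' daily survival rate at the reference covariate point (standardized
#' covariates at 0, indicators at their 0 reference level) together with
#' cumulative survival at the stage horizon — both per posterior draw, so the
#' identity `cumulative = dsr^horizon` holds draw-wise.
#'
#' @param model An `exposure_model`.
#' @param config A [run_config()]; defaults to the one stored in the model.
#' @return An object of class `exposure_fit` with components `summary`
#'   (coefficients plus derived DSR and cumulative-survival rows), `draws`
#'   (per-parameter iterations x chains matrices), `dsr_draws`, `cum_draws`,
#'   `converged` (all R-hat < 1.1) and the originating `model`. When any
#'   R-hat is >= 1.1 the fit is flagged unconverged (draws are still
#'   returned).
#' @export
fit_stage_model <- function(model, config = model$config) {
  stopifnot(inherits(model, "exposure_model"))
  K <- ncol(model$X)
  data <- list(n = nrow(model$X), X = model$X, days = model$days, y = model$y)
  if (K > 1L) data$K <- K
  if (!is.null(model$lambda_fixed)) {
    data$lambda <- model$lambda_fixed
  } else if (K > 1L) {
    data$shrink_lower <- config$shrink_lower
    data$shrink_upper <- config$shrink_upper
  }
  monitors <- if (K > 1L && is.null(model$lambda_fixed)) c("beta", "lambda") else "beta"
  jm <- rjags::jags.model(textConnection(model$jags_code), data = data,
                          n.chains = config$chains, n.adapt = config$adapt,
                          inits = jags_inits(config), quiet = TRUE)
  stats::update(jm, config$burn_in, progress.bar = "none")
  samp <- rjags::coda.samples(jm, monitors, n.iter = config$iterations,
                              thin = config$thin, progress.bar = "none")
  draws <- draws_to_matrices(samp)
  # rename beta[k] to covariate names
  beta_keys <- if (K > 1L) paste0("beta[", seq_len(K), "]") else "beta"
  names(draws)[match(beta_keys, names(draws))] <- model$coef_names
  if ("lambda" %in% names(draws)) {
    names(draws)[names(draws) == "lambda"] <- "Lambda"
  }
  summ <- posterior_summary(draws)
  rhats <- summ$rhat
  converged <- all(is.na(rhats) | rhats < 1.1)
  if (!converged) {
    warning("R-hat >= 1.1 for: ",
            paste(summ$parameter[!is.na(rhats) & rhats >= 1.1], collapse = ", "),
            "; fit flagged unconverged")
  }
  dsr_draws <- inv_logit(as.numeric(draws[["(Intercept)"]]))
  cum_draws <- dsr_draws^model$horizon
  derived <- data.frame(
    parameter = c("DSR", paste0("S", model$horizon)),
    mean = c(mean(dsr_draws), mean(cum_draws)),
    sd = c(stats::sd(dsr_draws), stats::sd(cum_draws)),
    q2.5 = c(stats::quantile(dsr_draws, 0.025, names = FALSE),
             stats::quantile(cum_draws, 0.025, names = FALSE)),
    q50 = c(stats::median(dsr_draws), stats::median(cum_draws)),
    q97.5 = c(stats::quantile(dsr_draws, 0.975, names = FALSE),
              stats::quantile(cum_draws, 0.975, names = FALSE)),
    rhat = NA_real_, pd = NA_real_, stringsAsFactors = FALSE)
  fit <- list(model = model, draws = draws, summary = rbind(summ, derived),
              dsr_draws = dsr_draws, cum_draws = cum_draws,
              converged = converged, config = config)
  class(fit) <- "exposure_fit"
  fit
}

#' @export
print.exposure_fit <- function(x, ...) {
  cat("Logistic-exposure survival model (", x$model$stage, " stage)\n", sep = "")
  cat(sprintf("  intervals: %d, coefficients: %d, horizon: %d days\n",
              nrow(x$model$X), ncol(x$model$X), x$model$horizon))
  cat(sprintf("  reference DSR: %.4f, %d-day survival: %.3f\n",
              mean(x$dsr_draws), x$model$horizon, mean(x$cum_draws)))
  cat("  converged:", x$converged, "\n")
  invisible(x)
}

#' @export
summary.exposure_fit <- function(object, ...) {
  if (!object$converged) {
    warning("summarizing an unconverged fit (some R-hat >= 1.1)")
  }
  object$summary
}

#' @export
coef.exposure_fit <- function(object, ...) {
  s <- object$summary
  s <- s[s$parameter %in% object$model$coef_names, ]
  stats::setNames(s$mean, s$parameter)
}

#' Predict daily survival for new covariate values
#'
#' @param object An `exposure_fit`.
#' @param newdata Data.frame of covariates on their original scale; columns
#'   standardized at fit time are standardized here with the stored
#'   centre/scale pairs. Missing columns default to the reference point.
#' @param ... Unused.
#' @return Data.frame with posterior mean DSR and 95% CRI per row.
#' @export
predict.exposure_fit <- function(object, newdata = NULL, ...) {
  m <- object$model
  n <- if (is.null(newdata)) 1L else nrow(newdata)
  X <- matrix(0, n, length(m$coef_names), dimnames = list(NULL, m$coef_names))
  X[, "(Intercept)"] <- 1
  if (!is.null(newdata)) {
    for (v in intersect(colnames(X), names(newdata))) {
      x <- as.numeric(newdata[[v]])
      if (v %in% names(m$centers)) x <- (x - m$centers[v]) / m$scales[v]
      X[, v] <- x
    }
    for (pair in m$interactions) {
      X[, paste(pair, collapse = ":")] <- X[, pair[1]] * X[, pair[2]]
    }
  }
  B <- sapply(m$coef_names, function(p) as.numeric(object$draws[[p]]))
  eta <- X %*% t(B)
  dsr <- inv_logit(eta)
  data.frame(dsr = rowMeans(dsr),
             q2.5 = apply(dsr, 1L, stats::quantile, 0.025),
             q97.5 = apply(dsr, 1L, stats::quantile, 0.975))
}

#' @export
bayesian_pvalue.exposure_fit <- function(fit, statistic = "deviance",
                                         seed = NULL, max_draws = 500L, ...) {
  m <- fit$model
  B <- sapply(m$coef_names, function(p) as.numeric(fit$draws[[p]]))
  if (nrow(B) > max_draws) {
    B <- B[round(seq(1L, nrow(B), length.out = max_draws)), , drop = FALSE]
  }
  eta <- m$X %*% t(B)                      # n x draws
  S <- inv_logit(eta)^m$days
  bayesian_pvalue.default(
    list(observed = m$y, expected = t(S),
         simulate = function(mu) stats::rbinom(length(mu), 1L, mu)),
    statistic = statistic, seed = seed)
}
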