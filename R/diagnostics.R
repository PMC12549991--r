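#' Gelman-Rubin potential scale reduction factor
#'
#' Computes the classic (non-split) potential scale reduction factor from
#' between- and within-chain variances. Values below 1.1 are conventionally
#' taken as evidence of chain convergence.
#'
#' @param chains A matrix with one column per chain (iterations in rows), or a
#'   list of equal-length numeric vectors, or a [coda::mcmc.list] of a single
#'   variable.
#' @param split If `TRUE`, each chain is split in half and the halves are
#'   treated as separate chains, which additionally detects within-chain
#'   non-stationarity.
#' @return A list with elements `rhat` (the PSRF; `NA` when the within-chain
#'   variance is zero, in which case the statistic is undefined) and
#'   `converged` (`rhat < 1.1`, `NA` when undefined).
#' @examples
#' ch <- cbind(rnorm(1000), rnorm(1000))
#' gelman_rubin(ch)$rhat
#' @export
gelman_rubin <- function(chains, split = FALSE) {
  chains <- as_chain_matrix(chains)
  if (ncol(chains) < 2L) stop("gelman_rubin() requires at least 2 chains")
  if (nrow(chains) < 10L) stop("gelman_rubin() requires chains of length >= 10")
  if (split) {
    n <- nrow(chains)
    h <- n %/% 2L
    chains <- cbind(chains[seq_len(h), , drop = FALSE],
                    chains[(n - h + 1L):n, , drop = FALSE])
  }
  n <- nrow(chains)
  m <- ncol(chains)
  means <- colMeans(chains)
  W <- mean(apply(chains, 2L, stats::var))
  B <- n * stats::var(means)
  if (W == 0) {
    return(list(rhat = NA_real_, converged = NA))
  }
  var_plus <- (n - 1) / n * W + B / n
  rhat <- sqrt(var_plus / W)
  list(rhat = rhat, converged = rhat < 1.1)
}

as_chain_matrix <- function(chains) {
  if (inherits(chains, "mcmc.list")) {
    chains <- lapply(chains, function(ch) as.numeric(as.matrix(ch)))
  }
  if (is.list(chains)) {
    lens <- lengths(chains)
    if (length(unique(lens)) != 1L) stop("all chains must have equal length")
    chains <- do.call(cbind, lapply(chains, as.numeric))
  }
  as.matrix(chains)
}

#' Probability of direction
#'
#' The proportion of posterior draws sharing the sign of the posterior median
#' (an index of certainty in the sign of an effect). Draws equal to zero are
#' counted with the median's sign. A variant relative to the sign of the
#' posterior mean is available via `reference = "mean"`; the two differ only
#' for markedly skewed posteriors.
#'
#' @param draws Numeric vector of posterior draws (length >= 2).
#' @param reference Sign reference: the posterior `"median"` (default) or
#'   `"mean"`.
#' @return A probability in \[0.5, 1\] (up to sampling granularity).
#' @examples
#' prob_direction(c(-1, -2, -3, 1)) # 0.75
#' @export
prob_direction <- function(draws, reference = c("median", "mean")) {
  reference <- match.arg(reference)
  draws <- as.numeric(draws)
  if (length(draws) < 2L) stop("prob_direction() requires at least 2 draws")
  ref <- if (reference == "median") stats::median(draws) else mean(draws)
  if (ref == 0) {
    if (all(draws == 0)) {
      warning("all draws are zero; pd is degenerate")
      return(1)
    }
    # median exactly zero with non-degenerate draws: use the majority sign
    ref <- if (sum(draws > 0) >= sum(draws < 0)) 1 else -1
  }
  s <- sign(ref)
  mean(sign(draws) == s | draws == 0)
}

#' Equal-tailed credible interval with evidence category
#'
#' @param draws Numeric vector of posterior draws.
#' @param level Credibility level in (0,1); default 0.95.
#' @return A list with `lower`, `upper` (linear-interpolation quantiles,
#'   type 7), `pd`, and `evidence`: `"strong"` when the interval excludes 0,
#'   `"moderate"` when it overlaps 0 but pd > 0.85, `"weak"` otherwise.
#' @export
credible_interval <- function(draws, level = 0.95) {
  if (level <= 0 || level >= 1) stop("level must be in (0,1)")
  a <- (1 - level) / 2
  q <- stats::quantile(draws, probs = c(a, 1 - a), names = FALSE, type = 7)
  pd <- if (length(draws) >= 2 && any(draws != draws[1])) prob_direction(draws) else 1
  evidence <- if (q[1] > 0 || q[2] < 0) {
    "strong"
  } else if (pd > 0.85) {
    "moderate"
  } else {
    "weak"
  }
  list(lower = q[1], upper = q[2], pd = pd, evidence = evidence)
}

#' Posterior-predictive Bayesian p-value
#'
#' Computes `Pr[T(y_rep, theta) >= T(y, theta)]` over posterior draws, where
#' replicated data `y_rep` are simulated from the fitted model at each draw.
#' Values approaching 0 or 1 imply lack of fit. The discrepancy is a
#' chi-square statistic for Poisson counts and the Bernoulli deviance for
#' exposure-interval data.
#'
#' @param fit A fitted model object (`lek_ssm_fit` or `exposure_fit`), or a
#'   list with elements `observed` (data vector), `expected` (draws x data
#'   matrix of per-draw expected values), and `simulate` (function of one
#'   expected-value vector returning one replicated data vector).
#' @param statistic `"chi_square"` or `"deviance"`.
#' @param seed Optional integer seed for the replicated-data simulation.
#' @param ... Unused.
#' @return Bayesian p-value in (0,1).
#' @export
bayesian_pvalue <- function(fit, statistic = c("chi_square", "deviance"),
                            seed = NULL, ...) {
  UseMethod("bayesian_pvalue")
}

#' @export
bayesian_pvalue.default <- function(fit, statistic = c("chi_square", "deviance"),
                                    seed = NULL, ...) {
  statistic <- match.arg(statistic)
  expected <- fit$expected
  y <- fit$observed
  if (is.null(dim(expected))) expected <- matrix(expected, nrow = 1L)
  n_draws <- nrow(expected)
  if (n_draws < 100L) {
    warning("fewer than 100 draws: Bayesian p-value has large Monte-Carlo error")
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  disc <- switch(statistic,
    chi_square = function(obs, mu) sum((obs - mu)^2 / pmax(mu, 1e-12)),
    deviance = function(obs, mu) {
      p <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
      -2 * sum(obs * log(p) + (1 - obs) * log1p(-p))
    })
  ge <- logical(n_draws)
  for (d in seq_len(n_draws)) {
    mu <- expected[d, ]
    y_rep <- fit$simulate(mu)
    ge[d] <- disc(y_rep, mu) >= disc(y, mu)
  }
  mean(ge)
}

#' Summarize posterior draws in the standard reporting format
#'
#' One row per parameter with posterior mean, SD, 2.5th/50th/97.5th draw
#' percentiles, the Gelman-Rubin statistic, and the probability of direction.
#'
#' @param draws A [coda::mcmc.list], or a named list of per-parameter matrices
#'   (iterations x chains).
#' @param params Optional character vector restricting/ordering parameters.
#' @return A `data.frame` with columns `parameter`, `mean`, `sd`, `q2.5`,
#'   `q50`, `q97.5`, `rhat`, `pd`.
#' @export
posterior_summary <- function(draws, params = NULL) {
  mats <- draws_to_matrices(draws)
  if (!is.null(params)) mats <- mats[params]
  rows <- lapply(names(mats), function(p) {
    m <- mats[[p]]
    v <- as.numeric(m)
    rhat <- if (ncol(m) >= 2L && nrow(m) >= 10L) gelman_rubin(m)$rhat else NA_real_
    q <- stats::quantile(v, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
    data.frame(parameter = p, mean = mean(v), sd = stats::sd(v),
               q2.5 = q[1], q50 = q[2], q97.5 = q[3],
               rhat = rhat,
               pd = if (stats::sd(v) == 0) 1 else prob_direction(v),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# coerce an mcmc.list or list of matrices into a named list of
# iterations x chains matrices, one per scalar parameter
draws_to_matrices <- function(draws) {
  if (inherits(draws, "mcmc.list")) {
    vars <- coda::varnames(draws)
    out <- lapply(vars, function(v) {
      do.call(cbind, lapply(draws, function(ch) as.numeric(as.matrix(ch)[, v])))
    })
    names(out) <- vars
    return(out)
  }
  if (is.list(draws)) {
    stopifnot(!is.null(names(draws)))
    return(lapply(draws, as.matrix))
  }
  stop("unsupported draws container")
}
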