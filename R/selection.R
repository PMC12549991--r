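#' Group candidate covariates by correlation structure
#'
#' Partitions covariates into the connected components of the graph whose
#' edges join pairs with `|r| >= threshold`. Transitively linked covariates
#' land in one group even when not all pairwise correlations exceed the
#' threshold. Ordering is deterministic (groups by first column position,
#' members in column order) and invariant to column permutation up to
#' relabelling.
#'
#' @param design Data.frame or matrix of candidate covariate columns.
#' @param threshold Absolute-correlation threshold in (0, 1); default 0.65.
#' @return A list of character vectors (the partition).
#' @export
group_covariates <- function(design, threshold = 0.65) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  M <- as.matrix(design)
  sds <- apply(M, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant column '", colnames(M)[sds == 0][1], "' cannot be standardized")
  }
  R <- abs(stats::cor(M))
  p <- ncol(M)
  comp <- integer(p)
  cur <- 0L
  for (s in seq_len(p)) {
    if (comp[s]) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (comp[v]) next
      comp[v] <- cur
      nb <- which(R[v, ] >= threshold & comp == 0L)
      queue <- c(queue, setdiff(nb, v))
    }
  }
  groups <- split(colnames(M), comp)
  names(groups) <- NULL
  lapply(groups, function(g) g[order(match(g, colnames(M)))])
}

#' Stage-1 screening of candidate covariates with scale selection
#'
#' First stage of the two-stage Bayesian variable selection. Each candidate
#' covariate is represented by one or more scale variants (columns of the
#' data, ordered from smallest to largest scale). Candidates are partitioned
#' into correlation groups (via [group_covariates()] on each candidate's
#' first variant); each group is fitted one at a time with all of its
#' members' scale variants as alternative columns under the Laplace shrinkage
#' prior. Per candidate, the scale maximizing the probability of direction is
#' selected (ties broken toward the smaller scale), and candidates are
#' retained when that pd meets the screening threshold. Candidates in
#' multi-member groups whose coefficient sign flips between the group fit and
#' a solo fit are flagged as confounded and dropped.
#'
#' @param histories An `encounter_history` data.frame holding all variant
#'   columns (or any data accepted by a custom `fit_fun`).
#' @param candidates Named list: candidate name -> character vector of its
#'   variant column names, ordered by increasing scale.
#' @param stage Life stage, for the default exposure-model fitter.
#' @param config A [run_config()]; `config$group_threshold` and
#'   `config$screen_pd` supply the grouping and screening thresholds.
#' @param fit_fun Optional custom fitter `(column names) -> data.frame` with
#'   columns `parameter`, `mean`, `pd` (one row per fitted column); defaults
#'   to a shrinkage logistic-exposure fit.
#' @return A list of class `selection_report` with elements `groups`,
#'   `scores` (per candidate: chosen column, pd, mean, retained, confounded)
#'   and `retained` (named vector of chosen columns, screened candidates
#'   only).
#' @export
screen_stage1 <- function(histories, candidates, stage = "nest",
                          config = run_config(), fit_fun = NULL) {
  stopifnot(is.list(candidates), !is.null(names(candidates)))
  if (is.null(fit_fun)) {
    fit_fun <- function(cols) {
      m <- build_stage_model(stage, histories, main = cols, config = config)
      f <- fit_stage_model(m)
      s <- f$summary[f$summary$parameter %in% cols, c("parameter", "mean", "pd")]
      s
    }
  }
  rep_cols <- vapply(candidates, `[`, character(1), 1L)
  grp_design <- as.data.frame(histories)[, rep_cols, drop = FALSE]
  names(grp_design) <- names(candidates)
  groups <- group_covariates(grp_design, config$group_threshold)

  scores <- list()
  for (g in groups) {
    cols <- unlist(candidates[g], use.names = FALSE)
    fit <- fit_fun(cols)
    for (cand in g) {
      variants <- candidates[[cand]]
      sub <- fit[match(variants, fit$parameter), , drop = FALSE]
      best <- which(sub$pd == max(sub$pd))[1L]   # tie -> smaller scale
      confounded <- FALSE
      if (length(g) > 1L) {
        solo <- fit_fun(variants[best])
        solo_mean <- solo$mean[match(variants[best], solo$parameter)]
        confounded <- sign(solo_mean) != sign(sub$mean[best]) &&
          sign(sub$mean[best]) != 0
      }
      scores[[cand]] <- data.frame(
        candidate = cand, chosen = variants[best],
        pd = sub$pd[best], mean = sub$mean[best],
        retained = sub$pd[best] >= config$screen_pd && !confounded,
        confounded = confounded, stringsAsFactors = FALSE)
    }
  }
  scores <- do.call(rbind, scores[names(candidates)])
  rownames(scores) <- NULL
  retained <- stats::setNames(scores$chosen[scores$retained],
                              scores$candidate[scores$retained])
  out <- list(groups = groups, scores = scores, retained = retained,
              screen_pd = config$screen_pd,
              group_threshold = config$group_threshold)
  class(out) <- "selection_report"
  out
}

#' @export
print.selection_report <- function(x, ...) {
  cat("Two-stage Bayesian variable selection\n")
  cat(sprintf("  %d candidates in %d correlation groups (|r| >= %.2f)\n",
              nrow(x$scores), length(x$groups), x$group_threshold))
  cat(sprintf("  retained %d (pd >= %.2f)", length(x$retained), x$screen_pd))
  if (any(x$scores$confounded)) {
    cat("; confounded:", paste(x$scores$candidate[x$scores$confounded],
                               collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

#' Stage-2 joint shrinkage fit of retained covariates
#'
#' Second stage of the variable selection: a joint fit of all retained
#' covariates (at their selected scales) under independent Laplace
#' (double-exponential) priors with a common estimated rate Lambda, given a
#' Uniform hyperprior over the configured bounds. Reporting follows the
#' standard posterior-summary convention; only covariates carried forward
#' from stage 1 appear.
#'
#' @param report A `selection_report` from [screen_stage1()] (or a named
#'   vector of chosen columns via `retained`).
#' @param histories An `encounter_history` data.frame.
#' @param stage Life stage.
#' @param interactions Optional interaction pairs (in terms of the retained
#'   column names), as in [build_stage_model()].
#' @param config A [run_config()].
#' @return A list with `fit` (an `exposure_fit`) and `report` (the
#'   selection report augmented with the Lambda posterior summary).
#' @export
fit_stage2 <- function(report, histories, stage = "nest", interactions = NULL,
                       config = run_config()) {
  retained <- if (inherits(report, "selection_report")) report$retained else report
  if (!length(retained)) stop("retained candidate set is empty")
  model <- build_stage_model(stage, histories, main = unname(retained),
                             interactions = interactions, config = config)
  fit <- fit_stage_model(model)
  lam <- fit$summary[fit$summary$parameter == "Lambda", , drop = FALSE]
  if (inherits(report, "selection_report")) {
    report$lambda_posterior <- lam
    report$final_fit_summary <- fit$summary
  }
  list(fit = fit, report = report)
}
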