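#' MCMC and selection run configuration
#'
#' Bundles sampler settings, selection thresholds and lag-window/scale choices
#' used throughout the pipeline. Two profiles are built in: `"desk"` (the
#' default; chain lengths sized for minutes-scale runs on simulated data) and
#' `"paper"` (50,000 iterations, 25,000 burn-in, thin 10 — the settings used
#' on the full field dataset; the variable-selection population model doubles
#' these).
#'
#' @param iterations Post-burn-in iterations per chain.
#' @param burn_in Burn-in (discarded) iterations per chain; must be less than
#'   `iterations + burn_in` total, i.e. `iterations > 0`.
#' @param thin Thinning interval (>= 1).
#' @param chains Number of chains (>= 2, required for R-hat).
#' @param seed Integer seed recorded in all outputs.
#' @param adapt JAGS adaptation iterations.
#' @param screen_pd Stage-1 screening threshold on the probability of
#'   direction (default 0.80).
#' @param group_threshold Absolute-correlation threshold for covariate
#'   grouping (default 0.65).
#' @param shrink_lower,shrink_upper Uniform prior bounds on the shrinkage
#'   rate Lambda (defaults 0.01 and 10).
#' @param windows Named list of lag-window definitions (default
#'   [lag_windows()]); recorded so the covariate-engineering conventions of a
#'   run are reproducible from its config file.
#' @param scales List with `population` and `life_stage` candidate radii
#'   (default [candidate_scales()] sets).
#' @param paths Optional named list of input/output paths recorded with the
#'   run.
#' @param profile Optional profile name; `"paper"` overrides the sampler
#'   settings with the full-scale values.
#' @return A list of class `run_config`.
#' @export
run_config <- function(iterations = 3000, burn_in = 1000, thin = 2,
                       chains = 2, seed = 1, adapt = 500,
                       screen_pd = 0.80, group_threshold = 0.65,
                       shrink_lower = 0.01, shrink_upper = 10,
                       windows = lag_windows(),
                       scales = list(population = candidate_scales("population"),
                                     life_stage = candidate_scales("life_stage")),
                       paths = list(),
                       profile = c("desk", "paper")) {
  profile <- match.arg(profile)
  if (profile == "paper") {
    iterations <- 50000; burn_in <- 25000; thin <- 10; adapt <- 1000
  }
  cfg <- list(iterations = iterations, burn_in = burn_in, thin = thin,
              chains = chains, seed = as.integer(seed), adapt = adapt,
              screen_pd = screen_pd, group_threshold = group_threshold,
              shrink_lower = shrink_lower, shrink_upper = shrink_upper,
              windows = windows, scales = scales, paths = paths,
              profile = profile)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (cfg$iterations <= 0) stop("iterations must be positive")
  if (cfg$burn_in < 0) stop("burn_in must be non-negative")
  if (cfg$iterations + cfg$burn_in <= cfg$burn_in) stop("iterations must exceed 0")
  if (cfg$thin < 1) stop("thin must be >= 1")
  if (cfg$chains < 2) stop("chains must be >= 2 (required for R-hat)")
  if (cfg$screen_pd <= 0.5 || cfg$screen_pd > 1) stop("screen_pd must be in (0.5, 1]")
  if (cfg$group_threshold <= 0 || cfg$group_threshold >= 1) {
    stop("group_threshold must be in (0, 1)")
  }
  if (cfg$shrink_lower <= 0 || cfg$shrink_upper <= cfg$shrink_lower) {
    stop("shrinkage prior bounds must satisfy 0 < lower < upper")
  }
  class(cfg) <- "run_config"
  cfg
}

#' Write / read a run configuration as YAML
#'
#' Every pipeline output directory gets the resolved configuration (including
#' the seed) written next to it, so a run is reproducible from its artifacts.
#'
#' @param cfg A `run_config`.
#' @param path YAML file path.
#' @return `path` (write) or a validated `run_config` (read).
#' @export
write_run_config <- function(cfg, path) {
  if (!requireNamespace("yaml", quietly = TRUE)) stop("package 'yaml' is required")
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) stop("package 'yaml' is required")
  validate_run_config(yaml::yaml.load_file(path))
}

# per-chain RNG initializers for reproducible JAGS runs
jags_inits <- function(cfg, extra = NULL) {
  lapply(seq_len(cfg$chains), function(ch) {
    c(list(.RNG.name = "base::Mersenne-Twister",
           .RNG.seed = (cfg$seed * 1009L + ch) %% 2147483647L),
      extra)
  })
}
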