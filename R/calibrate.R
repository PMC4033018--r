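#' Empirical coverage of the held-out prediction interval
#'
#' Per replicate: simulate a dataset with no target shift, hold the target
#' species out, fit the allometric regression through the remaining
#' species, compute the `level` prediction interval at the target's x, and
#' record whether the target's (latent species mean) value falls inside.
#' Reports the contained fraction with its binomial standard error. A
#' zero-width band counts as containing an exactly equal value.
#'
#' @param config a `sim_config` (its `target_shift` is forced to 0 and its
#'   seed is ignored in favor of `seed`).
#' @param n_reps number of replicates (>= 100).
#' @param level interval probability.
#' @param gate `"auto"`, `"OLS"` or `"CONTRASTS"` fitting route.
#' @param attachment interval attachment for the held-out species; the
#'   default `"tip"` uses its true position in the simulated tree.
#' @param seed RNG seed for the whole experiment.
#' @return list with `coverage`, `se`, `mean_width` (log10 units),
#'   `n_reps`, `level`.
#' @export
coverage_experiment <- function(config, n_reps = 500, level = 0.95,
                                gate = "CONTRASTS", attachment = "tip",
                                seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (n_reps < 100) stop("use at least 100 replicates", call. = FALSE)
  config$target_shift <- 0
  config$seed <- NULL
  if (is.null(config$tree)) {
    config$tree <- simulate_tree(config$n_tips, config$depth_my, seed = seed)
  }
  if (!is.null(seed)) set.seed(seed)
  contained <- logical(n_reps)
  width <- numeric(n_reps)
  for (i in seq_len(n_reps)) {
    ds <- simulate_dataset(config)
    tr <- ds$truth
    target <- tr$target
    sp <- aggregate_species_means(ds$individuals)
    model <- fit_allometry(sp, config$structure_name, tree = ds$tree,
                           target = target, gate = gate)
    x0 <- part_whole_log_transform(
      10^tr$structure_log_mean[[target]], 10^tr$hemisphere_log[[target]])$x
    band <- predict_with_interval(model, x0, level = level,
                                  attachment = attachment, target = target)
    y <- tr$structure_log_mean[[target]]
    contained[i] <- y >= band$lower - 1e-12 && y <= band$upper + 1e-12
    width[i] <- band$upper - band$lower
  }
  cov <- mean(contained)
  list(coverage = cov, se = sqrt(cov * (1 - cov) / n_reps),
       mean_width = mean(width), n_reps = n_reps, level = level)
}

#' Lambda recovery experiment
#'
#' Simulates `n_reps` datasets under the configured residual model and
#' runs the maximum-likelihood lambda estimator on each (all species,
#' shift forced to 0). Under iid residuals the estimates should pile up at
#' the 0 boundary; under pure Brownian residuals at 1.
#'
#' @param config a `sim_config`.
#' @param n_reps replicates.
#' @param seed RNG seed.
#' @return list with `lambda_hat` (vector), `median`, and `gates` (table
#'   of gate decisions).
#' @export
lambda_experiment <- function(config, n_reps = 200, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  config$target_shift <- 0
  config$seed <- NULL
  if (is.null(config$tree)) {
    config$tree <- simulate_tree(config$n_tips, config$depth_my, seed = seed)
  }
  if (!is.null(seed)) set.seed(seed)
  lam <- numeric(n_reps)
  gates <- character(n_reps)
  for (i in seq_len(n_reps)) {
    ds <- simulate_dataset(config)
    sp <- aggregate_species_means(ds$individuals)
    tv <- part_whole_log_transform(sp[[config$structure_name]],
                                   sp$hemisphere)
    est <- suppressWarnings(
      estimate_lambda(ds$tree, setNames(tv$x, sp$species),
                      setNames(tv$y, sp$species)))
    lam[i] <- est$lambda
    gates[i] <- est$gate
  }
  list(lambda_hat = lam, median = stats::median(lam), gates = table(gates))
}

#' Slope recovery experiment
#'
#' Simulates `n_reps` datasets, fits the OLS path through the reference
#' species of each, and summarizes the recovered slopes against the
#' generator's true slope.
#'
#' @param config a `sim_config`.
#' @param n_reps replicates.
#' @param gate fitting route (default `"OLS"`).
#' @param seed RNG seed.
#' @return list with `slopes`, `mean`, `sd`, `true` (the generator slope).
#' @export
slope_experiment <- function(config, n_reps = 500, gate = "OLS",
                             seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  config$seed <- NULL
  if (is.null(config$tree)) {
    config$tree <- simulate_tree(config$n_tips, config$depth_my, seed = seed)
  }
  if (!is.null(seed)) set.seed(seed)
  slopes <- vapply(seq_len(n_reps), function(i) {
    ds <- simulate_dataset(config)
    sp <- aggregate_species_means(ds$individuals)
    model <- fit_allometry(sp, config$structure_name, tree = ds$tree,
                           target = ds$truth$target, gate = gate)
    model$coef[["slope"]]
  }, numeric(1))
  list(slopes = slopes, mean = mean(slopes), sd = sd(slopes),
       true = config$slope)
}
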