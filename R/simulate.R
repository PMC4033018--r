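#' Simulation configuration for synthetic allometric datasets
#'
#' Collects the generator parameters: the tree (a `phylo` or `NULL` to
#' grow a pure-birth tree), the true allometric line, the residual model
#' (a Brownian-motion component with Pagel-lambda structure plus an iid
#' component), the hemisphere log-volume range the predictors are rescaled
#' to, within-species sampling, and a multiplicative shift for one
#' designated target species. The seed fully determines the output of
#' [simulate_dataset()].
#'
#' Default scales mimic the hominoid analyses that motivated the package:
#' 8 tips (7 reference + 1 target) on a 20-My-deep tree, slope 0.78 and
#' intercept -1.87 (log10 cc), no phylogenetic residual signal
#' (`lambda = 0`, `bm_sd_tip = 0`), iid residual s.d. 0.05 log10 units,
#' hemisphere log-range 1.8-2.8.
#'
#' @param tree `phylo` or `NULL` (simulate with [simulate_tree()]).
#' @param n_tips,depth_my pure-birth tree size and depth (used when `tree`
#'   is `NULL`).
#' @param slope,intercept true allometric line (log10 cc).
#' @param lambda true Pagel's lambda of the Brownian residual component.
#' @param bm_sd_tip tip standard deviation of the Brownian residual
#'   component (log10 cc); the BM rate is `bm_sd_tip^2 / depth`.
#' @param iid_sd s.d. of the independent residual component (log10 cc).
#' @param hemisphere_log_range length-2 range the simulated hemisphere
#'   log10 volumes are affinely rescaled to.
#' @param n_individuals specimens drawn per species.
#' @param within_sd within-species lognormal s.d. (log10 cc).
#' @param target target species label (default: last tip).
#' @param target_shift additive log10 shift of the target species mean
#'   (e.g. `log10(1.5)` for a 1.5-fold enlargement).
#' @param structure_name column name for the simulated structure.
#' @param seed RNG seed or `NULL`.
#' @return a `sim_config` list.
#' @export
sim_config <- function(tree = NULL, n_tips = 8, depth_my = 20,
                       slope = 0.78, intercept = -1.87, lambda = 0,
                       bm_sd_tip = 0, iid_sd = 0.05,
                       hemisphere_log_range = c(1.8, 2.8),
                       n_individuals = 1, within_sd = 0,
                       target = NULL, target_shift = 0,
                       structure_name = "structure", seed = NULL) {
  stopifnot(is.null(tree) || inherits(tree, "phylo"),
            n_tips >= 2, depth_my > 0,
            lambda >= 0, lambda <= 1,
            bm_sd_tip >= 0, iid_sd >= 0, within_sd >= 0,
            length(hemisphere_log_range) == 2,
            diff(hemisphere_log_range) >= 0,
            n_individuals >= 1)
  structure(list(tree = tree, n_tips = n_tips, depth_my = depth_my,
                 slope = slope, intercept = intercept, lambda = lambda,
                 bm_sd_tip = bm_sd_tip, iid_sd = iid_sd,
                 hemisphere_log_range = hemisphere_log_range,
                 n_individuals = n_individuals, within_sd = within_sd,
                 target = target, target_shift = target_shift,
                 structure_name = structure_name, seed = seed),
            class = "sim_config")
}

#' Preset simulation configurations
#'
#' `"hominoid"`: 8 tips, 20 My, slope 0.78 / intercept -1.87, two
#' individuals per species with 0.02 within-species s.d.
#' `"anthropoid"`: 26 tips, 40 My, slope 0.69 / intercept -1.77, one
#' individual per species, wider hemisphere range.
#'
#' @param name preset name.
#' @param ... overrides passed to [sim_config()].
#' @return a `sim_config`.
#' @export
sim_preset <- function(name = c("hominoid", "anthropoid"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    hominoid = list(n_tips = 8, depth_my = 20, slope = 0.78,
                    intercept = -1.87, hemisphere_log_range = c(1.8, 2.8),
                    n_individuals = 2, within_sd = 0.02),
    anthropoid = list(n_tips = 26, depth_my = 40, slope = 0.69,
                      intercept = -1.77, hemisphere_log_range = c(0.5, 2.8),
                      n_individuals = 1, within_sd = 0))
  do.call(sim_config, utils::modifyList(base, list(...)))
}

#' Simulate a pure-birth ultrametric tree
#'
#' A Yule (pure-birth) tree conditioned on `n_tips`, rescaled so every
#' root-to-tip path equals `depth_my`.
#'
#' @param n_tips number of tips (>= 2).
#' @param depth_my tree depth in millions of years.
#' @param seed optional RNG seed; the same seed gives the same Newick.
#' @return a `phylo` with tips `sp01`, `sp02`, ...
#' @export
simulate_tree <- function(n_tips, depth_my = 20, seed = NULL) {
  if (n_tips < 2) stop("need at least 2 tips", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  phy <- ape::rphylo(n_tips, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(phy))
  phy$edge.length <- phy$edge.length * depth_my / depth
  phy$tip.label <- sprintf("sp%02d", seq_len(n_tips))
  annotate_depth(phy)
}

# Draw one multivariate normal vector given the upper Cholesky factor
# (or NULL for a zero covariance).
draw_mvn <- function(U, n) {
  if (is.null(U)) return(numeric(n))
  drop(crossprod(U, rnorm(n)))
}

# Residual covariance implied by a sim_config on covariance V:
# BM rate * lambda-transformed V + iid variance on the diagonal.
residual_chol <- function(config, V) {
  depth <- max(diag(V))
  rate <- if (config$bm_sd_tip > 0) config$bm_sd_tip^2 / depth else 0
  Sigma <- rate * lambda_transform(V, config$lambda)
  diag(Sigma) <- diag(Sigma) + config$iid_sd^2
  if (max(abs(Sigma)) == 0) return(NULL)
  chol(Sigma)
}

# Solve the part-whole fixed point: mu satisfies
#   mu = a + b * log10(10^h - 10^mu) + r
# for one species. Returns NA when the structure would not fit inside the
# hemisphere.
solve_structure_mean <- function(a, b, h, r, tol = 1e-10, max_iter = 200) {
  mu <- a + b * h + r  # ignore part-whole coupling for the start value
  if (mu >= h) return(NA_real_)
  for (i in seq_len(max_iter)) {
    new <- a + b * log10(10^h - 10^mu) + r
    if (!is.finite(new) || new >= h) return(NA_real_)
    if (abs(new - mu) < tol) return(new)
    mu <- new
  }
  NA_real_
}

#' Simulate a synthetic allometric dataset
#'
#' Generates species hemisphere log-volumes by Brownian motion on the tree
#' (affinely rescaled to the configured range), species structure means on
#' the true allometric line of the part-whole-corrected predictor (solved
#' by fixed-point iteration, since the structure appears on both sides of
#' the transform) plus a phylogenetically structured residual, shifts the
#' designated target species by `target_shift`, and draws individuals
#' lognormally around the species means. Draws for which the structure
#' would not fit inside the hemisphere are resampled (error after 100
#' failures).
#'
#' @param config a `sim_config`.
#' @return a `synthetic_dataset`: list with `tree`, `individuals` (an
#'   `individual_table`), and `truth` (generator parameters plus latent
#'   per-species values, sufficient to recompute expected estimates).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  tree <- if (is.null(config$tree)) {
    simulate_tree(config$n_tips, config$depth_my)
  } else config$tree
  tips <- tree$tip.label
  n <- length(tips)
  target <- if (is.null(config$target)) tips[n] else config$target
  if (!target %in% tips) stop("target species not in tree", call. = FALSE)
  V <- bm_covariance(tree)
  Uh <- chol(V)
  Ur <- residual_chol(config, V)

  # hemisphere log-volumes: BM draw rescaled into the configured range
  z <- draw_mvn(Uh, n)
  rng <- config$hemisphere_log_range
  h <- if (diff(range(z)) > 0) {
    rng[1] + (z - min(z)) / diff(range(z)) * diff(rng)
  } else {
    rep(mean(rng), n)
  }
  names(h) <- tips

  shift <- ifelse(tips == target, config$target_shift, 0)
  for (attempt in seq_len(100)) {
    r <- draw_mvn(Ur, n)
    mu <- vapply(seq_len(n), function(i) {
      solve_structure_mean(config$intercept, config$slope, h[i],
                           r[i] + shift[i])
    }, numeric(1))
    if (!anyNA(mu)) break
    if (attempt == 1) {
      warning("structure exceeded hemisphere volume; resampling residuals")
    }
    if (attempt == 100) {
      stop("structure exceeds hemisphere volume after 100 resampling ",
           "attempts; shrink the residual scales or the shift",
           call. = FALSE)
    }
  }
  names(mu) <- tips

  k <- config$n_individuals
  rows <- lapply(tips, function(sp) {
    data.frame(species = sp,
               specimen_id = sprintf("i%02d", seq_len(k)),
               vol = 10^(mu[sp] + rnorm(k, 0, config$within_sd)),
               hemisphere = 10^(h[sp] + rnorm(k, 0, config$within_sd)),
               stringsAsFactors = FALSE)
  })
  ind <- do.call(rbind, rows)
  names(ind)[names(ind) == "vol"] <- config$structure_name
  ind <- validate_individual_table(ind, structures = config$structure_name)

  structure(list(tree = tree, individuals = ind,
                 truth = list(config = config, target = target,
                              hemisphere_log = h, structure_log_mean = mu,
                              residual = r)),
            class = "synthetic_dataset")
}

#' Write a synthetic dataset in the loader formats
#'
#' CSV specimen table, Newick tree, and a JSON truth record.
#'
#' @param ds a `synthetic_dataset`.
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
write_synthetic_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "individuals.csv")
  nwk <- file.path(dir, "tree.nwk")
  json <- file.path(dir, "truth.json")
  df <- as.data.frame(ds$individuals)
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) df[[j]] <- format(df[[j]], digits = 17)
  write.csv(df, csv, row.names = FALSE, quote = FALSE)
  ape::write.tree(ds$tree, nwk)
  truth <- ds$truth
  truth$config$tree <- NULL  # the tree is serialized separately
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, json, auto_unbox = TRUE, digits = I(15),
                       null = "null", pretty = TRUE)
  invisible(c(individuals = csv, tree = nwk, truth = json))
}
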