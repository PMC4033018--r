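#' Assemble and validate an end-to-end pipeline configuration
#'
#' @param data an `individual_table`, a `species_trait_table`, or a path to
#'   a specimen CSV/TSV readable by [read_trait_table()].
#' @param tree a `phylo` or a Newick file path.
#' @param target target species name (must be present in the data).
#' @param structures structure columns to analyze; default: all structure
#'   columns in the data.
#' @param hemisphere_col hemisphere volume column.
#' @param laterality passed to [read_trait_table()] when `data` is a path.
#' @param level prediction-interval probability (default 0.95).
#' @param gate `"auto"`, `"OLS"` or `"CONTRASTS"`.
#' @param attachment interval attachment for the target species.
#' @param outlier_screen run [detect_outlier_taxon()] per structure when
#'   individual-level residuals allow it.
#' @param output_dir optional directory for TSV/JSON reports.
#' @param seed optional seed (recorded; the analysis itself is
#'   deterministic).
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(data, tree, target, structures = NULL,
                            hemisphere_col = "hemisphere",
                            laterality = NULL, level = 0.95,
                            gate = c("auto", "OLS", "CONTRASTS"),
                            attachment = c("auto", "tip", "root"),
                            outlier_screen = FALSE, output_dir = NULL,
                            seed = NULL) {
  gate <- match.arg(gate)
  attachment <- match.arg(attachment)
  if (is.character(data) && length(data) == 1L) {
    data <- read_trait_table(data, laterality = laterality,
                             hemisphere_col = hemisphere_col)
    hemisphere_col <- "hemisphere"
  }
  if (is.character(tree) && length(tree) == 1L) tree <- read_phylo(tree)
  if (inherits(data, "individual_table")) {
    individuals <- data
    species <- aggregate_species_means(data)
  } else {
    individuals <- NULL
    species <- data
  }
  if (is.null(structures)) {
    structures <- attr(species, "structures")
    if (is.null(structures)) {
      structures <- setdiff(names(species),
                            c("species", hemisphere_col,
                              grep("^n_", names(species), value = TRUE)))
    }
  }
  if (length(structures) == 0) stop("empty structure list", call. = FALSE)
  miss <- setdiff(structures, names(species))
  if (length(miss)) {
    stop("structure column(s) not in data: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!target %in% species$species) {
    stop("target species '", target, "' not present in the data",
         call. = FALSE)
  }
  structure(list(individuals = individuals, species = species, tree = tree,
                 target = target, structures = structures,
                 hemisphere_col = hemisphere_col, level = level,
                 gate = gate, attachment = attachment,
                 outlier_screen = outlier_screen, output_dir = output_dir,
                 seed = seed),
            class = "pipeline_config")
}

#' Run the allometric-deviation pipeline
#'
#' For each requested structure: aggregate specimens to species means,
#' apply the part-whole log transform, estimate the lambda gate on the
#' reference species, fit the gated regression (target excluded), compute
#' the prediction interval at the target's x, classify the target, and —
#' when at least two target individuals carry both volumes — run the
#' mean-residual t-test. Structures with fewer than 4 usable reference
#' species are skipped with a warning. Gate decisions and exclusions are
#' collected in `$log`.
#'
#' @param config a `pipeline_config` (or arguments for one, via `...`).
#' @param ... used to build a config when `config` is not one already.
#' @return list with `report` (a `structure_report`), `calls`, `models`,
#'   `tests`, `outliers`, `log`, and (if `output_dir` was set) `files`.
#' @export
run_pipeline <- function(config, ...) {
  if (!inherits(config, "pipeline_config")) {
    config <- pipeline_config(config, ...)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  sp <- config$species
  target <- config$target
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  calls <- list(); models <- list(); tests <- list(); outliers <- list()
  for (s in config$structures) {
    usable <- sp$species[!is.na(sp[[s]]) & !is.na(sp[[config$hemisphere_col]])]
    refs <- setdiff(usable, target)
    if (length(refs) < 4) {
      warning("skipping '", s, "': only ", length(refs),
              " reference species with data")
      note("SKIP %s: %d reference species", s, length(refs))
      next
    }
    if (!target %in% usable) {
      warning("skipping '", s, "': target has no usable data")
      note("SKIP %s: target lacks data", s)
      next
    }
    model <- fit_allometry(sp, s, tree = config$tree, reference = refs,
                           target = target, gate = config$gate,
                           hemisphere_col = config$hemisphere_col)
    note("FIT %s: mode=%s lambda=%s n=%d", s, model$mode,
         if (!is.null(model$lambda)) sprintf("%.3f", model$lambda$lambda)
         else "forced", model$n)
    ti <- match(target, sp$species)
    tv <- part_whole_log_transform(sp[[s]][ti],
                                   sp[[config$hemisphere_col]][ti])
    calls[[s]] <- classify_target(model, sp[[s]][ti], tv$x,
                                  level = config$level,
                                  attachment = config$attachment,
                                  target = target)
    note("CALL %s: %s (%.0f%%)", s, calls[[s]]$classification,
         calls[[s]]$percent_residual)
    models[[s]] <- model

    if (!is.null(config$individuals)) {
      ind <- config$individuals
      lat <- attr(ind, "laterality")
      tr <- ind[ind$species == target, ]
      vols <- tr[[s]]
      if (!is.null(lat) && identical(lat[[s]], "bilateral_sum")) {
        vols <- vols / 2
      }
      pairs <- data.frame(volume = vols, hemisphere = tr$hemisphere)
      pairs <- pairs[!is.na(pairs$volume) & !is.na(pairs$hemisphere), ]
      if (nrow(pairs) >= 2) {
        tests[[s]] <- test_mean_residual(model, pairs)
        note("TTEST %s: t=%.2f p=%.3g", s, tests[[s]]$t, tests[[s]]$p)
      }
      if (isTRUE(config$outlier_screen)) {
        res_by_sp <- reference_residuals(model, ind, s, refs,
                                         hemisphere_col = "hemisphere",
                                         laterality = lat)
        enough <- sum(lengths(res_by_sp) >= 2) >= 3
        if (enough) {
          outliers[[s]] <- suppressWarnings(
            detect_outlier_taxon(res_by_sp))
          note("OUTLIER %s: flagged=%s", s,
               paste(outliers[[s]]$flagged, collapse = ","))
        }
      }
    }
  }
  if (length(calls) == 0) stop("no structure could be analyzed", call. = FALSE)
  report <- build_report(calls, models,
                         tests = if (length(tests)) tests else NULL)
  out <- list(report = report, calls = calls, models = models,
              tests = tests, outliers = outliers, log = log_lines)
  if (!is.null(config$output_dir)) {
    out$files <- write_report(report, config$output_dir)
    writeLines(log_lines, file.path(config$output_dir, "pipeline_log.txt"))
  }
  out
}

# Per-individual log10 residuals from a fitted model, grouped by species.
reference_residuals <- function(model, individuals, structure, species,
                                hemisphere_col = "hemisphere",
                                laterality = NULL) {
  out <- list()
  for (sp in species) {
    rows <- individuals[individuals$species == sp, ]
    v <- rows[[structure]]
    if (!is.null(laterality) && identical(laterality[[structure]],
                                          "bilateral_sum")) {
      v <- v / 2
    }
    h <- rows[[hemisphere_col]]
    ok <- !is.na(v) & !is.na(h)
    if (!any(ok)) next
    tv <- part_whole_log_transform(v[ok], h[ok])
    out[[sp]] <- tv$y - (model$coef[["intercept"]] +
                         model$coef[["slope"]] * tv$x)
  }
  out
}

#' Run a calibration experiment
#'
#' Dispatches to the synthetic-data experiments and returns their summary.
#'
#' @param config a `sim_config`.
#' @param experiment `"coverage"`, `"lambda"`, or `"slope"`.
#' @param n_reps replicates (defaults per experiment).
#' @param seed RNG seed.
#' @param ... passed to the experiment function.
#' @return the experiment's summary list, with a `summary` data.frame
#'   attached.
#' @export
run_calibration <- function(config,
                            experiment = c("coverage", "lambda", "slope"),
                            n_reps = NULL, seed = NULL, ...) {
  experiment <- match.arg(experiment)
  res <- switch(experiment,
    coverage = {
      n <- if (is.null(n_reps)) 500 else n_reps
      coverage_experiment(config, n_reps = n, seed = seed, ...)
    },
    lambda = {
      n <- if (is.null(n_reps)) 200 else n_reps
      lambda_experiment(config, n_reps = n, seed = seed, ...)
    },
    slope = {
      n <- if (is.null(n_reps)) 500 else n_reps
      slope_experiment(config, n_reps = n, seed = seed, ...)
    })
  res$summary <- switch(experiment,
    coverage = data.frame(metric = c("coverage", "se", "mean_width"),
                          value = c(res$coverage, res$se, res$mean_width)),
    lambda = data.frame(metric = c("median_lambda"), value = res$median),
    slope = data.frame(metric = c("mean_slope", "sd_slope", "true_slope"),
                       value = c(res$mean, res$sd, res$true)))
  res
}
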