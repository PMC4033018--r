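#' Classify an observed volume against a prediction band
#'
#' Lower-level companion to [classify_target()]: compares
#' `log10(y_obs_cc)` with explicit log10 interval bounds (e.g. bounds
#' quoted from a published table) and returns the same call object.
#'
#' @param y_obs_cc observed volume, cc.
#' @param lower,upper log10 prediction bounds.
#' @param y_hat optional log10 fitted value; enables the percent residual.
#' @param one_sided_upper optional log10 one-sided upper bound for the
#'   upper-tail flag.
#' @param structure label carried into the call.
#' @return a `deviation_call`.
#' @export
classify_in_band <- function(y_obs_cc, lower, upper, y_hat = NULL,
                             one_sided_upper = NULL, structure = NA_character_) {
  if (!is.finite(y_obs_cc) || y_obs_cc <= 0) {
    stop("observed volume must be positive", call. = FALSE)
  }
  if (lower > upper) stop("lower bound exceeds upper bound", call. = FALSE)
  y <- log10(y_obs_cc)
  classification <- if (y > upper) {
    "significantly_above"
  } else if (y < lower) {
    "significantly_below"
  } else "within"
  upper_tail <- classification == "within" &&
    !is.null(one_sided_upper) && y > one_sided_upper
  y_pred <- if (!is.null(y_hat)) 10^y_hat else NA_real_
  pct <- if (!is.null(y_hat)) percent_residual(y_obs_cc, y_pred) else NA_real_
  structure(list(structure = structure, y_obs = y_obs_cc, y_pred = y_pred,
                 percent_residual = pct, log_obs = y,
                 band = list(lower = lower, upper = upper, y_hat = y_hat),
                 classification = classification,
                 upper_tail_flag = isTRUE(upper_tail)),
            class = "deviation_call")
}

#' Classify the target species against the fitted allometry
#'
#' Predicts the structure volume for the target species at its own
#' part-whole-corrected hemisphere volume, compares the observed value
#' with the two-sided prediction interval (in log space; the verdict is
#' identical in arithmetic space since 10^ is monotone), and reports the
#' percent residual on untransformed volumes. A target falling inside the
#' two-sided interval but beyond the one-sided `level` upper bound gets
#' `upper_tail_flag = TRUE` ("within the upper tail of predicted values").
#'
#' @param model an `allometric_model` whose reference set excludes the
#'   target.
#' @param target_obs observed target structure volume, cc.
#' @param target_x0 target predictor value, log10 cc (from
#'   [part_whole_log_transform()]).
#' @param level interval probability (default 0.95).
#' @param attachment,target passed to [predict_with_interval()].
#' @return a `deviation_call`: observed and predicted cc, percent residual,
#'   the band, a classification in `significantly_above` / `within` /
#'   `significantly_below`, and the upper-tail flag.
#' @export
classify_target <- function(model, target_obs, target_x0, level = 0.95,
                            attachment = c("auto", "tip", "root"),
                            target = NULL) {
  stopifnot(inherits(model, "allometric_model"))
  if (!is.null(target) && target %in% model$reference) {
    stop("target species is in the model's reference set", call. = FALSE)
  }
  band <- predict_with_interval(model, target_x0, level = level,
                                attachment = attachment, target = target)
  one_sided <- band$y_hat + qt(level, band$df) * band$se
  call <- classify_in_band(target_obs, band$lower, band$upper,
                           y_hat = band$y_hat, one_sided_upper = one_sided,
                           structure = model$structure)
  call$band <- band
  call
}

#' @export
print.deviation_call <- function(x, ...) {
  cat(sprintf("Deviation call%s: %s\n",
              if (is.na(x$structure)) "" else paste0(" [", x$structure, "]"),
              x$classification))
  cat(sprintf("  observed %.3f cc (log10 %.3f); band [%.3f, %.3f] log10\n",
              x$y_obs, x$log_obs,
              if (is.list(x$band)) x$band$lower else NA,
              if (is.list(x$band)) x$band$upper else NA))
  if (!is.na(x$percent_residual)) {
    cat(sprintf("  percent residual: %.1f%%%s\n", x$percent_residual,
                if (x$upper_tail_flag) "  (upper tail)" else ""))
  }
  invisible(x)
}

#' One-sample t-test of mean target residual
#'
#' When several target individuals carry both structure and hemisphere
#' volumes, each individual's log10 residual from the reference regression
#' is computed at that individual's own part-whole-corrected x, and the
#' mean residual is tested against zero with a two-sided one-sample
#' t-test. More sensitive than the interval check, especially under the
#' (conservative) contrasts intervals.
#'
#' @param model an `allometric_model`.
#' @param individuals data.frame with columns `volume` and `hemisphere`
#'   (cc), one row per target individual.
#' @return a `mean_residual_test`: residuals, mean residual, `t`, `df`,
#'   two-sided `p`, and the mean percent residual
#'   (mean observed vs mean predicted, arithmetic).
#' @export
test_mean_residual <- function(model, individuals) {
  stopifnot(inherits(model, "allometric_model"))
  v <- individuals$volume
  h <- individuals$hemisphere
  ok <- !is.na(v) & !is.na(h)
  v <- v[ok]; h <- h[ok]
  if (length(v) < 2) {
    stop("need >= 2 target individuals with both volumes; ",
         "use classify_target() for a single observation", call. = FALSE)
  }
  tv <- part_whole_log_transform(v, h)
  pred <- model$coef[["intercept"]] + model$coef[["slope"]] * tv$x
  res <- tv$y - pred
  eps <- 1e-10 * max(1, abs(tv$y))  # guard against pure rounding noise
  if (sd(res) <= eps) {
    m0 <- if (abs(mean(res)) <= eps) 0 else mean(res)
    tt <- list(statistic = if (m0 == 0) 0 else sign(m0) * Inf,
               parameter = length(res) - 1,
               p.value = if (m0 == 0) 1 else 0)
  } else {
    tt <- t.test(res, mu = 0, alternative = "two.sided")
  }
  structure(list(residuals = res, mean_residual = mean(res),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value,
                 mean_percent_residual = percent_residual(mean(v),
                                                          mean(10^pred)),
                 n = length(res)),
            class = "mean_residual_test")
}

#' @export
print.mean_residual_test <- function(x, ...) {
  cat(sprintf(
    "Mean residual t-test: mean = %+.4f log10 cc (%.0f%%), t = %.2f, df = %d, p = %.3g\n",
    x$mean_residual, x$mean_percent_residual, x$t, x$df, x$p))
  invisible(x)
}

#' Screen for an outlier taxon among reference residuals
#'
#' One-way ANOVA of per-individual regression residuals across species;
#' when the ANOVA is significant, Tukey HSD pairwise comparisons follow
#' and any species whose residuals differ from those of every other
#' species at `alpha` is flagged. Species with fewer than two individuals
#' are excluded with a warning. If refit arguments are supplied, the model
#' is refitted with flagged species removed from the reference set.
#'
#' @param residuals_by_species named list of numeric residual vectors, one
#'   per species.
#' @param alpha significance threshold (default 0.05).
#' @param fit_args optional list of arguments to [fit_allometry()]; when
#'   given and species are flagged, a refit excluding them is attached as
#'   `$refit`.
#' @return an `outlier_report`: ANOVA `F`, `df`, `p`, symmetric Tukey HSD
#'   p-value matrix, `flagged`, `excluded`, and optionally `refit`.
#' @export
detect_outlier_taxon <- function(residuals_by_species, alpha = 0.05,
                                 fit_args = NULL) {
  stopifnot(is.list(residuals_by_species),
            !is.null(names(residuals_by_species)))
  sizes <- lengths(residuals_by_species)
  excluded <- names(residuals_by_species)[sizes < 2]
  if (length(excluded)) {
    warning("excluding species with a single individual: ",
            paste(excluded, collapse = ", "))
  }
  keep <- residuals_by_species[sizes >= 2]
  if (length(keep) < 3) {
    stop("need residuals for at least 3 species with >= 2 individuals",
         call. = FALSE)
  }
  species <- factor(rep(names(keep), lengths(keep)), levels = names(keep))
  res <- unlist(keep, use.names = FALSE)
  k <- nlevels(species)
  tukey_p <- matrix(NA_real_, k, k,
                    dimnames = list(levels(species), levels(species)))
  if (var(res) == 0) {
    return(structure(list(F = NA_real_, df = c(k - 1, length(res) - k),
                          p = NA_real_, tukey_p = tukey_p,
                          flagged = character(0), excluded = excluded),
                     class = "outlier_report"))
  }
  fit <- aov(res ~ species)
  an <- summary(fit)[[1]]
  Fval <- an[["F value"]][1]
  pval <- an[["Pr(>F)"]][1]
  flagged <- character(0)
  if (is.finite(pval) && pval < alpha) {
    hsd <- TukeyHSD(fit, "species")$species
    pairs <- strsplit(rownames(hsd), "-", fixed = TRUE)
    for (i in seq_along(pairs)) {
      aSp <- pairs[[i]][1]; bSp <- pairs[[i]][2]
      tukey_p[aSp, bSp] <- tukey_p[bSp, aSp] <- hsd[i, "p adj"]
    }
    flagged <- names(keep)[vapply(names(keep), function(sp) {
      others <- setdiff(names(keep), sp)
      all(tukey_p[sp, others] < alpha)
    }, logical(1))]
  }
  out <- list(F = Fval, df = c(k - 1, length(res) - k), p = pval,
              tukey_p = tukey_p, flagged = flagged, excluded = excluded)
  if (length(flagged) && !is.null(fit_args)) {
    fit_args$reference <- setdiff(
      if (!is.null(fit_args$reference)) fit_args$reference else
        setdiff(fit_args$data$species, fit_args$target),
      flagged)
    out$refit <- do.call(fit_allometry, fit_args)
  }
  structure(out, class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("Outlier-taxon screen: F(%d, %d) = %.2f, p = %.3g\n",
              x$df[1], x$df[2], x$F, x$p))
  cat("  flagged:",
      if (length(x$flagged)) paste(x$flagged, collapse = ", ") else "none",
      "\n")
  invisible(x)
}
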