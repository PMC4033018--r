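#' Part-whole log transform
#'
#' Builds the regression variables for structure-on-hemisphere allometry:
#' the response is `log10(structure volume)` and the predictor is
#' `log10(hemisphere volume - structure volume)`, so the structure is
#' never regressed against a total containing itself.
#'
#' @param structure structure volume(s), cc; must satisfy
#'   `0 < structure < hemisphere`.
#' @param hemisphere hemisphere volume(s), cc.
#' @return list with `x` (log10 corrected hemisphere volume) and `y`
#'   (log10 structure volume); names are preserved.
#' @export
#' @examples
#' part_whole_log_transform(1, 11)  # x = 1, y = 0
part_whole_log_transform <- function(structure, hemisphere) {
  if (any(is.na(structure)) || any(is.na(hemisphere))) {
    stop("missing volumes in part-whole transform", call. = FALSE)
  }
  if (any(structure <= 0) || any(hemisphere <= 0)) {
    stop("volumes must be strictly positive", call. = FALSE)
  }
  if (any(structure >= hemisphere)) {
    stop("structure volume must be smaller than hemisphere volume",
         call. = FALSE)
  }
  list(x = log10(hemisphere - structure), y = log10(structure))
}

#' Percent residual deviation
#'
#' The deviation statistic reported throughout: `(obs - pred)/obs * 100`,
#' computed on untransformed (arithmetic) volumes. It cannot exceed 100
#' (observed can be at most 100% of itself above prediction) but is
#' unbounded below.
#'
#' @param y_obs observed volume (cc), > 0.
#' @param y_pred predicted volume (cc), > 0.
#' @return percent residual.
#' @export
#' @examples
#' percent_residual(2, 1)    #  50
#' percent_residual(1, 2)    # -100
percent_residual <- function(y_obs, y_pred) {
  if (any(!is.finite(y_obs)) || any(!is.finite(y_pred)) ||
      any(y_obs <= 0) || any(y_pred <= 0)) {
    stop("observed and predicted volumes must be positive", call. = FALSE)
  }
  (y_obs - y_pred) / y_obs * 100
}

#' Fit the allometric regression through reference species
#'
#' Applies the part-whole log transform to species means and fits the
#' scaling line through the reference species only (the target species, if
#' named, is excluded). With `gate = "auto"` Pagel's lambda is estimated
#' on the reference data and routes the fit: ordinary least squares when
#' the residuals carry no phylogenetic signal, independent contrasts
#' (equivalently, GLS under Brownian motion) when they evolve as Brownian
#' motion. In contrasts mode the slope is the through-origin regression of
#' y-contrasts on x-contrasts and the intercept passes the line through the
#' root ancestral estimates of x and y.
#'
#' @param data a `species_trait_table` (or data.frame with `species`,
#'   the structure column, and `hemisphere`).
#' @param structure name of the structure column.
#' @param tree a `phylo` tree containing the reference species (required
#'   for `gate = "auto"` or `"CONTRASTS"`); a larger tree also containing
#'   the target species enables tip-position prediction later.
#' @param reference character vector of reference species; default all
#'   species with data except `target`.
#' @param target species to exclude (and later classify); optional.
#' @param gate `"auto"`, `"OLS"`, or `"CONTRASTS"`.
#' @param hemisphere_col name of the hemisphere volume column.
#' @return an `allometric_model`.
#' @export
fit_allometry <- function(data, structure, tree = NULL, reference = NULL,
                          target = NULL, gate = c("auto", "OLS", "CONTRASTS"),
                          hemisphere_col = "hemisphere") {
  gate <- match.arg(gate)
  if (!structure %in% names(data)) {
    stop("structure column '", structure, "' not found", call. = FALSE)
  }
  if (!hemisphere_col %in% names(data)) {
    stop("hemisphere column '", hemisphere_col, "' not found", call. = FALSE)
  }
  have <- !is.na(data[[structure]]) & !is.na(data[[hemisphere_col]])
  avail <- data$species[have]
  if (is.null(reference)) reference <- setdiff(avail, target)
  if (!is.null(target) && target %in% reference) {
    stop("target species must be excluded from the reference set",
         call. = FALSE)
  }
  miss <- setdiff(reference, avail)
  if (length(miss)) {
    stop("reference species without usable data: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  n <- length(reference)
  if (n < 4) {
    stop("need at least 4 reference species (got ", n, ")", call. = FALSE)
  }
  if (n == 4) {
    warning("only 4 reference species; regression will have little power")
  }
  idx <- match(reference, data$species)
  tv <- part_whole_log_transform(data[[structure]][idx],
                                 data[[hemisphere_col]][idx])
  x <- setNames(tv$x, reference)
  y <- setNames(tv$y, reference)

  lambda_rec <- NULL
  if (gate == "auto") {
    if (is.null(tree)) stop("gate = 'auto' requires a tree", call. = FALSE)
    lambda_rec <- estimate_lambda(tree, x, y)
    mode <- lambda_rec$gate
  } else {
    mode <- gate
  }

  model <- list(mode = mode, structure = structure, reference = reference,
                n = n, x = x, y = y, lambda = lambda_rec,
                tree_full = tree)
  if (mode == "OLS") {
    fit <- lm(y ~ x)
    s <- suppressWarnings(summary(fit))  # quiet on numerically perfect fits
    rss <- sum(fit$residuals^2)
    model$coef <- setNames(unname(coef(fit)), c("intercept", "slope"))
    model$s2 <- rss / (n - 2)
    model$R2 <- s$r.squared
    model$p <- pf(s$fstatistic[1], s$fstatistic[2], s$fstatistic[3],
                  lower.tail = FALSE)
    model$xbar <- mean(x)
    model$Sxx <- sum((x - mean(x))^2)
  } else {
    if (is.null(tree)) stop("contrasts mode requires a tree", call. = FALSE)
    tree_ref <- prune_to_species(tree, reference)
    cs <- compute_contrasts(tree_ref, cbind(x = x, y = y))
    cx <- cs$contrasts[, "x"]; cy <- cs$contrasts[, "y"]
    sxx <- sum(cx^2)
    if (sxx == 0) stop("x contrasts are all zero; slope undefined",
                       call. = FALSE)
    b <- sum(cx * cy) / sxx
    a <- cs$root_values[["y"]] - b * cs$root_values[["x"]]
    rss <- sum((cy - b * cx)^2)
    model$coef <- c(intercept = a, slope = b)
    model$s2 <- rss / (n - 2)
    syy <- sum(cy^2)
    model$R2 <- if (syy > 0) sum(cx * cy)^2 / (sxx * syy) else 1
    model$p <- if (model$s2 > 0) {
      pf(b^2 * sxx / model$s2, 1, n - 2, lower.tail = FALSE)
    } else 0
    model$tree_ref <- tree_ref
    model$contrasts <- cs
    model$V <- bm_covariance(tree_ref, reference)
  }
  class(model) <- "allometric_model"
  model
}

#' @export
print.allometric_model <- function(x, ...) {
  eq <- sprintf("y = %.2fx%s%.2f", x$coef[["slope"]],
                if (x$coef[["intercept"]] < 0) "-" else "+",
                abs(x$coef[["intercept"]]))
  cat(sprintf("Allometric model (%s) for '%s': %s\n", x$mode, x$structure, eq))
  cat(sprintf("  n = %d reference species, R2 = %.3f, p = %.3g\n",
              x$n, x$R2, x$p))
  if (!is.null(x$lambda)) {
    cat(sprintf("  lambda gate: lambda_hat = %.3f -> %s\n",
                x$lambda$lambda, x$lambda$gate))
  }
  invisible(x)
}

#' Prediction interval for a new species
#'
#' Computes the fitted value and a new-observation prediction interval at
#' `x0`, in log10 space, and maps the triple back to arithmetic volumes by
#' exponentiation. In OLS mode this is the classical interval
#' `y_hat +/- t * s * sqrt(1 + 1/n + (x0 - xbar)^2/Sxx)`. In contrasts
#' mode it is the exact GLS conditional prediction for a new tip under the
#' Brownian covariance: the conditional mean given the reference species'
#' residuals and the conditional variance including coefficient
#' uncertainty, with a t quantile on `n - 2` degrees of freedom. The new
#' tip's covariance with the references is taken from its true position in
#' the supplied full tree (`attachment = "tip"`, requires `target`), or it
#' is treated as a fresh lineage branching at the root
#' (`attachment = "root"`), sharing no history with the references.
#'
#' @param model an `allometric_model`.
#' @param x0 predictor value (log10 cc).
#' @param level interval probability (default 0.95).
#' @param attachment `"auto"` (tip when `target` is given and present in
#'   the model's full tree, else root), `"tip"`, or `"root"`. Ignored in
#'   OLS mode.
#' @param target target species name, for tip attachment.
#' @return a `prediction_band`: list with `x0`, `y_hat`, `lower`, `upper`,
#'   `level`, `se`, `df`, and `arithmetic` (10^ of the triple, cc).
#' @export
predict_with_interval <- function(model, x0, level = 0.95,
                                  attachment = c("auto", "tip", "root"),
                                  target = NULL) {
  stopifnot(inherits(model, "allometric_model"))
  attachment <- match.arg(attachment)
  if (!is.numeric(level) || level <= 0 || level >= 1) {
    stop("level must be in (0, 1)", call. = FALSE)
  }
  n <- model$n
  df <- n - 2
  a <- model$coef[["intercept"]]; b <- model$coef[["slope"]]
  if (model$mode == "OLS") {
    y_hat <- a + b * x0
    se <- sqrt(model$s2 * (1 + 1 / n + (x0 - model$xbar)^2 / model$Sxx))
  } else {
    refs <- model$reference
    V <- model$V
    in_tree <- function(tr, sp) {
      !is.null(tr) && normalize_taxon(sp) %in% normalize_taxon(tr$tip.label)
    }
    use_tip <- switch(attachment,
      tip = TRUE,
      root = FALSE,
      auto = !is.null(target) && in_tree(model$tree_full, target))
    if (use_tip) {
      if (is.null(target) || !in_tree(model$tree_full, target)) {
        stop("tip attachment requires a full tree containing the target",
             call. = FALSE)
      }
      Vall <- bm_covariance(model$tree_full, c(refs, target))
      v0 <- Vall[target, refs]
      v00 <- Vall[target, target]
    } else {
      v0 <- rep(0, n)
      v00 <- max(diag(V))  # new lineage from the root, full tree depth
    }
    U <- chol(V)
    X <- cbind(1, model$x)
    Xw <- backsolve(U, X, transpose = TRUE)
    yw <- backsolve(U, model$y, transpose = TRUE)
    vw <- backsolve(U, v0, transpose = TRUE)
    XtX_inv <- solve(crossprod(Xw))
    beta <- c(a, b)
    y_hat <- a + b * x0 + sum(vw * (yw - Xw %*% beta))
    d <- c(1, x0) - drop(crossprod(Xw, vw))
    varfac <- v00 - sum(vw^2) + drop(t(d) %*% XtX_inv %*% d)
    se <- sqrt(model$s2 * max(varfac, 0))
  }
  tq <- qt(1 - (1 - level) / 2, df)
  lower <- y_hat - tq * se
  upper <- y_hat + tq * se
  structure(list(x0 = x0, y_hat = unname(y_hat), lower = unname(lower),
                 upper = unname(upper), level = level, se = unname(se),
                 df = df,
                 arithmetic = 10^c(y_hat = unname(y_hat),
                                   lower = unname(lower),
                                   upper = unname(upper))),
            class = "prediction_band")
}

#' @export
print.prediction_band <- function(x, ...) {
  cat(sprintf(
    "%.0f%% prediction interval at x0 = %.3f (log10 cc):\n", 100 * x$level,
    x$x0))
  cat(sprintf("  y_hat = %.3f  [%.3f, %.3f]   (%.3f cc [%.3f, %.3f])\n",
              x$y_hat, x$lower, x$upper, x$arithmetic[["y_hat"]],
              x$arithmetic[["lower"]], x$arithmetic[["upper"]]))
  invisible(x)
}
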