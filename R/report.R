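#' Assemble a structure-by-structure deviation report
#'
#' One row per analyzed structure, in the layout of the published summary
#' table: lambda gate (0 for OLS, 1 for contrasts), regression equation at
#' two decimals, R2, p, the 95% prediction interval in log10 units, the
#' target percent residual rounded to the nearest integer, and a "*"
#' significance marker (outside the interval for interval-classified
#' structures; t-test p < 0.05 where a mean-residual test was run). Full
#' precision is retained in the `"full"` attribute.
#'
#' @param calls named list of `deviation_call` objects (names =
#'   structures).
#' @param models named list of matching `allometric_model` objects.
#' @param tests optional named list of `mean_residual_test` objects; for
#'   structures present here the marker follows the t-test.
#' @return a `structure_report` data.frame.
#' @export
build_report <- function(calls, models, tests = NULL) {
  if (length(calls) == 0) stop("no analyzed structures", call. = FALSE)
  stopifnot(identical(names(calls), names(models)))
  rows <- lapply(names(calls), function(s) {
    m <- models[[s]]; cl <- calls[[s]]
    tt <- if (!is.null(tests)) tests[[s]] else NULL
    sig <- if (!is.null(tt)) {
      tt$p < 0.05
    } else {
      cl$classification != "within"
    }
    band <- cl$band
    lo <- if (inherits(band, "prediction_band")) band$lower else band$lower
    hi <- if (inherits(band, "prediction_band")) band$upper else band$upper
    data.frame(
      structure = s,
      lambda = if (m$mode == "CONTRASTS") 1 else 0,
      equation = sprintf("y = %.2fx%s%.2f", m$coef[["slope"]],
                         if (m$coef[["intercept"]] < 0) "-" else "+",
                         abs(m$coef[["intercept"]])),
      R2 = round(m$R2, 2),
      p = signif(m$p, 2),
      pi_lower = round(lo, 2),
      pi_upper = round(hi, 2),
      percent_residual = round(unname(cl$percent_residual)),
      significant = if (isTRUE(sig)) "*" else "",
      stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  rownames(rep) <- NULL
  attr(rep, "full") <- list(calls = calls, models = models, tests = tests)
  class(rep) <- c("structure_report", "data.frame")
  rep
}

#' Write a structure report as TSV and full-precision JSON
#'
#' @param report a `structure_report`.
#' @param dir output directory (created if needed).
#' @param basename file stem; writes `<basename>.tsv` and
#'   `<basename>.json`.
#' @return invisibly, the two file paths.
#' @export
write_report <- function(report, dir, basename = "deviation_report") {
  stopifnot(inherits(report, "structure_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, paste0(basename, ".tsv"))
  json <- file.path(dir, paste0(basename, ".json"))
  utils::write.table(as.data.frame(report), tsv, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  full <- attr(report, "full")
  payload <- lapply(names(full$calls), function(s) {
    cl <- full$calls[[s]]; m <- full$models[[s]]
    band <- cl$band
    list(structure = s, mode = m$mode,
         lambda_hat = if (!is.null(m$lambda)) m$lambda$lambda else NULL,
         intercept = m$coef[["intercept"]], slope = m$coef[["slope"]],
         R2 = m$R2, p = m$p, n_reference = m$n,
         reference = m$reference,
         y_obs_cc = cl$y_obs, y_pred_cc = cl$y_pred,
         percent_residual = cl$percent_residual,
         pi_lower_log10 = band$lower, pi_upper_log10 = band$upper,
         classification = cl$classification,
         upper_tail_flag = cl$upper_tail_flag,
         t_test = if (!is.null(full$tests) && !is.null(full$tests[[s]])) {
           tt <- full$tests[[s]]
           list(t = tt$t, df = tt$df, p = tt$p,
                mean_residual_log10 = tt$mean_residual,
                mean_percent_residual = tt$mean_percent_residual)
         } else NULL)
  })
  names(payload) <- names(full$calls)
  jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = I(15),
                       null = "null", pretty = TRUE)
  invisible(c(tsv = tsv, json = json))
}

#' Read back the JSON companion of a written report
#'
#' @param path path to the JSON file written by [write_report()].
#' @return a named list, one element per structure.
#' @export
read_report_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}
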