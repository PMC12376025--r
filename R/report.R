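## Machine- and human-readable JSON fit reports.

#' Assemble a fit report
#'
#' Collects, per curve, every model's converged parameters, 1-sigma
#' uncertainties and chi-squared statistics, plus the per-curve
#' selection (and model probabilities when the probabilistic criterion
#' ran).
#'
#' @param fit_table a `sas_fit_table` from [fit_sas_pool].
#' @param selections optional named list of `sas_selection` objects
#'   (from [select_models]) aligned with the fit table.
#' @return A `sas_fit_report` (nested list).
#' @export
fit_report <- function(fit_table, selections = NULL) {
  curves <- lapply(names(fit_table), function(sid) {
    fits <- fit_table[[sid]]
    entry <- list(
      sample_id = sid,
      fits = lapply(fits, function(f) {
        list(model_id = f$model_id,
             params = as.list(f$params),
             uncertainties = as.list(f$uncertainties),
             chi2_total = f$chi2_total,
             chi2_reduced = f$chi2_reduced,
             n_points = f$n_points,
             k_varied = f$k_varied,
             converged = f$converged)
      }))
    sel <- selections[[sid]]
    if (!is.null(sel)) {
      entry$selection <- list(best = sel$best, criterion = sel$criterion,
                              gated = sel$gated)
      if (!is.null(sel$probabilities)) {
        if (abs(sum(sel$probabilities) - 1) > 1e-9)
          domain_error(sprintf("probabilities for '%s' do not sum to 1", sid))
        entry$selection$probabilities <- as.list(sel$probabilities)
      }
    }
    entry
  })
  names(curves) <- names(fit_table)
  structure(list(curves = curves), class = "sas_fit_report")
}

#' Write a fit report as JSON
#'
#' Floating point values are serialized at full precision (17
#' significant digits) so the report round-trips losslessly.
#'
#' @param report a `sas_fit_report` (or compatible list).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(report, path) {
  ok <- tryCatch({
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) io_error(sprintf("cannot write report to '%s'", path))
  invisible(path)
}

#' Read back a JSON fit report
#'
#' @param path file written by [write_fit_report].
#' @return A `sas_fit_report`.
#' @export
read_fit_report <- function(path) {
  if (!file.exists(path)) io_error(sprintf("cannot read report '%s'", path))
  structure(jsonlite::fromJSON(path, simplifyVector = FALSE),
            class = "sas_fit_report")
}

#' @export
print.sas_fit_report <- function(x, ...) {
  cat(sprintf("<sas_fit_report: %d curve(s)>\n", length(x$curves)))
  invisible(x)
}
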