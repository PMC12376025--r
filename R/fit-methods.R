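## Standard modelling-object methods for sas_fit.

#' @export
print.sas_fit <- function(x, ...) {
  cat(sprintf("<sas_fit '%s' (%s) on '%s'>\n", x$model_id, x$form, x$sample_id))
  cat(sprintf("  chi2_total = %.6g, chi2_reduced = %.6g  (N = %d, k = %d)%s\n",
              x$chi2_total, x$chi2_reduced, x$n_points, x$k_varied,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Summarize a fitted SAS model
#'
#' @param object a `sas_fit` from [fit_sas].
#' @param ... unused.
#' @return A `summary.sas_fit` with a coefficient table (estimate,
#'   1-sigma uncertainty, fixed flag) and fit statistics.
#' @export
summary.sas_fit <- function(object, ...) {
  est <- object$params
  se <- rep(NA_real_, length(est))
  names(se) <- names(est)
  if (!is.null(object$uncertainties))
    se[names(object$uncertainties)] <- object$uncertainties
  fixed <- !(names(est) %in% object$varied)
  tab <- data.frame(estimate = est, std_error = se, fixed = fixed,
                    row.names = names(est))
  structure(list(model_id = object$model_id, form = object$form,
                 sample_id = object$sample_id, coefficients = tab,
                 chi2_total = object$chi2_total,
                 chi2_reduced = object$chi2_reduced,
                 n_points = object$n_points, k_varied = object$k_varied,
                 converged = object$converged,
                 conditioned = object$conditioned),
            class = "summary.sas_fit")
}

#' @export
print.summary.sas_fit <- function(x, ...) {
  cat(sprintf("Fit of model '%s' (%s) to curve '%s'\n",
              x$model_id, x$form, x$sample_id))
  stats::printCoefmat(as.matrix(x$coefficients[, c("estimate", "std_error")]),
               na.print = "-", P.values = FALSE, has.Pvalue = FALSE)
  cat(sprintf("chi2_total = %.6g on N = %d points, k = %d varied; chi2_reduced = %.6g\n",
              x$chi2_total, x$n_points, x$k_varied, x$chi2_reduced))
  if (!x$converged) cat("WARNING: optimizer did not converge\n")
  if (x$conditioned) cat("note: ill-conditioned covariance (flag set)\n")
  invisible(x)
}

#' @export
coef.sas_fit <- function(object, ...) object$params

#' @export
vcov.sas_fit <- function(object, ...) object$covariance

#' Predict model intensities from a fit
#'
#' @param object a `sas_fit`.
#' @param q optional q vector; defaults to the fitted window (with the
#'   curve's resolution smearing applied there).
#' @param ... unused.
#' @return Intensities at `q` (unsmeared when `q` is supplied).
#' @export
predict.sas_fit <- function(object, q = NULL, ...) {
  if (is.null(object$model_fn))
    domain_error("fit holds no evaluable model (cell failed)")
  if (is.null(q)) return(object$model_fn(object$theta))
  sas_intensity(object$form, q, object$params, object$spec$pd_nbins)
}

#' @export
fitted.sas_fit <- function(object, ...) predict(object)

#' Weighted residuals of a fit
#'
#' @param object a `sas_fit`.
#' @param ... unused.
#' @return `(model - I) / dI` on the fitted window.
#' @export
residuals.sas_fit <- function(object, ...) object$resid_fn(object$theta)

#' Plot a fitted curve in log-log axes
#'
#' @param x a `sas_fit`.
#' @param ... passed to [graphics::plot].
#' @export
plot.sas_fit <- function(x, ...) {
  idx <- x$indices
  q <- x$curve$q[idx]; I <- x$curve$intensity[idx]
  graphics::plot(q, I, log = "xy", xlab = "q (1/Ang)", ylab = "I(q)",
                 main = sprintf("%s: %s fit", x$sample_id, x$model_id), ...)
  graphics::lines(q, fitted(x), col = 2, lwd = 2)
  invisible(x)
}
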