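## Per-curve model selection: lowest chi-squared, modified Occam's razor,
## AIC, and a Laplace-evidence probabilistic criterion, all guarded by a
## "none of the above" goodness-of-fit gate.

NONE_OF_THE_ABOVE <- "NONE_OF_THE_ABOVE"

converged_fits <- function(fits) fits[vapply(fits, `[[`, TRUE, "converged")]

## Deterministic tie-break: smaller k, then lower reduced chi2, then
## lexicographic model id.
break_ties <- function(fits, ids) {
  k <- vapply(fits[ids], `[[`, 0L, "k_varied")
  ids <- ids[k == min(k)]
  cr <- vapply(fits[ids], `[[`, 0, "chi2_reduced")
  ids <- ids[cr == min(cr)]
  sort(ids)[[1L]]
}

score_table <- function(fits, settings) {
  data.frame(
    model_id = vapply(fits, `[[`, "", "model_id"),
    chi2_total = vapply(fits, `[[`, 0, "chi2_total"),
    chi2_reduced = vapply(fits, `[[`, 0, "chi2_reduced"),
    k_varied = vapply(fits, `[[`, 0L, "k_varied"),
    converged = vapply(fits, `[[`, TRUE, "converged"),
    aic = vapply(fits, function(f)
      if (f$converged) aic_score(f, settings$aic_form) else NA_real_, 0),
    row.names = NULL)
}

new_selection <- function(best, criterion, scores, gated = FALSE,
                          probabilities = NULL) {
  structure(list(best = best, criterion = criterion, scores = scores,
                 gated = gated, probabilities = probabilities),
            class = "sas_selection")
}

#' @export
print.sas_selection <- function(x, ...) {
  cat(sprintf("<sas_selection: best = %s (criterion %s%s)>\n", x$best,
              x$criterion, if (x$gated) ", gated" else ""))
  print(x$scores, row.names = FALSE)
  if (!is.null(x$probabilities)) {
    cat("model probabilities:\n")
    print(round(x$probabilities, 5))
  }
  invisible(x)
}

#' Select the model with the lowest reduced chi-squared
#'
#' Ties are broken by smaller varied-parameter count, then lower reduced
#' chi-squared, then lexicographic model id.  With no converged fit the
#' result is `NONE_OF_THE_ABOVE` and the gate flag is set.
#'
#' @param fits named list of `sas_fit` objects for one curve.
#' @param settings a [selection_settings].
#' @return A `sas_selection`.
#' @export
select_lowest_chi2 <- function(fits, settings = selection_settings()) {
  scores <- score_table(fits, settings)
  ok <- converged_fits(fits)
  if (length(ok) == 0L)
    return(new_selection(NONE_OF_THE_ABOVE, "chi2", scores, gated = TRUE))
  cr <- vapply(ok, `[[`, 0, "chi2_reduced")
  cand <- names(ok)[cr == min(cr)]
  new_selection(break_ties(ok, cand), "chi2", scores)
}

#' Select by a modified Occam's razor
#'
#' Among models whose reduced chi-squared lies within `occam_delta` of
#' the best one, the model with the fewest varied parameters wins
#' (ties: lower chi-squared, then lexicographic id).  The default
#' threshold of 1 reads as one unit of reduced chi-squared.
#'
#' @inheritParams select_lowest_chi2
#' @return A `sas_selection`.
#' @export
select_occam <- function(fits, settings = selection_settings()) {
  scores <- score_table(fits, settings)
  ok <- converged_fits(fits)
  if (length(ok) == 0L)
    return(new_selection(NONE_OF_THE_ABOVE, "occam", scores, gated = TRUE))
  cr <- vapply(ok, `[[`, 0, "chi2_reduced")
  window <- names(ok)[cr - min(cr) < settings$occam_delta]
  new_selection(break_ties(ok, window), "occam", scores)
}

#' Akaike information criterion of a least-squares fit
#'
#' Default form `AIC = chi2_total + 2 k` (the Gaussian-likelihood
#' least-squares form with correctly weighted residuals); the
#' alternative `N * log(chi2_total / N) + 2 k` is available via
#' `form = "n_log_chi2"`.
#'
#' @param fit a converged `sas_fit`.
#' @param form `"chi2_plus_2k"` or `"n_log_chi2"`.
#' @return The AIC value.
#' @export
aic_score <- function(fit, form = c("chi2_plus_2k", "n_log_chi2")) {
  form <- match.arg(form)
  if (!fit$converged)
    domain_error(sprintf("AIC undefined: fit of '%s' did not converge",
                         fit$model_id))
  if (form == "chi2_plus_2k") fit$chi2_total + 2 * fit$k_varied
  else fit$n_points * log(fit$chi2_total / fit$n_points) + 2 * fit$k_varied
}

#' Select the model with the lowest AIC
#'
#' @inheritParams select_lowest_chi2
#' @return A `sas_selection`.
#' @export
select_aic <- function(fits, settings = selection_settings()) {
  scores <- score_table(fits, settings)
  ok <- converged_fits(fits)
  if (length(ok) == 0L)
    return(new_selection(NONE_OF_THE_ABOVE, "aic", scores, gated = TRUE))
  aic <- vapply(ok, function(f) aic_score(f, settings$aic_form), 0)
  cand <- names(ok)[aic == min(aic)]
  new_selection(break_ties(ok, cand), "aic", scores)
}

prior_widths_for <- function(fit, settings) {
  pw <- settings$prior_widths[[fit$model_id]]
  varied <- fit$varied
  widths <- vapply(varied, function(nm) {
    w <- pw[[nm]]
    if (is.null(w)) {
      p <- fit$spec$params[[nm]]
      w <- p$upper - p$lower
    }
    w
  }, 0)
  if (any(!is.finite(widths)) || any(widths <= 0))
    config_error(sprintf(
      "model '%s': prior widths must be finite and positive (set bounds or prior_widths)",
      fit$model_id))
  widths
}

#' Laplace approximation to the log-evidence of a fit
#'
#' Under a Gaussian likelihood and independent uniform parameter priors
#' of widths `dtheta_j`, the Laplace approximation to the marginal
#' likelihood is
#' `ln Z = -chi2_total/2 + (k/2) ln(2 pi) + (1/2) ln det C - sum_j ln dtheta_j`
#' where `C` is the parameter covariance at the optimum (eigenvalue
#' floor applied by [estimate_covariance]).  Models with uncertain,
#' non-contributing parameters are thereby penalized.
#'
#' @param fit a converged `sas_fit` with covariance.
#' @param prior_widths named vector of prior widths for the varied
#'   parameters; defaults to `upper - lower` from the spec bounds.
#' @return The log-evidence `ln Z`.
#' @export
laplace_log_evidence <- function(fit, prior_widths = NULL) {
  if (!fit$converged)
    domain_error(sprintf("log-evidence undefined: fit of '%s' did not converge",
                         fit$model_id))
  k <- fit$k_varied
  if (k == 0L) return(-fit$chi2_total / 2)
  if (is.null(fit$covariance))
    domain_error(sprintf("fit of '%s' has no covariance", fit$model_id))
  widths <- if (is.null(prior_widths)) {
    prior_widths_for(fit, selection_settings())
  } else {
    w <- unlist(prior_widths)[fit$varied]
    if (any(is.na(w)) || any(w <= 0))
      config_error("prior_widths must cover all varied parameters with positive values")
    w
  }
  ld <- determinant(fit$covariance, logarithm = TRUE)
  -fit$chi2_total / 2 + (k / 2) * log(2 * pi) + 0.5 * as.numeric(ld$modulus) -
    sum(log(widths))
}

#' Posterior model probabilities from Laplace evidences
#'
#' Equal model priors; probabilities are the softmax of the per-model
#' log-evidences, computed with log-sum-exp stabilization.  Models with
#' no usable evidence (non-converged or missing covariance) are
#' excluded and logged.
#'
#' @param fits named list of `sas_fit` objects for one curve.
#' @param settings a [selection_settings] supplying prior widths.
#' @return Named probability vector summing to 1 (empty if no model has
#'   a defined evidence).
#' @export
model_probabilities <- function(fits, settings = selection_settings()) {
  lz <- vapply(fits, function(f) {
    tryCatch({
      if (!f$converged) stop("not converged")
      if (f$k_varied > 0L && is.null(f$covariance)) stop("no covariance")
      laplace_log_evidence(f, settings$prior_widths[[f$model_id]])
    }, error = function(e) {
      log_event(sprintf("[%s] model '%s' excluded from probabilistic criterion: %s",
                        f$sample_id, f$model_id, conditionMessage(e)))
      NA_real_
    })
  }, 0)
  lz <- lz[is.finite(lz)]
  if (length(lz) == 0L) return(stats::setNames(numeric(0), character(0)))
  exp(lz - logsumexp(lz))
}

#' Select the most probable model
#'
#' Argmax of [model_probabilities]; ties broken as elsewhere.  With no
#' defined evidence the result is `NONE_OF_THE_ABOVE`.
#'
#' @inheritParams select_lowest_chi2
#' @return A `sas_selection` carrying the probability vector.
#' @export
select_most_probable <- function(fits, settings = selection_settings()) {
  scores <- score_table(fits, settings)
  p <- model_probabilities(fits, settings)
  if (length(p) == 0L)
    return(new_selection(NONE_OF_THE_ABOVE, "probability", scores, gated = TRUE))
  cand <- names(p)[p == max(p)]
  best <- break_ties(fits, cand)
  new_selection(best, "probability", scores, probabilities = p)
}

#' Apply the "none of the above" goodness-of-fit gate
#'
#' If the selected model's reduced chi-squared exceeds the threshold
#' (strictly), the selection is replaced by `NONE_OF_THE_ABOVE` and the
#' gate flag is set; flagging indicates that no appropriate model is in
#' the user-supplied pool.
#'
#' @param selection a `sas_selection`.
#' @param fits the fits the selection was computed from.
#' @param settings a [selection_settings] (`gof_threshold`).
#' @return The (possibly gated) `sas_selection`.
#' @export
apply_gof_gate <- function(selection, fits, settings = selection_settings()) {
  if (identical(selection$best, NONE_OF_THE_ABOVE)) return(selection)
  cr <- fits[[selection$best]]$chi2_reduced
  if (cr > settings$gof_threshold) {
    selection$best <- NONE_OF_THE_ABOVE
    selection$gated <- TRUE
  }
  selection
}

#' Select the best model for one curve under a chosen criterion
#'
#' Dispatches to the criterion named in `settings` and applies the
#' goodness-of-fit gate.
#'
#' @param fits named list of `sas_fit` objects for one curve (from one
#'   row of [fit_sas_pool]).
#' @param settings a [selection_settings].
#' @return A `sas_selection`.
#' @export
select_model <- function(fits, settings = selection_settings()) {
  sel <- switch(settings$criterion,
    chi2 = select_lowest_chi2(fits, settings),
    occam = select_occam(fits, settings),
    aic = select_aic(fits, settings),
    probability = select_most_probable(fits, settings))
  apply_gof_gate(sel, fits, settings)
}

#' Select models for every curve of a fit table
#'
#' @param fit_table a `sas_fit_table` from [fit_sas_pool].
#' @param settings a [selection_settings].
#' @return Named list of `sas_selection` objects, one per curve.
#' @export
select_models <- function(fit_table, settings = selection_settings()) {
  lapply(fit_table, select_model, settings = settings)
}
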