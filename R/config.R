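## Candidate-model configuration: parameter specs, model specs, fit and
## selection settings, JSON config loading, and the default study pool.

.FORMS <- c("guinier", "sphere", "poly_gauss_coil", "mixed")

.required_params <- list(
  guinier = c("i_zero", "rg", "background"),
  sphere = c("scale", "radius", "sld", "sld_solvent", "pd_width", "background"),
  poly_gauss_coil = c("scale", "i_zero", "rg", "pdi", "background"),
  mixed = c("scale_a", "scale_b", "coil_i_zero", "coil_rg", "coil_pdi",
            "sphere_radius", "sphere_sld", "sphere_sld_solvent",
            "sphere_pd_width", "background")
)

#' Describe one fit parameter
#'
#' @param name parameter name (model-form specific).
#' @param init initial value, must satisfy `lower <= init <= upper`.
#' @param lower,upper box bounds for the bounded LM optimizer.
#' @param fixed if `TRUE` the parameter is held at `init` and does not
#'   count towards the varied-parameter number `k`.
#' @return A `param_spec` list.
#' @export
param_spec <- function(name, init, lower = -Inf, upper = Inf, fixed = FALSE) {
  if (!is.character(name) || length(name) != 1L)
    config_error("param_spec: name must be a single string")
  if (!is.finite(init)) config_error(sprintf("parameter '%s': init must be finite", name))
  if (lower > upper)
    config_error(sprintf("parameter '%s': lower > upper", name))
  if (init < lower || init > upper)
    config_error(sprintf("parameter '%s': init %g outside bounds [%g, %g]",
                         name, init, lower, upper))
  structure(list(name = name, init = init, lower = lower, upper = upper,
                 fixed = isTRUE(fixed)), class = "param_spec")
}

#' Describe a candidate form-factor model
#'
#' A model spec names the functional form, its parameters (with initial
#' values, bounds and fixed flags) and the q-window the model is fitted
#' over.  Every parameter the form requires must be present exactly once.
#'
#' @param model_id unique label for this pool entry.
#' @param form one of `"guinier"`, `"sphere"`, `"poly_gauss_coil"`, `"mixed"`.
#' @param params list of [param_spec] objects.
#' @param q_min,q_max fitting window, 1/Angstrom, `0 < q_min < q_max`.
#' @param pd_nbins number of quadrature bins for sphere-radius
#'   polydispersity (forms `sphere` and `mixed`).
#' @param n_restarts optional per-model override of the number of random
#'   restarts used by [fit_sas].
#' @return A `model_spec` object.
#' @export
model_spec <- function(model_id, form, params, q_min, q_max,
                       pd_nbins = 81L, n_restarts = NULL) {
  if (!form %in% .FORMS)
    config_error(sprintf("model '%s': unknown form '%s'", model_id, form))
  if (!is.numeric(q_min) || !is.numeric(q_max) || q_min <= 0 || q_min >= q_max)
    config_error(sprintf("model '%s': need 0 < q_min < q_max", model_id))
  params <- lapply(params, function(p) {
    if (inherits(p, "param_spec")) p else do.call(param_spec, p)
  })
  names(params) <- vapply(params, `[[`, "", "name")
  need <- .required_params[[form]]
  if (anyDuplicated(names(params)))
    config_error(sprintf("model '%s': duplicated parameter '%s'", model_id,
                         names(params)[anyDuplicated(names(params))]))
  missing <- setdiff(need, names(params))
  extra <- setdiff(names(params), need)
  if (length(missing))
    config_error(sprintf("model '%s' (%s): missing parameter(s) %s",
                         model_id, form, paste(missing, collapse = ", ")))
  if (length(extra))
    config_error(sprintf("model '%s' (%s): unknown parameter(s) %s",
                         model_id, form, paste(extra, collapse = ", ")))
  pd_nbins <- as.integer(pd_nbins)
  has_pd <- form %in% c("sphere", "mixed")
  if (has_pd) {
    pdname <- if (form == "sphere") "pd_width" else "sphere_pd_width"
    if (params[[pdname]]$upper > 0 && pd_nbins < 3L)
      config_error(sprintf("model '%s': pd_nbins must be >= 3 when pd_width > 0",
                           model_id))
  }
  structure(list(model_id = model_id, form = form, params = params,
                 q_min = q_min, q_max = q_max, pd_nbins = pd_nbins,
                 n_restarts = n_restarts),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec '%s' (%s), q in [%g, %g]>\n",
              x$model_id, x$form, x$q_min, x$q_max))
  for (p in x$params)
    cat(sprintf("  %-18s init=%-10.4g bounds=[%g, %g]%s\n", p$name, p$init,
                p$lower, p$upper, if (p$fixed) " fixed" else ""))
  invisible(x)
}

k_varied <- function(spec) sum(!vapply(spec$params, `[[`, TRUE, "fixed"))

#' Optimizer settings for bounded Levenberg-Marquardt fitting
#'
#' @param method only `"lm"` (bounded Levenberg-Marquardt) is available;
#'   the enumeration leaves room for posterior-sampling extensions.
#' @param max_iterations iteration cap for the optimizer.
#' @param tolerance relative tolerance on the objective and step.
#' @param n_restarts number of additional random starts drawn uniformly
#'   within bounds from a seeded generator; best total chi-squared wins.
#' @param seed integer seed making restart draws (and the whole fit)
#'   reproducible.
#' @param chi2_divisor `"n"` divides total chi-squared by the point count
#'   N; `"n_minus_k"` uses N - k instead.
#' @param smear_nodes quadrature node count for resolution smearing.
#' @return A `fit_settings` list.
#' @export
fit_settings <- function(method = "lm", max_iterations = 2000L,
                         tolerance = 1e-8, n_restarts = 0L, seed = 1L,
                         chi2_divisor = c("n", "n_minus_k"),
                         smear_nodes = 21L) {
  if (!identical(method, "lm"))
    config_error(sprintf("unknown fit method '%s' (only 'lm' is available)", method))
  if (max_iterations < 1L) config_error("max_iterations must be positive")
  if (tolerance <= 0) config_error("tolerance must be positive")
  if (n_restarts < 0L) config_error("n_restarts must be non-negative")
  structure(list(method = method, max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed),
                 chi2_divisor = match.arg(chi2_divisor),
                 smear_nodes = as.integer(smear_nodes)),
            class = "fit_settings")
}

#' Model-selection settings
#'
#' @param criterion `"chi2"` (lowest reduced chi-squared), `"occam"`
#'   (modified Occam's razor), `"aic"` or `"probability"` (Laplace
#'   evidence under uniform priors).
#' @param occam_delta chi-squared window within which the simplest model
#'   is preferred; the default of 1 reads as one unit of reduced chi-squared.
#' @param gof_threshold reduced chi-squared above which the winner is
#'   replaced by `NONE_OF_THE_ABOVE`.
#' @param prior_widths optional named list (per model id) of named prior
#'   widths for the probabilistic criterion; defaults to `upper - lower`
#'   of each varied parameter.
#' @param aic_form `"chi2_plus_2k"` uses chi2_total + 2k;
#'   `"n_log_chi2"` uses N*log(chi2_total/N) + 2k.
#' @return A `selection_settings` list.
#' @export
selection_settings <- function(criterion = c("aic", "chi2", "occam", "probability"),
                               occam_delta = 1, gof_threshold = 10,
                               prior_widths = NULL,
                               aic_form = c("chi2_plus_2k", "n_log_chi2")) {
  criterion <- match.arg(criterion)
  if (!is.finite(occam_delta) || occam_delta <= 0)
    config_error("occam_delta must be finite and positive")
  if (!is.finite(gof_threshold) || gof_threshold <= 0)
    config_error("gof_threshold must be finite and positive")
  structure(list(criterion = criterion, occam_delta = occam_delta,
                 gof_threshold = gof_threshold, prior_widths = prior_widths,
                 aic_form = match.arg(aic_form)),
            class = "selection_settings")
}

## ---- JSON configuration ----------------------------------------------------

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    config_error(sprintf("unknown key '%s' in %s", bad[[1L]], where))
}

#' Load a candidate-model configuration from JSON
#'
#' The configuration document (schema in
#' `system.file("schema", "config-schema.json", package = "autosas")`)
#' defines the model pool, optimizer settings and selection settings.
#' Unknown keys are rejected; omitted settings take their documented
#' defaults.
#'
#' @param path JSON file.
#' @return A list with elements `models` (list of [model_spec]),
#'   `fit` ([fit_settings]) and `selection` ([selection_settings]).
#' @export
load_sas_config <- function(path) {
  if (!file.exists(path)) io_error(sprintf("cannot read config file '%s'", path))
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    config_error(sprintf("config '%s' is not valid JSON: %s",
                                         path, conditionMessage(e))))
  check_keys(doc, c("models", "fit", "selection"), "config root")
  if (is.null(doc$models) || length(doc$models) == 0L)
    config_error("config must define at least one model")
  models <- lapply(doc$models, function(m) {
    check_keys(m, c("model_id", "form", "params", "q_min", "q_max",
                    "pd_nbins", "n_restarts"), "model entry")
    for (k in c("model_id", "form", "q_min", "q_max"))
      if (is.null(m[[k]]))
        config_error(sprintf("model entry missing required key '%s'", k))
    params <- mapply(function(p, nm) {
      check_keys(p, c("init", "lower", "upper", "fixed"),
                 sprintf("parameter '%s'", nm))
      if (is.null(p$init))
        config_error(sprintf("parameter '%s' missing 'init'", nm))
      param_spec(nm, init = p$init, lower = p$lower %||% -Inf,
                 upper = p$upper %||% Inf, fixed = p$fixed %||% FALSE)
    }, m$params, names(m$params), SIMPLIFY = FALSE)
    model_spec(m$model_id, m$form, params, m$q_min, m$q_max,
               pd_nbins = m$pd_nbins %||% 81L, n_restarts = m$n_restarts)
  })
  ids <- vapply(models, `[[`, "", "model_id")
  if (anyDuplicated(ids))
    config_error(sprintf("duplicated model_id '%s'", ids[anyDuplicated(ids)]))
  names(models) <- ids

  fit_doc <- doc$fit %||% list()
  check_keys(fit_doc, c("method", "max_iterations", "tolerance", "n_restarts",
                        "seed", "chi2_divisor", "smear_nodes"), "fit settings")
  fit <- do.call(fit_settings, fit_doc)

  sel_doc <- doc$selection %||% list()
  check_keys(sel_doc, c("criterion", "occam_delta", "gof_threshold",
                        "prior_widths", "aic_form"), "selection settings")
  sel <- do.call(selection_settings, sel_doc)

  list(models = models, fit = fit, selection = sel)
}

## ---- Default pool ----------------------------------------------------------

#' The default three-model candidate pool
#'
#' Builds the study's candidate set: a polydisperse Gaussian coil (the
#' free unimer), a polydisperse sphere (the micelle) and their mixed
#' model (coexistence across the critical micelle concentration).  The
#' Guinier model is available separately via [guinier_model_spec] for
#' ground-truth labelling but is not part of the selection pool.
#'
#' Scattering length densities are fixed so that the sphere component's
#' forward intensity per unit scale is about 20 times the coil's,
#' emulating the brightness contrast between a surfactant micelle and
#' its unimers; `scale_a`/`scale_b` of the mixed model are then
#' volume-fraction-like weights and their ratio is the micelle fraction.
#'
#' @param q_min,q_max common fitting window (1/Angstrom).
#' @param pd_nbins radius-polydispersity quadrature bins.
#' @param n_restarts_multimodal random restarts for the multimodal sphere
#'   and mixed fits (the coil fit gets none).
#' @return Named list of three [model_spec] objects.
#' @export
default_model_pool <- function(q_min = 0.005, q_max = 0.4, pd_nbins = 41L,
                               n_restarts_multimodal = 2L) {
  drho <- sqrt(20 / (4 / 3 * pi * 45^3))  # forward intensity 20 per unit scale at r = 45
  list(
    poly_gauss_coil = model_spec(
      "poly_gauss_coil", "poly_gauss_coil",
      list(param_spec("scale", 1, 1, 1, fixed = TRUE),
           param_spec("i_zero", 1, 1e-6, 1e4),
           param_spec("rg", 60, 10, 200),
           param_spec("pdi", 1.2, 1.2, 1.2, fixed = TRUE),
           param_spec("background", 0.01, 0, 10)),
      q_min, q_max, n_restarts = 0L),
    sphere = model_spec(
      "sphere", "sphere",
      list(param_spec("scale", 1, 1e-8, 1e4),
           param_spec("radius", 50, 15, 120),
           param_spec("sld", drho, drho, drho, fixed = TRUE),
           param_spec("sld_solvent", 0, 0, 0, fixed = TRUE),
           param_spec("pd_width", 0.12, 0.01, 0.35),
           param_spec("background", 0.01, 0, 10)),
      q_min, q_max, pd_nbins = pd_nbins, n_restarts = n_restarts_multimodal),
    mixed = model_spec(
      "mixed", "mixed",
      list(param_spec("scale_a", 1, 1e-8, 1e4),
           param_spec("scale_b", 0.1, 1e-8, 1e4),
           param_spec("coil_i_zero", 1, 1, 1, fixed = TRUE),
           param_spec("coil_rg", 60, 40, 120),
           param_spec("coil_pdi", 1.2, 1.2, 1.2, fixed = TRUE),
           param_spec("sphere_radius", 50, 15, 120),
           param_spec("sphere_sld", drho, drho, drho, fixed = TRUE),
           param_spec("sphere_sld_solvent", 0, 0, 0, fixed = TRUE),
           param_spec("sphere_pd_width", 0.12, 0.01, 0.35),
           param_spec("background", 0.01, 0, 10)),
      q_min, q_max, pd_nbins = pd_nbins, n_restarts = n_restarts_multimodal)
  )
}

#' Guinier model spec for ground-truth labelling
#'
#' The Guinier law is fitted on a restricted low-q window to extract the
#' forward intensity `i_zero` and radius of gyration; it is excluded
#' from the default selection pool.
#'
#' @param q_min,q_max low-q fitting window (1/Angstrom).
#' @return A [model_spec].
#' @export
guinier_model_spec <- function(q_min = 0.005, q_max = 0.03) {
  model_spec(
    "guinier", "guinier",
    list(param_spec("i_zero", 10, 1e-6, 1e4),
         param_spec("rg", 30, 1, 300),
         param_spec("background", 0.01, 0, 10)),
    q_min, q_max, n_restarts = 2L)
}
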