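## Bounded Levenberg-Marquardt weighted least-squares fitting of model
## specs to scattering curves, with chi-squared and covariance estimation.

#' Weighted chi-squared of a model against a curve
#'
#' `chi2_total = sum(((model - I) / dI)^2)` over the given indices;
#' `chi2_reduced = chi2_total / N`.  A reduced chi-squared of 1 means
#' the model matches the data to within one standard deviation on
#' average.
#'
#' @param model_I model intensities aligned with `indices`.
#' @param curve a [sas_curve].
#' @param indices index set into the curve (default: all points).
#' @param k number of varied parameters, used only when
#'   `divisor = "n_minus_k"`.
#' @param divisor `"n"` (default) or `"n_minus_k"`.
#' @return List with `chi2_total` and `chi2_reduced`.
#' @export
chi_squared <- function(model_I, curve, indices = seq_along(curve$q),
                        k = 0L, divisor = c("n", "n_minus_k")) {
  divisor <- match.arg(divisor)
  if (length(indices) == 0L) domain_error("chi_squared: empty index set")
  if (length(model_I) != length(indices))
    domain_error("chi_squared: model_I and indices lengths differ")
  r <- (model_I - curve$intensity[indices]) / curve$d_intensity[indices]
  total <- sum(r^2)
  n <- length(indices)
  denom <- if (divisor == "n") n else max(n - k, 1L)
  list(chi2_total = total, chi2_reduced = total / denom)
}

## Residual closure over the varied parameters of `spec` on `curve`.
make_residual_fn <- function(spec, curve, n_nodes = 21L) {
  idx <- which(curve$q >= spec$q_min & curve$q <= spec$q_max)
  if (length(idx) < 5L)
    insufficient_error(sprintf(
      "curve '%s': only %d points inside [%g, %g] for model '%s'",
      curve$sample_id, length(idx), spec$q_min, spec$q_max, spec$model_id))
  q <- curve$q[idx]
  I <- curve$intensity[idx]
  dI <- curve$d_intensity[idx]
  dq <- if (is.null(curve$d_q)) NULL else curve$d_q[idx]
  p_full <- vapply(spec$params, `[[`, 0, "init")
  varied <- names(spec$params)[!vapply(spec$params, `[[`, TRUE, "fixed")]
  model_fn <- function(par) {
    p_full[varied] <- par
    ideal <- function(qq) sas_intensity(spec$form, qq, p_full, spec$pd_nbins)
    if (is.null(dq)) ideal(q) else smear_curve(ideal, q, dq, n_nodes)
  }
  resid_fn <- function(par) {
    r <- (model_fn(par) - I) / dI
    r[!is.finite(r)] <- 1e10
    r
  }
  list(resid_fn = resid_fn, model_fn = model_fn, indices = idx,
       varied = varied, p_full = p_full)
}

#' Fit one model spec to one curve by bounded Levenberg-Marquardt
#'
#' Minimizes the weighted residual sum of squares over the spec's varied
#' parameters with box bounds, using the MINPACK Levenberg-Marquardt
#' solver (bound-clamped).  Resolution smearing is applied inside the
#' residual whenever the curve carries `d_q`.  With restarts, additional
#' initial points are drawn uniformly within bounds from a generator
#' seeded deterministically by (`settings$seed`, model id, sample id),
#' and the start with the lowest total chi-squared wins; results are
#' bit-reproducible for identical inputs.
#'
#' @param spec a [model_spec].
#' @param curve a [sas_curve].
#' @param settings a [fit_settings]; `spec$n_restarts`, when set,
#'   overrides `settings$n_restarts`.
#' @param extra_starts optional list of named parameter vectors used as
#'   additional deterministic starting points (e.g. component solutions
#'   when fitting the mixed model).
#' @return An object of class `sas_fit`; see [summary.sas_fit].  A fit
#'   that cannot be evaluated returns with `converged = FALSE` rather
#'   than raising an error.
#' @export
fit_sas <- function(spec, curve, settings = fit_settings(),
                    extra_starts = list()) {
  stopifnot(inherits(spec, "model_spec"), inherits(curve, "sas_curve"))
  fns <- make_residual_fn(spec, curve, settings$smear_nodes)
  varied <- fns$varied
  k <- length(varied)
  lower <- vapply(spec$params[varied], `[[`, 0, "lower")
  upper <- vapply(spec$params[varied], `[[`, 0, "upper")
  init <- fns$p_full[varied]
  n_restarts <- spec$n_restarts %||% settings$n_restarts

  starts <- list(init)
  if (k > 0L && n_restarts > 0L) {
    rs <- with_seed(derive_seed(settings$seed, spec$model_id, curve$sample_id), {
      lapply(seq_len(n_restarts), function(i) {
        lo <- ifelse(is.finite(lower), lower, init - abs(init) - 1)
        hi <- ifelse(is.finite(upper), upper, init + abs(init) + 1)
        stats::setNames(stats::runif(k, lo, hi), varied)
      })
    })
    starts <- c(starts, rs)
  }
  for (es in extra_starts) {
    s <- init
    common <- intersect(names(es), varied)
    s[common] <- pmin(pmax(unlist(es)[common], lower[common]), upper[common])
    starts <- c(starts, list(s))
  }

  best <- NULL
  n_eval <- 0L
  ctrl <- minpack.lm::nls.lm.control(maxiter = min(settings$max_iterations, 1024L),
                                     ftol = settings$tolerance,
                                     ptol = settings$tolerance)
  for (s0 in starts) {
    res <- if (k == 0L) {
      r <- fns$resid_fn(numeric(0))
      list(par = numeric(0), deviance = sum(r^2), info = 1L, niter = 0L)
    } else {
      tryCatch(
        minpack.lm::nls.lm(par = s0, lower = lower, upper = upper,
                           fn = fns$resid_fn, control = ctrl),
        error = function(e) NULL)
    }
    if (is.null(res)) next
    n_eval <- n_eval + (res$niter %||% 0L)
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }

  n <- length(fns$indices)
  if (is.null(best)) {
    log_event(sprintf("[%s] model '%s': all starts failed to evaluate",
                      curve$sample_id, spec$model_id))
    return(new_sas_fit(spec, curve, fns, params = fns$p_full,
                       theta = init, chi2_total = Inf, n = n, k = k,
                       converged = FALSE, n_eval = n_eval,
                       settings = settings))
  }
  theta <- stats::setNames(as.numeric(best$par), varied)
  ## clip roundoff-level bound violations
  if (k > 0L) theta <- pmin(pmax(theta, lower), upper)
  params <- fns$p_full
  params[varied] <- theta
  chi2_total <- sum(fns$resid_fn(theta)^2)
  converged <- (best$info %in% 1:4)
  if (!converged)
    log_event(sprintf("[%s] model '%s': no convergence (info=%d)",
                      curve$sample_id, spec$model_id, best$info))
  fit <- new_sas_fit(spec, curve, fns, params = params, theta = theta,
                     chi2_total = chi2_total, n = n, k = k,
                     converged = converged, n_eval = n_eval,
                     settings = settings)
  if (converged && k > 0L) {
    cv <- estimate_covariance(fit)
    fit$covariance <- cv$covariance
    fit$uncertainties <- cv$uncertainties
    fit$conditioned <- cv$conditioned
  }
  fit
}

new_sas_fit <- function(spec, curve, fns, params, theta, chi2_total, n, k,
                        converged, n_eval, settings) {
  denom <- if (settings$chi2_divisor == "n") n else max(n - k, 1L)
  structure(list(
    model_id = spec$model_id,
    form = spec$form,
    sample_id = curve$sample_id,
    params = params,
    theta = theta,
    varied = names(theta),
    uncertainties = NULL,
    covariance = NULL,
    conditioned = FALSE,
    chi2_total = chi2_total,
    chi2_reduced = chi2_total / denom,
    n_points = n,
    k_varied = k,
    converged = converged,
    n_evaluations = n_eval,
    indices = fns$indices,
    spec = spec,
    curve = curve,
    resid_fn = fns$resid_fn,
    model_fn = fns$model_fn,
    settings = settings), class = "sas_fit")
}

#' Parameter covariance of a converged fit
#'
#' Builds the weighted-residual Jacobian at the optimum by finite
#' differences (relative step 1e-6, one-sided at active bounds) and
#' returns `(J^T J)^{-1}` with its square-root diagonal as 1-sigma
#' uncertainties.  If `J^T J` is singular, eigenvalues below
#' `1e-12 * lambda_max` are floored there and a conditioning flag is
#' set; the flag is also set when a varied parameter sits at a bound.
#'
#' @param fit a converged `sas_fit`.
#' @return List with `covariance` (k x k matrix), `uncertainties`
#'   (named vector) and `conditioned` (logical flag).
#' @export
estimate_covariance <- function(fit) {
  stopifnot(inherits(fit, "sas_fit"))
  if (!fit$converged)
    domain_error(sprintf("fit of '%s' to '%s' did not converge; no covariance",
                         fit$model_id, fit$sample_id))
  theta <- fit$theta
  k <- length(theta)
  varied <- fit$varied
  lower <- vapply(fit$spec$params[varied], `[[`, 0, "lower")
  upper <- vapply(fit$spec$params[varied], `[[`, 0, "upper")
  r0 <- fit$resid_fn(theta)
  J <- matrix(0, nrow = length(r0), ncol = k)
  at_bound <- logical(k)
  for (j in seq_len(k)) {
    h <- 1e-6 * max(abs(theta[j]), 1)
    up <- theta; dn <- theta
    hi_ok <- theta[j] + h <= upper[j]
    lo_ok <- theta[j] - h >= lower[j]
    at_bound[j] <- !(hi_ok && lo_ok)
    if (hi_ok) up[j] <- theta[j] + h
    if (lo_ok) dn[j] <- theta[j] - h
    step <- up[j] - dn[j]
    if (step == 0) { J[, j] <- 0; next }
    J[, j] <- (fit$resid_fn(up) - fit$resid_fn(dn)) / step
  }
  jtj <- crossprod(J)
  ee <- eigen(jtj, symmetric = TRUE)
  floor_val <- 1e-12 * max(ee$values, 0)
  floored <- ee$values < floor_val
  vals <- pmax(ee$values, floor_val)
  conditioned <- any(floored) || any(at_bound)
  if (any(floored))
    log_event(sprintf("[%s] model '%s': singular information matrix, %d eigenvalue(s) floored",
                      fit$sample_id, fit$model_id, sum(floored)))
  cov <- ee$vectors %*% diag(1 / vals, k) %*% t(ee$vectors)
  dimnames(cov) <- list(varied, varied)
  list(covariance = cov,
       uncertainties = stats::setNames(sqrt(diag(cov)), varied),
       conditioned = conditioned)
}

#' Fit every model in a pool to every curve
#'
#' All model-curve combinations are optimized independently; a failure
#' on one cell (e.g. too few in-window points) is recorded there and
#' does not abort the batch.  Results are independent of curve or model
#' ordering.
#'
#' @param specs list of [model_spec] objects.
#' @param curves list of [sas_curve] objects.
#' @param settings a [fit_settings].
#' @return A `sas_fit_table`: a list (one entry per curve, named by
#'   sample id) of lists of `sas_fit` objects (named by model id).
#' @export
fit_sas_pool <- function(specs, curves, settings = fit_settings()) {
  stopifnot(length(specs) >= 1L, length(curves) >= 1L)
  if (inherits(curves, "sas_curve")) curves <- list(curves)
  if (inherits(specs, "model_spec")) specs <- list(specs)
  ids <- vapply(curves, `[[`, "", "sample_id")
  mids <- vapply(specs, `[[`, "", "model_id")
  forms <- vapply(specs, `[[`, "", "form")
  out <- lapply(curves, function(cv) {
    row <- list()
    ## fit mixed specs last so component solutions can seed them
    for (ix in order(forms == "mixed")) {
      sp <- specs[[ix]]
      extra <- if (sp$form == "mixed") mixed_component_starts(sp, row) else list()
      row[[sp$model_id]] <- tryCatch(fit_sas(sp, cv, settings, extra_starts = extra),
               autosas_insufficient_data_error = function(e) {
                 log_event(sprintf("[%s] model '%s': %s", cv$sample_id,
                                   sp$model_id, conditionMessage(e)))
                 structure(list(model_id = sp$model_id, form = sp$form,
                                sample_id = cv$sample_id,
                                params = NULL, theta = NULL,
                                uncertainties = NULL, covariance = NULL,
                                conditioned = TRUE, chi2_total = Inf,
                                chi2_reduced = Inf, n_points = 0L,
                                k_varied = k_varied(sp), converged = FALSE,
                                n_evaluations = 0L, failure = conditionMessage(e),
                                spec = sp, curve = cv, settings = settings),
                           class = "sas_fit")
               })
    }
    row[mids]
  })
  names(out) <- ids
  structure(out, class = "sas_fit_table")
}

## Deterministic extra starting points for a mixed-model fit, mapped from
## already-fitted pure-component solutions on the same curve: the coil
## solution (sphere weight at its lower bound), the sphere solution (coil
## weight at its lower bound), and a half/half combination.  These make
## the mixed model's chi-squared effectively nested below its components.
mixed_component_starts <- function(spec, row) {
  coil <- NULL; sph <- NULL
  for (f in row) {
    if (!isTRUE(f$converged)) next
    if (f$form == "poly_gauss_coil" && is.null(coil)) coil <- f
    if (f$form == "sphere" && is.null(sph)) sph <- f
  }
  i0_mix <- spec$params[["coil_i_zero"]]$init
  from_coil <- function(f, fac = 1) {
    p <- f$params
    c(scale_a = unname(p[["scale"]] * p[["i_zero"]]) / i0_mix * fac,
      coil_rg = unname(p[["rg"]]), coil_pdi = unname(p[["pdi"]]),
      background = unname(p[["background"]]))
  }
  from_sphere <- function(f, fac = 1) {
    p <- f$params
    drho_f <- p[["sld"]] - p[["sld_solvent"]]
    drho_m <- spec$params[["sphere_sld"]]$init -
      spec$params[["sphere_sld_solvent"]]$init
    ratio <- if (drho_m != 0) (drho_f / drho_m)^2 else 1
    c(scale_b = unname(p[["scale"]]) * ratio * fac,
      sphere_radius = unname(p[["radius"]]),
      sphere_pd_width = unname(p[["pd_width"]]),
      background = unname(p[["background"]]))
  }
  starts <- list()
  if (!is.null(coil))
    starts <- c(starts, list(c(from_coil(coil), scale_b = 0)))
  if (!is.null(sph))
    starts <- c(starts, list(c(from_sphere(sph), scale_a = 0)))
  if (!is.null(coil) && !is.null(sph))
    starts <- c(starts, list(c(from_coil(coil, 0.5), from_sphere(sph, 0.5))))
  starts
}

#' @export
print.sas_fit_table <- function(x, ...) {
  cat(sprintf("<sas_fit_table: %d curve(s) x %d model(s)>\n",
              length(x), length(x[[1]])))
  invisible(x)
}

#' Tabulate a fit table as a data frame
#'
#' @param x a `sas_fit_table` from [fit_sas_pool].
#' @param ... unused.
#' @return One row per (curve, model) with chi-squared statistics.
#' @export
as.data.frame.sas_fit_table <- function(x, ...) {
  rows <- lapply(unlist(x, recursive = FALSE), function(f)
    data.frame(sample_id = f$sample_id, model_id = f$model_id,
               chi2_total = f$chi2_total, chi2_reduced = f$chi2_reduced,
               n_points = f$n_points, k_varied = f$k_varied,
               converged = f$converged))
  do.call(rbind, c(rows, make.row.names = FALSE))
}
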