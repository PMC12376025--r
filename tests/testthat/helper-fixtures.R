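## Shared fixtures for the test suite.  Expensive fixtures are memoized so
## several test files can reuse one computation.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

## Sphere SLD contrast used throughout: forward intensity 20 per unit
## scale at radius 45 (matches default_model_pool / phase_diagram_spec).
DRHO <- sqrt(20 / (4 / 3 * pi * 45^3))

## Truth parameter sets consistent with the synthetic P188-like preset.
truth_coil <- function(i_zero = 5) {
  c(scale = 1, i_zero = i_zero, rg = 70, pdi = 1.2, background = 0.01)
}

truth_sphere <- function(scale = 5) {
  c(scale = scale, radius = 45, sld = DRHO, sld_solvent = 0,
    background = 0.01, pd_width = 0.12)
}

truth_mixed <- function(scale_a = 2.5, scale_b = 0.15) {
  c(scale_a = scale_a, scale_b = scale_b, coil_i_zero = 1, coil_rg = 70,
    coil_pdi = 1.2, sphere_radius = 45, sphere_sld = DRHO,
    sphere_sld_solvent = 0, sphere_pd_width = 0.12, background = 0.01)
}

truth_guinier <- function() c(i_zero = 100, rg = 20, background = 0.01)

## A noiseless curve (eps = 0) with dI set by the noise model, handy for
## exact-recovery tests.
noiseless_curve <- function(form, truth, q = q_grid(), dq_frac = 0.02,
                            rel = 0.01, sample_id = "noiseless") {
  truth <- unlist(truth)
  ideal <- function(qq) autosas:::sas_intensity(form, qq, truth, 81L)
  d_q <- if (dq_frac > 0) dq_frac * q else NULL
  I <- if (is.null(d_q)) ideal(q) else smear_curve(ideal, q, d_q)
  sas_curve(sample_id, q, I, pmax(rel * I, 1e-12), d_q = d_q)
}

## Small well-separated coil/sphere curve families for clustering tests.
ml_fixture_curves <- function(n_per = 10, noise_rel = 0.02, seed = 99) {
  curves <- list()
  for (i in seq_len(n_per)) {
    curves[[length(curves) + 1L]] <- simulate_sas_curve(
      "poly_gauss_coil", truth_coil(), noise = noise_model(noise_rel),
      seed = seed + i, sample_id = sprintf("coil%02d", i))$curve
    curves[[length(curves) + 1L]] <- simulate_sas_curve(
      "sphere", truth_sphere(), noise = noise_model(noise_rel),
      seed = seed + 100 + i, sample_id = sprintf("sphere%02d", i))$curve
  }
  curves
}

## Minimal stand-in for a converged sas_fit, for selection-criterion unit
## tests that do not need a real optimization behind them.
stub_fit <- function(model_id, chi2_total, n = 10L, k = 1L,
                     covariance = NULL, bounds_width = 10,
                     converged = TRUE, sample_id = "stub") {
  varied <- if (k > 0L) paste0("p", seq_len(k)) else character(0)
  params <- lapply(varied, function(nm)
    list(name = nm, init = 0, lower = -bounds_width / 2,
         upper = bounds_width / 2, fixed = FALSE))
  names(params) <- varied
  if (is.null(covariance) && k > 0L) covariance <- diag(k)
  if (!is.null(covariance)) dimnames(covariance) <- list(varied, varied)
  structure(list(model_id = model_id, form = "stub", sample_id = sample_id,
                 params = stats::setNames(numeric(k), varied),
                 theta = stats::setNames(numeric(k), varied),
                 varied = varied, uncertainties = NULL,
                 covariance = covariance, conditioned = FALSE,
                 chi2_total = chi2_total, chi2_reduced = chi2_total / n,
                 n_points = as.integer(n), k_varied = as.integer(k),
                 converged = converged, n_evaluations = 0L,
                 spec = list(params = params)),
            class = "sas_fit")
}
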