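## Candidate form-factor models: Guinier, polydisperse sphere, polydisperse
## Gaussian coil (Schulz-Zimm), and their linear mixed model, plus Gaussian
## instrument-resolution smearing and windowed model evaluation.

check_q <- function(q) {
  if (!is.numeric(q) || any(!is.finite(q)) || any(q <= 0))
    domain_error("q must be finite and > 0")
}

#' Guinier intensity
#'
#' The Guinier law `I(q) = i_zero * exp(-q^2 rg^2 / 3) + background`, the
#' low-q approximation giving the radius of gyration of dilute particles.
#'
#' @param q scattering vector, 1/Angstrom, `> 0`.
#' @param i_zero forward intensity `I(0)`, `> 0`.
#' @param rg radius of gyration, Angstrom, `> 0`.
#' @param background flat background, `>= 0`.
#' @return Intensity at each `q`.
#' @export
guinier_intensity <- function(q, i_zero, rg, background = 0) {
  check_q(q)
  if (!all(is.finite(c(i_zero, rg, background))) || i_zero <= 0 || rg <= 0 ||
      background < 0)
    domain_error("guinier: need finite i_zero > 0, rg > 0, background >= 0")
  i_zero * exp(-q^2 * rg^2 / 3) + background
}

## Quadrature nodes/weights for a Gaussian radius distribution truncated at
## 3 sigma and r > 0: pd_nbins equal-width bins, midpoint nodes, weights
## proportional to the normal density, renormalized.
sphere_pd_nodes <- function(radius, pd_width, pd_nbins) {
  sigma <- pd_width * radius
  lo <- max(radius - 3 * sigma, .Machine$double.eps * radius)
  hi <- radius + 3 * sigma
  h <- (hi - lo) / pd_nbins
  r <- lo + (seq_len(pd_nbins) - 0.5) * h
  w <- stats::dnorm(r, radius, sigma)
  list(r = r, w = w / sum(w))
}

#' Sphere form-factor intensity with optional radius polydispersity
#'
#' Monodisperse: `I(q) = (scale / V) * (3 V drho * (sin(qr) - qr cos(qr)) /
#' (qr)^3)^2 + background` with `V = (4/3) pi r^3` and `drho = sld -
#' sld_solvent`.  For `pd_width > 0` the intensity is the number-weighted
#' quadrature of the monodisperse formula over a Gaussian radius
#' distribution (sigma = `pd_width * radius`) truncated at 3 sigma and
#' `r > 0`, using `pd_nbins` equal-width bins.
#'
#' The formula is implemented exactly as written, with no absolute-units
#' conversion constant; see [absolute_scale_factor] for conventional
#' (1e-6/Angstrom^2, 1/cm) bookkeeping.
#'
#' @param q scattering vector, 1/Angstrom, `> 0`.
#' @param scale volume-fraction-like weight, `>= 0`.
#' @param radius mean sphere radius, Angstrom, `> 0`.
#' @param sld,sld_solvent scattering length densities, 1/Angstrom^2; only
#'   the contrast `sld - sld_solvent` enters.
#' @param background flat background, `>= 0`.
#' @param pd_width relative width (sigma/r) of the radius distribution.
#' @param pd_nbins quadrature bins, `>= 3` when `pd_width > 0`.
#' @return Intensity at each `q`.
#' @export
sphere_intensity <- function(q, scale, radius, sld, sld_solvent = 0,
                             background = 0, pd_width = 0, pd_nbins = 81L) {
  check_q(q)
  if (!all(is.finite(c(scale, radius, sld, sld_solvent, background, pd_width))) ||
      scale < 0 || radius <= 0 || background < 0 || pd_width < 0)
    domain_error("sphere: need scale >= 0, radius > 0, background >= 0, pd_width >= 0")
  drho <- sld - sld_solvent
  if (pd_width == 0) {
    nodes <- list(r = radius, w = 1)
  } else {
    if (pd_nbins < 3L)
      config_error("sphere: pd_nbins must be >= 3 when pd_width > 0")
    nodes <- sphere_pd_nodes(radius, pd_width, pd_nbins)
  }
  scale * .sphere_pd_sum(q, nodes$r, nodes$w, drho) + background
}

#' Conventional absolute-intensity conversion factor
#'
#' When scattering length densities are bookkept in units of
#' 1e-6/Angstrom^2 and intensities in 1/cm, the bare sphere formula must
#' be multiplied by 1e-4 (= 1e-12 for the squared SLD times 1e8 for the
#' Angstrom-to-centimetre volume conversion).  Scale factors are free in
#' all fits, so this constant matters only for absolute-units reporting.
#'
#' @return The scalar `1e-4`.
#' @export
absolute_scale_factor <- function() 1e-4

#' Polydisperse Gaussian coil intensity
#'
#' Scattering of a Gaussian polymer chain with a Schulz-Zimm molecular
#' weight distribution.  With `U = pdi - 1` and `Z = q^2 rg^2`:
#' `P(q) = 2 * ((1 + U Z)^(-1/U) + Z - 1) / ((1 + U) Z^2)` for `U > 0`,
#' reducing to the Debye function `P(q) = 2 (exp(-Z) + Z - 1) / Z^2` at
#' `pdi = 1` (the switch happens below `U = 1e-6`); `P(0) = 1` by series
#' continuation for `Z < 1e-4`.  `I = scale * i_zero * P + background`.
#'
#' @param q scattering vector, 1/Angstrom, `> 0`.
#' @param scale weight, `>= 0`.
#' @param i_zero forward intensity, `> 0`.
#' @param rg radius of gyration, Angstrom, `> 0`.
#' @param pdi polydispersity index Mw/Mn of the Schulz-Zimm distribution, `>= 1`.
#' @param background flat background, `>= 0`.
#' @return Intensity at each `q`.
#' @export
poly_gauss_coil_intensity <- function(q, scale, i_zero, rg, pdi = 1,
                                      background = 0) {
  check_q(q)
  if (!all(is.finite(c(scale, i_zero, rg, pdi, background))) ||
      scale < 0 || i_zero <= 0 || rg <= 0 || background < 0)
    domain_error("poly_gauss_coil: need scale >= 0, i_zero > 0, rg > 0, background >= 0")
  if (pdi < 1) domain_error("poly_gauss_coil: pdi must be >= 1")
  Z <- q^2 * rg^2
  U <- pdi - 1
  P <- numeric(length(Z))
  small <- Z < 1e-4
  P[small] <- 1 - (1 + 2 * U) * Z[small] / 3
  zb <- Z[!small]
  if (U < 1e-6) {
    P[!small] <- 2 * (exp(-zb) + zb - 1) / zb^2
  } else {
    P[!small] <- 2 * ((1 + U * zb)^(-1 / U) + zb - 1) / ((1 + U) * zb^2)
  }
  scale * i_zero * P + background
}

#' Mixed coil + sphere intensity
#'
#' Linear composition `I = scale_a * I_coil(q) + scale_b * I_sphere(q) +
#' background` where the coil and sphere components are evaluated with
#' their own scale forced to 1 and background to 0; a single shared
#' background term contributes.  This model represents coexistence of
#' unimers and micelles across the critical micelle concentration.
#'
#' @param q scattering vector, 1/Angstrom, `> 0`.
#' @param scale_a coil weight, `>= 0`.
#' @param scale_b sphere weight, `>= 0`.
#' @param coil named list of coil parameters (`i_zero`, `rg`, `pdi`).
#' @param sphere named list of sphere parameters (`radius`, `sld`,
#'   `sld_solvent`, `pd_width`, optionally `pd_nbins`).
#' @param background shared flat background, `>= 0`.
#' @param pd_nbins polydispersity quadrature bins for the sphere part.
#' @return Intensity at each `q`.
#' @export
mixed_intensity <- function(q, scale_a, scale_b, coil, sphere, background = 0,
                            pd_nbins = 81L) {
  if (!all(is.finite(c(scale_a, scale_b, background))) ||
      scale_a < 0 || scale_b < 0 || background < 0)
    domain_error("mixed: need scale_a >= 0, scale_b >= 0, background >= 0")
  ic <- poly_gauss_coil_intensity(q, scale = 1, i_zero = coil$i_zero,
                                  rg = coil$rg, pdi = coil$pdi %||% 1,
                                  background = 0)
  is <- sphere_intensity(q, scale = 1, radius = sphere$radius,
                         sld = sphere$sld,
                         sld_solvent = sphere$sld_solvent %||% 0,
                         background = 0,
                         pd_width = sphere$pd_width %||% 0,
                         pd_nbins = sphere$pd_nbins %||% pd_nbins)
  scale_a * ic + scale_b * is + background
}

## Dispatch a flat named parameter vector to the model forms.
sas_intensity <- function(form, q, p, pd_nbins = 81L) {
  switch(form,
    guinier = guinier_intensity(q, p[["i_zero"]], p[["rg"]], p[["background"]]),
    sphere = sphere_intensity(q, p[["scale"]], p[["radius"]], p[["sld"]],
                              p[["sld_solvent"]], p[["background"]],
                              p[["pd_width"]], pd_nbins),
    poly_gauss_coil = poly_gauss_coil_intensity(q, p[["scale"]], p[["i_zero"]],
                                                p[["rg"]], p[["pdi"]],
                                                p[["background"]]),
    mixed = mixed_intensity(q, p[["scale_a"]], p[["scale_b"]],
                            coil = list(i_zero = p[["coil_i_zero"]],
                                        rg = p[["coil_rg"]],
                                        pdi = p[["coil_pdi"]]),
                            sphere = list(radius = p[["sphere_radius"]],
                                          sld = p[["sphere_sld"]],
                                          sld_solvent = p[["sphere_sld_solvent"]],
                                          pd_width = p[["sphere_pd_width"]]),
                            background = p[["background"]], pd_nbins = pd_nbins),
    domain_error(sprintf("unknown model form '%s'", form)))
}

## Quadrature rule for the Gaussian resolution kernel truncated at 3 sigma:
## Gauss-Legendre nodes on [-3, 3] with standard-normal density weights,
## renormalized so a constant model is smeared exactly.
smear_rule <- function(n_nodes) {
  gl <- pracma::gaussLegendre(n_nodes, -3, 3)
  w <- gl$w * stats::dnorm(gl$x)
  list(x = gl$x, w = w / sum(w))
}

#' Smear an ideal intensity model with a Gaussian q-resolution kernel
#'
#' Each reported `q[i]` is replaced by a weighted average of the ideal
#' model over `q[i] + x_j * d_q[i]`, where `x_j, w_j` is a Gaussian
#' quadrature rule truncated at `|x| <= 3` standard deviations.  Nodes
#' falling at `q' <= 0` are dropped and the remaining weights
#' renormalized.  Points with `d_q[i] = 0` return the ideal model
#' exactly.
#'
#' @param ideal function mapping a q vector to intensities.
#' @param q reported scattering vector, 1/Angstrom.
#' @param d_q 1-sigma resolution widths, `>= 0`, recycled if scalar.
#' @param n_nodes quadrature nodes, `>= 5`.
#' @return Smeared intensity at each `q`.
#' @export
smear_curve <- function(ideal, q, d_q, n_nodes = 21L) {
  check_q(q)
  if (n_nodes < 5L) config_error("smear_curve: n_nodes must be >= 5")
  d_q <- rep_len(d_q, length(q))
  if (any(!is.finite(d_q)) || any(d_q < 0))
    domain_error("smear_curve: d_q must be finite and >= 0")
  out <- numeric(length(q))
  zero <- d_q == 0
  if (any(zero)) out[zero] <- ideal(q[zero])
  if (any(!zero)) {
    rule <- smear_rule(n_nodes)
    qs <- q[!zero]; dqs <- d_q[!zero]
    ## n_curve x n_nodes matrix of shifted q values
    qp <- outer(qs, rep(1, n_nodes)) + outer(dqs, rule$x)
    wt <- matrix(rule$w, nrow = length(qs), ncol = n_nodes, byrow = TRUE)
    bad <- qp <= 0
    if (any(bad)) {
      wt[bad] <- 0
      qp[bad] <- qs[row(qp)[bad]]  # placeholder, weight zero
    }
    iv <- matrix(ideal(as.vector(qp)), nrow = length(qs))
    out[!zero] <- rowSums(iv * wt) / rowSums(wt)
  }
  out
}

#' Evaluate a model spec on a curve's fitting window
#'
#' Restricts the curve to the spec's `[q_min, q_max]` window, evaluates
#' the model form there, and applies Gaussian resolution smearing iff
#' the curve carries a `d_q` column.
#'
#' @param spec a [model_spec].
#' @param params named numeric vector/list covering the spec's parameters.
#' @param curve a [sas_curve].
#' @param n_nodes smearing quadrature nodes.
#' @return List with `intensity` (model values on the retained points)
#'   and `indices` (the retained index set into the curve).
#' @export
evaluate_model <- function(spec, params, curve, n_nodes = 21L) {
  stopifnot(inherits(spec, "model_spec"), inherits(curve, "sas_curve"))
  p <- unlist(params)
  idx <- which(curve$q >= spec$q_min & curve$q <= spec$q_max)
  if (length(idx) < 5L)
    insufficient_error(sprintf(
      "curve '%s': only %d points inside [%g, %g] for model '%s'",
      curve$sample_id, length(idx), spec$q_min, spec$q_max, spec$model_id))
  q <- curve$q[idx]
  ideal <- function(qq) sas_intensity(spec$form, qq, p, spec$pd_nbins)
  intensity <- if (is.null(curve$d_q)) ideal(q)
  else smear_curve(ideal, q, curve$d_q[idx], n_nodes)
  list(intensity = intensity, indices = idx)
}
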