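## Seeded synthetic-data generator: single curves with a counting-statistics
## noise model, and full three-component phase diagrams with known ground
## truth, emulating a poloxamer/phenol/benzyl-alcohol micellization system.

#' Counting-statistics noise model for reduced SAS data
#'
#' The per-point 1-sigma uncertainty is
#' `dI = sqrt(rel_floor^2 * I^2 + I / count_scale + bkg_sigma^2)`:
#' a multiplicative relative floor, a sqrt(I) counting term and an
#' additive constant.  Gaussian noise with this standard deviation is
#' used (reduced data are background-subtracted averages, so Gaussian
#' rather than Poisson), which keeps `dI` strictly positive by
#' construction whenever the intensity is positive.
#'
#' @param rel_floor multiplicative relative error, `>= 0`.
#' @param count_scale scale of the counting term, `> 0` (larger means
#'   less counting noise).
#' @param bkg_sigma additive constant term, `>= 0`.
#' @return A `noise_model` list.
#' @export
noise_model <- function(rel_floor = 0.01, count_scale = 1e4, bkg_sigma = 0) {
  if (rel_floor < 0 || count_scale <= 0 || bkg_sigma < 0)
    config_error("noise_model: need rel_floor >= 0, count_scale > 0, bkg_sigma >= 0")
  structure(list(rel_floor = rel_floor, count_scale = count_scale,
                 bkg_sigma = bkg_sigma), class = "noise_model")
}

#' A log-spaced q grid specification
#'
#' @param q_min,q_max grid range, 1/Angstrom.
#' @param n number of points.
#' @return Numeric q vector.
#' @export
q_grid <- function(q_min = 0.005, q_max = 0.4, n = 200L) {
  exp(seq(log(q_min), log(q_max), length.out = n))
}

#' Simulate one scattering curve from known truth parameters
#'
#' The ideal intensity is computed from the named form factor, smeared
#' with a Gaussian resolution kernel of width `dq = dq_frac * q`; the
#' observed intensity is `I_ideal + dI * eps` with `eps` iid standard
#' normal from a seeded generator and `dI` from the noise model
#' (evaluated on the ideal intensity).
#'
#' @param form model form (`"guinier"`, `"sphere"`, `"poly_gauss_coil"`,
#'   `"mixed"`).
#' @param truth named parameter vector/list for the form (flat names as
#'   in [model_spec]).
#' @param q q grid, e.g. from [q_grid].
#' @param noise a [noise_model].
#' @param dq_frac relative resolution width `dq/q`; 0 disables smearing
#'   and yields a 3-column curve.
#' @param seed integer seed.
#' @param sample_id curve name.
#' @param composition optional named concentrations.
#' @param pd_nbins sphere polydispersity bins.
#' @return List with `curve` (a [sas_curve]) and `truth` (form,
#'   parameters, seed).
#' @export
simulate_sas_curve <- function(form, truth, q = q_grid(),
                               noise = noise_model(), dq_frac = 0.02,
                               seed = 1L, sample_id = "sim",
                               composition = NULL, pd_nbins = 81L) {
  truth <- unlist(truth)
  ideal <- function(qq) sas_intensity(form, qq, truth, pd_nbins)
  d_q <- if (dq_frac > 0) dq_frac * q else NULL
  I_ideal <- if (is.null(d_q)) ideal(q) else smear_curve(ideal, q, d_q)
  if (any(!is.finite(I_ideal))) domain_error("non-finite ideal intensity")
  dI <- sqrt(noise$rel_floor^2 * I_ideal^2 + I_ideal / noise$count_scale +
               noise$bkg_sigma^2)
  if (any(dI <= 0))
    domain_error("noise model yields non-positive dI; add bkg_sigma or background")
  eps <- with_seed(seed, stats::rnorm(length(q)))
  curve <- sas_curve(sample_id, q, I_ideal + dI * eps, dI, d_q = d_q,
                     composition = composition)
  list(curve = curve, truth = list(form = form, params = truth, seed = seed))
}

#' Logistic micellization field over solution composition
#'
#' `f = logistic(alpha * phenol + beta * benzyl_alcohol + gamma * P188 - c0)`
#' gives the micellized fraction of surfactant in (0, 1); the truth
#' label is `"unimer"` for `f < f_lo`, `"mixed"` for
#' `f_lo <= f <= f_hi`, `"micelle"` for `f > f_hi`.  Positive `gamma`
#' reproduces micellization with increasing surfactant concentration
#' (CMC behaviour).
#'
#' @param composition named vector with `P188`, `phenol`,
#'   `benzyl_alcohol` (mg/ml).
#' @param cmc_rule list with coefficients `alpha`, `beta`, `gamma`, `c0`.
#' @return The micellized fraction `f`.
#' @export
micellization_field <- function(composition, cmc_rule) {
  comp <- unlist(composition)
  arg <- cmc_rule$alpha * comp[["phenol"]] +
    cmc_rule$beta * comp[["benzyl_alcohol"]] +
    cmc_rule$gamma * comp[["P188"]] - cmc_rule$c0
  stats::plogis(unname(arg))
}

label_of_f <- function(f, f_lo, f_hi) {
  ifelse(f < f_lo, "unimer", ifelse(f > f_hi, "micelle", "mixed"))
}

#' Specification of a synthetic three-component phase diagram
#'
#' Defaults emulate a poloxamer-P188/phenol/benzyl-alcohol system on a
#' 10 x 5 x 5 composition grid within the stock-solution ranges
#' (P188 up to 100 mg/ml, phenol up to 35 mg/ml, benzyl alcohol up to
#' 30 mg/ml): coil-like unimer scattering, sphere-like micelle
#' scattering (about 20-fold brighter per unit material), a logistic
#' micellization field whose steepness keeps the mixed region about one
#' phenol grid step wide, 2% q-resolution and counting-statistics noise.
#'
#' @param grid named list of level vectors for `P188`, `phenol`,
#'   `benzyl_alcohol` (mg/ml).
#' @param cmc_rule logistic coefficients, see [micellization_field].
#' @param f_lo,f_hi fraction cut points separating unimer / mixed /
#'   micelle truth labels.
#' @param coil_rg,coil_pdi unimer coil size (Angstrom) and
#'   polydispersity index.
#' @param sphere_radius,sphere_pd_width micelle radius (Angstrom) and
#'   relative radius polydispersity.
#' @param sphere_drho sphere SLD contrast (1/Angstrom^2); the default
#'   makes the sphere forward intensity 20 per unit scale at the true
#'   radius.
#' @param coil_i0_per_conc coil forward intensity per mg/ml of
#'   unmicellized P188.
#' @param sphere_i0_per_conc sphere forward intensity per mg/ml of
#'   micellized P188.
#' @param background flat background intensity.
#' @param q q grid.
#' @param dq_frac relative resolution width.
#' @param noise a [noise_model].
#' @param seed integer master seed.
#' @return A `phase_diagram_spec` list.
#' @export
phase_diagram_spec <- function(
    grid = list(P188 = seq(10, 100, length.out = 10),
                phenol = seq(0, 35, length.out = 5),
                benzyl_alcohol = seq(0, 30, length.out = 5)),
    cmc_rule = list(alpha = 3.0, beta = 0.3, gamma = 0.03, c0 = 30),
    f_lo = 0.05, f_hi = 0.95,
    coil_rg = 70, coil_pdi = 1.2,
    sphere_radius = 45, sphere_pd_width = 0.12,
    sphere_drho = sqrt(20 / (4 / 3 * pi * 45^3)),
    coil_i0_per_conc = 0.05, sphere_i0_per_conc = 1.0,
    background = 0.01,
    q = q_grid(0.005, 0.4, 120L), dq_frac = 0.02,
    noise = noise_model(rel_floor = 0.02), seed = 1L) {
  if (f_lo >= f_hi) config_error("need f_lo < f_hi")
  ranges <- list(P188 = c(0, 100), phenol = c(0, 35), benzyl_alcohol = c(0, 30))
  for (nm in names(ranges)) {
    lv <- grid[[nm]]
    if (is.null(lv) || any(lv < ranges[[nm]][1] | lv > ranges[[nm]][2]))
      config_error(sprintf("grid levels for %s must lie within [%g, %g] mg/ml",
                           nm, ranges[[nm]][1], ranges[[nm]][2]))
  }
  structure(list(grid = grid, cmc_rule = cmc_rule, f_lo = f_lo, f_hi = f_hi,
                 coil_rg = coil_rg, coil_pdi = coil_pdi,
                 sphere_radius = sphere_radius,
                 sphere_pd_width = sphere_pd_width, sphere_drho = sphere_drho,
                 coil_i0_per_conc = coil_i0_per_conc,
                 sphere_i0_per_conc = sphere_i0_per_conc,
                 background = background, q = q, dq_frac = dq_frac,
                 noise = noise, seed = as.integer(seed)),
            class = "phase_diagram_spec")
}

## Truth mixed-model parameters at one composition.
truth_params_at <- function(spec, comp, f) {
  c_p <- comp[["P188"]]
  V <- 4 / 3 * pi * spec$sphere_radius^3
  c(scale_a = spec$coil_i0_per_conc * c_p * (1 - f),
    scale_b = spec$sphere_i0_per_conc * c_p * f / (V * spec$sphere_drho^2),
    coil_i_zero = 1, coil_rg = spec$coil_rg, coil_pdi = spec$coil_pdi,
    sphere_radius = spec$sphere_radius, sphere_sld = spec$sphere_drho,
    sphere_sld_solvent = 0, sphere_pd_width = spec$sphere_pd_width,
    background = spec$background)
}

#' Simulate a full phase diagram with known ground truth
#'
#' At every grid composition the micellized fraction `f` comes from the
#' logistic field; the mixture intensity is `(1 - f)`-weighted coil plus
#' `f`-weighted sphere, both forward intensities tied to the P188
#' concentration, noised via [simulate_sas_curve].  Deterministic per
#' seed (each curve's noise seed derives from the master seed and the
#' sample id).
#'
#' @param spec a [phase_diagram_spec].
#' @return List with `curves` (list of [sas_curve]) and `truth` (data
#'   frame: sample id, composition, `f`, truth `label`, truth
#'   parameters as attribute `"params"`).
#' @export
simulate_phase_diagram <- function(spec = phase_diagram_spec()) {
  stopifnot(inherits(spec, "phase_diagram_spec"))
  grid <- expand.grid(P188 = spec$grid$P188, phenol = spec$grid$phenol,
                      benzyl_alcohol = spec$grid$benzyl_alcohol,
                      KEEP.OUT.ATTRS = FALSE)
  curves <- vector("list", nrow(grid))
  truth <- grid
  truth$sample_id <- sprintf("pt%03d", seq_len(nrow(grid)))
  truth$f <- NA_real_
  truth$label <- NA_character_
  params_list <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    comp <- c(P188 = grid$P188[i], phenol = grid$phenol[i],
              benzyl_alcohol = grid$benzyl_alcohol[i])
    f <- micellization_field(comp, spec$cmc_rule)
    p <- truth_params_at(spec, comp, f)
    sim <- simulate_sas_curve("mixed", p, q = spec$q, noise = spec$noise,
                              dq_frac = spec$dq_frac,
                              seed = derive_seed(spec$seed, truth$sample_id[i]),
                              sample_id = truth$sample_id[i],
                              composition = comp)
    curves[[i]] <- sim$curve
    truth$f[i] <- f
    truth$label[i] <- label_of_f(f, spec$f_lo, spec$f_hi)
    params_list[[i]] <- p
  }
  names(curves) <- truth$sample_id
  truth <- truth[, c("sample_id", "P188", "phenol", "benzyl_alcohol",
                     "f", "label")]
  attr(truth, "params") <- params_list
  list(curves = curves, truth = truth, spec = spec)
}

#' Write a simulated phase diagram to disk
#'
#' Emits one 4-column ASCII curve file per composition (the format
#' [read_sas_curve] reads), a `labels.csv` with compositions and truth
#' labels, and a `truth.json` manifest with the generator settings and
#' per-point truths.
#'
#' @param sim result of [simulate_phase_diagram].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_phase_diagram <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (cv in sim$curves)
    write_sas_curve(cv, file.path(outdir, paste0(cv$sample_id, ".dat")))
  utils::write.csv(sim$truth, file.path(outdir, "labels.csv"),
                   row.names = FALSE)
  manifest <- list(
    seed = sim$spec$seed,
    cmc_rule = sim$spec$cmc_rule,
    f_lo = sim$spec$f_lo, f_hi = sim$spec$f_hi,
    points = lapply(seq_len(nrow(sim$truth)), function(i)
      c(as.list(sim$truth[i, ]),
        list(params = as.list(attr(sim$truth, "params")[[i]])))))
  jsonlite::write_json(manifest, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
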