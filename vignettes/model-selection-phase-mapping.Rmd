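---
title: "Form-factor fitting, model selection and phase mapping for small-angle scattering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Form-factor fitting, model selection and phase mapping for small-angle scattering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A reduced small-angle scattering (SAS) measurement is a curve $I(q)$ with
per-point uncertainties $dI(q)$ and, often, an instrument resolution width
$dq(q)$.  Interpreting such curves usually means fitting analytic form-factor
models, and the hard part is rarely the optimization: it is deciding *which*
model the data support, automatically and reproducibly, when several
physically plausible candidates fit comparably well.  autosas implements that
workflow for a surfactant-preservative solution system: a small pool of
expert-constrained candidate models is fitted to every curve by bounded
least squares, an information-theoretic criterion picks the winner (or
declares that none of the candidates is adequate), and the winning models are
translated into phase labels, sizes and micelle fractions over a
solution-composition grid.

## The candidate models

All models are implemented exactly as their standard closed forms, with a
flat `background` added:

* **Guinier law**: $I(q) = I_0 \exp(-q^2 R_g^2 / 3)$.  Used for independent
  "expert" ground-truth labelling via the uptick of $I_0$; it is not part of
  the default selection pool.
* **Sphere**: $I(q) = \frac{\mathrm{scale}}{V}\left[3 V \Delta\rho
  \frac{\sin qr - qr\cos qr}{(qr)^3}\right]^2$, $V = \tfrac43\pi r^3$.
  Radius polydispersity is a number-weighted quadrature of this formula over
  a Gaussian radius distribution truncated at $3\sigma$ and $r>0$, with
  `pd_nbins` equal-width bins (default 81; doubling to 162 changes the
  intensity by less than $10^{-4}$ at widths up to 0.3).  The distribution
  family is a package choice; a stratified Monte-Carlo average over the same
  distribution serves as the correctness oracle in the tests.  No
  absolute-units constant is applied (see `absolute_scale_factor()` for the
  conventional $10^{-4}$ bookkeeping factor); scale factors are free in all
  fits, so units need not be resolved.
* **Polydisperse Gaussian coil**: $I = \mathrm{scale}\cdot I_0 P(q)$ with the
  Schulz–Zimm closed form $P = 2[(1+UZ)^{-1/U} + Z - 1]/[(1+U)Z^2]$,
  $Z = q^2R_g^2$, $U = \mathrm{PDI}-1$.  Below $U = 10^{-6}$ the code
  switches to the Debye function and below $Z = 10^{-4}$ to the series
  $P \approx 1 - (1+2U)Z/3$; the two branches agree to better than
  $10^{-6}$ relative across $Z \in [10^{-3}, 10^{3}]$.
* **Mixed model**: $I = \mathrm{scale}_A I_\mathrm{coil} +
  \mathrm{scale}_B I_\mathrm{sphere} + \mathrm{background}$, the exact
  linear composition with a single shared background; the component scale
  and background are pinned to 1 and 0.  It represents unimer–micelle
  coexistence across the critical micelle concentration (CMC), and the
  micelle fraction is read off as
  $f = \mathrm{scale}_B / (\mathrm{scale}_A + \mathrm{scale}_B)$.

**Resolution smearing.**  `dq` is interpreted as the 1-$\sigma$ width of a
Gaussian resolution kernel (the dominant reduced-data convention; the choice
matters only through a factor in the kernel width).  Smearing evaluates the
ideal model at Gauss–Legendre nodes on $\pm 3\sigma$ weighted by the normal
density, renormalized so constants are smeared exactly; nodes falling at
$q' \le 0$ are dropped and the weights renormalized.  21 nodes agree with a
$10^4$-point trapezoid convolution to better than $10^{-3}$ relative on the
oscillatory sphere model.  Curves without a `dq` column are fitted
unsmeared.  Smearing is applied inside the fit residual, i.e. the smeared
model is compared to the data.

## Fitting

`fit_sas()` minimizes $\chi^2_\mathrm{tot} = \sum_i \left[(I_\mathrm{model}(q_i)
- I_i)/dI_i\right]^2$ over the model's varied parameters within box bounds,
using the MINPACK Levenberg–Marquardt solver with bound clamping
(`minpack.lm::nls.lm`).  Reduced chi-squared divides by the point count $N$
(the $N-k$ variant is available via `chi2_divisor = "n_minus_k"`; the
selection criteria consume $\chi^2_\mathrm{tot}$, so the convention does not
leak into selection).  Defaults: 2000 iterations, tolerance $10^{-8}$.

The sphere and mixed models are multimodal (form-factor oscillations), so
their pool entries use seeded random restarts drawn uniformly within
bounds (2 by default); the Guinier and coil entries use none (2 for the
Guinier ground-truth preset, whose forward intensity can span decades).
Heavier restarting was evaluated and changes no fitted optimum in the
studies shipped with the package, because the deterministic
component-seeded starts below already cover the mixed model's
troublesome basins; the restart count is a pool setting, not a cap.
The pool also fits with 41 polydispersity quadrature bins — the 81-bin
evaluator default is for standalone evaluation; the 41-vs-162-bin
difference (~1e-4 relative) is two orders of magnitude below the noise
floor of any fitted curve.  When
`fit_sas_pool()` fits a mixed model it additionally seeds the fit with the
already-fitted pure-component solutions (coil with zero sphere weight,
sphere with zero coil weight, and a half/half combination).  These
deterministic starts make the mixed model's $\chi^2$ nest below both
components in practice — without them the optimizer occasionally parks in a
sphere-only local minimum on strongly micellar curves.  Every source of
randomness is seeded per (model, curve, seed), so batch results are
bit-reproducible and independent of iteration order.

Parameter covariance is $(J^\top J)^{-1}$ from a finite-difference Jacobian
of the weighted residuals at the optimum (relative step $10^{-6}$, one-sided
at active bounds); eigenvalues below $10^{-12}$ of the largest are floored
and a conditioning flag raised.  On linear submodels this matches the
analytic $(X^\top W X)^{-1}$ to better than $10^{-6}$ relative.

## Model selection

Four criteria are implemented, in increasing sophistication:

1. **Lowest $\chi^2_\mathrm{red}$** — transparent, but systematically
   prefers the most flexible model on noisy data (overfitting): on
   coil-generated curves it selects the mixed model far more often than AIC
   does, and its phase maps score markedly worse against ground truth.
2. **Modified Occam's razor** — among models within `occam_delta` (default
   1, i.e. one unit of reduced chi-squared) of the best reduced chi-squared,
   the fewest-varied-parameters model wins.  The comparison uses reduced
   chi-squared, matching the $\chi^2$-value phrasing of the rule.
3. **AIC** — $\chi^2_\mathrm{tot} + 2k$, the Gaussian-likelihood
   least-squares form with correctly weighted residuals (differences are
   then invariant to rescaling intensity and uncertainty together).  The
   alternative $N\ln(\chi^2_\mathrm{tot}/N) + 2k$ is available via
   `aic_form = "n_log_chi2"`.
4. **Probabilistic** — a Laplace approximation to the model evidence under
   independent uniform parameter priors, by default of width equal to each
   parameter's bound range:
   $\ln Z = -\chi^2_\mathrm{tot}/2 + \tfrac{k}{2}\ln 2\pi +
   \tfrac12 \ln\det C - \sum_j \ln \Delta\theta_j$,
   with $C$ the conditioned covariance.  Model probabilities are the
   softmax of $\ln Z$ under equal model priors, computed with log-sum-exp
   stabilization.  The Laplace form is validated against direct quadrature
   of the likelihood over the prior box on one- and two-parameter linear
   models (agreement well within 0.1 in $\ln Z$, exact for the pure
   Gaussian case).

Ties everywhere break deterministically: fewer varied parameters, then lower
reduced chi-squared, then lexicographic model id.  Finally a
goodness-of-fit gate replaces any winner whose reduced chi-squared exceeds
`gof_threshold` (default 10, strictly) with `NONE_OF_THE_ABOVE` — the
"no adequate model in the pool" flag.  The exact AIC and evidence formulas
are implementation-defined choices anchored by the quadrature oracle; both
standard AIC variants are exposed.

## From selections to phases

Labels derive deterministically from the selected form: coil → unimer,
mixed → mixed, sphere → micelle, gated → none.  Each point also carries a
Guinier-equivalent size: the fitted $R_g$ for the coil, $\sqrt{3/5}\,r$ for
the sphere (the exact Guinier radius of a homogeneous sphere), and for the
mixed model the forward-intensity-weighted combination
$R_{g,\mathrm{eff}}^2 = (w_c I_{0,c} R_{g,c}^2 + w_s I_{0,s} R_{g,s}^2) /
(w_c I_{0,c} + w_s I_{0,s})$ — the standard low-$q$ expansion of a
two-population mixture.

Boundaries are extracted per composition line (fixed P188 and benzyl
alcohol, ordered by phenol): the CMC point is the midpoint of the first
edge where the label leaves *unimer*, the micelle-conversion threshold
(MCT) the midpoint of the first edge where it enters *micelle*.  MCT is an
operational marker — the composition beyond which micelles dominate the
scattering volume — not a thermodynamic transition.  Boundary points are
edge midpoints; no surface interpolation is attempted.
`boundary_fraction_summary()` reports quartiles of the fitted micelle
fraction over the mixed points adjacent to each boundary, without
distributional smoothing.

The independent "expert" ground truth mimics a Guinier analysis: label
*micelle* when the fitted $I_0$ strictly exceeds `multiplier` times the mean
$I_0$ of the low-phenol baseline (lowest `baseline_quantile` of the phenol
range, default 0.2).  The function default multiplier is 1; for the
synthetic preset below the analyses pass `multiplier = 2.4`.  The reason is
structural: with $I_0$ proportional to surfactant concentration, some
high-concentration unimer always exceeds the baseline *mean*, so a
multiplier-1 threshold misclassifies it by construction.  The preset's
unimer branch tops out at $I_0 = 5$ and its micelle branch starts at
$I_0 = 10$; $2.4\times$ the baseline mean ($\approx 2.8$) puts the threshold
at $\approx 6.6$, between the branches with margin on both sides.

## The reference data-driven classifier

The comparison baseline interpolates $\log_{10} I$ onto a shared 128-point
log-spaced grid over the common $q$ range, standardizes each row, computes
Savitzky–Golay derivatives of orders 0–2 (window 11, polynomial order 3,
with respect to $\log q$), builds a Gaussian affinity per derivative order
(bandwidth = median nonzero pairwise distance), combines the three
affinities by elementwise geometric mean, and clusters the
symmetric-normalized Laplacian embedding with seeded k-means (20 restarts)
at a *fixed* cluster count.  Agreement between labelings is scored by the
Fowlkes–Mallows score (FMS), validated against brute-force pair counting.
These hyperparameters are declared package defaults, not tuned values; the
method needs the cluster count supplied and is an indicative benchmark, not
a definitive best.  Curve intensities that dip non-positive under noise are
clipped to a small positive floor before the log transform (and logged).

## The synthetic study system

The generator stands in for a poloxamer-P188 / phenol / benzyl-alcohol
formulation dataset.  Per composition, a micellized fraction
$f = \mathrm{logistic}(\alpha\,\mathrm{phenol} + \beta\,\mathrm{BA} +
\gamma\,\mathrm{P188} - c_0)$ splits the surfactant between a coil
(forward intensity $0.05\,c_\mathrm{P188}(1-f)$) and a sphere (forward
intensity $1.0\,c_\mathrm{P188} f$); truth labels are unimer below
$f = 0.05$, micelle above $0.95$, mixed between.  Gaussian noise with
$dI = \sqrt{(0.02 I)^2 + I/10^4}$ and a $dq/q = 0.02$ resolution column
emulate counting statistics of reduced synchrotron data (Gaussian rather
than Poisson because reduced data are background-subtracted averages).
Defaults and why:

* **Coil $R_g = 70$ Å, PDI 1.2** — chosen so the unimer preset genuinely
  shows the coil-like $q^{-2}$ regime over the 0.03–0.11 Å$^{-1}$ analysis
  window (log–log slope $-1.88$); a chain small enough to probe only the
  Guinier shoulder there would not reproduce the qualitative mid-$q$
  contrast that separates the phases.
* **Sphere $r = 45$ Å, $\sigma_r/r = 0.12$** — micelle-like, with the
  smeared Guinier-to-Porod crossover steepening past $-3$ in the same
  window.
* **Brightness contrast 20** — the sphere's forward intensity per unit
  material is 20 times the coil's, an aggregation-number-like contrast.
  The pool's sphere SLD is normalized so that $V\Delta\rho^2 = 20$ at the
  true radius, which makes the fitted mixed-model scale ratio estimate the
  generator's micellized fraction directly.  Much larger contrasts make the
  coil component statistically invisible through most of the mixed band
  (its fraction then cannot be recovered); much smaller ones collapse the
  $I_0$ uptick that the Guinier ground truth relies on.
* **Field steepness** ($\alpha = 3$ per mg/ml phenol, $c_0 = 30$, weaker
  benzyl-alcohol and P188 terms) — a fitted classifier detects a sphere
  component well below the $f = 0.05$ label cut (a percent-level intensity
  contribution is statistically significant over a hundred points at 2%
  noise), so compositions sitting in that detectable-but-below-cut band are
  intrinsically ambiguous.  A steep field keeps the band to a fraction of a
  phenol grid step: disagreements shift an extracted boundary by at most
  one step instead of erasing it.
* **Mixed-model coil size bounds [40, 120] Å** — the expert-constraint
  principle: the unimer size is known from the pure-unimer region, so the
  coexistence model's coil is confined to it.  Unconstrained, the barely
  visible coil component of micelle-dominated curves drifts to degenerate
  sizes and corrupts the micelle-fraction estimate.
* **Grid** — 10 P188 levels (10–100 mg/ml) by 5 phenol (0–35) by 5 benzyl
  alcohol (0–30), the stock-solution ranges; 120 log-spaced $q$ points in
  0.005–0.4 Å$^{-1}$ per curve (the parameter-recovery studies use 200).
  These sizes keep a full 250-curve, 3-model mapping within minutes on one
  CPU while leaving every phase and both boundaries represented.

What the generator does *not* emulate: inter-particle structure factors,
the turbid-aggregate phase, solvent-contrast series, non-Gaussian outliers,
and instrument artefacts (beamstop spill, detector seams).  Passing tests
therefore demonstrate the machinery's correctness and the selection logic's
behaviour under realistic counting noise — not performance on arbitrary
experimental data, where model inadequacy (caught by the gate) and
structure-factor effects dominate the difficulty.

## Worked example

```{r, eval = FALSE}
library(autosas)

sim   <- simulate_phase_diagram(phase_diagram_spec(seed = 1))
fits  <- fit_sas_pool(default_model_pool(), sim$curves, fit_settings(seed = 2))
sels  <- select_models(fits, selection_settings("aic"))
map   <- build_phase_map(sels, fits)
table(map$label)
extract_boundaries(map)
boundary_fraction_summary(map)

## agreement with the generator's truth
truth <- sim$truth[match(map$sample_id, sim$truth$sample_id), ]
fowlkes_mallows(map$label, truth$label)
```

## Numerical choices and degenerate inputs

* Sphere kernel: series below $qr = 10^{-2}$; the polydispersity loop uses
  an angle-addition recurrence over the equally spaced radius nodes
  (compiled code), agreeing with direct evaluation to $10^{-13}$.
* Restart draws, noise draws and k-means restarts run under seeds derived
  from the user seed and stable identifiers; the caller's RNG state is
  saved and restored.
* Fits that cannot be evaluated return `converged = FALSE` results rather
  than raising, so one bad cell never aborts a batch; curves with fewer
  than 5 points in a model's window are flagged per-cell the same way.
* Rows with $q \le 0$ or $dI \le 0$ are dropped at read time and logged
  (`sas_log()`); fewer than 5 surviving rows is a malformed-input error.
* Probabilities are computed by log-sum-exp; evidence uses the conditioned
  covariance determinant, so near-singular fits are penalized rather than
  fatal.

## Known limitations

* Only the four forms of the study are implemented — no cylinders,
  core–shell variants or structure factors; the gate is the designed
  escape hatch when none applies.
* The LM optimizer handles bounds by clamping; parameters that converge
  onto a bound get a conditioning flag, and their 1-$\sigma$ uncertainties
  should be read as approximate.
* The probabilistic criterion inherits the Laplace approximation's bias on
  strongly non-Gaussian posteriors (e.g. weakly identified mixed fits near
  the pure-micelle end), where it tends toward the simpler model.
* The micelle fraction is identifiable only while both components
  contribute detectably; near the band edges its uncertainty grows
  regardless of optimizer quality.
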