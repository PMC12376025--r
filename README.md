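# autosas

Automated small-angle scattering (SAS) model fitting, information-theoretic
model selection, and phase mapping — for scientists who need reduced 1-D
SAXS/SANS curves turned into physically meaningful labels without a human
in the loop for every curve.

A measurement is a curve `q, I(q), dI(q)[, dq(q)]`.  autosas fits a small
pool of expert-constrained form-factor models to every curve by bounded
Levenberg–Marquardt weighted least squares, picks the best model per curve
by one of four criteria, and converts the winners into phase labels and
structural descriptors over a solution-composition grid.  The built-in
candidate set targets a surfactant/preservative formulation (poloxamer
P188 with phenol and benzyl alcohol):

| model | form | represents |
|---|---|---|
| `poly_gauss_coil` | Schulz–Zimm polydisperse Gaussian coil, `I = scale·I₀·P(q) + bkg` | free unimer chains |
| `sphere` | `I = (scale/V)·[3VΔρ(sin qr − qr·cos qr)/(qr)³]² + bkg`, Gaussian radius polydispersity | micelles |
| `mixed` | `scale_A·I_coil + scale_B·I_sphere + bkg` | unimer–micelle coexistence |
| `guinier` | `I₀·exp(−q²Rg²/3) + bkg` | ground-truth labelling only |

Selection criteria: lowest reduced χ² (`χ²_red = Σ[(I_model−I)/dI]²/N`),
a modified Occam's razor (simplest model within `occam_delta = 1` of the
best χ²), AIC (`χ²_tot + 2k`), and a probabilistic method (Laplace
approximation to the model evidence under uniform priors, softmax over
models).  A goodness-of-fit gate labels curves `NONE_OF_THE_ABOVE` when
even the winner's χ²_red exceeds a threshold — the signal that no adequate
model is in the pool.  Phase analysis derives labels (coil→unimer,
mixed→mixed, sphere→micelle), Guinier-equivalent sizes, micelle fractions
`scale_B/(scale_A+scale_B)`, and critical-micelle-concentration (CMC) and
micelle-conversion-threshold (MCT) boundaries along phenol lines.  A
derivative-similarity spectral-clustering classifier is included as the
data-driven comparison baseline, and a seeded synthetic-data generator
produces full phase diagrams with known ground truth.

## Worked example

```r
library(autosas)

## three compositions along a phenol line of the synthetic P188 preset
sim  <- simulate_phase_diagram(phase_diagram_spec(
          grid = list(P188 = 60, phenol = c(0, 8.5, 28), benzyl_alcohol = 10),
          seed = 1))
fits <- fit_sas_pool(default_model_pool(), sim$curves, fit_settings(seed = 2))
sels <- select_models(fits, selection_settings("aic"))
map  <- build_phase_map(sels, fits)
as.data.frame(map)[, c("phenol", "selected_model", "label",
                       "rg_effective", "micelle_fraction")]
#>   phenol  selected_model   label rg_effective micelle_fraction
#> 1    0.0 poly_gauss_coil  unimer     69.94014               NA
#> 2    8.5           mixed   mixed     38.11037         0.499949
#> 3   28.0          sphere micelle     34.86244               NA
```

AIC picks the coil at zero phenol (unimer, fitted Rg ≈ 70 Å), the mixed
model at the micellization boundary (fitted micelle fraction 0.50 against
a generator truth of 0.57), and the pure sphere at high phenol (Rg_eff =
√(3/5)·r ≈ 34.9 Å for the 45 Å micelle).  The mixed fit itself:

```r
summary(fits[["pt002"]]$mixed)
#> Fit of model 'mixed' (mixed) to curve 'pt002'
#>                      estimate std_error
#> scale_a             1.7185151    0.3446
#> scale_b             1.7181643    0.0072
#> coil_rg            79.0528068    7.6056
#> sphere_radius      44.9341825    0.0542
#> sphere_pd_width     0.1201319    0.0016
#> background          0.0099314    0.0006
#> chi2_total = 99.4946 on N = 120 points, k = 6 varied; chi2_reduced = 0.829122
```

χ²_red ≈ 0.83 means the model describes the data to within the stated
uncertainties; the large `scale_a` error reflects the genuine difficulty
of seeing a 4%-intensity coil component beside a micelle.

A command-line front-end wraps the same functions:

```sh
Rscript inst/cli/autosas simulate --preset p188 --seed 1 --outdir sim/
Rscript inst/cli/autosas fit --config cfg.json --data sim/ --criterion aic --output report.json
Rscript inst/cli/autosas classify-ml --data sim/ --k 3 --output ml.csv
Rscript inst/cli/autosas evaluate --pred report.json --truth sim/labels.csv
```

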