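# lucifit

Progress-curve kinetics for luciferase bioluminescence assays.

Luciferases report on biology by emitting light: every catalytic turnover of
a luciferin substrate yields a photon, so a plate-reader luminescence trace
is a direct, if uncalibrated, record of the reaction rate. lucifit is for
enzymologists and protein engineers who characterize luciferase variants
(e.g. NanoLuc-type enzymes with coelenterazine or furimazine) and want full
kinetic constants — not just initial rates — from injection-assay time
series.

## The model

The mechanism is Michaelis–Menten catalysis with two inhibitory complexes:
a competitive enzyme–product complex EP (dissociation constant K_p, the
origin of flash-type luminescence decay) and an uncompetitive dead-end
enzyme–substrate–substrate complex ESS (dissociation constant K_s,
substrate inhibition). The quasi-steady-state rate law is

    v = k_cat * E0 * S / ( K_m * (1 + P/K_p) + S * (1 + S/K_s) )

Recorded intensity is the average product-formation rate over each read
window scaled by a signal factor f (RLU·s per µM); its running integral —
the cumulative luminescence, proportional to product concentration — lets
full conversion curves be fitted in relative units, with f pinned by the
end state of curves run to complete conversion. `fit_global()` fits all
curves of a 0.25–4 × K_m concentration series simultaneously (bounded
Levenberg–Marquardt in log-parameter space, sigma-normalized residuals,
per-level ±5% concentration corrections), returning k_cat, K_m, K_p (and
K_s) with standard errors. Identifiability is probed with FitSpace-style
profile-likelihood confidence contours. A mass-action simulator, a
plate-reader-like synthetic data generator, initial-rate fitting, and
delta-method error propagation for specificity constants (k_cat/K_m) and
fold changes round out the workflow.

## Worked example

Simulate a wild-type/coelenterazine study at its published constants
(k_cat = 2.48 s⁻¹, K_m = 0.57 µM, K_p = 0.256 µM), then refit it:

```r
library(lucifit)

truth <- tibble::tibble(variant = "WT", luciferin = "CTZ",
                        k_cat = 2.48, K_m = 0.57, K_p = 0.256, K_s = Inf,
                        E0_uM = 0.01, scaling_f = 1e6)
study  <- generate_study(truth, design = series_design(replicates = 3),
                         noise = noise_model(seed = 42), read_interval_s = 2)
curves <- study_conversion_curves(study)
fit    <- fit_global(curves, E0 = 0.01, multistart_n = 2, seed = 42)
fit
#> <lucifit_fit>  scheme mm_prod_inhib, chi2 = 3317 (3377 points, 24 params)
#> # A tibble: 3 × 3
#>   term  estimate      se
#>   <chr>    <dbl>   <dbl>
#> 1 k_cat    2.44  0.0286
#> 2 K_m      0.562 0.00720
#> 3 K_p      0.252 0.00306
#> scaling_f = 1.01537e+06 RLU.s/uM
```

All three constants are recovered within roughly two standard errors of the
generating values under 2% read noise and ±5% concentration jitter, and the
reduced chi-squared (`glance(fit)$reduced_chi2`, 0.99 here) confirms the
noise model is consistently propagated. Derived quantities carry
first-order errors:

```r
specificity_constant(2.44, 0.562, 0.029, 0.007)
#> # A tibble: 1 × 3
#>   name                 value     se
#> 1 specificity_constant  4.35 0.0755
```

`confidence_contours(fit, c("k_cat", "K_m"))` maps the jointly acceptable
region; `autoplot()` works on fits and contour maps, and `tidy()`,
`glance()`, `augment()` follow the broom conventions. `run_pipeline()` ties
the stages together from a single seeded configuration.

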