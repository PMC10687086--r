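---
title: "Progress-curve kinetics of luciferase bioluminescence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Progress-curve kinetics of luciferase bioluminescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

lucifit analyses injection-assay luminescence of luciferase reactions — an
enzyme E oxidizing a luciferin substrate S to an oxidized amide product P,
each turnover emitting light. The mechanism is Michaelis–Menten catalysis
extended by two inhibitory complexes:

* **EP** — the enzyme–product complex with dissociation constant $K_p$
  (µM). Product rebinding competes with substrate for free enzyme; a low
  $K_p$ produces flash-type luminescence, a fast decay long before the
  substrate is exhausted.
* **ESS** — a dead-end enzyme–substrate–substrate complex with dissociation
  constant $K_s$ (µM), giving substrate inhibition at high substrate.
  $K_s = \infty$ (the default) switches the pathway off.

Under the quasi-steady-state approximation (QSSA) the reaction rate is

$$v \;=\; \frac{k_{cat}\,E_0\,S}{K_m\left(1 + P/K_p\right) + S\left(1 + S/K_s\right)},$$

which is the standard algebra for a competitive EP complex and an
uncompetitive dead-end ESS complex; with $K_p = K_s = \infty$ it reduces
exactly to $k_{cat} E_0 S / (K_m + S)$. Progress curves integrate
$dP/dt = v(S_0 - P,\, P)$ from injection. `simulate_mass_action()` integrates
the same network at the level of elementary steps (one shared association
rate $k_1$, ES dissociation fixed by $K_m = (k_{off}+k_{cat})/k_1$, EP and
ESS as rapid equilibria); the QSSA and mass-action routes agree to within 1%
once binding is fast ($k_1 \gtrsim 1000\ \mu M^{-1} s^{-1}$), which is one of
the package's standing cross-checks. Units are fixed package-wide: µM,
seconds, RLU (relative light units).

Because `product_uM` in a mass-action run means *total turned-over product*
(free P plus enzyme-bound EP), completion sends it to $S_0$ even when a
fraction of product remains enzyme-bound; the species map reports free P and
EP separately.

## From photons to concentrations

A plate reader integrates photons over each read window, so recorded
intensity is modelled as the average product-formation rate over the
interval times a signal scaling factor $f$ (RLU·s per µM):
$I_i = f\,(P(t_i)-P(t_{i-1}))/\Delta t_i$. Summing $I_i \Delta t_i$
telescopes to $f P(t)$ — the *cumulative luminescence* or conversion curve —
which is why full progress curves can be fitted in relative units without
absolute photon-yield calibration: $f$ is determined by the end state of
curves run to complete conversion.

When a reaction is too slow to complete within the 1000 s monitoring cap,
$f$ is not identifiable from the series: `calibrate_scaling()` then supplies
it from an excess-enzyme run driven to > 99.5% conversion, and
`fit_global(scaling_f_fixed = ...)` imposes it. The calibration corrects its
plateau for the unconverted remainder by extrapolating the terminal
exponential intensity decay (remaining signal $\approx I_{end}/|\text{decay
rate}|$); without this the stop rule's 0.5% cutoff leaves an irreducible
downward bias of the same order in $f$.

## The two-stage workflow

1. **Initial rates** (`initial_velocity()`, `fit_initial_rates()`): the
   slope of the conversion curve over the first 15 s gives $v_0$ per
   substrate concentration; weighted nonlinear regression of
   $v_0 = V_{max} S/(K_m + S + S^2/K_s)$ yields a provisional $K_m$ that
   seeds stage 2 and defines the 0.25–4 × $K_m$ concentration series.
2. **Global progress-curve fit** (`fit_global()`): all curves of a series
   are fitted simultaneously by bounded Levenberg–Marquardt in
   log-parameter space (positivity without penalties; the constants span
   three decades). Free quantities: the kinetic constants of the chosen
   scheme, one scaling factor, and one multiplicative concentration
   correction per level, hard-bounded to [0.95, 1.05] to reflect ±5%
   preparation accuracy.

Derived quantities (`specificity_constant()`, `fold_change()`) carry
first-order (delta-method) standard errors assuming independent inputs —
the convention when published tables report ± values without covariances;
the contour machinery is the corrective for correlated pairs.

## Statistical choices

**Whitened objective.** The natural observable of the workflow is the
conversion curve, but with independent read noise the cumulative curve's errors form a random
walk: consecutive residuals share all preceding noise draws. Naively
sigma-normalized least squares on the running sum therefore overstates the
information (we measured reduced $\chi^2 \approx 0.15$ and far-too-small
confidence regions). Differencing the cumulative curve recovers exactly the
independent per-read intensities, so the default objective
(`observable = "intensity"`) normalizes the per-interval increments — the
GLS-whitened fit of the same conversion curve. `observable = "cumulative"`
retains the naive form for comparison; estimates barely move, but only the
whitened mode has calibrated standard errors and contours.

**Residual background offsets.** The 10 s pre-injection baseline estimates
the background as its median; the estimate's error (SE
$\approx 1.25\,\sigma/\sqrt{n}$) survives subtraction as a small constant
offset on every read of that well. Ignoring it degrades contour coverage
badly (we measured ~60% where 95% is nominal). Since the offset enters the
intensity model linearly, each well's offset is profiled in closed form
under a Gaussian prior at that SE, at no extra cost to the optimizer;
profiled offsets are counted in the fitted-parameter total.

**Concentration-scale gauge.** Scaling $k_{cat}, K_m, K_p, K_s$ and all
$S_0$ by a common factor $c$ while dividing $f$ by $c$ leaves every curve
unchanged — a exact one-dimensional degeneracy once per-level concentration
corrections are free. The nominal concentrations define the scale: the
corrections carry a weak Gaussian pull toward 1 (SD 0.025, keeping ~95% of
draws inside the ±5% box), and after optimization the geometric-mean
correction is folded back into the kinetic constants (an exact symmetry
operation) before a final polish. The reported $\chi^2$ is the data-only
objective.

**Confidence contours.** `confidence_contours()` maps the profiled
$\chi^2$ over a log-spaced grid for a parameter pair, re-optimizing every
other fitted quantity at each node. The boundary uses
$\chi^2_{min}\,(1 + \tfrac{2}{n-p} F_{0.95}(2, n-p))$ — the two-dimensional
profile-region rule, which we verified covers the generating pair ~95% of
the time in refit studies; the all-parameter variant ($F(p, n-p)$) is the
more conservative joint region. On a linear-Gaussian toy the numerical
boundary matches the analytic covariance ellipse to within one grid cell.

## The synthetic-data generator

`generate_study()` emulates the injection assay end to end: 10 s
background-only baseline (default 100 RLU — instrument backgrounds are not
standardized, so the value used is recorded), injection, sampling at a fixed
read interval, and termination at the first read where the 5-point running
median of the background-free signal falls below 0.5% of its running
maximum, or at the 1000 s cap. The centered running median leaves zero-noise
traces stopping at exactly the first sub-threshold read while protecting
noisy traces from premature stops.

Defaults and their reasons:

| Parameter | Default | Why |
|---|---|---|
| proportional CV | 0.02 | replicate-level scatter typical of injector reads |
| additive SD | 5 RLU | detector noise floor |
| read interval | 0.5 s | resolves the fastest series ($k_{cat} \approx 8\,s^{-1}$ at nM enzyme) |
| concentration jitter | ±5% uniform, per level | dilution series prepared once; replicates share the prepared solution |
| $K_s$ truth | $\infty$ | the published table constrains no $K_s$; a finite preset (20 µM) exercises the ESS pathway |
| scaling factor | $10^6$ RLU·s/µM | arbitrary detector gain |

Noise is Gaussian with SD $\sqrt{(cv \cdot I)^2 + sd^2}$; the generating SD
is recorded per point, so sigma-normalized residuals are exactly unit-scaled
under the truth. Noise-free runs record sigma = 1 RLU (unit weights). The
generator does **not** emulate injector mixing artifacts, well crosstalk,
detector saturation or photobleaching — passing recovery tests show the
estimator is correct under the assumed noise law, not that real instruments
obey it.

## Numerical choices and problem sizes

The stiff-capable lsoda integrator (compiled right-hand sides) runs at
rel_tol $10^{-8}$, abs_tol $10^{-10}$ µM, with output evaluated exactly at
the read times. The QSSA route is independently verified against a 1 ms
explicit-Euler oracle (0.1% sup-norm). Multistart initialization perturbs
log-parameters uniformly within ×/÷3; ties break by lowest $\chi^2$, then
lowest parameter norm.

Validation studies bundled with the package run at desk scale, chosen once:
recovery and coverage studies use a 2 s read grid (statistically equivalent
information per curve shape, four times fewer points than the 0.5 s
acquisition default), the noisy recovery study uses the wild-type/CTZ
parameter set with 3 replicates across 100 seeds, and coverage studies use
3-level series with single replicates. Noiseless recovery is exercised on
all eight published parameter sets.

## Known limitations

* The Y94A mutant is reported to follow an altered kinetic scheme whose
  exact topology is not public; the scheme variants of `kinetic_scheme()`
  cover the plausible space.
* With all curves truncated below ~50% conversion the scaling factor is
  weakly identified (its SE inflates more than fivefold) — a documented
  failure mode, surfaced rather than patched.
* Ratio SEs assume independent numerator and denominator; for strongly
  correlated pairs read the contour maps instead.
* A common-mode concentration error beyond the ±5% box is fundamentally
  indistinguishable from a rescaling of the kinetic constants; no fit can
  recover it.
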