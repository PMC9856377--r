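# epibarrier

Quantification of epithelial transport and barrier function from
Ussing-chamber experiments on intestinal mucosa.

Functional studies of colonic biopsies — for example in irritable bowel
syndrome, where a "leaky gut" for macromolecules can coexist with normal
ionic barrier function — rest on a chain of quantifications that is usually
scattered across instrument software and spreadsheets. `epibarrier`
implements that chain as tested, reusable R functions:

* **Impedance spectroscopy.** The transepithelial impedance sampled at 48
  frequencies (1.3 Hz–65 kHz) is fitted with the one-path equivalent
  circuit `Z(f) = R^sub + R^epi / (1 + i·2πf·R^epi·C)`, decomposing the
  transmural resistance into the epithelial part `R^epi = R^t − R^sub`
  (barrier function proper) and the subepithelial series part, plus the
  epithelial capacitance. End-intercept reading is available as a
  fallback method.
* **Short-circuit current dissection.** Baseline Isc; bumetanide-sensitive
  ΔIsc (active anion secretion: maximum Isc before vs 20 min after the
  blocker); amiloride-sensitive ΔIsc (ENaC-mediated Na⁺ absorption, by
  plateau difference) with Faraday conversion to µmol·h⁻¹·cm⁻².
* **Tracer permeability.** Fluorescein and FITC-dextran-4000 appearance in
  the basolateral compartment, through fluorescence calibration and an OLS
  appearance rate, to flux `J` and apparent permeability `P = J/Δc` in
  cm/s with explicit unit conversion.
* **Tricellular tight-junction delocalization.** The tTJ/bTJ intensity
  ratio from junctional line profiles (anchor vs ±2 µm), aggregated
  per section and per subject.
* **Crypt morphometry.** Mucosal-to-serosal surface amplification
  `1 + nπdL` from inner crypt diameter, length and density; apoptosis rate
  from nucleus counts.
* **Upstream-regulator statistics.** One-sided Fisher/hypergeometric
  overlap p-values and sign-concordance activation z-scores
  `(n_agree − n_disagree)/√N` over a DE results table and a signed
  regulator→target network.
* **Cohort reporting.** Per-subject metric tables, pooled Student t
  comparisons with the n.s./*/**/*** convention, and a summary report —
  end-to-end via `runPipeline()`.

A seeded synthetic cohort generator (`simulateCohort()`,
`defaultCohortConfig()`) emulates every input modality with known ground
truth, so each stage supports exact parameter-recovery testing without
patient data. See the methods vignette
(`vignettes/epibarrier-methods.Rmd`) for the models, conventions and their
rationale.

## Worked example

Fit a noisy simulated spectrum and recover the circuit parameters:

```r
library(epibarrier)
sp  <- simulateImpedanceSpectrum(rSub = 12, rEpi = 25, cap = 3e-6,
                                 noiseSd = 0.01, seed = 42)
fitOnePath(sp)
#> OnePathFit (fit): rSub = 12, rEpi = 25.1, rT = 37 Ohm.cm2, cap = 2.99 uF/cm2
#>   residual norm 2.58, converged
```

The true values (12, 25, 3 µF) are recovered within the 1% measurement
noise. The permeability chain on the hand-worked accumulation series —
0.5 nmol per 15 min over 0.049 cm² at Δc = 100 µM:

```r
fs <- FluxSeries("fluorescein", c(0, 15, 30, 45, 60),
                 amounts = c(0, 0.5, 1, 1.5, 2), amountUnit = "nmol",
                 apicalConc = 1e-4, area = 0.049)
fluxFromSeries(fs)
#> PermeabilityResult: J = 4.082e-08 mol/h/cm2, P = 0.0001134 cm/s (r2 = 1.0000, n = 5)
```

i.e. J = 40.8 nmol·h⁻¹·cm⁻² and P = 1.134 × 10⁻⁴ cm/s. A full synthetic
cohort under the packaged default configuration, analyzed end to end:

```r
rep <- runPipeline(simulateCohort(defaultCohortConfig(seed = 7)))
rep$comparisons[, c("metric", "mean_control", "mean_ibsm", "t", "p", "label")]
#>                metric mean_control mean_ibsm     t        p label
#>                 r_epi     2.38e+01  2.71e+01 -0.75 4.65e-01  n.s.
#>          baseline_isc     1.74e+02  6.35e+01  2.77 1.42e-02     *
#>  delta_isc_bumetanide     5.78e+01  2.02e+01  4.03 1.10e-03    **
#>         p_fluorescein     6.01e-07  2.07e-06 -3.77 1.87e-03    **
#>             ttj_ratio     2.38e+00  1.28e+00  7.31 2.58e-06   ***
#>                  j_na     5.35e-01  3.85e-01  1.28 2.19e-01  n.s.
```

The disease arm shows the expected pattern: reduced bumetanide-sensitive
secretion, unchanged epithelial resistance and sodium absorption, a
roughly 4-fold fluorescein permeability increase, and a collapsed tTJ/bTJ
ratio. The cohort-level regulator ranking recovers the simulated
proinflammatory activation (`rep$regulators`).

Published mean ± SD tables can be checked directly:

```r
tTestFromSummary(138, 75, 10, 74, 35, 6)   # pooled t = 1.95, p = 0.072, n.s.
```

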