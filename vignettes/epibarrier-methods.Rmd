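---
title: "Methods: quantifying epithelial transport and barrier function"
author: "epibarrier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying epithelial transport and barrier function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epibarrier)
```

# Overview

`epibarrier` implements the quantification chain of an Ussing-chamber study
of colonic mucosal biopsies: impedance spectroscopy with equivalent-circuit
decomposition of the transepithelial resistance, pharmacological dissection
of the short-circuit current, paracellular tracer-flux permeability,
tricellular tight-junction (tTJ) delocalization scoring from junctional
intensity profiles, crypt morphometry, upstream-regulator enrichment
statistics, and two-group cohort reporting. Because patient biopsies are
not distributable, the package pairs every analysis stage with a seeded
synthetic-data generator whose ground truth is known exactly; all
validation is parameter recovery against that truth, against independent
brute-force oracles, or against analytic identities.

# Impedance spectroscopy and the one-path circuit

A mounted biopsy is probed with 48 discrete sine-wave frequencies spanning
1.3 Hz to 65 kHz. The tissue is modelled as a subepithelial series
resistance $R^{sub}$ in front of a parallel RC element for the epithelium:

$$Z(f) = R^{sub} + \frac{R^{epi}}{1 + i\,2\pi f\,R^{epi} C}.$$

At low frequency $\mathrm{Re}(Z) \to R^t = R^{sub} + R^{epi}$; at high
frequency the epithelial capacitance $C$ shorts the RC element and
$\mathrm{Re}(Z) \to R^{sub}$. The epithelial resistance is the difference
$R^{epi} = R^t - R^{sub}$ and reflects tight-junctional barrier function.
The Nyquist locus ($-\mathrm{Im}$ vs $\mathrm{Re}$) is a semicircle of
diameter $R^{epi}$ whose apex sits at $f_c = 1/(2\pi R^{epi} C)$.

Classically $R^t$ and $R^{sub}$ are read off the two frequency ends of the
Nyquist plot. `fitOnePath()` instead fits the full complex model to all 48
points by unweighted least squares on the stacked real and imaginary
residuals, because the full fit uses every sample and is markedly more
robust to measurement noise; the end-reading convention remains available
as `method = "intercept"`, where each "end" is the mean real part over the
3 extreme frequencies (the number of end frequencies is a documented
choice — the classical procedure does not fix it). Design notes:

* Parameters are optimized on the log scale (Levenberg–Marquardt via
  `minpack.lm`), which enforces positivity without explicit constraints.
  Convergence tolerances are set near machine precision so noiseless
  spectra are recovered to better than $10^{-6}$ relative error.
* Starting values come from the data: $R^{sub}$ from the highest-frequency
  real part, $R^t$ from the lowest, $C$ from the apex frequency of
  $-\mathrm{Im}(Z)$.
* Residuals are unweighted because no frequency-dependent noise model is
  available for the rig.
* A spectrum with no measurable reactive component (all
  $\mathrm{Im}(Z) \approx 0$) makes the RC element unidentifiable and is
  rejected with a pointer that $R^{epi} \approx 0$; non-convergence on
  other inputs is reported through a flag, not an error.
* A constant-phase-element generalization is deliberately not implemented;
  the one-path RC semicircle is the adopted model.

Bath-solution series resistance is handled by
`correctBathResistance()`, which subtracts a scalar from the real part
exactly once (double correction and corrections exceeding the smallest
real part are errors).

# Short-circuit current dissection

`baselineIsc()` averages all samples before the first drug event.
Bumetanide (NKCC1 blocker, serosal) quantifies active anion secretion:
`bumetanideResponse()` returns the maximum Isc before the addition minus
the Isc 20 min after it, taking the nearest sample within ±1 min of the
+20 min mark and interpolating linearly otherwise (the sampling tolerance
is a documented default). Amiloride (ENaC blocker, mucosal, after
aldosterone stimulation) quantifies electrogenic Na⁺ absorption:
`amilorideJNa()` uses plateau differences — the mean of the last 5
pre-event samples minus the mean over 5–15 min after the addition; the
window sizes are documented defaults since the classical procedure does
not fix them. Negative responses are returned signed and flagged.
`iscToMolarFlux()` converts µA·cm⁻² to µmol·h⁻¹·cm⁻² through the Faraday
constant ($1\,\mu A\,cm^{-2} \equiv 0.0373\,\mu mol\,h^{-1}cm^{-2}$ for a
monovalent ion).

Both response statistics are invariant to adding a constant to the whole
trace, and both scale linearly with the simulated drug effect; the test
suite asserts this.

# Tracer flux and permeability

Fluorescein (332 Da, 100 µM apical) and FITC-dextran-4000 (4 kDa, 0.4 mM
apical) probe size-dependent paracellular leak. Basolateral samples are
read as fluorescence, mapped to concentration through an ordinary
least-squares calibration line fitted on duplicate-averaged dilution
readings (`fitCalibration()`), and converted to amounts via the
basolateral volume. `fluxFromSeries()` fits amount vs time by OLS; the
slope gives the flux $J$ and the apparent permeability

$$P = J/\Delta c.$$

The printed unit triplet ($J$ in mol·h⁻¹·cm⁻², $c$ in mol/L, $P$ in cm/s)
is dimensionally inconsistent without conversion, so the package fixes the
conversion path explicitly: the OLS slope (mol/min) is scaled by
$60/\mathrm{area}$ to mol·h⁻¹·cm⁻², and $P = (J/3600)/(\Delta c \cdot
10^{-3})$ with $\Delta c$ converted from mol/L to mol·cm⁻³. This is the
central unit-handling decision of the module and the identity is stored
exactly in every result object.

Linear accumulation assumes a sink condition (basolateral concentration
negligible against apical over the 60-min sampling hour) — justified at
the measured permeability scale, where back-flux is negligible. All
samples including $t = 0$ enter the slope; `skipFirst` exists for
lag-phase handling. The basolateral chamber volume is not part of the
published protocol and is a required parameter (default 1.0 mL,
documented as arbitrary); no sample-replacement volume correction is
applied by default.

# Tricellular tight-junction delocalization

Tricellulin normally concentrates at tricellular meeting points. Its
delocalization is scored on 1-D intensity line profiles drawn along the
junction: `ttjBtjRatio()` divides the intensity at the tricellular anchor
by the bicellular reference read 2 µm away. Two conventions were left
open by the imaging procedure and are resolved as documented defaults:

* the bicellular reference is the mean of both sides (anchor ± 2 µm) when
  both lie inside the profile, one side otherwise (flagged);
* the tTJ reading is the anchor-position intensity; `localMaxRadius`
  switches to a local-maximum reading for off-anchor peaks.

Sub-sample positions are linearly interpolated; no background subtraction
is applied (none is described for the source workflow). The ratio is
exactly scale invariant, so staining intensity differences between
sections cancel. The measurement scheme is 3 profiles in each of 3–7
sections per subject; `aggregateSubject()` stores per-measurement values,
per-section means and both subject-level aggregates (flat mean over all
measurements — the default used in group comparisons — and the mean of
section means), since the aggregation convention is not fixed by the
protocol.

# Crypt morphometry and apoptosis

Three measured quantities — inner crypt diameter $d$, crypt length $L$,
and crypt density $n$ per serosal area — determine the mucosal surface
amplification under the minimal geometric model they support, a right
circular cylinder per crypt opening onto a flat plane:

$$\mathrm{ratio} = 1 + n\,\pi\,d\,L$$

(openings and flat bottoms cancel). A hemispherical-bottom variant adds
$n \pi d^2/4$; both are provided because the published description cannot
distinguish them. Geometries whose openings exceed the reference plane are
rejected. `apoptosisRate()` is the TUNEL-positive percentage of all
DAPI-positive nuclei.

# Upstream-regulator statistics

Over a DESeq2-style results table and a signed regulator→target network,
`rankRegulators()` computes per regulator (i) the one-sided
Fisher/hypergeometric overlap p-value $P(X \ge k)$ for the overlap $k$
between the thresholded DE selection and the target set, and (ii) an
activation z-score from sign concordance,
$z = (n_{agree} - n_{disagree})/\sqrt{n_{agree} + n_{disagree}}$, where
"agree" means the observed fold-change sign equals the expected regulation
sign under activation. Unit edge weights are used — the commercial
implementation weights edges by literature confidence, but no weights are
available to an open network format — and this is documented as a
simplification. The gene universe defaults to the DE table size
(overridable). No-overlap z-scores are `NA`, deliberately distinct from
$z = 0$. Whether DE membership uses raw or adjusted p-values is exposed
as a flag because the upstream analysis convention is not fixed.
Ranking is by overlap p ascending, ties by $|z|$ descending, then
regulator id.

# Group statistics

All group comparisons use Student's t-test (pooled variance by default,
Welch by flag) with mean ± SD reporting and the three-star convention
(n.s. / * p < 0.05 / ** p < 0.01 / *** p < 0.001). The test is computed
from the group moments — which makes `tTestFromSummary()` available for
checking published mean ± SD tables, algebraically identical to the
raw-data path for the pooled variant — and is validated against
`stats::t.test` to $10^{-10}$ in the test suite. No multiple-testing
correction is applied across metrics, matching the source convention.
Recomputing the pooled t from the published baseline-Isc summaries
(138 ± 75, n = 10 vs 74 ± 35, n = 6) gives p ≈ 0.072 rather than the
printed 0.0839; the printed value comes from unrounded raw data that are
not public, so the package notes the discrepancy and does not assert it.

# The synthetic cohort generator

`defaultCohortConfig()` packages the study conditions: 10 control vs 7
IBS-M subjects; baseline Isc 138 ± 75 vs 74 ± 35 µA·cm⁻²; equal group
means for epithelial resistance, subepithelial resistance, capacitance and
amiloride-sensitive transport; 4-fold (fluorescein) and 3-fold
(FITC-dextran-4000) permeability increases; surface ratios near 4.57 vs
4.97 with apoptosis fractions 1.0 ± 0.7 % vs 1.1 ± 0.6 %. Where the
source reports only a bar chart or a direction, values were fixed once at
field-realistic magnitudes: bumetanide-sensitive ΔIsc 60 ± 20 vs
20 ± 8 µA·cm⁻² (a marked secretory reduction in stimulated biopsies),
R^epi 25 ± 8 over R^sub 12 ± 3 Ω·cm² with 3 ± 1 µF·cm⁻² capacitance
(typical for sigmoid biopsies), absolute permeabilities of
0.5 × 10⁻⁶ cm/s (fluorescein) and 0.2 × 10⁻⁶ cm/s (FD4) in control, and
tTJ enrichment 2.5 ± 0.3 (control-like) vs 1.2 ± 0.3 (delocalized).

Generator conventions:

* Noise is Gaussian everywhere — the simplest model consistent with
  mean ± SD reporting: multiplicative on impedance and fluorescence,
  additive (µA·cm⁻²) on current traces.
* Drug responses follow first-order kinetics toward the post-drug plateau;
  the kinetic shape is a generator decision (the source does not describe
  it) chosen for a smooth, parameterizable ΔIsc ground truth.
* Subject-level parameter draws are truncated into their physical ranges
  (resistances positive, apoptosis fraction in [0, 1], enrichment ≥ 1).
* Generated modalities are independent across subjects and across
  modalities; no inter-subject correlation structure (e.g. low occludin
  with high permeability) is simulated because none is quantified in the
  source.
* Everything derives from a single config seed; regenerating with the
  same seed yields identical in-memory bundles and byte-identical files.

What passing tests show — and what they do not: the generators emulate
the statistical structure the analysis assumes (linear accumulation,
exponential drug kinetics, Gaussian peaks on flat backgrounds, Gaussian
noise). Real biopsies violate these idealizations in ways the synthetic
cohort cannot probe: edge damage, drifting baselines, non-Gaussian
staining artefacts, correlated modality failures. Parameter-recovery
results therefore validate the computational chain, not the biology.

# Numerical choices and problem sizes

Validation anchors: noiseless impedance round-trips to $10^{-6}$ relative
(50 random triples) and a coarse-grid + refinement search oracle agreeing
to 0.1% (20 instances); permeability round-trips to $10^{-9}$ across four
orders of magnitude plus the hand-worked example (slope 2 nmol/h over
0.049 cm² at Δc 100 µM → P = 1.134 × 10⁻⁴ cm/s); exhaustive
hypergeometric enumeration up to universe 25; discretized surface
integration over 100 random crypt geometries; 1000-instance t-test
equivalence. Stochastic checks use 200 seeded replicates for the tTJ
group separation, 50 seeds for the directional cohort pattern and 200
for type-I control — sizes chosen to keep the binomial uncertainty of the
estimated rates a few percent while the whole suite runs in minutes on a
single core. The type-I criterion is enforced per metric (each metric
non-significant in ≥ 90% of null-configuration seeds); with ~12 metrics
tested at the 5% level, demanding joint non-significance would contradict
the nominal level itself ($0.95^{12} \approx 0.54$).

# Known limitations

* The one-path model cannot separate paracellular from transcellular
  conductance; two-path scanning and dilution potentials are out of scope.
* No back-flux correction for the flux chamber; permeabilities at which
  the sink assumption fails would be underestimated.
* The tTJ statistic operates on extracted line profiles, not images; no
  vertex detection or 2-D segmentation is attempted.
* The regulator statistics implement the open, unit-weight form; numbers
  from proprietary weighted knowledge bases will differ.
* Group comparisons assume approximate normality of per-subject metrics;
  with n of 6–11 per group this is untestable, which matches the source's
  own convention of reporting Student's t throughout.
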