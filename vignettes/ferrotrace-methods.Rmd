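---
title: "Methods: isotope-dilution absorption analysis and its companions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isotope-dilution absorption analysis and its companions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ferrotrace)
```

## The measurement model

Erythrocyte-incorporation tracer studies estimate fractional iron absorption
(FIA) without balance chambers: a participant ingests a few milligrams of
iron enriched in a minor stable isotope, and about two weeks later the iron
isotope pattern of their red cells has shifted by an amount set by how much
tracer was absorbed. The package models one circulating pool. If the pool
holds `total_mol` of iron at a blood draw, of which `q_i` came from tracer
`i` and the rest carries the previous draw's pattern `baseline`, the
measured abundance pattern is the mole-weighted mixture

```
measured = ((total_mol - sum(q)) * baseline + sum_i q_i * tracer_i) / total_mol
```

Given `measured`, `baseline`, the certified tracer patterns and `total_mol`,
this is linear in `q` and `solve_tracer_increments()` solves it by least
squares. Absorption is then `FIA = q / (F * dose_mol)`, where `F` is the
erythrocyte incorporation factor and `dose_mol` converts the administered
elemental-iron mass through the *tracer's own* molar mass (enriched iron is
up to 3% lighter or heavier than natural iron; using 55.85 g/mol for a
54Fe-enriched dose would bias FIA by that much).

Pool size comes from anthropometry: blood volume by the adult-female
height–weight regression `0.3561 H(m)^3 + 0.03308 W(kg) + 0.1833` (the male
variant is selectable by name; the convention used is echoed in the run
report), times the haemoglobin concentration, times 3.47 mg iron per gram of
haemoglobin. Mass is converted to moles with the molar mass of the baseline
pattern, the same convention the forward simulator uses, so the
forward-then-invert round trip is exact rather than exact-up-to-convention.

Assumptions worth keeping in view: a single well-mixed pool (no marrow/spleen
compartments), full isotopic equilibration by the draw day, a constant `F`
across participants and conditions, and no iron loss between draws. These
are the standard assumptions of the method, not claims the package tests.

## Key parameters

| parameter | default | units | role |
|---|---|---|---|
| `incorporation_factor` (F) | 0.80 | – | fraction of absorbed iron appearing in erythrocytes |
| `fe_per_hb` | 3.47 | mg/g | haemoglobin iron stoichiometry |
| `bv_formula` | `nadler_female` | – | blood-volume regression |
| dose | 4.0 | mg Fe | elemental iron per administration |
| `noise_sd_rel` | 5e-4 | – | relative SD of multiplicative noise per isotope ratio |
| `gsd_fia` | exp(0.158) | – | residual (within-person) geometric SD of true FIA |
| `person_effect_sd` | 0.60 | ln units | shared per-person log-scale effect |

The dispersion defaults are derived, not invented: a 95% CI of 38.9–55.0%
around a geometric mean of 46.2% at n = 52 implies a log-scale SE of 0.086
and hence a total between-participant log-SD of ≈ 0.62; a paired
log-difference SD of 0.223 implies a residual component of 0.223/√2 ≈ 0.158;
the person effect is the quadrature remainder, √(0.62² − 0.158²) ≈ 0.60.
(The same source prints a second, slightly different CI for that GM —
39.1–54.7%; the derivation uses the first. The difference moves the total SD
by under 1%.) The noise default 5e-4 is a typical multi-collector ICP-MS
ratio precision; two simulated replicates are averaged, mirroring duplicate
measurement.

## What the generator emulates — and what it does not

`simulate_trial()` reproduces the design skeleton: 52 participants screened
on ferritin, haemoglobin, BMI, weight, age and CRP; three labelled compounds
(the ascorbate-reduced hybrid carrying ⁵⁷Fe, the NaOH-reduced hybrid ⁵⁸Fe,
ferrous sulfate ⁵⁴Fe) given in randomized order within each phase, in water
on days 1/3/5 and in an açai-puree meal on days 19/21/23; draws on days
1/19/37 with the day-19 measurement serving as the phase-2 baseline
(sequential baselining — the day-19 sample both closes phase 1 and opens
phase 2). True FIA is lognormal per condition around the study-scale
geometric means (water: 46.2%, 20.3%, 26.3%; meal: 13.4%, 6.3%, 8.1%) with
the shared person effect above, truncated at 0.95 to keep mass balance
physical.

It deliberately does **not** emulate: ferritin/inflammation kinetics,
menstrual loss or dropout, Hb drift between draws (weight and Hb are held at
screening values, which is also why `process_trial()`'s "sampling-day"
anthropometry equals the screening table here), tracer
cross-contamination, or any systematic deviation from the one-pool model.
Passing tests therefore certify the *arithmetic* — that the inversion undoes
the stated measurement model at the stated noise — not that the model
describes real physiology. The truncation at 0.95 matters quantitatively:
with total log-SD 0.62 around a GM of 0.462, ~12% of draws for the
best-absorbed condition hit the ceiling, which biases that condition's
recovered GM downward by ≈ 4% relative. That is a property of the generating
conditions, visible in any replicate of the full pipeline.

## Numerical choices

* **Ratio space by default.** The mixing model is solved on the three
  ratios to ⁵⁶Fe rather than the four abundances, because the simulated (and
  physical) noise acts on measured ratios. Both solvers are implemented and
  agree to < 1e-6 on noiseless data; either recovers noiseless increments to
  < 1e-10 relative.
* **Non-negativity by active-set clipping.** Tiny negative `q` estimates are
  noise artefacts; the solver drops the most negative component and refits.
  An all-negative solution is an error, not a zero.
* **Ill-conditioning is refused.** If the design matrix's condition number
  exceeds `cond_max` (e.g. a "tracer" indistinguishable from baseline), the
  solve stops rather than returning garbage.
* **FIA > 1 is flagged, never clipped** — it is evidence of mass-balance or
  model failure and must survive into the output tables.
* **Sample-size conventions are swept, not asserted.** A published "30%
  difference, 80% power, 5% error" statement under-determines n: natural vs
  common logs and whether alpha is Bonferroni-divided span n = 6 to 46
  (`sample_size_conventions()`); the base-10, alpha/4 pair lands nearest the
  recruitment arithmetic (44 completers, +20% dropout by multiply-then-floor
  → 52). No single convention is claimed as anyone's intent.
* **R-Index null by rank permutation.** Critical values come from permuting
  tieless rating ranks between test and reference labels — exactly (full
  enumeration, small totals) or by 200,000 Monte-Carlo draws — which
  reproduces the chance expectation of 50 without a parametric rating model.
  The decision at the boundary is strict (`R > c`), documented in
  `classify_difference()`. Published table values built by other
  constructions can differ by a fraction of a point; the exact permutation
  value for 30 vs 30 at one-sided 0.05 is 62.4.
* **Valence calibration is data.** The EELS white-line L₃/L₂ → ferric
  fraction mapping is shipped as monotone anchor points with linear
  interpolation and refuses extrapolation by default. The default anchors
  are a synthetic curve with the shape of published universal calibrations;
  any quantitative claim requires the user's own calibration, measured under
  the same background model and integration windows (default: double-arctan
  continuum, ±2 eV windows around the detected peaks).
* **One seed, split deterministically.** Every stage derives a child seed
  from the run seed and a stage label, so reruns are byte-identical and no
  stage consumes another's stream.

## Problem sizes in the test suite

The suite runs the full 52-participant pipeline several times (≈ 0.5 s
each), a 200-replicate coverage study of the recovered GM, 2000 null
replicates for the paired-test type-I error, 1000 for CI coverage, and
200,000 permutation draws for the R-Index critical value — sizes chosen so
every stochastic check has sampling error comfortably inside its asserted
band while the whole suite stays in the low minutes.

## Known limitations

The one-pool, fixed-F model is the method's convention, and the package
inherits its blind spots (true inter-individual variation in incorporation
reads as variation in absorption). The generator's lognormal-plus-truncation
truth is a convenient emulation, not a fitted model of any cohort. The
speciation module quantifies spectra it is given; it makes no attempt at
instrument-level EELS corrections (plural scattering, zero-loss alignment),
and no default calibration should be read as reproducing any published
ferric-fraction number.
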