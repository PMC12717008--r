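# ferrotrace

Simulation and analysis machinery for **multi-tracer stable-isotope
iron-absorption cross-over trials**, with companion tools for iron
speciation arithmetic, colour-difference measurement, and R-Index sensory
discrimination.

## The problem and the model

Fractional iron absorption (FIA) in humans is measured by feeding small doses
of iron enriched in a minor stable isotope (⁵⁴Fe, ⁵⁷Fe or ⁵⁸Fe) and, ~14 days
later, reading how far the erythrocyte iron isotope ratios have shifted away
from natural abundance. With the circulating iron pool estimated from blood
volume (height–weight regression) and haemoglobin, the shift is inverted by
**isotopic dilution**: the measured pattern is a mole-weighted mixture

&nbsp;&nbsp;&nbsp;&nbsp;measured ≈ (N·baseline + Σᵢ qᵢ·tracerᵢ) / (N + Σᵢ qᵢ),&nbsp;&nbsp;N + Σᵢ qᵢ = total circulating mol,

solved for the incorporated moles qᵢ of each tracer by non-negative least
squares over the isotope ratios to ⁵⁶Fe. Absorption follows as

&nbsp;&nbsp;&nbsp;&nbsp;FIA = q / (F · dose_mol),

with F = 0.80 the assumed erythrocyte incorporation factor. A two-phase
cross-over design (three tracers in water on days 1/3/5, the same three in a
polyphenol-rich açai matrix on days 19/21/23, blood draws on days 1/19/37
with sequential baselining) yields six FIA values per participant —
312 measurements for a cohort of 52. Condition summaries are geometric means
with t-based CIs on the log scale; relative bioavailability is the geometric
mean of the per-participant test/reference ratios; prespecified comparisons
use two-sided paired t-tests on ln FIA with Bonferroni adjustment.

Because no participant-level data are public, the package ships a
**synthetic-data generator** that emulates the cohort (lognormal
per-condition true absorption with a shared person effect, randomized
tracer order, multiplicative isotope-ratio measurement noise) so the entire
pipeline is testable end to end: forward simulation and inversion are exact
inverses at zero noise.

Companion modules implement the study's desk arithmetic: ferrous
fraction r/(1+r) from a Fe²⁺/Fe³⁺ ratio, EELS white-line L₃/L₂ integration
with a configurable valence calibration, CIELAB ΔE*ab colour difference, and
the R-Index (scaled rank-sum probability that a test sample is rated more
"different" than the reference, ties half) with permutation critical values.

## Worked example

```r
library(ferrotrace)
out <- run_end_to_end(run_config(seed = 1), out_dir = "runs/demo")
out$summary
#>          condition_id         gm      ci_lo      ci_hi  n
#> 1          FeSO4|acai 0.07780035 0.06269944 0.09653825 52
#> 2         FeSO4|water 0.25088866 0.20246008 0.31090139 52
#> 3  OatNF-NaOH-Fe|acai 0.06458162 0.05176824 0.08056650 52
#> 4 OatNF-NaOH-Fe|water 0.19025109 0.15358234 0.23567473 52
#> 5    OatNF-SA-Fe|acai 0.13314897 0.10620407 0.16693003 52
#> 6   OatNF-SA-Fe|water 0.41767478 0.35034039 0.49795064 52
out$rbv[c("pair", "gm_ratio", "p_adj")]
#>                                 pair  gm_ratio        p_adj
#> 1   OatNF-SA-Fe|water vs FeSO4|water 1.6647814 1.212508e-16
#> 2 OatNF-NaOH-Fe|water vs FeSO4|water 0.7583088 2.767638e-09
#> 3     OatNF-SA-Fe|acai vs FeSO4|acai 1.7114186 1.267765e-14
#> 4   OatNF-NaOH-Fe|acai vs FeSO4|acai 0.8300942 1.580149e-03
```

One simulated 52-participant trial: each row of `summary` is a condition's
geometric-mean FIA with its 95% CI (e.g. the ascorbate-stabilized hybrid in
water absorbs at ~42% in this replicate, against a generating value of
46.2%); `rbv` gives the per-participant relative bioavailability of each
hybrid against the ferrous-sulfate reference in the same matrix, with
Bonferroni-adjusted paired-test p-values. `runs/demo/` receives every table
(cohort, design, measurements, fia, summary, rbv) plus `report.txt` echoing
the seed and every convention in force.

A thin shell wrapper is installed as `exec/ferrotrace`
(`ferrotrace report --seed 1 --n 52 --out runs/demo`).

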