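# frailtrans

Design machinery for frailty prevention trials built around a **composite
outcome**: progression from prefrailty to frailty, death, or dropout due to
illness. Frailty-transition trials are painful to power — prefrail-to-frail
transitions are rare (~10% over four years) while death and illness-related
dropout are common — and a composite endpoint both shrinks the required
sample and keeps participants who die or drop out in the analysis. The
package is aimed at trial statisticians and ageing researchers who need
event-rate inputs and sample sizes for such designs, and at anyone
re-deriving frailty transition rates from two-wave panel data.

## What it does

1. **Phenotypic (Fried) frailty scoring** — the five deficits (weight loss,
   exhaustion, low grip, slow gait, low activity) from raw measures, with
   sex-specific covariate adjustments (e.g. adjusted grip = grip − (BMI −
   27.6) × 0.31 for men) and quintile thresholds derived from the baseline
   cohort: 0 deficits = robust, 1–2 = prefrail, 3–5 = frail; any missing
   component makes a participant unscorable.
2. **Multi-state transition estimation** — counts of moves between
   {robust, prefrail, frail, dead, dropped out} over a panel interval, row
   normalised to a transition matrix *P* under three dropout attributions
   (all / none / half of dropout due to illness). The published ELSA
   wave-2/wave-4 count table ships as a fixture.
3. **Markov interpolation** — shorter-horizon probabilities as matrix roots
   *P*^(1/2) and *P*^(1/4) via eigendecomposition, *P* = *Z* Λ *Z*⁻¹, root =
   *Z* Λ^(1/k) *Z*⁻¹, with embeddability diagnostics.
4. **Sample sizes** — per-group *n* for the simple binary transition and the
   composite (pooled-variance normal approximation), the three-category
   ordinal analysis under proportional odds (Whitehead's method,
   n = 6(z₁₋α/₂+z₁₋β)² / ((ln θ)²(1 − Σp̄ₖ³)) per group), and continuous
   comparators with optional ANCOVA baseline adjustment — each validated by
   vectorised Monte-Carlo power simulation.
5. **Synthetic two-wave cohorts** — a calibrated generator reproducing the
   published baseline mix and transition structure, so the whole pipeline is
   testable without access to the restricted microdata.

## Worked example

Two-year design inputs for a trial enrolling prefrail participants, starting
from the packaged four-year count table:

```r
library(frailtrans)

counts <- elsa_transition_counts()
P <- apply_scenario(counts, "all_ill", digits = 2)  # 4-state, published precision
R2 <- matrix_root(P, 2)                             # matrix square root = 2-year
round(extract_row(R2, "prefrail"), 3)
#>          robust        prefrail           frail dead_or_too_ill
#>           0.159           0.494           0.113           0.234
```

So a prefrail control participant has a 2-year probability of 0.113 of
becoming frail but 0.347 (= 0.113 + 0.234) of the composite event. Per-group
sample sizes over a grid of relative risk reductions:

```r
build_design_tables(extract_row(R2, "prefrail"))$transitions
#>    rrr n_frail_only n_composite n_ordinal
#> 1 0.20         3760         934       719
#> 2 0.25         2346         588       444
#> 3 0.30         1587         401       296
#> 4 0.40          845         217       152
#> 5 0.50          509         133        87
```

Read: to detect a 30% relative reduction with 90% power, a frail-only
endpoint needs 1587 per arm, the composite 401, and the ordinal analysis
(robust vs prefrail vs frail/dead/too-ill) 296 — the composite and ordinal
approaches cut the trial to a fraction of the simple-transition design.
`run_pipeline(out_dir = "results")` writes all published-style tables
(counts, interpolated probabilities for every scenario at 1/2/4 years, and
both sample-size tables) plus eigen/clipping diagnostics as CSV/JSON.

`apply_scenario(..., digits = 2)` matters: the original analysis interpolated
from transition probabilities at their two-decimal reporting precision, and
only that choice reproduces the published 1- and 2-year tables; omit
`digits` for the full-precision analysis (entries shift by ≤ ~0.004). See the
vignette (`vignettes/composite-frailty-outcomes.Rmd`) for this and the other
numerical findings, including why the four-year matrix has no strictly
stochastic fourth root.

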