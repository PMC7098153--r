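---
title: "Composite outcomes for frailty prevention trials: models, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite outcomes for frailty prevention trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frailtrans)
```

## The problem

Trials that try to prevent or slow frailty in older people face an awkward
combination: transitions from prefrailty to frailty are rare (roughly 10%
over four years in the ELSA panel this package is calibrated to), while
death and dropout due to illness are common and informative. A trial powered
on "became frail" alone needs thousands of participants per arm and discards
exactly the participants whose deterioration the intervention was meant to
prevent. The package implements the alternative this methodology proposes: a
composite outcome (progression to frailty, death, or dropout due to
illness), analysed either as a binary event or as a three-category ordinal
outcome (robust < prefrail < frail/dead/too ill), with event probabilities
obtained from panel data via a multi-state Markov model.

The pipeline has four stages, each usable on its own:

1. **Phenotypic frailty scoring** (`score_cohort()`): the five-deficit Fried
   phenotype on raw component measures.
2. **Transition estimation** (`count_transitions()`, `apply_scenario()`):
   4-year transition matrices over {robust, prefrail, frail, dead, dropped
   out}, with three attributions of dropout to illness.
3. **Markov interpolation** (`matrix_root()`): matrix square and fourth
   roots via eigendecomposition give 2- and 1-year transition probabilities.
4. **Sample-size comparison** (`build_design_tables()`): simple binary,
   composite binary, proportional-odds ordinal, and continuous comparators,
   validated by Monte-Carlo power simulation.

A calibrated synthetic two-wave cohort generator (`generate_cohort()`)
stands in for the registration-restricted ELSA microdata, so the whole
pipeline is testable end to end against a known truth.

## Frailty scoring

A participant scores one point for each of: weight loss (BMI < 18.5 kg/m²
or > 10% weight loss since the prior wave), exhaustion (a positive answer to
either CES-D item), low BMI-adjusted grip strength, low height-adjusted gait
speed, and low MET-weighted activity. Scores 0 / 1–2 / 3–5 map to robust /
prefrail / frail. The grip and gait adjustments are linear recentring
formulas with sex-specific coefficients; the activity index weights mild,
moderate and vigorous activity by 1.5, 3 and 6 METs and frequency by 0 / 2 /
4 / 8 (never through more than weekly).

"Low" means *strictly below* the sex-specific 20th percentile of the
baseline cohort. Because no percentile convention was stated in the source
analysis and the printed cuts cannot be re-derived without the microdata,
`derive_thresholds()` uses the inverse-empirical-CDF (order-statistic,
`quantile` type 1) estimator, and ties at the cut are *not* flagged — this
matches the "< 31.12 kg" style in which the published thresholds are
written. The published wave-2 cuts ship as `default_thresholds()` and as a
YAML file, so ELSA-faithful runs can pin them instead of re-deriving.

Missingness follows a completeness rule: if any of the five components
cannot be evaluated, the participant is unscorable and carries no score.
Two asymmetries are deliberate:

* **Exhaustion**: one "yes" flags the component even if the other answer is
  missing (the criterion defines the positive case); a negative requires
  both answers, so "no" plus missing is unevaluable.
* **Weight loss**: the dual criterion makes the component evaluable from
  BMI alone when the prior-wave weight is missing.

A weight loss of exactly 10% is not flagged (the criterion is strict).

## Transition estimation and dropout scenarios

Pairs of (baseline category, follow-up outcome) are tabulated into a 3 × 5
count matrix; the packaged fixture is the published wave-2/wave-4 table for
the 4650 participants with a complete baseline score. A recorded death takes
precedence over non-assessment; participants alive and not withdrawn but
unscorable at follow-up count as dropped out (they could not complete all
tests). Because the panel cannot distinguish dropout due to illness from
dropout by choice, three scenarios bracket the truth: all dropout ill
(dropout merges with death into one absorbing state), none ill, and half ill
(a deterministic 50/50 split of each row's dropout count — expected counts,
not randomised individuals, which is why non-integer cells are allowed).
Absorbing states get exact unit-vector rows, making the matrix square and
row-stochastic.

## Matrix roots and the two rounding regimes

With P the 4-year matrix, the 2- and 1-year estimates are P^(1/2) and
P^(1/4), computed as Z Λ^(1/k) Z⁻¹ from the eigendecomposition, with
principal roots of the eigenvalues, `solve()` for Z⁻¹ when Z is well
conditioned and the Moore–Penrose generalised inverse beyond a condition
number of 1e12 (the 5-state scenarios have the eigenvalue 1 twice — one per
absorbing state — which can push Z toward singularity). Complex arithmetic
is used throughout and realness is verified (imaginary residual above 1e-8
is an error), diagonalisability is checked by the reconstruction residual
(1e-8), and eigenvalues must be positive reals: a negative or complex
eigenvalue has no admissible principal root and raises a
"non-embeddable" error rather than silently returning a branch choice.

Two findings from reproducing the published tables deserve emphasis.

**Reporting-precision inputs.** The published 1- and 2-year interpolations
are *not* reproducible from the raw counts: full precision gives an all-ill
2-year prefrail row of 0.157/0.493/0.112/0.238 against the published
0.159/0.494/0.113/0.234. They are reproduced exactly when the scenario
matrix is rounded to two decimals — the precision at which the transition
probabilities were reported — and renormalised before rooting. Evidently the
original interpolation was run on the tabulated rather than the raw
probabilities. `apply_scenario(digits = 2)` reproduces that arithmetic and
is the default in `run_pipeline()`, with `input_digits = NULL` giving the
full-precision analysis; the two differ by at most ~0.004 in any prefrail
entry. The published half-ill 1- and 2-year rows appear to use yet another
rounding order (rounding the five-state probabilities before the 50/50
split); the difference is ≤ 0.003 and only the measured 4-year half-ill
value (0.266, exact from counts) is anchored.

**Strict embeddability fails — visibly and harmlessly.** The fixture
matrix's fourth root has small negative entries (≈ −0.011 for
robust→frail, ≈ −0.001 for frail→robust) in every scenario and at either
precision. This is the classical embedding problem: a 4-year chain need not
be a 4-fold composition of identical 1-year chains. The published analysis
reported only the prefrail row, whose entries are all positive.
`matrix_root()` therefore returns the *exact* root by default — rows sum
to 1 analytically (the all-ones vector is an eigenvector) and R^k = P to
machine precision — and reports the most negative entry in its diagnostics;
`clip_negatives = TRUE` gives a proper stochastic matrix by truncation and
row renormalisation, at the (reported) cost of exact closure, and entries
below `-neg_tol` (default −0.02) are an error. Clipping never touches the
prefrail row of the fixture.

## Sample-size calculators

All designs are two-arm, 1:1, two-sided α = 0.05, power 0.90 by default
(`design_spec()`).

* **Binary** (`n_two_proportions()`): the pooled-variance normal
  approximation with ceiling rounding. The published binary cells could not
  be reverse-engineered from any standard closed form (the frail-only 20%
  RRR cell prints 3621 where pooled/unpooled/arcsine forms give ~3755), so
  fidelity to those cells is directional — the ordering and magnitudes hold
  — and correctness is established by simulation instead: at the returned
  n, the empirical power of the pooled z-test is within Monte-Carlo error
  of 0.90.
* **Ordinal** (`rrr_to_ordinal()`, `n_whitehead_ordinal()`): the published
  analysis never states how a relative risk reduction translates into an
  ordinal effect. The package anchors the proportional-odds model at the
  worst-category cutpoint: the treated worst-category probability is
  p₃(1 − RRR), the cumulative odds ratio θ follows from that pair, and θ is
  applied to the second cumulative split to complete the treated
  distribution. Whitehead's closed form then gives the per-group size
  n = ⌈6 (z₁₋α/₂ + z₁₋β)² / ((ln θ)² (1 − Σ p̄ₖ³))⌉. Two readings of that
  expression (per group vs total) circulate; simulation settles it — at the
  per-group reading the tie-corrected Wilcoxon/proportional-odds score test
  achieves 0.90 ± 0.01 empirical power over 10,000 trials at every grid
  point, while the halved reading achieves ~0.63.
* **Continuous** (`n_continuous()`): 2 (z₁₋α/₂ + z₁₋β)² (σ/Δ)², times
  (1 − ρ²) for ANCOVA baseline adjustment; ρ defaults to 0.5, a
  conservative value for physical-performance measures. This reproduces all
  published walk-speed and SPPB cells exactly (526/395 and 132/99). The
  published Fried-score row (352/264) is inconsistent with its own printed
  SD of 1.2 (the formula gives 337/253, matching an unrounded SD ≈ 1.23);
  the package reproduces that row only under a user-supplied SD.

`build_design_tables()` assembles the comparison over the RRR grid
{0.20, 0.25, 0.30, 0.40, 0.50}, driving all three transition columns from
one interpolated 2-year prefrail row; the composite control probability is
the sum of its frail and dead/too-ill entries (0.347 under the all-ill
scenario).

## The synthetic cohort generator

`generate_cohort()` emulates the *statistical structure the analysis
consumes*, not the physiology: baseline categories from the published mix
(47.9/41.0/11.1%), within-category score distributions from the published
score table, follow-up states drawn from a known 5-state transition matrix
(default: the fixture's row proportions, including ~8% death and 29–48%
dropout by baseline state), and raw component measures realised so that the
intended deficit flags hold under the published thresholds.

The one subtle design constraint is *threshold self-consistency*: grip,
gait and activity cuts are re-derived from the generated baseline as 20th
percentiles, so the marginal flag rate of each quintile component must sit
at 20% or the derived cut drifts into the wrong side of the distribution and
misclassifies participants near the boundary. Deficit counts are fixed by
category, so the generator calibrates *which* components carry the flags:
an iterative water-filling solve yields per-score inclusion probabilities
pinning grip and gait at 20% (activity at 18%, just below the quintile, so
its discrete cut resolves to the first non-low activity pattern), with
exhaustion and weight loss absorbing the remainder; a systematic
probability-proportional sampler realises each participant's flag set with
exactly those inclusion probabilities. Adjusted grip and gait values are
drawn from truncated normals on either side of the cut with a small gap
(0.3 kg, 0.01 m/s), so re-derived cuts land in the gap and scoring
reproduces the intended category for ≥ 99% of participants in practice
(≥ 95% is asserted in tests). Infeasible demands — e.g. a category mix
whose deficit load cannot be carried by five components — fail explicitly.

What the generator does *not* emulate: covariate structure (age and sex
affect nothing but the sex-specific thresholds), informative missingness
(injection is independent per component at configurable rates, zero by
default), longitudinal correlation of components other than weight, and
any real measurement error model. Passing recovery tests therefore show
that the *pipeline arithmetic* is right — scoring, counting, scenario
attribution and rooting invert the generative process — not that the
package would recover truth from data violating these simplifications.

Component distribution parameters live in a YAML file
(`cohort_model_default.yaml`), not in code; means and SDs were chosen once
so the published cuts sit near the 20th percentile of plausible
distributions for a 60+ cohort (e.g. male adjusted grip ~N(38, 7) kg,
female gait ~N(0.82, 0.24) m/s).

## Problem sizes and runtime

Test and acceptance runs use: the 4650-participant fixture for everything
anchored to published values; 20,000 participants per baseline state
(60,000 total) for parameter recovery, where the binomial standard error
(≤ 0.0035 per cell) sits comfortably under the 0.015 acceptance bound;
200,000 participants for marginal-convergence checks at the 0.005
tolerance; and 10,000 replicates per Monte-Carlo power validation, giving a
standard error of ~0.003 on a power of 0.90. The power simulators are
vectorised across replicates (closed-form U statistic from category
counts), so the full 15-cell validation grid runs in seconds.

## Known limitations

* The interpolation assumes time-homogeneous Markov dynamics; a 4-year
  panel conceals multiple transitions, and the embedding failure above is a
  symptom of that coarseness, not a numerical defect.
* Only the prefrail row of the interpolated matrices is anchored to
  published values; full matrices are produced but their robust and frail
  rows carry the negativity caveat.
* The published binary/ordinal design table is not cell-exactly
  reproducible (software unnamed in the source); this package's cells are
  defensible by simulation but differ from the printed ones.
* Sample-size calculators assume 1:1 allocation and no covariate
  adjustment beyond the baseline value of a continuous outcome.
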