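---
title: "Validating a weighted-checklist subtyping instrument: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a weighted-checklist subtyping instrument: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pesval)
```

This vignette documents the statistical model behind `pesval`, the design
choices that were genuinely open, the numerical conventions, and what the
package's synthetic-data tests do and do not establish about real cohorts.

## The instrument and its scoring model

The Pattern Element Scale rates 11 pattern elements of dementia — phlegm
muddiness, kidney deficiency, spleen deficiency, blood stasis, *qi*
deficiency, *yin* deficiency, *yang* deficiency, blood deficiency, marrow
deficiency, endogenous heat, *yang* hyperactivity — each on a subscale of
seven weighted clinical-feature items. The scoring model implemented here
is **binary presence/absence with full weight**: a subscale score is
$\sum_i w_i x_i$ with $x_i \in \{0,1\}$, and the pattern element is
diagnosed when the score reaches the cut-off of 6 points, inclusively
("6 points and above"). Two modelling points deserve note:

* The instrument's published description of subscale maxima is internally
  inconsistent: the prose speaks of a uniform maximum of 30 points, while
  the item weights sum to 24, 23, 24, 21.5, 27.5, 25, 29, 30, 24.5, 21.5
  and 27 across the eleven subscales. `pesval` treats the item weights as
  authoritative — `max_score` is defined as the sum of its subscale's
  weights — because every downstream computation (scores, ROC sweeps)
  depends on the weights, not on the prose.
* Whether clinicians graded item *severity* (weights as maxima of a graded
  response) rather than presence/absence is not documented; the
  all-or-nothing reading is the simplest model consistent with the weight
  table, and a graded extension is deliberately out of scope.

Half-point weights are represented exactly as doubles (all weights are
multiples of 0.5, exactly representable), and no rounding is applied to
scores; printed-precision rounding is purely a rendering concern in
`write_reports()`.

Missing responses follow a **strict policy** by default (error naming the
item): the validation study reports no missing data, so silent imputation
would only mask upstream problems. `missing = "absent"` opts into
treating a missing response as "item not present".

Eligibility screening implements the study's inclusion thresholds:
education-specific MMSE cut-offs (19 illiteracy / 22 primary / 23 middle /
26 higher), ADL ≥ 16, CDR ≥ 0.5, HAMD ≤ 12, each failure reported by name.

## Accuracy, agreement and ROC machinery

All 2×2 statistics are closed-form (see the README for the formulas). Three
conventions matter for reproducing printed tables:

* **Rounding is half-away-from-zero** (`round_half_up()`), the behaviour of
  spreadsheets and the major commercial statistics packages — not R's
  round-half-even. This is what makes printed percentages invertible (next
  section).
* **Pearson χ² is uncorrected** (no Yates continuity correction): on the
  reconstructed tables the uncorrected statistic reproduces the printed
  values; the corrected one does not.
* **ROC thresholds classify positive at score ≥ threshold**, matching the
  inclusive diagnostic cut-off; thresholds sweep every distinct observed
  score plus a +∞ sentinel. The AUC is computed from midranks, which is
  exactly the Mann–Whitney pair-counting probability with ties counted ½,
  and is therefore invariant under strictly monotone transforms of the
  score. The standard error is the Hanley–McNeil closed form; the 95% CI
  and the test against AUC = 0.5 use the normal approximation with
  z = 1.96. Degenerate cases are explicit: single-class truth refuses a
  ROC; SE = 0 with AUC ≠ 0.5 flags a degenerate test rather than reporting
  a spurious p-value.
* Metrics with zero denominators are **flagged `NA`**, never silent zeros;
  published tables have no degenerate rows but synthetic data can.

The Youden-optimal cut-off maximizes J = Se + Sp − 1, breaking ties toward
the lower threshold — the more sensitive choice, appropriate for a
screening instrument.

## Reconstructing 2×2 tables from printed percentages

The reconstruction engine answers: *which integer tables (TP, FN, FP, TN)
with TP+FN+FP+TN = n could have produced the printed Se/Sp/PPV/NPV?* For
each split of n into reference positives/negatives it enumerates all
numerators whose rates round — half-away-from-zero, at each rate's printed
number of decimals — to the printed values, then intersects the four
constraints. The search is exhaustive over TP+FN ∈ [1, n−1] with all four
rate denominators required positive (all four rates were printed, so all
denominators must have been non-zero).

Three outcomes are possible and all are reported honestly: a **unique**
candidate (the study's table is recovered exactly, and the printed kappa
and χ² can be independently re-derived from it); **multiple** candidates
(printed precision under-determines the table — e.g. error-free rows at
small n); or **zero** candidates (no integer table is consistent with the
printed row — a typographical error, or predictive values computed from a
prevalence other than the sample's). The package never picks silently and
never "corrects" an inconsistent row.

On the bundled published table (n = 171), seven of eleven rows reconstruct
uniquely, and kappa recomputed from each recovered table matches the
printed value to all three printed decimals in all seven. The recomputed
χ² matches the printed value to one decimal for four rows
(yang hyperactivity 84.4, *qi* deficiency 50.9, marrow deficiency 66.7,
phlegm muddiness 75.6) and differs by exactly 0.1 for three (blood stasis
108.09 vs 108.0, endogenous heat 44.26 vs 44.2, *yin* deficiency 87.79 vs
87.7) — a final-digit reporting ambiguity, flagged as such. Four rows
(kidney deficiency, spleen deficiency, *yang* deficiency, blood
deficiency) admit **no** consistent integer table; the blood-deficiency
row's sensitivity printed at anomalous three-decimal precision (71.428)
narrows the search without rescuing it.

## Canonical correlation analysis

CCA relates the six MMSE cognition domains (set 1) to the eleven subscale
scores (set 2). `pesval` computes **correlation-matrix CCA** (standardized
columns): the canonical correlations are the singular values of
$R_{xx}^{-1/2} R_{xy} R_{yy}^{-1/2}$, so structure loadings and cross
loadings come out directly as correlations — the scale on which published
cross-loading tables are printed. Design notes:

* **Bartlett's test** uses the classic multiplier $n - 1 - (p+q+1)/2$
  on $-\ln \Lambda_k$ with $(p-k+1)(q-k+1)$ df. On the published
  correlations this gives χ²₁ ≈ 84.3–84.4 (depending on whether Λ is taken
  at full precision or as the printed 0.592), whereas the published first
  χ² is 85.433; no standard variant of the multiplier reproduces that
  number from the printed Λ, so the formula is fixed and the discrepancy
  documented rather than reverse-fitted. Likewise the published df ladder
  (42, 30, …) corresponds to q = 7 rather than the stated 11 subscales;
  `pesval` reports the df implied by the data it is given (66, 50, 36, 24,
  14, 6 for p = 6, q = 11).
* **Sign convention**: the first nonzero raw-variable coefficient of each
  x-variate is made positive (the paired y-variate follows), so results
  are reproducible across platforms; canonical correlations themselves are
  sign-free.
* **Degeneracy**: a singular within-set correlation matrix is an error
  naming the most collinear columns — no silent ridging — and n must
  exceed max(p, q) to fit at all (and (p+q+3)/2 for the test).
* The per-loading significance stars of published cross-loading tables are
  not reproduced; the package's Bartlett tests cover the correlations
  themselves, and any per-loading inference would be approximate.

The Wilks identity $\Lambda_k = \prod_{i \ge k}(1-r_i^2)$ is exposed
directly (`wilks_sequence()`); on the published six correlations it yields
Λ₁ = 0.5924, matching the printed 0.592.

## The synthetic cohort generator

The generator (`simulate_cohort()`) emulates the *structure* the analysis
assumes, with every parameter explicit in `simulation_config()`:

* **Latent status** per patient × subscale: probit liability with
  per-subscale prevalence. Defaults use the reconstructed positive
  fractions where a unique reconstruction exists (0.12 yang hyperactivity
  … 0.60 phlegm muddiness) and plausible values in the same span for the
  four non-reconstructible subscales; these defaults are illustrative
  study conditions, not estimates endorsed by any source.
* **Items** are conditionally independent given status, present with
  probability 0.40 (positive) / 0.06 (negative) by default — chosen once
  so the implied operating characteristics (exact, by 2⁷ enumeration:
  Se ≈ 0.73–0.84, Sp ≈ 0.90–0.96 across subscales) resemble the
  better-performing published subscales. Per-item probabilities can be
  supplied per subscale.
* **Experts**: three independent raters with miss rate 0.10 and
  false-alarm rate 0.05 per subscale; the adjudication rule is exactly the
  study protocol (experts 1–2 decide when they agree; expert 3 settles
  disagreements). Adjudication measurably reduces label error relative to
  a single expert.
* **MMSE domains** are linear in a shared latent severity factor plus
  noise, generated on a continuous scale (mean 55%, SD 25% of each
  domain's maximum) and then rounded and truncated to the valid integer
  ranges (5/5/3/5/3/9 points). The *qi*-deficiency and blood-stasis
  liabilities load 0.8 on the same factor; memory and language load −0.5,
  the other domains −0.2. This plants the negative
  subscale-score-by-cognition coupling the CCA is meant to detect, with
  the coupling specified on the pre-truncation scale (truncation
  attenuates realized correlations).
* **Seeding**: the master seed expands into five fixed per-component
  streams (severity, latent, items, experts, MMSE), so extending one
  component never perturbs the draws of another; identical configs
  serialize byte-identically.

What the generator does **not** emulate: item correlations beyond the
latent class (real symptoms co-occur within and across subscales),
AD-versus-VaD case mix, expert errors correlated between raters or with
case difficulty, and any real-world missingness. Passing parameter-recovery
tests therefore demonstrates that the estimators are correct *under the
stated model*, not that the instrument performs at any particular level in
real patients.

`planted_truth_report()` gives the exact operating characteristics of the
scoring rule under a config by enumerating all 2⁷ response patterns per
subscale — a closed-form oracle against which simulated cohorts are checked
(seed-averaged empirical Se/Sp at n = 5000 within ±0.02), and
`simulate_planted_cca()` constructs two sets sharing a single factor so the
population first canonical correlation is known exactly (recovered within
±0.03 at n = 5000).

## Problem sizes and tolerances in the test suite

The suite verifies: ROC AUC against exhaustive pair counting on 1000
random cohorts of ≤ 12 patients; 2×2 metrics against direct recounts on
every label-vector pair exhaustively for n ≤ 8 (distinct induced tables
checked once); reconstruction against a brute-force O(n³) scan for n ≤ 60
and the round-trip property (true table always among candidates) on 500
random tables with n ≤ 300; CCA against `stats::cancor`, the
determinant-ratio Λ identity, affine invariance to 1e-8, and the
cross-loading factorization to 1e-10; and the simulation recoveries above
(n = 5000, 10 seeds). These sizes keep the whole suite at a few minutes on
one CPU while leaving the binomial/sampling error comfortably inside each
tolerance.

## Known limitations

* Severity banding of PES totals (mild/moderate/severe cut-offs) is
  undefined for this instrument and deliberately not provided.
* No DeLong covariance between correlated AUCs and no exact/bootstrap CI
  for kappa; the asymptotic forms match what validation reports print.
* The reconstruction engine requires all four rates printed for the same
  2×2 table; rows whose PPV/NPV were derived through a prevalence other
  than the sample's are reported as inconsistent rather than re-derived.
* The CLI is a thin wrapper over the exported functions; programmatic use
  is the primary interface.
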