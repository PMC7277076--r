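# cigdc

Validation toolkit for ordinal screening scales with a second-order factor
structure, built around the 27-item Chinese Internet Gaming Disorder
Checklist (C-IGDC) — a DSM-5-aligned screening instrument for Internet
gaming disorder (IGD) in Chinese gamers. It is aimed at psychometricians
and epidemiologists who need the full validation chain for a
multidimensional ordinal symptom checklist: simulation, measurement-model
estimation, item reduction, reliability/validity statistics, and screening
cutoff selection against a binary diagnostic reference.

## The model and the statistics

Items are 3-point ordinal indicators (0 = never, 1 = sometimes, 2 = often)
of nine first-order subconstructs F1–F9 (preoccupation, withdrawal,
tolerance, unsuccessful control, loss of interests, continued gaming,
deception, escape/relief, problems), which load on one general IGD factor
G. Writing λ_i for the loading of item i on its subconstruct and γ_j for
the loading of subconstruct j on G (all factors standardized), the implied
item correlation matrix is

    Σ = Λ Φ Λᵀ + Θ,   Φ = γγᵀ + diag(1 − γ²),   Θ = diag(1 − λ²)

so a same-factor pair correlates λ_i·λ_k and a cross-factor pair
λ_i·λ_k·γ_j·γ_l. Estimation is two-stage: item thresholds
τ_c = Φ⁻¹(cumulative proportion) from the margins, pairwise polychoric
correlations by 1-D maximum likelihood with thresholds fixed, then
(diagonally weighted) least squares on the polychoric matrix with
χ² = (n−1)·F_min and the usual CFI/TLI/RMSEA/SRMR. Item reduction keeps
the top-3 loading items per subconstruct (27 items, sum score 0–54).
Screening efficacy against the 9-criterion DSM-5 reference (positive at
≥ 5) is summarized per integer cutoff by sensitivity, specificity,
predictive rates, Cohen's κ, Youden's J and the diagnostic odds ratio; the
optimal cutoff is chosen by a three-step rule — strict > 75 % sensitivity
and specificity screen, maximal κ after rounding to 2 decimals, ties
broken by higher sensitivity, then Youden, then DOR.

## Worked example

```r
library(cigdc)

data <- generate_dataset(igdc_config(n_persons = 464, seed = 7))
report <- run_validation(data)
report
```

```
== Scale validation report ==
Items: 27 retained of 34
Second-order model: chi-square(518) = 338.54, CFI = 1.000, TLI = 1.003
RMSEA = 0.000 (90% CI [0.000, 0.000]), SRMR = 0.037
One-factor model:   chi-square(527) = 2307.85, CFI = 0.972, TLI = 0.970
RMSEA = 0.085 (90% CI [0.082, 0.089]), SRMR = 0.077
Reduced scale alpha = 0.94 (subscales 0.71-0.86); reference KR-20 = 0.71
Criterion correlations: internet_addiction 0.46, gameplay_frequency 0.40, depression 0.29
AUC vs reference = 0.93
Selected cutoff: >= 36 (screen-positive 16.8%)
```

The simulated sample is drawn from the published second-order loading
pattern, so the second-order model fits essentially perfectly while the
one-factor alternative is clearly worse (RMSEA 0.085 vs 0.000) — the same
qualitative contrast the instrument's validation reported. The reliability,
criterion-correlation and AUC figures land in the calibrated bands (scale
α ≈ 0.92–0.94, r ≈ 0.45/0.40/0.28, DSM-5 prevalence ≈ 12.9 %). The selected
cutoff of a synthetic run depends on the synthetic score distribution and
is not meant to match the instrument's published ≥ 20.

The published cutoff analysis itself can be reproduced exactly from the
printed efficacy percentages, which pin down the underlying 2×2 tables
uniquely:

```r
ref <- cigdc_cutoff_reference()
tables <- lapply(seq_len(nrow(ref)), function(i)
  reconstruct_counts(ref$sensitivity[i], ref$specificity[i],
                     ref$ppr[i], ref$npr[i], n_pos = 60, n_neg = 404))
select_optimal_cutoff(scan_from_tables(ref$cutoff, tables))
```

```
scan: cutoffs 16-22
step 1 (sens > 75% and spec > 75%, strict): {17, 18, 19, 20, 21}
step 2 (max kappa rounded to 2 dp = 0.50): {20, 21} (unrounded: 17:0.4348 ...)
step 3 (higher sensitivity, then Youden, then DOR, then lowest cutoff): 20
```

A thin command-line wrapper is included at
`inst/scripts/run_pipeline.R` (`simulate` and `all` subcommands).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch with the installed package, the optimal screening
cutoff implied by the published cutoff-scan rows (via the exhaustive 2×2
reconstruction above) and the number of items retained by the top-3
reduction of the published 34-item loadings, and writes them as JSON.
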