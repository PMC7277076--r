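---
title: "Methods: simulating and validating a second-order ordinal screening scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and validating a second-order ordinal screening scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cigdc)
```

## The measurement model

The package is organised around the two-level measurement model of the
C-IGDC: 34 (later 27) three-category ordinal items indicate nine
first-order subconstructs, which indicate one general Internet gaming
disorder factor. Each item i has a standard-normal latent response
y*_i = λ_i F_j(i) + e_i with residual variance 1 − λ_i², discretised at
thresholds τ₁ < τ₂ into codes 0/1/2; each subconstruct satisfies
F_j = γ_j G + d_j with disturbance variance 1 − γ_j². All factors are
standardised, so the implied item correlations are λ_i λ_k for same-factor
pairs and λ_i λ_k γ_j γ_l across factors. The model assumes
unidimensional items (no cross-loadings), uncorrelated residuals, and
normal latent responses — the standard assumptions behind polychoric
correlations.

Degrees of freedom are counted on correlations only:
p(p−1)/2 free moments minus (p + 9) parameters for the second-order model
(518 at p = 34, 315 at p = 27) and minus p for the one-factor model
(527 / 324). These match the published model comparison, which is a
useful structural cross-check even though the fitted indices themselves
are not comparable run-for-run (see "Estimator" below).

## Polychoric estimation

Estimation is two-stage, the standard categorical-SEM convention:

* **Thresholds** come from the univariate margins,
  τ_c = Φ⁻¹(cumulative proportion). They exactly reproduce the empirical
  cumulative proportions through Φ (a round-trip identity asserted in the
  tests) and are held fixed afterwards.
* **Pairwise correlation** maximises the bivariate-normal
  cell-probability log-likelihood over ρ ∈ [−0.999, 0.999] by Brent
  search. The bound keeps near-deterministic tables away from the
  singular |ρ| = 1 boundary. Cell probabilities below 1e−12 are floored
  before taking logs.
* **Empty categories** are collapsed into their nearest observed
  neighbour with a warning; a fully constant item is an error naming the
  item, since it carries no threshold information at all.

Bivariate normal rectangle probabilities use a Gauss–Legendre scheme
(Drezner–Wesolowsky 1990, with Genz's 2004 refinement for |ρ| > 0.925),
accurate to ~1e−14; the tests check it against the closed form
P(X<0, Y<0) = 1/4 + asin(ρ)/2π and an adaptive-quadrature oracle, and
the pairwise estimates against an exhaustive likelihood grid search at
step 0.001.

## Estimator and fit indices

`fit_model()` minimises F(θ) = Σ_{i>k} w_ik (s_ik − σ_ik(θ))² with
L-BFGS-B from starting values 0.7, bounds ±0.999, at most 500
iterations and a gradient tolerance of 1e−8. Under the default `dwls`
the weights are inverse asymptotic variances of the polychoric estimates
on the unit-information scale, computed from the fixed-threshold Fisher
information (the ρ-derivative of a rectangle probability is the
four-corner bivariate-density difference); `uls` sets all weights to 1.
Non-convergence flags the result and withholds fit indices; a loading at
the bound raises a Heywood warning. A non-positive-definite input matrix
is repaired by clipping eigenvalues at 1e−6 and rescaling to unit
diagonal, with a warning.

The test statistic is deliberately the naive χ² = (n−1)·F_min, and the
baseline for CFI/TLI is the zero-correlation model with
χ²_b = (n−1)·Σ w s². The mean-and-variance adjustment that full WLSMV
software applies to this statistic is **not** replicated — its internals
are not part of the model definition this package implements. The
consequence is documented and respected throughout: fit indices are
comparable in spirit but not bit-compatible with WLSMV output, so the
package's checks rest on parameter recovery, self-consistency (fitting a
model-implied matrix returns the model to 1e−4) and model ordering (the
one-factor submodel never out-fits the second-order model), never on
matching published index values. The 90 % RMSEA interval is provided
best-effort by noncentral-χ² inversion and excluded from any acceptance
claim.

## What the generator emulates — and what it does not

`igdc_config()` defaults are a stated world, fixed once:

* **Loadings**: the published 34-item standardized loading pattern
  (λ between 0.62 and 0.95, γ between 0.67 and 0.93).
* **Thresholds**: (−0.25, 0.84) for every item, i.e. category
  probabilities (0.40, 0.40, 0.20). Item-level category frequencies were
  never published, so this is a declared choice, not an inference:
  right-skewed endorsement is what symptom checklists in general
  population samples show. It makes the synthetic sum-score distribution
  sit higher than the real sample's (whose optimal cutoff of 20 on a
  0–54 range implies a much more skewed distribution), which is why a
  synthetic run's selected cutoff should not be compared to the
  published ≥ 20.
* **Diagnostic reference**: nine exchangeable binary criteria
  1{a·G + e > c} with a = 0.6461 and c = 0.8111, solved by quadrature so
  that the ≥ 5 rule has exactly 12.9 % prevalence and the reference's
  KR-20 is exactly 0.74 in the infinite-sample limit — the two published
  anchors.
* **Criterion measures**: affine-transformed Gaussians driven by G only
  (ia: 45 + 12z clipped to [20, 100]; depression: 9.5 + 5.5z clipped to
  [0, 30]; gameplay frequency: 4 ordinal bands with the published
  marginals 23.3 % / 8.6 % / 8.6 % / 59.5 %). The latent correlations are
  back-computed from the target sum-score correlations (0.45 / 0.40 /
  0.28) through two frozen constants: cor(27-item sum, G) = 0.9392,
  derived exactly from the loading/threshold arithmetic, and the 4-band
  ordinalisation attenuation 0.8277 = Σφ(cuts)/sd(band). Driving
  criteria through G alone is the simplest structure consistent with the
  published sum-score correlations; it ignores subconstruct-specific
  criterion effects (the published subscale–criterion spread, e.g. 0.14
  to 0.41 for gameplay frequency, is not reproduced item by item).
* **Expenditure** (3 bands, 67.7 % / 20.9 % / 11.4 %) takes a fixed
  moderate latent correlation of 0.30 with G — enough to produce the
  reported "spends more" group contrast; no published correlation
  constrains it. **Device** (smartphone/computer/tablet/console,
  59.3 / 31.5 / 6.7 / 2.6 %) is independent of G, mirroring the null
  device association.
* **Randomness**: one root seed spawns eight fixed component substreams
  (latent factors, items, reference, each criterion, device), so every
  component is individually reproducible.

Not emulated: missing data, differential item functioning, longitudinal
structure, non-normal latent responses, and local dependence. A green
simulation test therefore establishes that the estimation chain recovers
the stated world, not that the instrument behaves this way in any real
population.

## Item reduction and scoring

`select_top_items()` keeps the k = 3 highest-loading items per
subconstruct, comparing loadings at full floating precision; exact ties
fall back to questionnaire order and are reported. Applied to the
published 34-item loadings this retains the documented 27 items. Sum
scores refuse rows with missing scale items; missingness is handled once,
listwise, at data loading (`read_responses()`), since the development
analysis reports a complete-case sample.

## Reliability and group-contrast conventions

* Cronbach's α uses sample (n−1) variances throughout.
* KR-20 uses item variances p(1−p) from the item means together with the
  sample variance of the total — the common spreadsheet-style convention,
  and the one consistent with this package's frozen hand-computed test
  value (0.849 for the 4-person fixture). Its finite-sample quirk is
  documented: for literally identical items it exceeds 1 by a factor
  (n−1)·k/((k)·(n−1)+...) that vanishes as n grows; with population
  variances in both places the value would be exactly 1 but the frozen
  fixture value would change. One convention had to be chosen; it is
  asserted explicitly in the tests.
* The two-sample t is the pooled Student form by default because the
  published group contrasts report df = n − 2 (462 at n = 464), which
  identifies the pooled convention; Welch is available via
  `pooled = FALSE`.
* The Mann–Whitney U is returned in both orientations (U_a and
  U_b = n_a n_b − U_a) because the published convention is not
  identifiable from a single printed value.
* p-values use the standard reference distributions (normal approximation
  with tie correction for U) and are reported for completeness only.

## Screening and cutoff selection

Efficacy indices follow the textbook 2×2 definitions; percentages are
rounded half-up to 1 decimal and κ / Youden to 2 decimals when displayed,
matching the development table's formatting. The DOR uses the
cross-product with Haldane's +0.5-to-all-cells correction only when a
cell is zero. Undefined ratios (empty screen margin) surface as `NaN`
plus a flag, never as silent zeros.

The optimal-cutoff rule is three steps: (1) keep cutoffs with sensitivity
**and** specificity strictly above 75 % — strict, because the published
candidate list excludes a row sitting at 73.0 % specificity; (2) keep
cutoffs tying the maximal κ **after rounding to 2 decimals** — at the
development sample's cutoffs 20 and 21 the unrounded κ differ in the
third decimal (0.5002 vs 0.5025) and only the rounded comparison
reproduces the published two-way tie; (3) break ties by higher
sensitivity, then Youden, then DOR, then the lowest cutoff. Every step
is recorded in an audit trail, including both rounded and unrounded κ.

`reconstruct_counts()` recovers the 2×2 tables behind a printed scan row
by exhaustive search over all integer tables with the stated reference
margins; for the development table (60 positives, 404 negatives) each of
the seven rows pins down its counts uniquely, which the tests verify.
Two printed cells are knowingly irreproducible from those unique counts
and are excluded from every check: the DOR column (e.g. 26.62 printed at
cutoff 20 where the cross-product of the unique counts gives 26.05 — the
original software's internal DOR convention is unknown) and the Youden
value at cutoff 17 (0.69 printed, consistent with rounding the already
rounded percentages, 0.6847 → 0.68 from exact counts).

## Known limitations

* Fit-index values are estimator-specific (no WLSMV adjustment); compare
  models within this package only.
* Polychoric standard errors serve only as DWLS weights; no loading
  standard errors, modification indices, or invariance testing.
* The cutoff scan assumes integer scores; fractional scoring rules would
  need a finer grid.
* The generator's threshold choice is unconstrained by published
  information; conclusions that depend on the absolute score scale
  (e.g. where the optimal cutoff lands) do not transfer from synthetic
  to real data.
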