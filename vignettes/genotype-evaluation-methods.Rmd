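---
title: "Methods: multi-year forage genotype evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-year forage genotype evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bromeval)
```

This vignette documents the statistical machinery of `bromeval`, the
assumptions behind each stage, the defaults and why they were chosen,
and the numerical decisions a maintainer would otherwise have to
reverse-engineer from the code.

## The evaluation problem

A small set of candidate forage genotypes plus a control cultivar is
grown in a randomized complete block design (four blocks) and measured
over several consecutive production years on fifteen indicators: six
agronomic traits, three yield-related measures, and six nutritional
quality indicators. The questions are (i) which sources of variation —
genotype, year, genotype × year — drive each trait, (ii) which genotype
has the best overall multi-trait balance, and (iii) through which
trait-mediated pathways the design factors shape yield.

## The synthetic trial generator

`generate_trial()` draws plot-level records from the additive model

$$x_{gybj} = \mu_j + G_{gj} + Y_{yj} + (GY)_{gyj} + B_{bj} +
\varepsilon,\qquad \varepsilon \sim N(0, \sigma_j^2),$$

for indicator $j$: a grand mean, additive genotype/year effects, a
directly specified interaction, a block effect drawn once per (block,
indicator), and i.i.d. Gaussian residual noise. One seed governs a
single RNG stream whose order (block matrix first, then residuals
column by column) is fixed, so output is bit-reproducible across
sessions.

`default_effect_spec()` encodes the reference study conditions: five
genotypes ("1-10", "2-10", "3-12", "4-4", "WUSU") × three years × four
blocks, with "4-4" and "3-12" planted as the high-performing pair
(taller, thicker-stemmed, higher yield and protein, lower fibre), the
third year carrying the largest year effect, and an interaction that
pulls the strong genotypes further ahead in the peak year. Baselines
sit at magnitudes typical for perennial grass trials (e.g. plant
height 95 cm, hay yield 5600 kg·hm⁻², ADF 33%), residual SDs at 2.5%
of baseline and block SDs at 1.2% — dispersion levels in the range of
well-run agronomic trials. Because every formula downstream of TOPSIS
requires strictly positive inputs, the generator *errors* on a
non-positive draw rather than truncating; with the default
baseline-to-noise ratios this never occurs in practice.

What the generator deliberately does not emulate: weather-driven year
effects (year is a free additive profile, not a climate model),
spatial autocorrelation within blocks, cross-indicator residual
correlation, and measurement rounding. Tests passing on this generator
therefore certify the statistical machinery — effect recovery,
calibration, ranking logic — not robustness to field pathologies like
spatial trends or missing plots.

`sem_ground_truth()`/`generate_sem_dataset()` provide the second
generator: a linear-Gaussian DAG in which exogenous variables are
standard normal and each endogenous variable is the
coefficient-weighted sum of its parents plus a residual scaled so the
variable has unit variance in expectation (the implied covariance is
accumulated in topological order, so correlated parents are handled
exactly). Under that construction the planted coefficients *are*
standardized path coefficients, which is what makes OLS refits an
unbiased recovery check. `yield_path_truth()` fixes the reference DAG
with coefficients (−0.52, 0.70, −0.24, 0.29, −0.29, 0.54, 0.79); the
genotype and interaction scores are continuous unit-variance stand-ins
so that every edge carries a single coefficient.

## Quality indices

`ddm()`, `dmi()`, `rfv()` and `crude_protein()` are the standard
detergent-fibre hay evaluation formulas, taken on the 0–100 percent
scale. They are computed and stored at full precision; rounding to
reporting precision (one decimal) happens only in display methods.
This matters: `rfv(22, 42)` is 158.94, which a report may print as
roughly 158 — rounding inside the computation would silently compound.

## Assumption screening and ANOVA

The Lilliefors-corrected KS test estimates mean and SD from the
sample, which invalidates the classical KS null; `lilliefors_ks()`
therefore simulates the null (10,000 replicates by default). The null
depends only on the sample size, so it is cached per *n* with a fixed
internal seed and the caller's RNG state restored — repeated screening
of many 4-replicate cells costs one simulation. The simulation-based p
has resolution ~1/10,000 and Monte-Carlo error of roughly ±0.01 near
0.05. A cell passes normality at p ≥ 0.05 outright, or in the marginal
band 0.01 < p < 0.05 when |skewness| < 2 and excess |kurtosis| < 7.
Variance homogeneity uses the median-centred (Brown–Forsythe) Levene
form, robust to non-normality.

`twoway_anova()` requires a balanced complete factorial and refuses
anything else — with equal replication, sequential and partial sums of
squares coincide and partial η² = SS/(SS + SS_error) is unambiguous.
Sum-to-zero contrasts are set explicitly; they do not change balanced
SS but make the coding reproducible. `lsd_pairwise()` implements
protected LSD: pairwise declarations only after a significant omnibus
F. Under protection the "significant ⇔ |difference| > LSD" rule holds
conditional on the omnibus gate; with `protect = FALSE` it holds
unconditionally. Compact letters use the insert-and-split sweep, with
groups processed in ascending mean order so ties break
deterministically. The two-sample test defaults to pooled-variance
Student t — consistent with the balanced layout and the LSD machinery
— with Welch available via `var_equal = FALSE`.

## Clustering and association

`kmeans_fit()` implements the k-means++/Lloyd protocol directly
(25 restarts, 300-iteration cap) rather than delegating to
`stats::kmeans`, because the protocol requires k-means++ seeding and a
per-iteration WSS trace — the trace is asserted non-increasing on
every run, and tests cross-check the final WSS against the stock
solver on separable data. Emptied clusters are refilled with the
current worst-fit point. `select_k()` picks the k maximizing mean
silhouette width (`cluster::silhouette`), reporting the elbow curve
alongside; ties go to the smaller k via first-maximum semantics. With
only five genotypes the silhouette rests on five points — the function
permits it but warns whenever rows < 2k. The clustering input is the
genotype profile matrix (per-genotype indicator means over all years
and blocks), z-scored per column; constant columns are dropped with a
warning since they carry no contrast.

`mantel_test()` is implemented in-package: the permutation p needs the
+1-corrected one-tailed form, a seedable stream, and enough speed for
thousand-replicate calibration; the statistic is cross-checked against
`vegan::mantel` in the tests. The default tail is one-sided
("greater"), matching the positive-association framing of trait-yield
analyses; two-sided is available. Distance matrices are expected as
Euclidean distances on z-scored trait subsets — the standard default
when no metric is otherwise specified.

## Entropy-weighted TOPSIS

The ranking stage is the package's own implementation of the
four-stage entropy weighting (proportion normalization → entropy →
dispersion → weights) followed by the ideal-solution ranking on the
weighted proportion matrix, with cost indicators (ADF, NDF, ash)
handled by direction at the ideal-solution stage, not by reciprocal
transformation. Numerical choices:

* `0 · ln 0 = 0` is applied literally, so one-hot columns get entropy
  exactly 0; entropies are clamped to [0, 1] against FP excursions.
* Strict positivity is enforced with an instructive error. For signed
  input (z-scores), `rescale = TRUE` min-max rescales each column to
  [0.05, 1] first — the lower bound keeps log terms finite while
  preserving ordering. Whether a ranking should consume raw trait
  means or standardized values is genuinely open; the package defaults
  to raw per-genotype means over all years and blocks
  (`decision_matrix()`) and exposes the rescaled pathway explicitly.
* An all-uniform matrix has zero total dispersion (weights undefined)
  and identical rows make closeness 0/0; both are errors, not NaNs.
* Ties in closeness get dense ranks. Weights are reported at 2 dp in
  displays only; printed weight vectors may visibly sum to 1.01 while
  the internal vector sums to 1 within 1e-12.
* Under entropy weights, duplicating an indicator redistributes the
  weight mass, so closeness is *not* duplication-invariant; it is
  invariant when weights are supplied externally. The tests assert
  this documented behaviour rather than a false invariance.

Correctness is anchored by an oracle test: an independent,
loop-by-loop transcription of the equation stages must agree with the
vectorized implementation to 1e-12 on 100 random 5 × 15 fixtures.

## Random-forest importance

The forest itself is `randomForest` — the canonical implementation of
the out-of-bag permutation importance used here — behind a thin
fit/importance/pseudo-R² contract so the permutation machinery is
backend-independent. Importance is the scaled OOB %IncMSE (constant
predictors, whose scaled score is 0/0, are reported as exactly 0).
Model significance permutes the response and refits; per-variable
significance permutes one predictor column at a time; both use the
+1-corrected p. The protocol default is 1000 trees and 1000
permutations; the test and calibration suites run a scaled-down mode
(ntree = 200, 199 permutations, 40-record tables) that keeps the
estimator identical and only coarsens Monte-Carlo resolution — chosen
as the smallest sizes at which the planted-signal and null-calibration
properties are stable. The printed report also shows %IncMSE
normalized to sum to 100 ("contribution %"), a common reporting
convention, clearly separated from the raw scores.

## Piecewise SEM

`sem_fit()` fits one OLS per endogenous variable,
standardizes numeric-parent coefficients as
$\beta = b\,\mathrm{SD(parent)}/\mathrm{SD(child)}$ (numerically
identical to regressing z-scored child on z-scored parents, which the
tests verify), and evaluates global fit through the d-separation basis
set: for each non-adjacent pair, one claim conditioned on the union of
both variables' parents, with the topologically later variable as
response (ties lexicographic). Claim p-values are partial-F tests of
the claim variable in the conditional regression, which generalizes
cleanly to categorical variables as dummy blocks; a claim between two
unconditioned categorical variables falls back to a chi-square
association test, and a conditional claim between two categorical
variables is refused. Fisher's C = −2Σln pᵢ is referred to χ² with 2k
degrees of freedom; claim p-values that underflow to zero are floored
at 1e-300 with a warning (configurable to an error), and a saturated
model returns C = 0, df = 0, p = 1 with a warning. Effect
decomposition enumerates all directed paths: direct is the single-edge
β, indirect the sum of products over multi-edge paths, total their sum
— defined only along edges carrying scalar coefficients.

Categorical design factors are handled two ways, matching two uses: in
trial-table models (`default_trial_sem()`) genotype and year enter as
dummy blocks; in the reference yield DAG the genotype and interaction
terms are continuous unit-variance scores so each edge reports the
single standardized coefficient that effect decomposition needs.

## Calibration and problem sizes

The test suite ties every inferential tool to its nominal behaviour:
type-I error of the two-way ANOVA terms, protected LSD, median-Levene
and Mantel tests must fall in [0.03, 0.07] at α = 0.05 over 1000 null
simulations; path-coefficient recovery averages 50 replicates of
n = 10,000; model-fit calibration uses 100 replicates at n = 200
(large enough that a deliberately omitted strong edge is rejected in
≥ 90% of replicates); forest checks use 100 replicates of 40-record
tables. These sizes are the package's chosen trade-off between
Monte-Carlo resolution and a test suite that runs in minutes on a
single core.

## Known limitations

* Year is a fixed effect; there is no mixed-model or repeated-measures
  pathway, and no multiple-testing correction beyond the protected
  LSD gate.
* The "CF" indicator is treated as an opaque benefit-type trait (field
  usage is ambiguous between crude fat and crude fibre); the package
  never computes it.
* TOPSIS supports entropy weights only — no expert/AHP weighting.
* The Lilliefors p is simulation-based; expect ±0.01 wobble across
  cache cold-starts with different replicate counts.
* Effect decomposition is undefined across dummy-block edges; total
  effects of categorical factors require the continuous-score coding.
* The pipeline assumes complete balanced tables; unbalanced or
  missing-plot data must be handled upstream.
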