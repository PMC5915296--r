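---
title: "Models and design choices in mrsummary"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in mrsummary}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrsummary)
```

## The two-sample MR model

Two-sample summary-data Mendelian randomization takes, for each of L
independent genetic instruments, the per-allele association with the
exposure (βX_j, σX_j) from one GWAS and with the binary outcome
(βY_j, σY_j, on the log-odds scale) from another. Under the
instrumental-variable assumptions — each variant is associated with the
exposure, independent of confounders, and affects the outcome only
through the exposure — every ratio θ̂_j = βY_j/βX_j estimates the same
causal log-odds effect θ per unit of exposure, and the estimators differ
only in how they pool the ratios when some instruments may violate the
exclusion restriction.

- **IVW** pools with weights w_j = σY_j⁻² applied to the regression of
  βY on βX through the origin. It is efficient when all instruments are
  valid and biased when pleiotropic effects do not average out. We
  report both the fixed-effect SE, (Σ w_j βX_j²)^−1/2, and the
  multiplicative random-effects SE, inflated by max(1, √(Q/(L−1)))
  with Q Cochran's heterogeneity statistic on the ratio scale. The
  random-effects model is the default because at typical L (tens of
  instruments) heterogeneity is the rule, and the max(1, ·) floor means
  it can never report a narrower interval than the fixed model.
- **MR-Egger** frees the intercept: E[βY_j] = θ0 + θ βX_j. Instruments
  are first oriented so every βX_j > 0 (flipping βX and βY jointly),
  since the intercept is only interpretable for a fixed orientation.
  The intercept θ0 estimates mean directional pleiotropy per instrument
  and its t-test (L − 2 df; t rather than normal for small-L
  calibration) is the formal pleiotropy test. The intercept is *not*
  rescaled per SD of exposure: it is an outcome-scale quantity (log
  odds per instrument), not an effect per exposure unit, and we
  document it as such.
- **Weighted median**: ratios are sorted, each carries normalized
  weight w_j = (βX_j/σY_j)², and the estimate is the linear
  interpolation of the sorted ratios against the cumulative weight
  midpoints s_j = Σ_{k≤j} w_k − w_j/2 evaluated at 0.5. It is
  consistent while valid instruments hold > 50% of the weight. Since no
  closed-form SE exists, a parametric bootstrap resamples
  (βX_j, βY_j) from N(observed, reported SE²) and takes the SD of the
  recomputed medians; the seed is a required argument — there is no
  silent clock seeding — and is recorded in the result. Default 1000
  replicates; below ~200 the SE itself becomes noticeably noisy.

Simple-median and penalized-median variants, mode-based estimators,
outlier-removal schemes and multivariable MR are deliberately out of
scope.

## Scales and units

Exposure GWAS often report percentage changes per allele;
`percent_to_log()` maps these to additive log-unit effects
(ln(1 + pct/100)), with the delta-method SE `se/(100 + pct)` applied by
`convert_scale()`. Causal estimates are computed per unit of βX and
then multiplied by `sd_scale`, the exposure SD in those units, to give
effects per SD — for serum GGT, 1 SD = 0.65 log units, a 92% increase
in concentration. Rescaling leaves z-statistics and p-values untouched.
Outcome odds ratios are expected to arrive log-transformed (`log-odds`
scale tag), with SEs interpreted as SEs of the log-OR, the GWAS
convention.

## Harmonization

Exposure and outcome tables are intersected by rsid; at each variant
the outcome alleles must match the exposure's pair either directly
(same effect allele), reversed (outcome β sign is flipped), or after
complementing the strand; anything else is an error naming the rsid.
Palindromic variants (A/T, G/C) cannot be strand-resolved from alleles
alone, so a policy governs them: the default is `flag` — keep the
instrument but mark it — because instrument lists for published MR
analyses are curated upstream, and silently dropping variants would
change L; `drop` and `keep` are available. Duplicate rsids within a
table are an error, not a silent deduplication: a curated instrument
list should be unique. Allele comparison is case-insensitive, and
indel-style multi-nucleotide allele strings are accepted literally
(strand complementing is attempted base-wise).

## Diagnostics

Instrument strength is summarised by F_j = (βX_j/σX_j)², with F > 10
the conventional adequacy threshold. Variance explained uses
2·eaf(1−eaf)βX_j²/var(X) when allele frequencies are present, falling
back to F_j/(n − 2 + F_j) otherwise; the two agree asymptotically.
I²GX quantifies how much measurement error in the exposure effects
dilutes the MR-Egger slope (the NOME assumption): it uses
exposure-side precisions σX_j⁻² about their weighted mean, after the
same βX > 0 orientation as Egger, and values near 1 mean minimal
dilution bias. Funnel data plot each θ̂_j against its precision
1/se(θ̂_j) by default; because "precision" in a genetic funnel plot is
sometimes read as instrument strength, |βX_j| is available via
`y_axis = "exposure_effect"` rather than guessing a single intent.
The per-variant outcome screen reports raw p-values alongside
Bonferroni-adjusted significance at 0.05/L.

## Power

The binary-outcome power calculation attenuates the causal OR per SD
to the risk-difference scale, b = K(OR/(1 + K(OR − 1)) − 1) for case
fraction K, sets v = K(1 − K) − b², and uses
NCP = N·R²·b²/v in a one-degree-of-freedom normal test. An optional
`adjust_r2` flag divides the NCP by (1 − R²), a variant some
calculators apply; it is off by default. The approximation degenerates
as v → 0 (extreme OR/K combinations), which is treated as a domain
error; `minimum_detectable_or()` inverts the calculation by bisection
and restricts its search to ORs where b² ≤ 0.9·K(1 − K), since inside
the degenerate fringe the NCP blows up and the reported "power" would
be an artifact of the approximation rather than a property of the
design.

## The synthetic-data generator

`simulate_summary_stats()` draws summary statistics directly from
their asymptotic sampling distributions rather than simulating
individual-level genotypes: that is exactly the structure two-sample
MR consumes, and it keeps every replicate sub-millisecond. The default
configuration is the benchmark study design: L = 26 instruments, an
exposure GWAS of n = 61,089, a case-control outcome study of 54,162
with case fraction 17,008/54,162, and a target total R² of 1.9%.
Minor-allele frequencies are uniform on [0.05, 0.45] — a generic
common-variant range chosen once; the bounds exclude rare variants
(whose SEs would explode) and exact 0.5 (degenerate heterozygosity).

Per instrument: heterozygosity h_j = 2·maf_j(1 − maf_j); true effects
a_j are half-normal magnitudes rescaled so Σ h_j a_j² equals the
target R² exactly (the exposure is standardized to unit variance
internally; the 0.65-log-unit SD conversion is exercised downstream
exactly as for real data). The magnitudes are deliberately all
positive: curated instrument tables orient the effect allele to raise
the exposure, and this orientation is what makes *directional*
pleiotropy directional — with random-signed instrument effects a
constant direct outcome effect would cancel out of the IVW estimator
in expectation. SEs follow the standard asymptotics,
σX_j = (h_j n_exp)^−1/2 and σY_j = (h_j n_out K(1 − K))^−1/2, so
doubling n_out shrinks every outcome SE by exactly √2. Direct
(pleiotropic) effects α_j ~ N(μ_α, τ²) are assigned to a configured
fraction of instruments, independently of a_j (so InSIDE holds by
construction); the true outcome effect is Γ_j = θ a_j + α_j. Observed
effects add normal noise with those SEs. Everything is reproducible
from the seed, and the caller's RNG stream is saved and restored.

What the generator does *not* emulate: linkage disequilibrium between
instruments (the benchmark instruments are independent), winner's
curse in instrument selection, sample overlap between the two studies,
and non-normal sampling error. Passing tests therefore demonstrate
estimator correctness and calibration under the idealized two-sample
model, not robustness to those real-data complications.

`run_scenario_grid()` replicates a configuration (replicate r reseeds
at seed + r − 1), runs the full harmonization-plus-estimation
pipeline, and reports bias, empirical SE, 95% CI coverage and
rejection rates per method, plus the Egger intercept rejection rate —
the harness behind the calibration and robustness tests.

## Numerical choices and problem sizes

- CI level 0.95 with the 1.96 normal critical value (configurable);
  Egger uses t(L − 2).
- Egger declares collinearity when the weighted design determinant
  falls below 1e-10 of its scale.
- Weighted-median interpolation clamps to the extreme ratios when 0.5
  falls outside the cumulative midpoints (possible only under severe
  weight concentration).
- The test suite verifies IVW/Egger against an independent
  weighted-least-squares oracle (R's `lm`) to 1e-10 on random
  instances, and the weighted median against hand-enumerated
  interpolation instances. Calibration tests use 500 replicates of the
  benchmark preset (coverage asserted in [0.93, 0.97]) and robustness
  tests 300 replicates with 30% of instruments pleiotropic
  (μ_α = 0.04 ≈ the typical instrument effect size, τ = 0.01) — sizes
  at which the Monte-Carlo error of each asserted quantity is several
  times smaller than the asserted margin.
- The realized observed-effect R² exceeds the target slightly in
  expectation (by L/n_exp, the summed sampling variances); tests bound
  each replicate within 3.5 analytic SDs of that expectation.

## Known limitations

The weighted-median p-value is normal-theory on a bootstrap SE, which
can be optimistic at very small L. MR-Egger is imprecise when the
spread of instrument strengths is small (low I²GX); the package
reports I²GX but applies no SIMEX-style correction. The power formula
is an approximation whose accuracy degrades for very common outcomes
or very large ORs, exactly the v → 0 regime it refuses.
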