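---
title: "Stock identification from morphometric and fatty-acid signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stock identification from morphometric and fatty-acid signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stockdiscrim)
```

## The problem

Anadromous fishes that mix at sea but home (or stray) among river basins
pose a classic management question: do the spawners entering different
basins form one panmictic population or several *stocks* — groups with
enough temporal and spatial integrity to be managed separately?
`stockdiscrim` implements the phenotypic route to that answer for a
three-group design built around sea lamprey entering Portuguese rivers: a
northern/central group of six basins, a Tagus group and a Guadiana group.
Two independent character suites are analysed with the same discriminant
machinery: size-adjusted morphometric measurements, and the fatty-acid
composition of heart phospholipids, whose acyl structure is
physiologically constrained and comparatively robust to short-term diet.

## Allometric size adjustment

Morphometric characters grow allometrically: on log scales, a character
relates linearly to total length (TL). Mixing specimens of different
sizes therefore confounds shape with size. The package removes size in
three steps.

1. `regress_on_length()` fits `log(value) ~ log(TL)` per character. A
   character whose slope is not significant (like eye length in the
   motivating study) is treated as size-free and only log-transformed.
2. `ancova_common_slope()` compares the separate-slopes model
   `log(v) ~ group + log(TL):group` against the common-slope model by a
   nested-model F test, and reports the pooled within-group slope
   \(b_c\). The common slope is used for **all** characters, including
   those with significant heterogeneity — heterogeneous slopes are
   reported, not special-cased, because a per-group adjustment would fold
   group information into the "size-free" values and bias the
   discriminant step.
3. `adjust_for_size()` computes
   \(\mathrm{adj} = \ln v - b_c(\ln TL - \ln TL_{ref})\), with
   \(TL_{ref}\) the grand mean length. The adjustment is invariant to a
   common rescaling of lengths and reference, and at the reference length
   it reduces to a pure log transform.

Outliers are screened on the within-group residuals of the adjusted
values (threshold 3 SD, the "extreme" convention) and, for meristic
counts, by boxplot fences at 3 × IQR. Both thresholds are exposed in
`pipeline_config()`; they are conventions, not estimates, and the
defaults mirror what SPSS-era studies in this literature used.

One genuinely open choice: whether the common slope should be pooled over
the full analysis sample or re-estimated per analysis subset. The package
pools over the sample handed to the pipeline, which matches how the
published adjusted means behave and keeps the adjustment a fixed
transformation of the data.

## Screening: MANOVA, dimorphism, PERMANOVA

Sex and group effects are screened with a two-way crossed MANOVA
(`manova_two_way()`). Hypothesis SSCP matrices use sum-to-zero contrasts
and Type-III style tests — each effect adjusted for the other and the
interaction — because that is the convention the published tables in this
literature follow; for the balanced designs the generator produces, all
conventions coincide. Pillai's trace \(V = \mathrm{tr}\,H(H+E)^{-1}\) is
the headline statistic with its standard F approximation; Wilks'
\(\Lambda = \det E / \det(H+E)\) is reported alongside. Two SPSS-style
extras are included because studies report them: a partial effect size
\(V/s\) (with \(s = \min(p, q)\)) and observed power from the noncentral
F implied by the sample estimate (noncentrality \(F \cdot df_1\)). Both
are descriptive conveniences, not inferential quantities.

Characters with a significant per-variable sex F
(`per_variable_F()`, raw \(\alpha = 0.05\), uncorrected — the field's
convention for dimorphism screens) are removed by
`select_nondimorphic()`. Screening at raw \(\alpha\) means roughly 5% of
genuinely non-dimorphic characters are removed by chance; the pipeline
logs the removals rather than pretending the screen is error-free, and
the test suite asserts frequencies, not single-run certainties.

Meristic counts get a two-way PERMANOVA (`permanova_two_way()`):
Euclidean distances on z-scored counts (counts are commensurate, and this
choice makes the SS table decompose exactly like a classical ANOVA),
sequential SS via projection onto the design terms, pseudo-F =
MS_term/MS_residual, and significance by free permutation of specimen
rows with \(p = (\#\{F^* \ge F\} + 1)/(n_{perm} + 1)\). The number of
distinct permutations drawn is reported. Unrestricted permutation is the
simplest scheme valid under the crossed, near-balanced designs this
pipeline sees; in the univariate Euclidean case the pseudo-F reproduces
the classical F exactly, which the tests exploit as an oracle.

## Stepwise discriminant analysis

The discriminant step is the package's core. Variables enter greedily:
at each step the candidate that maximizes the **minimum pairwise
Mahalanobis distance**
\(D^2 = (\bar x_i - \bar x_j)^\top S^{-1} (\bar x_i - \bar x_j)\)
(with \(S = W/(n-K)\) the pooled within-group covariance) is tested with
a partial F-to-enter derived from the Wilks ratio of the augmented to the
current model; after every entry, included variables whose partial
F-to-remove falls below the exit threshold are pruned. Defaults are the
conventional F-to-enter 3.84 and F-to-remove 2.71. An all-noise input
yields an empty selection, reported as such rather than as an error.

`fit_discriminant()` solves the \(W^{-1}B\) eigenproblem through its
Cholesky-symmetrized form (numerically stable and guaranteed real
spectrum), keeps \(\min(p, K-1)\) functions, and scales coefficients so
each score has unit pooled within-group variance. Loadings are pooled
within-group variable–score correlations; each function is oriented so
its largest-magnitude loading is positive, making reports reproducible.
Variance shares are \(\lambda_f / \sum \lambda\), and
\(PI_j = \sum_f \ell_{jf}^2\, \mathrm{share}_f\) is the potency index, a
single-number summary of variable \(j\)'s contribution.

Classification is nearest-centroid in function space with equal priors —
group sizes are deliberately balanced by the stratified subsampler before
the MDA, so equal priors are the honest choice — and exact ties break
deterministically toward the lowest group index (random tie-breaking
would silently break reproducibility). Cross-validation
(`loocv_confusion()`) refits the model n times on n−1 specimens with the
variable set **fixed** from the full-data stepwise run; per-fold
reselection is a different (and more expensive) estimator than the one
this literature reports. Press's Q
\((N - nK)^2 / (N(K-1))\) against \(\chi^2_1\) tests whether the
cross-validated accuracy beats chance.

`stratified_subsample()` reduces an oversized group by proportional
allocation across river × sex strata with largest-remainder rounding,
then samples without replacement inside strata — deterministic given its
seed, which the pipeline derives from the single configured seed via
fixed named offsets so each stochastic stage has an isolated,
reproducible substream.

## Fatty-acid arithmetic

Profiles are percentages of the summed identified fatty acids
(`normalize_percent()`), arcsine-square-root transformed
(`arcsine_transform()`) before normal-theory analysis. `class_sums()`
and `unsaturation_index()` compute the signature summaries: ΣSFA, ΣMUFA,
ΣPUFA, omega-series sums, DHA/EPA, EPA+DPA+DHA, and
\(UI = \sum_i p_i \cdot db_i\). Components marked "not detected" are
structural zeros: they participate in sums as exact 0 and are never
imputed. A PUFA without a series annotation (C20:2 as printed in the
reference tables) belongs to neither the ω3 nor the ω6 sum. When EPA is
absent the DHA/EPA ratio is flagged undefined rather than reported as
infinity.

`select_fa_for_mda()` applies the membrane-phospholipid subset rules
used before discriminant analysis — drop chains shorter than 10 or longer
than 22 carbons, drop C14:1 and odd-chain monounsaturates, drop
components undetected everywhere — each individually toggleable.

## The synthetic-data generator

No raw specimen data were ever deposited for the motivating study, so the
generator is a first-class module, not a test fixture. It emulates the
study's **marginal** structure:

- stratified sampling over group × river × sex (default 14 per stratum:
  224 specimens over 8 rivers, the study's size);
- total length Normal(864, 60) mm truncated positive by redrawing
  (the study's range was 639–979 mm; at this coefficient of variation
  the truncation bias is negligible);
- characters \(v = \exp(\mu_{g,s,c} + b_c(\ln TL - \ln \overline{TL}) +
  \varepsilon)\), with the published adjusted log-scale sex means as
  \(\mu\), group-level deviations only on the three characters the study
  found discriminating, slope 1 for all length-linked characters and 0
  for eye length, and residual SD 0.05 (≈5% CV — chosen once as a
  realistic measurement-plus-biology scatter for field morphometrics);
- fatty-acid profiles by additive logistic-normal noise (SD 0.3 on the
  log-ratio scale) around group mean compositions, back-transformed and
  renormalized to 100%, with each group's not-detected set as structural
  zeros. A logistic-normal rather than Dirichlet model preserves the
  zero structure and yields heavier-tailed, more realistic profiles.
  Because the published composition table lists only 24 of the 30
  identified fatty acids (its group means sum to 76–90%), the default
  configuration carries an explicit `other` remainder component so every
  tabulated component keeps its published mean percentage while the
  composition closes to 100%;
- meristic counts as rounded truncated normals at the published
  means/SDs — a deliberately minimal model whose only job is to make the
  PERMANOVA branch exercisable.

`null_config()` strips all group effects (pooling means across groups,
preserving sex effects) for type-I-error and null-behaviour suites.

**What the emulation does not reproduce.** Within-group covariances are
diagonal on the log scale (the source tables contain no covariance
information; the flag is structural, not estimable). Two consequences
matter for interpreting green tests. First, multivariate power on
synthetic data differs from the real data's. Second — and more visibly —
group-specific not-detected components are *perfect* discriminators
(zero within-group variance in one group, positive values elsewhere), so
the synthetic fatty-acid branch classifies at or near 100%, above the
83.8% the real profiles support. Passing pipelines therefore demonstrate
correctness of the machinery, not field performance.

## Numerical and testing choices

- Wilks/eigen computations go through Cholesky factors of \(W\); a
  singular \(W\) (collinear variables) is an explicit error naming the
  columns, not an NA.
- All percentages keep full precision in CSV/JSON output; rounding to
  1 dp (percentages) and 3 dp (statistics) happens only in printing.
- Degenerate inputs have defined behaviour: constant-length regressions
  error; an all-constant PERMANOVA matrix errors (all distances zero);
  a character with zero residual variance is skipped with a warning in
  the outlier screen; an empty stepwise selection is a reported outcome.
- Simulation suites use fixed seeds and study-scale or smaller problem
  sizes chosen for statistical validity: the ANCOVA heterogeneity power
  study uses 210 specimens (the scale at which the published df pair
  2, 201 arises), the MANOVA type-I calibration uses 500 replicates of a
  60 × 5 design, and stepwise/LOOCV oracle comparisons use 36–45
  specimens with 3–6 candidates so exhaustive oracles stay exact.
- Frequency assertions (recovery rates, type-I error) are tested against
  thresholds derived from binomial error bounds, never as single-run
  certainties: a raw-α dimorphism screen *will* occasionally remove a
  clean character, and a size-independence check over two functions has
  a ~10% familywise false-positive rate under the null. The tests treat
  those rates as the quantity under test.

## Known limitations

- No curvilinear allometry; the log-log linear model is assumed.
- No quadratic or regularized discriminant analysis; \(W\) must be
  nonsingular on the selected variables.
- The PERMANOVA offers only the documented unrestricted permutation
  scheme; residual-permutation schemes for unbalanced designs are out of
  scope.
- The published fatty-acid Press's Q (754.735) cannot be reproduced from
  the published confusion counts by the standard formula and is not used
  anywhere in this package; the morphometric value (16.759) reproduces
  exactly.
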