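---
title: "Statistical methods in snpgxe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods in snpgxe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpgxe)
```

`snpgxe` implements the complete statistical toolchain of a two-stage
case-control association study of a single SNP with gene-environment
(G×E) interaction analysis, as used in cardiovascular genetic
epidemiology: contingency-table association under the standard genetic
models, Hardy-Weinberg and homogeneity testing, Monte-Carlo permutation
empirical p-values, logistic-regression adjustment with multiplicative
interaction likelihood-ratio tests, modified Gensini coronary severity
scoring, and multifactor dimensionality reduction (MDR) with
interaction-entropy decomposition. This vignette documents the models,
the conventions chosen where the methodological literature leaves
latitude, and what the synthetic cohort generator does and does not
emulate.

## Contingency-table association

A single biallelic SNP with major allele G and minor allele A yields a
2×3 case-control genotype table. Four codings are analyzed:

* **allelic** — each subject contributes two alleles; 2×2 table of A vs G;
* **additive** — logistic regression of case status on allele dosage
  (GG = 0, AG = 1, AA = 2), fitted on grouped counts via frequency
  weights; the per-allele OR is `exp(beta)`;
* **dominant** — carriers (AG + AA) vs GG;
* **recessive** — AA vs (AG + GG).

For 2×2 codings the odds ratio is the cross-product `ad/bc` with the
Woolf (log-scale) 95% CI and a two-sided Wald p-value from
`z = log(OR)/SE`. When any cell is zero, the Haldane–Anscombe correction
adds 0.5 to all four cells. We report the Wald p as primary because, on
every printed table we reproduce, it matches the published unadjusted
p-values to their printed precision (e.g. the merged allelic
p = 6.08×10⁻⁵); the Pearson χ² p-value is computed alongside since some
software reports that instead, and the two agree asymptotically.

```{r}
g <- rs2107595_genotype_tables()$merged
odds_ratio(allele_table(g))
odds_ratio(recode_model(g, "dominant"))
```

Hardy-Weinberg equilibrium is assessed in controls by the 1-df Pearson
χ² against `p², 2pq, q²` at the sample allele frequency. Homogeneity of
odds ratios between the discovery and replication stages uses the
Breslow-Day statistic around the Mantel–Haenszel common OR with
Tarone's correction (on by default; on the bundled study tables the
correction is numerically negligible). Because the printed merged counts
are exactly the stage sums, the "merged set" is implemented as pooled
counts; an inverse-variance fixed-effect combiner is provided as a
clearly labeled extra, not the primary route.

Statistical power for a difference in allele frequencies uses the
two-sided two-sample proportion z-test without continuity correction,
with per-group n equal to the number of *subjects*. This is the variant
that reproduces the study-scale 81.0% power from MAFs 0.3442 vs 0.3055
at n = 2317/2404, and it is the convention of the PS power calculator
family.

## Adjusted models and multiplicative interaction

Logistic models are fitted by IRLS (`stats::glm`, binomial family) with
a convergence tolerance of 10⁻⁸ on the deviance and at most 100
iterations, wrapped behind a model-spec interface that supports
frequency weights so grouped eight-cell tables reproduce
individual-level fits exactly (coefficients agree to 10⁻⁶ in the test
suite). Perfect separation (detected as |β| > 15 or non-convergence) and
rank deficiency are errors, not silent results.

The multiplicative G×E interaction test compares
`outcome ~ G + E (+ covariates)` against the same model plus `G×E` by
the likelihood-ratio test; the interaction OR `exp(beta_GE)` is reported
with its Wald CI. Unadjusted interaction p-values are computed on the
published eight-cell stratum counts:

```{r}
s <- rs2107595_subgroup_tables()$t2dm
interaction_test(ge_strata_data(s$exposed, s$unexposed),
                 "g", "e", weights = "n")
```

Adjusted interaction analyses require individual-level covariates; the
same function accepts an individual-level cohort and a covariate list.
Subgroup fits exclude the stratifying variable from their own covariate
set, since a variable constant within a stratum is not estimable there.

Group comparisons of continuous phenotypes (e.g. relative mRNA
expression) use ANCOVA: an OLS model with the group factor and
covariates, a partial-F test for the group effect, and adjusted means
evaluated at the grand covariate means (the classic ANCOVA convention;
with no covariates the test reduces exactly to the equal-variance
t-test). Severity comparisons use the Mann-Whitney U test (exact
enumeration when `n_x * n_y <= 400` without ties, otherwise the normal
approximation with tie and continuity correction), and correlations the
Spearman rank test with average ranks and the t-approximation.

## Permutation empirical p-values and multiple testing

The Monte-Carlo permutation test holds both table margins fixed and
redraws tables from the multivariate hypergeometric null via Patefield's
algorithm (`stats::r2dtable`) — distributionally identical to permuting
case/control labels over subjects, but far cheaper, which is what makes
100,000 permutations routine. The permuted statistic is the same
single-model statistic being tested (squared Wald z for allelic /
dominant / recessive; Cochran-Armitage trend χ² for additive), not a
max-over-models statistic. The estimator is
`(1 + exceedances) / (1 + permutations)`, which cannot return zero.
Tests verify the Monte-Carlo p against exhaustive enumeration of all
tables with the observed margins on small fixtures.

Bonferroni control reports `min(1, m·p)` and flags at `alpha/m`; the
study-scale families are m = 24 (association analyses) and m = 56
(subtype/subgroup analyses).

## Modified Gensini scoring

Each coronary segment lesion is scored by stenosis band — 1 (0–25%),
2 (26–50%), 4 (51–75%), 8 (76–90%), 16 (91–99%), 32 (100%) — times a
segment-importance multiplier (5 main left coronary artery; 2.5 proximal
LAD and proximal circumflex; 1.5 mid LAD; 0.5 second diagonal and
posterolateral; 1 otherwise), and the weighted contributions are summed
per subject.

Two conventions deserve note. First, the printed integer bands are
implemented as half-open real intervals ([0,25], (25,50], (50,75],
(75,90], (90,100), {100}) so that continuous stenosis estimates map
unambiguously while integer inputs land exactly in the printed bands.
Second, an *acute total occlusion* is scored as a non-critical lesion:
its points are forced to the lowest band (1) and its weighted
contribution is additionally capped at 5. The cap guarantees the
documented 0–5 range for every multiplier, including the main left
coronary artery (1×5 = 5); the exact arithmetic intended by the "0–5
score" convention is ambiguous in the clinical literature, and this is
our documented resolution. Unknown segment labels are errors, not
silent multiplier-1 lesions.

Severity dichotomization uses a strict cutoff (`score > cutoff`), with
`"median"` resolving to the sample median — the study-scale convention
that splits a cohort at the median score of 30.

## Multifactor dimensionality reduction

The MDR engine is written from scratch. For a candidate factor
combination, every multilocus cell is labeled high-risk when its
training case:control ratio is at least the overall training ratio
(ties high; nonempty zero-control cells high; empty cells low, so
unseen combinations predict control). Model quality is *balanced*
testing accuracy, (sensitivity + specificity)/2 — the MDR-software
convention that is robust to mild case-control imbalance; plain
accuracy is reported alongside.

"100-time cross-validation" is implemented as 10-fold stratified CV
repeated 10 times: 100 held-out evaluations. Within each size, every
evaluation votes for the combination with the best held-out accuracy;
the vote count is the cross-validation consistency (CVC out of 100,
matching the /100 denominators reported by MDR software). The overall
best model maximizes CVC, with ties broken by mean testing accuracy and
then by smaller size. Significance comes from permuting outcome labels
and re-running the full search (add-one empirical p). Note that a size
class containing a single combination (e.g. the full four-factor model
among four candidates) trivially attains maximal CVC; testing accuracy
is the informative quantity there.

Interaction-entropy graphs use base-2 entropies: the univariate effect
of factor A is `100·I(A;Y)/H(Y)` and the pairwise effect of A, B is the
interaction information `100·[I(A,B;Y) − I(A;Y) − I(B;Y)]/H(Y)`
(positive = synergy, negative = redundancy). Closed-form identities
anchor the implementation: a balanced XOR outcome gives univariate 0 and
pairwise 100%, and a duplicated factor gives pure redundancy −I(A;Y).
Pairs are classed strong/moderate/weak at ≥2% and ≥1% of H(Y) by
default — configurable, since the convention in the field is a color
legend without printed thresholds.

## Synthetic cohort generator

The generator exists so that every analysis stage is exercisable and
calibratable without external data. Its defaults are the study
conditions the package targets: control MAF 0.306 in Hardy-Weinberg
proportions, dominant genotype OR 1.28, age/sex-matched design (their
ORs are 1), binary risk-factor prevalences and ORs at values realistic
for a middle-aged cardiovascular case-control sample (smoking 30%/OR
1.6, drinking 26%/1.2, T2DM 25%/1.8, hyperlipidemia 23%/1.7,
hypertension 40%/1.9, BMI>25 effect 1.4), baseline disease probability
8%, and case severity scores log-normal with median ≈ 28 for
non-carriers, dispersion 0.85 on the log scale and a ×1.18 carrier
shift, which puts the cohort median near 30. G×E interaction ORs
(≈1.4–1.6 at study scale) are off by default and supplied per
experiment. Prevalence defaults are configurable choices, not canonical
values: the study reports covariate distributions only in supplementary
material.

Sampling is *retrospective*: a source population at least 20× the
requested cohort (doubled automatically on shortfall) receives disease
status from the logistic model, and cases/controls are then drawn
without replacement. This preserves the odds-ratio interpretation of
every embedded coefficient, which is why parameter-recovery tests
(adjusted dominant OR 1.28 and interaction OR 1.46 recovered within
95% CIs in ≥90% of 100 seeds at n = 2317/2404) are meaningful. Age and
BMI are normal with thresholding for subgroup flags (BMI > 25); lesion
sets are constructed greedily over distinct segments to match each
case's drawn severity, so computed Gensini scores track the configured
distribution (correlation > 0.95 in tests).

What the generator does **not** emulate: linkage disequilibrium or
haplotypes (single SNP only), correlated covariates (risk factors are
independent Bernoulli draws, so real-data confounding structure is
absent), genotyping error, and longitudinal follow-up. Passing
recovery/calibration tests therefore demonstrates internal statistical
correctness, not robustness to those real-data features.

## Numerical and design notes

* Fixed seeds give bit-identical cohorts, folds, and permutation
  draws; seeded code restores the caller's RNG state. The pipeline
  derives stable per-stage child seeds from one global seed, so
  toggling a stage never shifts another stage's randomness.
* Published empirical permutation p-values for weak-signal models are
  not reproduction targets: the permuted statistic behind them is not
  recoverable from the methodological description (some printed
  empirical p exceed their asymptotic p by >60%). Our empirical p is
  validated against exhaustive enumeration and against the asymptotic p
  on strong-signal tables instead.
* Published MDR testing accuracies, CVC values and entropy percentages
  depend on the individual-level study dataset and are likewise covered
  by property-based tests (oracle equivalence on small cohorts, chance
  behavior under outcome permutation, entropy identities) rather than
  value reproduction.
* Test-suite problem sizes — e.g. 100-seed recovery at full study n,
  1000-simulation type-I calibration at n = 800, permutation oracles at
  a few thousand draws — were chosen to keep the default run fast on a
  laptop while leaving Monte-Carlo error well inside the asserted
  tolerances.
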