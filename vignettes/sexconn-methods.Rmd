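---
title: "Sex-stratified differential connectivity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex-stratified differential connectivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexconn)
```

# The scientific problem

Tumors from men and women differ transcriptomically, and some of those
differences translate into sex-dependent drug response. `sexconn`
implements a pipeline that goes from a gene-by-sample expression matrix
with per-sample sex and tumor/normal labels to a ranked list of
perturbagens — drugs and genetic reagents — predicted to act
sex-specifically:

1. **Univariate statistics** (`sex_de()`, `tumor_vs_normal_de()`):
   per-gene Wilcoxon rank-sum tests of male vs. female expression within
   tumors, and of tumor vs. normal expression within each sex, with
   Benjamini–Hochberg (BH) adjustment and median fold changes.
2. **Sex classification** (`fit_sex_classifier()`): an L1-penalized
   logistic model of sex from expression, scored by 10-fold
   cross-validated AUC; its sparse active set names the most sex-linked
   transcripts.
3. **Pathway over-representation** (`pathway_enrichment()`):
   hypergeometric enrichment of each sex's significant tumor-vs-normal
   genes in a GMT gene-set collection, classified per pathway as
   male-only / female-only / both, summarized by the discordance
   proportion.
4. **Signatures** (`build_signatures()`): per sex, the significant genes
   with the largest tumor/normal fold change form the *resistance*
   signature and the largest normal/tumor fold change the *sensitivity*
   signature (capped, default 250 per side).
5. **Connectivity scoring** (`score_library()`): each perturbagen's rank
   profile is scored against the (sensitivity = up, resistance = down)
   query with the two-sided Kolmogorov–Smirnov connectivity statistic,
   averaged over replicates and normalized to [−100, 100].
6. **Permutation classification** (`differential_connectivity()`): the
   whole derivation is repeated under random relabelings of sex to
   calibrate empirical p-values for each perturbagen's male−female score
   difference, followed by BH adjustment and Type I/II/III calls.

A seeded synthetic-data module (`generate_cohort()`,
`generate_library()`) supplies cohorts and perturbagen libraries with
planted, recoverable structure, so that every stage of the pipeline is
testable end to end without any external download.

# Statistical model, stage by stage

## Rank-based differential expression

All univariate tests are two-sample Wilcoxon rank-sum tests — robust to
outliers and invariant under monotone transforms of expression, which is
why the synthetic generator's choice of noise family (log-normal) is
innocuous. Exact enumeration is used for small tie-free groups (both
sizes ≤ 10); otherwise the normal approximation with tie and continuity
correction. The vectorized matrix implementation used inside the
permutation loop is tested for exact agreement with `stats::wilcox.test`.

Fold changes are ratios of group medians with a pseudocount (default 1)
on both medians, since normalized expression can have zero medians. BH
values come from the standard step-up procedure; `significant` always
means BH < `alpha` (default 0.05).

Fisher's method combines per-cancer p-values: X = −2·Σ log p is referred
to a chi-square with 2k degrees of freedom. Empirical permutation
p-values can be exactly zero, so zeros are clamped to the smallest
positive double with a warning (configurable to an error).

## Sex classifier

`glmnet` fits the lasso path; the penalty is chosen by minimizing
10-fold cross-validated binomial deviance, with folds stratified by sex
and a seeded assignment. The reported AUC is computed *only* from
held-out (prevalidated) linear predictors, pooled across folds, by the
rank/Mann–Whitney formula; a test cross-checks it against an independent
ROC implementation. Features are standardized internally so the penalty
is comparable across genes of different scale; as a consequence the
active-set membership is invariant under uniform rescaling of the
matrix. The final active set comes from a fit on all samples at the
selected penalty. On data with genuine sex-chromosome structure
(Y-linked transcripts near zero in females, XIST high in females) the
model attains AUC ≈ 1 with a handful of sex-chromosome transcripts.

## Pathway over-representation

A commercial pathway product originally filled this stage; its algorithm
is proprietary, so the package substitutes the transparent standard: the
upper-tail hypergeometric probability of the observed-or-greater overlap
between a pathway and the significant-gene list, against the measured
universe. The per-sex classification rule is purely threshold-based:
enriched in exactly one sex at p < alpha. A p-value exactly equal to
alpha counts as *not* significant (the published wording leaves the
boundary unassigned; assigning it to non-significance is the
conservative reading). Pathway p-values are reported raw by default —
matching how such per-sex enrichment tables are conventionally printed —
with an optional BH flag. Pathway *identities* are collection-dependent
and are not a validation surface; only the classification logic and the
discordance arithmetic are.

## Connectivity scoring

Profiles are complete rankings of the gene universe (rank 1 = most
up-regulated by the perturbagen). For a query set of n genes in a
universe of N, the running sum steps up 1/n at hits and down 1/(N−n) at
misses; the enrichment score ES is the signed extreme deviation, computed
in closed form from the sorted hit positions. The two-sided score is

> raw = (ES(up) − ES(down)) / 2 if the two have opposite signs, else 0.

Raw scores are averaged over a perturbagen's replicates (the stand-in
for the cell lines, doses and time points a real connectivity-map
service averages over), then normalized by a signed percentile
transform: within each sign class, score = sign × 100 × percentile of
|mean raw|, ties sharing the mean rank. The original service's exact
normalization is unpublished; the signed percentile reproduces its
reported scale ([−100, 100]) and its monotonicity, which is all the
downstream permutation machinery relies on. Published score *values* are
therefore not comparable number-for-number, and the package never treats
them as such. The transform is exactly antisymmetric: exchanging a
query's up and down sets negates every score, a property the test suite
asserts with zero tolerance.

## Permutation calibration and Type I/II/III calls

Sex labels are permuted uniformly over samples, male/female totals held
constant, tumor/normal labels untouched. For each of N permutations the
pipeline re-runs in full — sex-stratified DE, signature construction,
library scoring — and records each perturbagen's male−female score
difference. The empirical p-value is the fraction of permutations whose
null difference is at least as large *in magnitude* as the observed one,
p = r/N. This convention admits p = 0, which is deliberate: with N =
1000 the analysis this package models reported adjusted values below
1/N, implying attainable zeros. The (r+1)/(N+1) variant is available by
flag. The sample-size floor on tumor/normal arms applies to the observed
labels only; a permutation that happens to shrink an arm below the floor
is still a valid draw from the null (it is scored with the technical
minimum of two samples per arm), and a permutation that empties a
signature side contributes a zero difference and is counted and
reported.

Typing, with BH-adjusted p-values:

* **Type I** (male-sensitive, female-resistant): bh < 0.05, male score
  > 0, female score < 0;
* **Type II**: the mirror image;
* **Type III** (sensitive in both sexes): the sex difference is *not*
  significant (bh > `bh_floor_type3`) and both scores are ≥ 90.

Boundary values fall to "none", and a BH-significant perturbagen whose
scores share a sign is "none" (significance alone is not a sex-specific
*direction*).

**The Type III floor.** Two readings of the Type III insignificance
requirement circulate for this class of analysis: a strict ceiling (BH
above 0.95) and simple non-significance at the working threshold (BH
above 0.05, with the score floor of 90 doing the real work). Published
Type III predictions in this literature include BH values such as
0.9498, which a strict 0.95 ceiling would reject, so only the
non-significance reading reproduces them. `bh_floor_type3` therefore
defaults to `alpha_sexspec` — Type III means "not sex-specific at the
working threshold and strong in both sexes" — and the stricter 0.95
ceiling remains one threshold away for users who prefer the more
demanding reading.

# The synthetic-data generators

## What the cohort generator emulates

`generate_cohort()` draws expression as exp(log-baseline + planted
log-effects + Normal(0, dispersion)): nonnegative, right-skewed,
multiplicative — the aspects of normalized RNA-seq data the rank-based
pipeline is sensitive to. Per-gene baselines have median ≈ 100;
`dispersion = 0.5` on the log scale is a realistic biological
coefficient of variation for bulk expression. Planted structure:

* **Y-linked genes** are near zero (level 0.05) in females; four carry
  marker names (ZFY/EIF1AY/DDX3Y/RPS4Y1-like) mirroring the canonical
  Y-linked sex classifiers. All are labelled synthetic (`_like`).
* **An XIST-like X gene** is female-high in tumors only and
  sex-concordant in normal tissue by default (`xist_like = TRUE`),
  reproducing the qualitative contrast in which XIST discriminates sex
  in tumors but is never selected in normal samples.
* **Planted sex-DE genes** are drawn X-first, then autosomal, with
  alternating up/down direction at a single multiplicative
  `effect_size`.
* **Planted tumor-vs-normal genes** are autosomal and come in three
  classes — shared, male-only, female-only — with alternating direction,
  so both resistance and sensitivity signature sides exist. Shared
  effects have their own `effect_size_shared` (default equal), because
  the relative strength of the shared versus sex-specific tumor program
  is a property of the biology being emulated.

What it does **not** emulate: count-level sampling noise (negative
binomial library-size artifacts), batch effects, copy-number structure,
or gene–gene correlation. Passing tests on this generator therefore
demonstrate the *statistical machinery* — calibration, ranking,
recovery — not robustness to those real-data complications.

## What the library generator emulates

`generate_library()` produces complete rankings per replicate. A planted
perturbagen's ranking interpolates between a target ranking (its target
gene sets placed uniformly at random within the top/bottom bands) and an
independent uniform ranking, with weight `mimic_strength`; at strength 0
every perturbagen — planted or not — is an exchangeable uniform
permutation, and at strength 1 the target sets occupy the exact
extremes. Type I reverses the male signature (male sensitivity genes to
the top, male resistance to the bottom) while anti-reversing the female
signature; Type II mirrors; Type III reverses both. A gene pulled both
ways (e.g. a gene in both sexes' sensitivity sets, for Type I) has its
biases summed, so overlapping signatures behave sensibly. The optional
per-perturbagen `mimic` column models heterogeneous reagent potency.

# Frozen study conditions for the stochastic validations

The test suite validates the pipeline under three fixed, seeded
configurations; sizes were chosen once, on the generator, before the
assertions were frozen.

**Classifier benchmark.** 2,000 genes (60 X, 20 Y), 100 tumors per sex,
marker effects at fold change 4. The cross-validated AUC is asserted at
≥ 0.99 and the active set must lie on the simulated sex chromosomes.

**Null calibration.** A cohort with *no* sex-linked structure (no sex
chromosomes, no planted sex effects; an 80-gene shared tumor program at
fold change 3 so signatures exist), 30 tumors and 15 normals per sex,
600 genes; an all-null 100-perturbagen library; 200 permutations. Under
label exchangeability the empirical p-values must be approximately
Uniform(0,1) (KS p > 0.01) and the fraction below 0.05 must sit inside
binomial 99% bounds of 0.05.

**Planted recovery.** A cohort at the scale of a real tumor atlas — 120
tumors and 40 normals per sex, 1,000 genes — with shared, male-only and
female-only tumor programs of 60 genes each at fold change 6; signature
caps of 25 per side, proportionate to the reduced gene universe; a
220-perturbagen library (2 replicates) with 6 planted perturbagens per
type at potencies between 0.91 and 0.98; 200 permutations. The pooled
fraction of planted perturbagens recovered at their generated type must
be ≥ 0.9, and no null perturbagen may be called Type III.

Three design observations from the calibration, recorded because they
are properties of the method, not of the implementation:

* Large arms matter for the *permutation* null, not just the observed
  fit. In small cohorts a random relabeling can resemble the true
  labeling closely enough that diluted sex-specific genes survive into
  the permuted signatures, which keeps the null differences as extreme
  as the observed one and destroys power. At atlas scale the dilution is
  concentrated near 50/50 and the fc-ranked signature cap filters
  half-strength sex-specific genes out of every permuted signature.
* The percentile normalization saturates: any systematic bias component
  in a profile puts it at the extreme of its sign class regardless of
  magnitude. Sex-specific power therefore depends on permuted signatures
  being *sex-neutral*, which the shared tumor program guarantees; shared
  genes also anchor the sign of planted profiles' null scores through
  their asymmetric membership in the two sexes' observed signatures.
* With percentile scores, "score ≥ 90 in both sexes" is a statement
  about rank occupancy: planted perturbagens of heterogeneous potency
  occupy the top of both sexes' positive classes, which simultaneously
  keeps every planted Type III at or above the floor and makes a null
  Type III call structurally impossible as long as the planted count is
  at least the number of ≥ 90 slots.

# Numerical and design choices

* **Signature ranking ties** break by smaller BH value, then
  lexicographic gene id — fully deterministic tables.
* **Fold change exactly 1** qualifies for neither signature side.
* **Fewer than `size_cap` qualifying genes**: all are taken, with a
  warning (silenced inside the permutation loop, where shallow permuted
  signatures are expected and recorded).
* **Pan-cancer signatures** combine per-cancer DE tables by
  Fisher-combined, BH-adjusted p-values and rank by the geometric mean
  of per-cancer fold changes; with one cancer this reduces exactly to
  the single-cancer construction.
* **Signature/library universe mismatches** drop the missing genes with
  a warning before querying; capping happens before the intersection.
* **ES sign ties** (walk extremes of equal magnitude) resolve toward the
  positive extreme; a query equal to the whole universe is degenerate
  and scores 0 with a warning.
* **Empirical p ties** count as exceedances (|null| ≥ |obs|), the
  conservative direction.
* **Seeding**: every stochastic entry point takes a seed; the
  permutation run derives one child seed per permutation from the master
  seed, so the entire analysis is reproducible and the RNG state of the
  calling session is never disturbed.
* **Problem sizes** in the frozen configurations (gene counts, arm
  sizes, library sizes, 200 permutations) are the package's desk-scale
  defaults for validation; the pipeline itself has no upper limits, and
  `n_permutations = 1000` is the analysis default.

# Known limitations

* The connectivity normalization is a documented stand-in; absolute
  published connectivity scores from the original online service cannot
  be reproduced, only the scale, the ordering semantics, and everything
  downstream of them.
* The percentile transform makes scores library-relative: adding
  perturbagens changes other perturbagens' scores (not their order).
* The pathway stage is collection-dependent; it validates logic and
  arithmetic, not biological pathway identities.
* Pan-cancer pooling for the classifier is naive (no batch/cohort
  adjustment); with strong cohort effects the pooled model's active set
  should be interpreted cautiously.
* The generator's independence across genes means planted-recovery
  results are best-case with respect to gene–gene correlation.
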