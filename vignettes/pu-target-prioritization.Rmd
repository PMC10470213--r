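---
title: "Positive-unlabeled prioritization of immuno-oncology targets: methods and design"
author: "ioTargets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Positive-unlabeled prioritization of immuno-oncology targets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ioTargets)
```

## The problem

Genome-wide association studies for breast cancer incidence implicate
hundreds of candidate genes through linkage disequilibrium with risk
loci, but give no direct evidence about *which* candidates act through
the immune tumor microenvironment, and none of the well-powered cancer
GWAS collect immune phenotypes. `ioTargets` implements a functional
fine-mapping strategy for this setting: learn the shared evidence
profile of known immuno-oncology (I-O) therapeutic targets from a
multi-source gene feature matrix, and score every candidate gene by how
closely it resembles that profile.

The statistical obstacle is that only a small positive class is known
(tens of validated I-O targets) while everything else is *unlabeled*,
not negative — many unlabeled genes may be undiscovered targets. This
is positive-unlabeled (PU) learning with severe class imbalance.

## The scoring model

The scorer combines *easy ensemble* subsampling with *bagging*:

1. For model $i = 1, \dots, M$, draw a pseudo-negative set $N_i$ of
   size $|P|$ uniformly without replacement from the gene universe
   excluding the positive set $P$ (candidates and curated negatives may
   be drawn — the pool excludes only $P$).
2. Fit a random forest of $T$ trees on $P$ vs $N_i$ over the $p$
   feature columns.
3. Record each gene's positive-class probability (the fraction of trees
   voting positive) under model $i$.

The I-O target probability score of gene $g$ is the arithmetic mean
$\hat s(g) = \frac{1}{M} \sum_i \hat p_i(g)$, and feature importance is
the mean across models of each forest's mean decrease in Gini impurity.
Defaults follow the source protocol: $M = 10{,}000$ models, $T =
1{,}000$ trees, mtry $= \lfloor\sqrt{p}\rfloor$. An out-of-bag grid
walk for mtry is available (`tune = TRUE`, accepting a step only on a
relative out-of-bag error improvement above `improve = 0.01`) but is
off by default: at $p = 22$ the out-of-bag error on 90 training genes
is itself noisy, and a fixed mtry keeps runs exactly reproducible. The
conventional multiplicative step (`stepFactor = 2`) is the default;
tuneRF-style literal step factors below 1 are accepted but collapse the
walk onto its bounds, so they are not meaningful here.

Two properties of the implementation are worth stating:

* **Reproducibility and linearity.** Each model's negative-sampling and
  fitting RNG streams are derived from the master seed and the *model
  index*, so enlarging `nModels` never changes earlier models, and a
  run split into disjoint index ranges merges exactly
  (`combinePUEnsembles()`). The forest accumulates integer tree-vote
  counts and divides once at the end, so the merge is bit-identical,
  not merely close.
* **Training-set scores are in-bag.** Positives appear in every model's
  training set, so their scores are optimistic and must not be read as
  generalization estimates; use the cross-validation schemes for that.

## The feature matrix

The evidence matrix holds genes in rows and (by default 22) features in
columns, mixing four kinds: continuous genetic-perturbation screen
scores, standardized as $z = (x - \bar x)/s$ with the sample
($n-1$) standard deviation (the population convention is selectable —
the choice is irrelevant after standardization for tree learners, which
are monotone-invariant); non-negative integer concept-hit counts
summarizing Mendelian-disease text-mining (the per-gene row sum of a
binary gene-by-concept matrix); binary knockout-phenotype and
cancer-driver annotations; and signed leukocyte eQTL effect sizes.
Standardization is computed over all supplied genes, not only the
candidates, since the model trains and predicts across the full
universe.

Missingness is structural in real data (a gene absent from a screen is
missing all of that screen's features), and the pipeline keeps an
explicit mask: genes with more than `maxMissing = 6` missing features
are omitted from predictions (a gene with exactly 6 is retained — the
rule is a strict inequality), and remaining missing cells are filled by
the per-feature median over non-missing values. Median imputation is
the package's own choice where the protocol is silent: it is
deterministic, learner-agnostic, and preserves ranks of the observed
values. The mask is retained after imputation as provenance.

Gene identifiers are matched as exact case-sensitive strings; no
ortholog or alias resolution is attempted, so real inputs must be
pre-harmonized. Duplicate gene rows within one source are collapsed to
the maximum-magnitude value with a warning.

## Model evaluation

`computeRocAuc()` computes the AUC as the Mann–Whitney pair statistic
via midranks, with the ROC curve returned for plotting; the two agree
by construction (the trapezoidal integral of the curve equals the rank
statistic). Two cross-validation schemes mirror the two ways the
ensemble can be interrogated:

* `crossvalRandomNegatives()` — for each model index, draw the same
  pseudo-negative set the ensemble would draw, run a stratified
  10-fold CV on positives vs that set, and average AUCs across models.
* `crossvalFixedNegatives()` — one stratified 10-fold CV of positives
  vs a curated negative set (genes chosen to be non-essential and not
  expressed in immune or breast tissue). A leave-one-out mode is
  provided because the source material describes both variants;
  10-fold is the default.

AUCs are computed from pooled out-of-fold predictions rather than
averaged per fold: with 45 positives a fold holds 4–5 of them, and
per-fold AUCs are extremely noisy. Pooling across folds can introduce
a small pessimistic bias when fold-specific probability calibrations
differ; a per-fold breakdown is returned alongside. Folds are
stratified by class with seeded shuffling (stratification is the
package's choice; it guarantees every fold retains both classes at
45 vs 185).

A small-positive-set caveat quantified during development: under a
*null* generator (no signal), the random-negative CV AUC *conditional
on a particular draw of 45 positives* has a standard deviation of
roughly 0.04 around 0.5, because a random 45-gene set can by chance be
slightly clusterable in 22-dimensional feature space. Calibration
statements at this positive-set size are therefore meaningful averaged
over positive draws, not for any single draw.

The elastic-net logistic benchmark (`fitElasticNetEnsemble()`) runs
under the *identical* bagging protocol and seed schedule — the same
negative sets in the same order — with per-model $(\alpha, \lambda)$
chosen from a configured grid by 10-fold CV accuracy at the 0.5
probability threshold (the threshold is the package's choice; the
protocol specifies accuracy without defining it). Forest and
elastic-net score vectors are compared with Pearson's $r$ and the exact
$t$-transform p-value on $n - 2$ degrees of freedom
(`compareScoreVectors()`).

## Colocalization of risk loci from two traits

`permutationColocalizationTest()` asks whether one trait's risk loci
(e.g. breast cancer) lie unexpectedly close to another trait's lead
SNPs (e.g. autoimmunity). Each locus is reduced to a single anchor
point (its lead SNP); the statistic is the number of query loci whose
nearest same-chromosome lead lies within 500 kb (display windows use
250 kb flanks, a separate convention). Under the null, every query
locus is independently re-placed uniformly over the concatenated
chromosome lengths (landing on a chromosome with probability
proportional to its length), and the statistic is recomputed against
the fixed lead set; the empirical p-value is the add-one estimator
$(1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_\text{perm})$, which is
never zero and equals $1/10{,}001 < 10^{-4}$ when no permutation
reaches the observed count at the default 10,000 permutations.
`sensitivitySweep()` re-thresholds one shared set of placements at
several distances, so curves across thresholds are comparable.
Distances are lead-to-lead base pairs — deliberately LD-unaware; this
is a genomic-proximity test, not a posterior-probability
colocalization method. Coordinates are 1-based inclusive throughout,
and the genome is always caller-supplied (a `.chrom.sizes` file or
name/length vectors); no build is hard-coded.

## Candidate ranking and clustering

`rankCandidates()` ranks candidates by descending score with
competition (minimum) ranks for ties and percentile rank/n.
`clusterTopCandidates()` clusters the imputed, z-standardized feature
rows of the top-ranked candidates (default the top 105, matching the
sum of the two subfamilies reported in the source study) with Ward
linkage on Euclidean distances, cut to `k = 2`. Metric, linkage, and
`nTop` are reimplementation choices — the source does not state them —
and all are configurable. Genes are processed in sorted order and
labels renumbered by decreasing cluster size, so the partition is
invariant to input order and to feature-column order.

## The synthetic-data generators

Because the assembled real feature tables and curated locus lists are
not redistributable, every pipeline stage is exercised on generated
data with the statistical structure the analysis assumes.

`generateFeatureTable()` draws a universe of genes (default 4,500, the
scale of the study's scoreable set) over a 22-feature spec mixing the
four kinds (14 standard-normal screens, one Poisson(1) concept count,
four Bernoulli(0.05) annotations, three normal(0, 0.3) effect sizes).
A latent positive class (default 200 genes, enough to supply a 45-gene
training set plus planted candidate positives) is drawn with
per-feature shifts: a mean shift in sd units for continuous features, a
probability increment for binary, a rate increment for counts. Missing
cells are masked completely at random at a per-feature rate (default
0.1). `generateLabelSets()` then draws training sets at the study
sizes (45 positives, 185 curated negatives, 1,362 candidates) with a
configurable planted fraction of latent positives among candidates
(floor rule: fraction 0.1 of 1,362 plants exactly 136).

What the generator does *not* emulate: structural missingness (real
missingness is per-source, not per-cell), correlated features, the
empirical marginal distributions of the real supplementary tables, or
gene-symbol realism. Passing tests therefore demonstrate that the
machinery is correct and recovers planted signal under MCAR
missingness and independent features — not that the real-data
headline values are reproduced.

`generateLocusScenario()` places lead SNPs uniformly over a synthetic
genome (22 round-length autosomes summing to 3.24 Gb, shipped as
`extdata/synthetic.chrom.sizes`; no build claim) and plants a
configurable fraction of query loci within 500 kb of a random lead.
One realism limitation matters for power analyses: real autoimmune
lead SNPs are heavily clustered, so at the study's raw count (4,076
leads) *uniform* placement nearly saturates the genome — 500 kb
windows cover about 72% of it — and a planted 48% overlap is almost
indistinguishable from the null. Power experiments therefore use a
sparser uniform lead set (about 300 leads, under 10% null coverage) as
the effective density; type-I-error experiments are unaffected by
density.

## Problem sizes and numerical choices

The package defaults keep the source protocol (10,000 models, 1,000
trees, 10,000 permutations). The test-suite and acceptance experiments
run the same code at desk scale — 100–200 models of 100 trees on the
4,500-gene universe, 200–10,000 permutations — sizes at which every
asserted property is already stable. Other numerical conventions:
probabilities are tree-vote fractions (no Platt/isotonic calibration);
competition ranks break score ties; the degenerate inputs rejected
with informative errors include constant features under
standardization, fewer than two observed values, all-missing features
under imputation, single-class label vectors under ROC, and sampling
pools smaller than the requested negative set.

## A worked example

```{r example, eval = FALSE}
spec <- withShiftedFeatures(defaultSyntheticSpec(),
                            sprintf("screen_%02d", 1:5), 2)
gen <- generateFeatureTable(featureGenParams(spec = spec, seed = 1))
ft <- imputeMissing(gen$features)
labels <- generateLabelSets(gen$latentPositive, seed = 2)

cfg <- ensembleConfig(nModels = 200, nTrees = 100, seed = 3)
fit <- fitPUEnsemble(ft, labels, cfg)
head(scoreTable(fit))
crossvalFixedNegatives(ft, positives(labels), curatedNegatives(labels), cfg)

ranked <- rankCandidates(fit, candidates(labels))
clusterTopCandidates(ft, ranked, nTop = 105, k = 2)

scen <- generateLocusScenario(locusGenParams(overlapFraction = 0.48,
                                             seed = 4))
permutationColocalizationTest(scen$query, scen$leads, syntheticGenome(),
                              nPermutations = 10000, seed = 5)
```

## Known limitations

* Calibration and power statements hold under the generator's
  assumptions (MCAR missingness, independent features, uniform lead
  placement); real evidence sources violate all three.
* The PU score is a relative ranking signal, not a calibrated
  probability of being a true target; the pseudo-negative pools contain
  unknown positives by construction, which deflates cross-validated
  AUCs (the motivation for the curated-negative scheme).
* With 45 positives, any single cross-validation estimate carries
  substantial draw-conditional variability; conclusions should rest on
  the ensemble averages, not a single split.
* No LD-aware distances, no SNP-level statistical colocalization, no
  network or enrichment analysis — cluster outputs are written so
  external tools can consume them.
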