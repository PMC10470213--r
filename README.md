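# ioTargets

Positive-unlabeled prioritization of immuno-oncology (I-O) therapeutic
targets among GWAS candidate genes.

## What problem this solves

Breast-cancer GWAS implicate over a thousand candidate genes through
linkage disequilibrium with risk loci, but say nothing about which of
them modify antitumor immunity — the well-powered cancer GWAS collect
no immune phenotypes. `ioTargets` is for computational geneticists who
want to *functionally fine-map* such loci: integrate heterogeneous gene
evidence (genetic-perturbation screens, Mendelian-disease concept
mining, mouse knockout and cancer-driver annotations, leukocyte eQTL
effect sizes) into a genes × features matrix, learn the evidence
profile of known I-O targets, and rank every candidate by how closely
it resembles that profile. A companion permutation test asks whether
the disease's risk loci colocalize with autoimmunity risk loci —
independent evidence that heritable immunity contributes to disease
risk.

## The model

Only a small positive set P of validated I-O targets is known;
everything else is unlabeled, not negative. The scorer handles this
positive-unlabeled problem with an easy-ensemble/bagging scheme. For
each model *i* = 1,…,M:

1. draw a pseudo-negative set Nᵢ with |Nᵢ| = |P| uniformly without
   replacement from the gene universe excluding P;
2. fit a random forest (T trees) on P vs Nᵢ over the p features;
3. record every gene's positive-class vote fraction p̂ᵢ(g).

The I-O target probability score is the ensemble mean
ŝ(g) = (1/M) Σᵢ p̂ᵢ(g), and feature importance is the across-model
mean decrease in Gini impurity. Defaults follow the source protocol
(M = 10,000, T = 1,000, mtry = ⌊√p⌋, genes with more than 6 missing
features omitted). Evaluation machinery includes ROC/AUC (Mann–Whitney
midranks), a per-model random-negative CV scheme and a fixed
curated-negative CV scheme, and an elastic-net logistic benchmark run
under the identical bagging protocol and negative-set seed schedule.
The colocalization module tests the number of risk loci within 500 kb
of another trait's lead SNPs against 10,000 uniform genome
permutations, with the add-one empirical p-value
(1 + #{null ≥ obs})/(1 + n_perm).

A synthetic-data module generates feature tables, label sets and locus
scenarios with controllable planted signal, so the whole pipeline is
testable without any data downloads.

## Worked example

Plant a 2-sd shift on 5 of 22 features in a latent positive class,
draw study-sized label sets (45 positives / 185 curated negatives /
1,362 candidates in a 4,500-gene universe), and run the pipeline:

```r
library(ioTargets)

spec <- withShiftedFeatures(defaultSyntheticSpec(),
                            sprintf("screen_%02d", 1:5), 2)
gen    <- generateFeatureTable(featureGenParams(spec = spec, seed = 1))
ft     <- imputeMissing(gen$features)
labels <- generateLabelSets(gen$latentPositive, seed = 2)

cfg <- ensembleConfig(nModels = 200, nTrees = 100, seed = 3)
fit <- fitPUEnsemble(ft, labels, cfg)
fit
#> PUEnsembleFit: 4500 genes scored over 200 random_forest models
#> top features: screen_01, screen_02, screen_03

crossvalFixedNegatives(ft, positives(labels), curatedNegatives(labels), cfg)
#> CVReport [fixed_negatives]: mean AUC = 0.984 (10 folds)

head(rankCandidates(fit, candidates(labels)), 3)
#>   gene_id   score rank   percentile
#> 1  g00330 0.95295    1 0.0007342144
#> 2  g01129 0.95095    2 0.0014684288
#> 3  g01942 0.94680    3 0.0022026432

scen <- generateLocusScenario(locusGenParams(overlapFraction = 0.48,
                                             seed = 4))
permutationColocalizationTest(scen$query, scen$leads, syntheticGenome(),
                              nPermutations = 10000, seed = 5)
#> ColocalizationResult: 133 loci (85.8%) within 500000 bp;
#>   empirical p = 0.0002 (10000 permutations)
```

Reading the output: the cross-validated AUC of 0.984 says the forest
separates the 45 training positives from the curated negatives almost
perfectly when 5 features carry a 2-sd shift; the five shifted screens
occupy the top five importance ranks; the top-ranked candidates (score
≈ 0.95, top 0.1% percentile) are planted latent positives; median
ensemble scores were 0.931 / 0.167 / 0.194 for the positive /
curated-negative / candidate sets. In the locus scenario, 133 of 155
loci fall within 500 kb of a lead SNP — the planted 48% plus chance
proximity from the dense uniform lead set — and no permutation class
reaches it often, giving an empirical p of 2 × 10⁻⁴.

The methods vignette
(`vignettes/pu-target-prioritization.Rmd`) documents the model, its
assumptions, every tunable parameter, and what the synthetic generators
do and do not emulate about real data.

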