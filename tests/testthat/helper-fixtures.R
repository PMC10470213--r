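# Shared in-code fixtures: all synthetic, generated at test time.

# Small strong-signal scenario: 5/22 continuous features shifted by 2 sd
# in the latent positive class.
makeSignalScenario <- function(nGenes = 300L, nLatentPositives = 60L,
                               missingRate = 0, seed = 7L,
                               shift = 2, nShifted = 5L) {
  spec <- withShiftedFeatures(defaultSyntheticSpec(),
                              sprintf("screen_%02d", seq_len(nShifted)),
                              shift)
  gen <- generateFeatureTable(featureGenParams(
    nGenes = nGenes, spec = spec, nLatentPositives = nLatentPositives,
    missingRate = missingRate, seed = seed))
  labels <- generateLabelSets(gen$latentPositive,
    sizes = c(positives = 20L, curatedNegatives = 40L, candidates = 100L),
    candidatePositiveFraction = 0.2, seed = seed + 1L)
  list(features = imputeMissing(gen$features),
       latent = gen$latentPositive, labels = labels, spec = spec)
}

# Independent O(n_pos * n_neg) pair-counting AUC oracle.
pairCountAuc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  wins <- 0
  for (p in pos) for (q in neg)
    wins <- wins + (p > q) + 0.5 * (p == q)
  wins / (length(pos) * length(neg))
}

# Independent double-loop proximity-count oracle over locus tables.
bruteForceProximal <- function(qChrom, qPos, lChrom, lPos, maxDistance) {
  count <- 0L
  for (i in seq_along(qPos)) {
    hit <- FALSE
    for (j in seq_along(lPos))
      if (qChrom[i] == lChrom[j] && abs(qPos[i] - lPos[j]) <= maxDistance)
        hit <- TRUE
    count <- count + hit
  }
  count
}

toyGenome10Mb <- function() genomeModel("chr1", 1e7)
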