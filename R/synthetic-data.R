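#' Default synthetic feature specification
#'
#' Twenty-two features emulating the structure of the study's evidence
#' matrix: 14 continuous z-scored screen scores (standard normal under
#' the null), one non-negative concept-count feature (Poisson), four
#' sparse binary annotations (Bernoulli), and three signed eQTL-style
#' effect sizes (normal with sub-unit sd). `shift` is the latent-positive
#' displacement: for continuous/effect-size features a mean shift in sd
#' units, for binary features a probability increment, for count features
#' a rate increment. All shifts default to 0 (null generator);
#' [withShiftedFeatures()] plants signal.
#'
#' @return data.frame with columns `name`, `kind`, `par1`, `par2`,
#'   `shift`.
#' @export
defaultSyntheticSpec <- function() {
  screens <- sprintf("screen_%02d", 1:14)
  data.frame(
    name = c(screens, "concept_hits",
             "mgi_immune", "mgi_brca", "cosmic_census", "nonessential",
             "eqtl_beta_1", "eqtl_beta_2", "eqtl_beta_3"),
    kind = c(rep("continuous_score", 14), "count_matrix",
             rep("binary_annotation", 4), rep("effect_size", 3)),
    par1 = c(rep(0, 14), 1.0, rep(0.05, 4), rep(0, 3)),
    par2 = c(rep(1, 14), NA, rep(NA, 4), rep(0.3, 3)),
    shift = 0,
    stringsAsFactors = FALSE)
}

#' @rdname defaultSyntheticSpec
#' @param spec a feature spec data.frame.
#' @param features names of features to shift.
#' @param shift displacement (see above for per-kind semantics).
#' @export
withShiftedFeatures <- function(spec, features, shift) {
  stopifnot(all(features %in% spec$name))
  spec$shift[spec$name %in% features] <- shift
  spec
}

#' Parameters of the synthetic feature generator
#'
#' @param nGenes genes in the universe (default 4500, matching the scale
#'   of the study's scoreable gene set).
#' @param spec feature spec, see [defaultSyntheticSpec()].
#' @param nLatentPositives genes carrying the latent I-O class (default
#'   200: enough to supply a 45-gene training positive set plus planted
#'   positives among 1,362 candidates).
#' @param missingRate per-feature missing-at-random cell probability,
#'   scalar or one per feature (default 0.1).
#' @param seed RNG seed.
#' @return a list of class `FeatureGenParams`.
#' @export
featureGenParams <- function(nGenes = 4500L, spec = defaultSyntheticSpec(),
                             nLatentPositives = 200L, missingRate = 0.1,
                             seed = 1L) {
  stopifnot(nGenes >= 2, nLatentPositives < nGenes,
            all(missingRate >= 0 & missingRate <= 1),
            all(spec$kind %in% .FEATURE_KINDS),
            !anyDuplicated(spec$name), all(is.finite(spec$shift)))
  structure(list(nGenes = as.integer(nGenes), spec = spec,
                 nLatentPositives = as.integer(nLatentPositives),
                 missingRate = rep_len(missingRate, nrow(spec)),
                 seed = as.integer(seed)),
            class = "FeatureGenParams")
}

#' Generate a synthetic feature table with a latent I-O class
#'
#' Background genes are drawn from the null distributions of the spec
#' (continuous/effect-size: normal; binary: Bernoulli; count: Poisson);
#' latent positives are drawn with the per-feature shifts. Cells are then
#' masked missing-at-random at the per-feature rate, independently of the
#' latent class. Fully seed-reproducible.
#'
#' @param params a [featureGenParams()] object.
#' @return list with `features` (a [FeatureTable-class]) and
#'   `latentPositive` (named logical over genes).
#' @export
generateFeatureTable <- function(params) {
  stopifnot(inherits(params, "FeatureGenParams"))
  set.seed(params$seed)
  n <- params$nGenes
  genes <- sprintf("g%05d", seq_len(n))
  latent <- stats::setNames(logical(n), genes)
  latent[sample(n, params$nLatentPositives)] <- TRUE
  spec <- params$spec
  vals <- matrix(NA_real_, n, nrow(spec), dimnames = list(genes, spec$name))
  for (j in seq_len(nrow(spec))) {
    kind <- spec$kind[j]; p1 <- spec$par1[j]; p2 <- spec$par2[j]
    sh <- spec$shift[j]
    vals[, j] <- switch(kind,
      continuous_score = ,
      effect_size = stats::rnorm(n, mean = p1 + ifelse(latent, sh * p2, 0),
                                 sd = p2),
      binary_annotation = stats::rbinom(n, 1,
        prob = pmin(1, p1 + ifelse(latent, sh, 0))),
      count_matrix = stats::rpois(n, lambda = p1 + ifelse(latent, sh, 0)))
  }
  miss <- matrix(FALSE, n, nrow(spec), dimnames = dimnames(vals))
  for (j in seq_len(nrow(spec)))
    if (params$missingRate[j] > 0)
      miss[, j] <- stats::runif(n) < params$missingRate[j]
  vals[miss] <- NA_real_
  list(features = featureTable(vals, kinds = spec$kind, missing = miss),
       latentPositive = latent)
}

#' Draw label sets from the latent classes
#'
#' Samples the positive training set from the latent positives, the
#' curated negative set from the latent negatives, and a candidate set
#' containing `floor(candidatePositiveFraction * nCandidates)` planted
#' latent positives (the floor rule), the remainder latent negatives.
#' Candidates are disjoint from the training positives and curated
#' negatives. Default sizes mirror the study: 45 / 185 / 1,362.
#'
#' @param latentPositive named logical from [generateFeatureTable()].
#' @param sizes named integer vector with `positives`,
#'   `curatedNegatives`, `candidates`.
#' @param candidatePositiveFraction share of candidates that are latent
#'   positives (default 0.1).
#' @param seed RNG seed.
#' @param provenance free-text note stored on the result.
#' @return a [LabelSets-class].
#' @export
generateLabelSets <- function(latentPositive,
                              sizes = c(positives = 45L,
                                        curatedNegatives = 185L,
                                        candidates = 1362L),
                              candidatePositiveFraction = 0.1,
                              seed = 1L,
                              provenance = "synthetic latent classes") {
  stopifnot(candidatePositiveFraction >= 0, candidatePositiveFraction <= 1)
  set.seed(seed)
  posPool <- names(latentPositive)[latentPositive]
  negPool <- names(latentPositive)[!latentPositive]
  nCandPos <- floor(candidatePositiveFraction * sizes[["candidates"]])
  if (length(posPool) < sizes[["positives"]] + nCandPos)
    stop("generateLabelSets: too few latent positives")
  pos <- sample(posPool, sizes[["positives"]])
  neg <- sample(negPool, sizes[["curatedNegatives"]])
  candPosPool <- setdiff(posPool, pos)
  candNegPool <- setdiff(negPool, neg)
  nCandNeg <- sizes[["candidates"]] - nCandPos
  if (length(candNegPool) < nCandNeg)
    stop("generateLabelSets: too few latent negatives")
  cand <- c(if (nCandPos) sample(candPosPool, nCandPos),
            sample(candNegPool, nCandNeg))
  labelSets(positives = pos, universe = names(latentPositive),
            curatedNegatives = neg, candidates = cand,
            provenance = provenance)
}

#' Synthetic genome for locus scenarios
#'
#' Twenty-two synthetic autosomes with round lengths summing to ~3.2 Gb
#' (no genome-build claim); shipped also as
#' `extdata/synthetic.chrom.sizes`.
#'
#' @return a [genomeModel()] `Seqinfo`.
#' @export
syntheticGenome <- function() {
  mb <- c(240, 235, 225, 215, 205, 195, 185, 175, 165, 155, 150, 140,
          130, 120, 110, 100, 95, 90, 85, 80, 75, 70)
  genomeModel(paste0("chr", seq_along(mb)), mb * 1e6)
}

#' Parameters of the synthetic locus-scenario generator
#'
#' @param genome a [genomeModel()] `Seqinfo` (default [syntheticGenome()]).
#' @param nQuery number of query-trait loci (default 155, the study's
#'   BrCa locus count).
#' @param nLeads number of other-trait lead SNPs (default 4076, the
#'   study's autoimmune locus count).
#' @param overlapFraction share of query loci planted within
#'   `maxDistance` of a lead SNP (default 0, i.e. a null scenario).
#' @param maxDistance bp (default 500000).
#' @param seed RNG seed.
#' @return a list of class `LocusGenParams`.
#' @export
locusGenParams <- function(genome = syntheticGenome(), nQuery = 155L,
                           nLeads = 4076L, overlapFraction = 0,
                           maxDistance = 500000, seed = 1L) {
  stopifnot(overlapFraction >= 0, overlapFraction <= 1,
            nQuery >= 1, nLeads >= 0)
  structure(list(genome = genome, nQuery = as.integer(nQuery),
                 nLeads = as.integer(nLeads),
                 overlapFraction = overlapFraction,
                 maxDistance = maxDistance, seed = as.integer(seed)),
            class = "LocusGenParams")
}

#' Generate a two-trait locus scenario with controllable true overlap
#'
#' Lead SNPs of the other trait are placed uniformly over the genome. A
#' `floor(overlapFraction * nQuery)` share of query loci is planted
#' uniformly within +/- `maxDistance` of a randomly chosen lead (clipped
#' to chromosome bounds); the remaining query loci are uniform. Unplanted
#' loci may still fall near a lead by chance; the ground-truth planted
#' flag is returned in `mcols(query)$planted`.
#'
#' @param params a [locusGenParams()] object.
#' @return list with `query` and `leads`, both [locusSet()] `GRanges`.
#' @export
generateLocusScenario <- function(params) {
  stopifnot(inherits(params, "LocusGenParams"))
  set.seed(params$seed)
  g <- params$genome
  ai <- .uniformPlacements(params$nLeads, g)
  leads <- locusSet(sprintf("lead%05d", seq_len(params$nLeads)),
                    ai$chrom, ai$pos, g)
  nPlanted <- floor(params$overlapFraction * params$nQuery)
  if (nPlanted > 0 && params$nLeads == 0)
    stop("generateLocusScenario: cannot plant overlap without leads")
  chrom <- character(params$nQuery)
  pos <- numeric(params$nQuery)
  if (nPlanted > 0) {
    anchor <- sample(params$nLeads, nPlanted, replace = TRUE)
    off <- round(stats::runif(nPlanted, -params$maxDistance,
                              params$maxDistance))
    chrom[seq_len(nPlanted)] <- ai$chrom[anchor]
    lens <- seqlengths(g)[ai$chrom[anchor]]
    pos[seq_len(nPlanted)] <- pmin(pmax(ai$pos[anchor] + off, 1), lens)
  }
  nFree <- params$nQuery - nPlanted
  if (nFree > 0) {
    u <- .uniformPlacements(nFree, g)
    chrom[nPlanted + seq_len(nFree)] <- u$chrom
    pos[nPlanted + seq_len(nFree)] <- u$pos
  }
  query <- locusSet(sprintf("locus%04d", seq_len(params$nQuery)),
                    chrom, pos, g)
  query$planted <- seq_len(params$nQuery) <= nPlanted
  list(query = query, leads = leads)
}
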