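#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData
NULL

#' FeatureTable: a genes x features evidence matrix with missingness mask
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding
#' two assays over genes (rows) and features (columns): `"values"`, the
#' numeric evidence grid, and `"missing"`, a logical mask that is `TRUE`
#' where no source reported the gene. `colData` carries a per-feature
#' `kind` tag, one of `"continuous_score"`, `"binary_annotation"`,
#' `"count_matrix"`, `"effect_size"`. Cells flagged missing may be `NA`
#' (pre-imputation) or carry an imputed value (post-imputation, mask
#' retained as provenance); cells outside the mask must be non-`NA`.
#'
#' @slot .. inherits all SummarizedExperiment slots.
#' @seealso [featureTable()], [imputeMissing()], [filterForPrediction()]
#' @export
setClass("FeatureTable", contains = "SummarizedExperiment")

.FEATURE_KINDS <- c("continuous_score", "binary_annotation",
                    "count_matrix", "effect_size")

setValidity("FeatureTable", function(object) {
  msg <- NULL
  if (!all(c("values", "missing") %in% names(assays(object))))
    msg <- c(msg, "assays must contain 'values' and 'missing'")
  else {
    v <- assay(object, "values")
    m <- assay(object, "missing")
    if (!is.logical(m)) msg <- c(msg, "'missing' assay must be logical")
    else if (any(is.na(v) & !m))
      msg <- c(msg, "NA values found outside the missing mask")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene ids (rownames) must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "feature names (colnames) must be present and unique")
  if (!"kind" %in% names(colData(object)))
    msg <- c(msg, "colData must carry a 'kind' column")
  else if (!all(colData(object)$kind %in% .FEATURE_KINDS))
    msg <- c(msg, sprintf("feature kinds must be one of: %s",
                          paste(.FEATURE_KINDS, collapse = ", ")))
  if (is.null(msg)) TRUE else msg
})

#' LabelSets: positive / curated-negative / candidate gene sets
#'
#' Gene-identifier sets defining the positive-unlabeled learning problem:
#' a positive training set (known I-O targets; study size 45), an optional
#' curated negative set (study size 185), the candidate genes to be scored
#' (study size 1,362), and the full scoreable universe. Positives and
#' curated negatives must be disjoint and all sets contained in the
#' universe.
#'
#' @slot positives character, positive training gene ids.
#' @slot curatedNegatives character, curated negative gene ids.
#' @slot candidates character, candidate gene ids to be ranked.
#' @slot universe character, all scoreable gene ids.
#' @slot provenance character, free-text origin metadata.
#' @export
setClass("LabelSets",
  representation(positives = "character", curatedNegatives = "character",
                 candidates = "character", universe = "character",
                 provenance = "character"))

setValidity("LabelSets", function(object) {
  msg <- NULL
  if (anyDuplicated(object@universe)) msg <- c(msg, "universe ids not unique")
  if (length(intersect(object@positives, object@curatedNegatives)))
    msg <- c(msg, "positives and curated negatives overlap")
  for (nm in c("positives", "curatedNegatives", "candidates")) {
    s <- slot(object, nm)
    if (anyDuplicated(s)) msg <- c(msg, sprintf("%s ids not unique", nm))
    if (!all(s %in% object@universe))
      msg <- c(msg, sprintf("%s not contained in universe", nm))
  }
  if (is.null(msg)) TRUE else msg
})

#' EnsembleConfig: hyperparameters of the PU bagging ensemble
#'
#' Defaults follow the study protocol: 10,000 models of 1,000 trees each,
#' genes with more than 6 missing features omitted from predictions, and
#' split-count (mtry) tuning disabled in favour of the floor(sqrt(p))
#' convention. `stepFactor`/`improve` parameterize the optional
#' out-of-bag grid walk for mtry.
#'
#' @slot nModels integer, number of bagged models.
#' @slot nTrees integer, trees per random forest.
#' @slot tune logical, enable OOB mtry tuning.
#' @slot stepFactor numeric, multiplicative step of the mtry walk.
#' @slot improve numeric, relative OOB improvement required to accept a step.
#' @slot maxMissing integer, missing-feature omission threshold.
#' @slot baseLearner character, "random_forest" or "elastic_net_logistic".
#' @slot seed integer, master seed of the model-indexed RNG streams.
#' @slot enAlpha numeric, elastic-net alpha candidates (benchmark only).
#' @slot enLambda numeric, elastic-net lambda candidates (benchmark only).
#' @export
setClass("EnsembleConfig",
  representation(nModels = "integer", nTrees = "integer", tune = "logical",
                 stepFactor = "numeric", improve = "numeric",
                 maxMissing = "integer", baseLearner = "character",
                 seed = "integer", enAlpha = "numeric", enLambda = "numeric"))

setValidity("EnsembleConfig", function(object) {
  msg <- NULL
  if (object@nModels < 1L) msg <- c(msg, "nModels must be >= 1")
  if (object@nTrees < 1L) msg <- c(msg, "nTrees must be >= 1")
  if (object@improve < 0) msg <- c(msg, "improve must be >= 0")
  if (object@maxMissing < 0L) msg <- c(msg, "maxMissing must be >= 0")
  if (!object@baseLearner %in% c("random_forest", "elastic_net_logistic"))
    msg <- c(msg, "unknown base learner")
  if (is.null(msg)) TRUE else msg
})

#' PUEnsembleFit: result of a bagged positive-unlabeled ensemble run
#'
#' @slot scoreTable `DataFrame` with columns `gene_id`, `score` (mean
#'   positive-class probability across models), `n_models_used`,
#'   `set_membership`.
#' @slot importance `DataFrame` with `feature`, `mean_gini_decrease`,
#'   `rank` (for the elastic-net learner, mean absolute standardized
#'   coefficient instead of Gini).
#' @slot voteSum numeric, accumulated positive votes (or probability sums)
#'   per gene; exact integer counts for the forest learner so that
#'   half-ensembles combine bit-identically via [combinePUEnsembles()].
#' @slot importanceSum numeric, accumulated per-feature importance.
#' @slot nModels integer, models accumulated.
#' @slot config the [EnsembleConfig-class] used.
#' @slot modelIndices integer, which model indices of the seed schedule ran.
#' @export
setClass("PUEnsembleFit",
  representation(scoreTable = "DataFrame", importance = "DataFrame",
                 voteSum = "numeric", importanceSum = "numeric",
                 nModels = "integer", config = "EnsembleConfig",
                 modelIndices = "integer"))

setMethod("show", "FeatureTable", function(object) {
  v <- assay(object, "values")
  m <- assay(object, "missing")
  cat(sprintf("FeatureTable: %d genes x %d features (%.1f%% missing%s)\n",
              nrow(object), ncol(object), 100 * mean(m),
              if (anyNA(v)) "" else ", imputed/complete"))
  cat("kinds:", paste(sprintf("%s(%d)",
      names(table(colData(object)$kind)), table(colData(object)$kind)),
      collapse = " "), "\n")
})

setMethod("show", "LabelSets", function(object) {
  cat(sprintf(paste0("LabelSets: %d positives, %d curated negatives, ",
                     "%d candidates, universe %d\n"),
              length(object@positives), length(object@curatedNegatives),
              length(object@candidates), length(object@universe)))
  if (length(object@provenance) && nzchar(object@provenance[1]))
    cat("provenance:", object@provenance[1], "\n")
})

setMethod("show", "EnsembleConfig", function(object) {
  cat(sprintf(paste0("EnsembleConfig: %d models x %d trees, learner %s, ",
                     "maxMissing %d, seed %d, tune %s\n"),
              object@nModels, object@nTrees, object@baseLearner,
              object@maxMissing, object@seed, object@tune))
})

setMethod("show", "PUEnsembleFit", function(object) {
  cat(sprintf("PUEnsembleFit: %d genes scored over %d %s models\n",
              nrow(object@scoreTable), object@nModels,
              object@config@baseLearner))
  top <- utils::head(object@importance, 3)
  cat("top features:", paste(top$feature, collapse = ", "), "\n")
})
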