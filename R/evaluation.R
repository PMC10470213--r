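#' ROC curve and AUC
#'
#' Computes the ROC curve and its area for a score vector against binary
#' labels. The AUC equals the Mann-Whitney pair statistic
#' P(score_pos > score_neg) + 0.5 P(tie), computed via midranks; the
#' returned curve starts at (0,0), ends at (1,1), and its trapezoidal
#' integral agrees with the AUC to float tolerance.
#'
#' @param scores numeric vector.
#' @param labels logical or 0/1 vector, TRUE/1 = positive.
#' @return a list of class `ROCResult`: `auc`, `curve` (data.frame with
#'   `fpr`, `tpr`), `n_pos`, `n_neg`.
#' @examples
#' computeRocAuc(c(.9, .4, .5, .1), c(1, 1, 0, 0))$auc  # 0.75
#' @export
computeRocAuc <- function(scores, labels) {
  pos <- as.logical(labels)
  stopifnot(length(scores) == length(pos), !anyNA(scores), !anyNA(pos))
  nPos <- sum(pos); nNeg <- sum(!pos)
  if (nPos == 0L || nNeg == 0L)
    stop("computeRocAuc: need at least one positive and one negative")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  # curve over descending unique thresholds
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- !duplicated(grp, fromLast = TRUE)
  curve <- data.frame(fpr = c(0, fp[last] / nNeg),
                      tpr = c(0, tp[last] / nPos))
  structure(list(auc = auc, curve = curve, n_pos = nPos, n_neg = nNeg),
            class = "ROCResult")
}

#' @export
print.ROCResult <- function(x, ...) {
  cat(sprintf("ROCResult: AUC = %.4f (%d pos / %d neg)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

# Positive-class probabilities for xTest from a model trained on
# (xTrain, yTrain) with the configured base learner.
.predictProb <- function(xTrain, yTrain, xTest, config, fitSeed) {
  fit <- .fitBaseModel(xTrain, yTrain, xTest, config, fitSeed)
  if (config@baseLearner == "random_forest") fit$votes / config@nTrees
  else fit$votes
}

# One stratified k-fold CV on labeled genes; returns pooled out-of-fold
# probabilities (and fold ids).
.cvPredict <- function(X, ids, y, config, nFolds, foldSeed, fitSeed) {
  set.seed(foldSeed)
  folds <- .stratifiedFolds(y, nFolds)
  prob <- numeric(length(ids))
  for (f in seq_len(nFolds)) {
    te <- folds == f
    prob[te] <- .predictProb(X[ids[!te], , drop = FALSE], y[!te],
                             X[ids[te], , drop = FALSE], config,
                             fitSeed + f)
  }
  list(prob = prob, folds = folds)
}

#' Cross-validation with per-model random negative sets
#'
#' For each of `nModels` model indices, draws the same size-matched
#' pseudo-negative set the ensemble's seed schedule would draw, runs a
#' stratified k-fold CV on the positives vs that set, computes the AUC
#' from pooled held-out predictions, and reports the mean AUC across
#' models (the study reports 0.71 under this scheme on its real inputs).
#'
#' @param features complete [FeatureTable-class].
#' @param labels a [LabelSets-class].
#' @param config an [EnsembleConfig-class].
#' @param nModels models to average over (default `config@nModels`).
#' @param nFolds folds (default 10).
#' @return a list of class `CVReport`: `scheme`, `mean_auc`,
#'   `per_model_auc`, `n_folds`, `seed`.
#' @export
crossvalRandomNegatives <- function(features, labels,
                                    config = ensembleConfig(),
                                    nModels = config@nModels, nFolds = 10L) {
  stopifnot(isComplete(features))
  X <- featureValues(features)
  pos <- positives(labels)
  if (length(pos) < nFolds)
    stop("crossvalRandomNegatives: fewer positives than folds")
  pool <- intersect(universe(labels), rownames(X))
  aucs <- numeric(nModels)
  for (i in seq_len(nModels)) {
    neg <- sampleNegativeSet(pool, pos, length(pos),
                             seed = modelSeed(config@seed, i, 0L))
    ids <- c(pos, neg)
    y <- factor(rep(c("pos", "neg"), c(length(pos), length(neg))),
                levels = c("neg", "pos"))
    cv <- .cvPredict(X, ids, y, config, nFolds,
                     foldSeed = modelSeed(config@seed, i, 2L),
                     fitSeed = modelSeed(config@seed, i, 1L))
    aucs[i] <- computeRocAuc(cv$prob, y == "pos")$auc
  }
  structure(list(scheme = "random_negatives_avg", mean_auc = mean(aucs),
                 per_model_auc = aucs, n_folds = as.integer(nFolds),
                 seed = config@seed), class = "CVReport")
}

#' Cross-validation with the fixed curated negative set
#'
#' A single stratified k-fold CV (default 10-fold; leave-one-out
#' selectable) on the imbalanced positives-vs-curated-negatives problem,
#' with the AUC computed from pooled held-out predictions (the study
#' reports 0.79 under this scheme on its real inputs).
#'
#' @param features complete [FeatureTable-class].
#' @param positives,curatedNegatives disjoint gene-id vectors, each
#'   present in `features`.
#' @param config an [EnsembleConfig-class].
#' @param nFolds folds (default 10); ignored when `loo = TRUE`.
#' @param loo leave-one-out instead of k-fold.
#' @return a `CVReport` with `scheme = "fixed_negatives"`, `mean_auc`
#'   (the pooled AUC), and `per_fold_auc` when folds retain both classes.
#' @export
crossvalFixedNegatives <- function(features, positives, curatedNegatives,
                                   config = ensembleConfig(), nFolds = 10L,
                                   loo = FALSE) {
  stopifnot(isComplete(features))
  if (length(intersect(positives, curatedNegatives)))
    stop("crossvalFixedNegatives: positive and negative sets overlap")
  X <- featureValues(features)
  ids <- c(positives, curatedNegatives)
  if (!all(ids %in% rownames(X)))
    stop("crossvalFixedNegatives: labeled genes missing from features")
  y <- factor(rep(c("pos", "neg"),
                  c(length(positives), length(curatedNegatives))),
              levels = c("neg", "pos"))
  if (loo) {
    prob <- numeric(length(ids))
    for (k in seq_along(ids))
      prob[k] <- .predictProb(X[ids[-k], , drop = FALSE], y[-k],
                              X[ids[k], , drop = FALSE], config,
                              modelSeed(config@seed, k, 1L))
    folds <- seq_along(ids)
    nFolds <- length(ids)
  } else {
    if (min(table(y)) < nFolds)
      stop("crossvalFixedNegatives: too few genes per class for ", nFolds,
           " stratified folds")
    cv <- .cvPredict(X, ids, y, config, nFolds,
                     foldSeed = modelSeed(config@seed, 0L, 2L),
                     fitSeed = modelSeed(config@seed, 0L, 1L))
    prob <- cv$prob; folds <- cv$folds
  }
  perFold <- if (!loo)
    vapply(seq_len(nFolds), function(f) {
      te <- folds == f
      if (length(unique(y[te])) < 2L) NA_real_
      else computeRocAuc(prob[te], y[te] == "pos")$auc
    }, numeric(1)) else NULL
  structure(list(scheme = "fixed_negatives",
                 mean_auc = computeRocAuc(prob, y == "pos")$auc,
                 per_fold_auc = perFold, pooled_prob = prob,
                 labels = y == "pos", n_folds = as.integer(nFolds),
                 loo = loo, seed = config@seed), class = "CVReport")
}

#' @export
print.CVReport <- function(x, ...) {
  cat(sprintf("CVReport [%s]: mean AUC = %.3f (%d folds)\n",
              x$scheme, x$mean_auc, x$n_folds))
  invisible(x)
}

#' Elastic-net logistic benchmark under the identical bagging protocol
#'
#' Runs [fitPUEnsemble()] with penalized logistic regression as the base
#' learner: the same model-indexed seed schedule (hence the same
#' size-matched negative sets as the forest ensemble under the same
#' config seed), per-model (alpha, lambda) chosen from the config grids
#' by 10-fold CV accuracy at the 0.5 threshold, and predicted
#' probabilities averaged across models.
#'
#' @inheritParams fitPUEnsemble
#' @return a [PUEnsembleFit-class].
#' @export
fitElasticNetEnsemble <- function(features, labels,
                                  config = ensembleConfig(),
                                  modelIndices = seq_len(config@nModels)) {
  if (!length(config@enAlpha) || !length(config@enLambda))
    stop("fitElasticNetEnsemble: empty tuning grid")
  config@baseLearner <- "elastic_net_logistic"
  fitPUEnsemble(features, labels, config, modelIndices)
}

.asScoreVector <- function(x) {
  if (is(x, "PUEnsembleFit")) x <- scoreTable(x)
  if (is(x, "DataFrame") || is.data.frame(x))
    return(stats::setNames(as.numeric(x$score), x$gene_id))
  stopifnot(is.numeric(x), !is.null(names(x)))
  x
}

#' Compare two score vectors by Pearson correlation
#'
#' Pearson's r over the gene intersection of two score tables, with the
#' two-sided p-value from the exact t-distribution transform of r on
#' n - 2 degrees of freedom.
#'
#' @param a,b [PUEnsembleFit-class] objects, score tables, or named
#'   numeric vectors.
#' @return a list of class `ComparisonResult`: `pearson_r`, `p_value`, `n`.
#' @export
compareScoreVectors <- function(a, b) {
  va <- .asScoreVector(a); vb <- .asScoreVector(b)
  shared <- intersect(names(va), names(vb))
  if (length(shared) < 3L)
    stop("compareScoreVectors: fewer than 3 shared genes")
  va <- va[shared]; vb <- vb[shared]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("compareScoreVectors: constant score vector")
  ct <- stats::cor.test(va, vb, method = "pearson")
  structure(list(pearson_r = unname(ct$estimate),
                 p_value = ct$p.value, n = length(shared)),
            class = "ComparisonResult")
}

#' @export
print.ComparisonResult <- function(x, ...) {
  cat(sprintf("ComparisonResult: r = %.3f, p = %.3g, n = %d\n",
              x$pearson_r, x$p_value, x$n))
  invisible(x)
}
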