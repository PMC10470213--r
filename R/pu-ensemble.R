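#' Ensemble configuration
#'
#' Builds an [EnsembleConfig-class] with the study-protocol defaults:
#' 10,000 bagged models of 1,000 trees, the >6-missing-features omission
#' rule, split-count tuning off (mtry = floor(sqrt(p))). `seed` is the
#' master seed from which every model's negative-sampling and fitting
#' streams are derived, keyed to the model index so that changing
#' `nModels` never reshuffles earlier models.
#'
#' @param nModels number of bagged models (default 10000).
#' @param nTrees trees per forest (default 1000).
#' @param tune enable out-of-bag mtry tuning (default FALSE).
#' @param stepFactor multiplicative step of the mtry walk (default 2; the
#'   literal 0.01 of tuneRF-style configuration is accepted but collapses
#'   the walk onto the candidate bounds).
#' @param improve relative OOB-error improvement required to accept a
#'   tuning step (default 0.01).
#' @param maxMissing missing-feature omission threshold (default 6).
#' @param baseLearner `"random_forest"` or `"elastic_net_logistic"`.
#' @param seed master seed (integer).
#' @param enAlpha,enLambda elastic-net tuning grids (benchmark learner).
#' @return an `EnsembleConfig`.
#' @export
ensembleConfig <- function(nModels = 10000L, nTrees = 1000L, tune = FALSE,
                           stepFactor = 2, improve = 0.01, maxMissing = 6L,
                           baseLearner = c("random_forest",
                                           "elastic_net_logistic"),
                           seed = 1L,
                           enAlpha = c(0.1, 0.5, 0.9),
                           enLambda = 10^seq(-3, 0, length.out = 5)) {
  new("EnsembleConfig", nModels = as.integer(nModels),
      nTrees = as.integer(nTrees), tune = tune,
      stepFactor = stepFactor, improve = improve,
      maxMissing = as.integer(maxMissing),
      baseLearner = match.arg(baseLearner), seed = as.integer(seed),
      enAlpha = as.numeric(enAlpha),
      enLambda = sort(as.numeric(enLambda), decreasing = TRUE))
}

# Deterministic 31-bit per-model seed; separate streams for negative
# sampling (0), model fitting (1) and fold shuffling (2). All terms stay
# below 2^53 so double arithmetic is exact.
modelSeed <- function(master, index, stream = 0L) {
  s <- (abs(as.double(master)) * 1009 + as.double(index) * 2654435 +
          as.double(stream) * 40503583) %% 2147483629
  as.integer(s + 1)
}

#' Sample a size-matched pseudo-negative gene set
#'
#' Draws `size` genes without replacement from `universe` after excluding
#' `exclude` (the positive training set). This is the negative-set
#' resampling at the heart of the easy-ensemble/bagging scheme: candidates
#' and curated negatives may be drawn as pseudo-negatives.
#'
#' @param universe character, the sampling pool before exclusion.
#' @param exclude character, ids never drawn (the positive set).
#' @param size number of genes to draw.
#' @param seed integer seed making the draw reproducible.
#' @return character vector of `size` distinct gene ids.
#' @export
sampleNegativeSet <- function(universe, exclude, size, seed) {
  pool <- setdiff(universe, exclude)
  if (length(pool) < size)
    stop("sampleNegativeSet: insufficient pool (", length(pool),
         " genes) for size ", size)
  set.seed(seed)
  sample(pool, size)
}

#' Tune the per-split feature count (mtry) by out-of-bag error
#'
#' Starting from floor(sqrt(p)), walks the candidate split count up and
#' down multiplicatively by `stepFactor`, accepting a move only when the
#' out-of-bag error improves by more than `improve` (relative). Bounded in
#' [1, p]; returns the starting value when no move improves or when
#' tuning is disabled in the config.
#'
#' @param x numeric feature matrix (training rows).
#' @param y two-level factor of labels.
#' @param config an [EnsembleConfig-class]; `tune`, `stepFactor`,
#'   `improve` and `nTrees` are used.
#' @param seed RNG seed for the OOB evaluations.
#' @return integer mtry in [1, ncol(x)].
#' @export
tuneSplitCount <- function(x, y, config = ensembleConfig(), seed = 1L) {
  p <- ncol(x)
  m0 <- as.integer(max(1, min(p, floor(sqrt(p)))))
  if (p <= 1L || !config@tune) return(m0)
  oob <- function(m) {
    set.seed(seed)
    rf <- randomForest::randomForest(x, y, ntree = config@nTrees, mtry = m)
    rf$err.rate[config@nTrees, "OOB"]
  }
  best <- m0; bestErr <- oob(m0)
  for (dir in c(1, -1)) {
    m <- best; err <- bestErr
    repeat {
      mNext <- if (dir > 0) min(p, as.integer(ceiling(m * config@stepFactor)))
               else max(1L, as.integer(floor(m / config@stepFactor)))
      if (mNext == m) break
      errNext <- oob(mNext)
      if (err == 0 || (err - errNext) / err <= config@improve) break
      m <- mNext; err <- errNext
      if (err < bestErr) { best <- m; bestErr <- err }
    }
  }
  as.integer(best)
}

# Fit one base model on (xTrain, yTrain) and return positive-class
# probabilities for xPredict plus a feature-importance vector. For the
# forest learner `prob` is returned as raw positive tree votes (integers)
# so ensemble sums stay exact; divide by nTrees for probabilities.
.fitBaseModel <- function(xTrain, yTrain, xPredict, config, fitSeed) {
  if (config@baseLearner == "random_forest") {
    mtry <- tuneSplitCount(xTrain, yTrain, config, seed = fitSeed)
    set.seed(fitSeed)
    rf <- randomForest::randomForest(xTrain, yTrain, ntree = config@nTrees,
                                     mtry = mtry, importance = FALSE)
    votes <- stats::predict(rf, xPredict, type = "vote", norm.votes = FALSE)
    list(votes = votes[, "pos"], importance = rf$importance[, "MeanDecreaseGini"])
  } else {
    set.seed(fitSeed)
    tuned <- .tuneElasticNet(xTrain, yTrain, config@enAlpha, config@enLambda)
    fit <- glmnet::glmnet(xTrain, yTrain, family = "binomial",
                          alpha = tuned$alpha, lambda = config@enLambda)
    prob <- stats::predict(fit, xPredict, s = tuned$lambda,
                           type = "response")[, 1]
    beta <- as.numeric(stats::coef(fit, s = tuned$lambda))[-1]
    sds <- apply(xTrain, 2, stats::sd)
    list(votes = prob,
         importance = stats::setNames(abs(beta) * sds, colnames(xTrain)))
  }
}

# Pick (alpha, lambda) maximizing 10-fold CV accuracy at the 0.5
# probability threshold; ties resolved toward the first alpha and the
# larger (more regularized) lambda.
.tuneElasticNet <- function(x, y, alphaGrid, lambdaGrid, nFolds = 10L) {
  n <- nrow(x)
  nFolds <- min(nFolds, min(table(y)))
  folds <- .stratifiedFolds(y, nFolds)
  best <- list(alpha = alphaGrid[1], lambda = lambdaGrid[1], acc = -Inf)
  for (a in alphaGrid) {
    correct <- numeric(length(lambdaGrid))
    for (f in seq_len(nFolds)) {
      te <- folds == f
      fit <- glmnet::glmnet(x[!te, , drop = FALSE], y[!te],
                            family = "binomial", alpha = a,
                            lambda = lambdaGrid)
      pr <- stats::predict(fit, x[te, , drop = FALSE], type = "response")
      # pad: glmnet may return fewer lambdas than requested
      for (j in seq_along(lambdaGrid)) {
        jj <- min(j, ncol(pr))
        correct[j] <- correct[j] +
          sum((pr[, jj] > 0.5) == (y[te] == "pos"))
      }
    }
    acc <- correct / n
    j <- which.max(acc)
    if (acc[j] > best$acc)
      best <- list(alpha = a, lambda = lambdaGrid[j], acc = acc[j])
  }
  best
}

# Stratified fold ids (1..nFolds) for a two-level factor, using the
# current RNG state for the within-class shuffles.
.stratifiedFolds <- function(y, nFolds) {
  folds <- integer(length(y))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    folds[idx] <- sample(rep_len(seq_len(nFolds), length(idx)))
  }
  folds
}

#' Fit the positive-unlabeled bagged ensemble
#'
#' The easy-ensemble/bagging scorer: for each model index, a fresh
#' size-matched pseudo-negative set is drawn from the universe excluding
#' the positives, one base model (random forest by default) is fit on
#' positives vs that set, and positive-class probabilities are recorded
#' for every gene of the feature table. The I-O target probability score
#' is the arithmetic mean of these probabilities across models, and
#' feature importance the arithmetic mean of per-model mean-decrease-Gini
#' vectors. The run is reproducible bit-for-bit under the config seed.
#'
#' Scores of training positives are in-bag (not cross-validated) and are
#' therefore optimistic; use the cross-validation schemes to assess
#' generalization.
#'
#' @param features a complete [FeatureTable-class] (run [imputeMissing()]
#'   first; genes failing the missingness rule should already be omitted
#'   via [filterForPrediction()]).
#' @param labels a [LabelSets-class]; positives must be rows of
#'   `features`.
#' @param config an [EnsembleConfig-class].
#' @param modelIndices which model indices of the seed schedule to run
#'   (default `1:nModels`); two disjoint runs can be merged exactly with
#'   [combinePUEnsembles()].
#' @param keepModelLog if TRUE, store per-model negative sets.
#' @return a [PUEnsembleFit-class]; see [scoreTable()] and
#'   [importanceTable()].
#' @export
fitPUEnsemble <- function(features, labels, config = ensembleConfig(),
                          modelIndices = seq_len(config@nModels),
                          keepModelLog = FALSE) {
  stopifnot(is(features, "FeatureTable"), is(labels, "LabelSets"))
  if (!isComplete(features))
    stop("fitPUEnsemble: features contain missing values; impute first")
  X <- featureValues(features)
  pos <- positives(labels)
  if (!length(pos)) stop("fitPUEnsemble: empty positive set")
  if (!all(pos %in% rownames(X)))
    stop("fitPUEnsemble: positives missing from the feature table")
  pool <- intersect(universe(labels), rownames(X))
  voteSum <- stats::setNames(numeric(nrow(X)), rownames(X))
  impSum <- stats::setNames(numeric(ncol(X)), colnames(X))
  log <- if (keepModelLog) vector("list", length(modelIndices)) else NULL
  for (k in seq_along(modelIndices)) {
    i <- modelIndices[k]
    neg <- sampleNegativeSet(pool, pos, length(pos),
                             seed = modelSeed(config@seed, i, 0L))
    xTr <- X[c(pos, neg), , drop = FALSE]
    yTr <- factor(rep(c("pos", "neg"), c(length(pos), length(neg))),
                  levels = c("neg", "pos"))
    fit <- .fitBaseModel(xTr, yTr, X, config, modelSeed(config@seed, i, 1L))
    voteSum <- voteSum + fit$votes
    impSum <- impSum + fit$importance
    if (keepModelLog) log[[k]] <- list(index = i, negatives = neg)
  }
  .buildEnsembleFit(voteSum, impSum, length(modelIndices), config,
                    as.integer(modelIndices), labels, log)
}

.buildEnsembleFit <- function(voteSum, impSum, nModels, config,
                              modelIndices, labels, log = NULL) {
  denom <- if (config@baseLearner == "random_forest")
    nModels * config@nTrees else nModels
  score <- voteSum / denom
  st <- DataFrame(gene_id = names(voteSum), score = as.numeric(score),
                  n_models_used = nModels,
                  set_membership = setMembership(labels, names(voteSum)))
  meanImp <- impSum / nModels
  imp <- DataFrame(feature = names(impSum),
                   mean_gini_decrease = as.numeric(meanImp),
                   rank = unname(rank(-meanImp, ties.method = "first")))
  fit <- new("PUEnsembleFit", scoreTable = st, importance = imp,
             voteSum = voteSum, importanceSum = impSum,
             nModels = as.integer(nModels), config = config,
             modelIndices = modelIndices)
  metadata(fit@scoreTable)$labels <- labels
  if (!is.null(log)) metadata(fit@scoreTable)$modelLog <- log
  fit
}

#' @rdname fitPUEnsemble
#' @param x a `PUEnsembleFit`.
#' @export
setMethod("scoreTable", "PUEnsembleFit", function(x) x@scoreTable)

#' @rdname fitPUEnsemble
#' @export
setMethod("importanceTable", "PUEnsembleFit", function(x) x@importance)

#' Merge two ensemble runs over disjoint model indices
#'
#' Because the forest learner accumulates integer tree-vote counts,
#' merging two half-ensembles reproduces the single full run exactly
#' (bit-identical scores).
#'
#' @param a,b [PUEnsembleFit-class] objects sharing a config (same seed,
#'   learner, trees) over disjoint model indices.
#' @return a merged `PUEnsembleFit`.
#' @export
combinePUEnsembles <- function(a, b) {
  stopifnot(is(a, "PUEnsembleFit"), is(b, "PUEnsembleFit"))
  if (a@config@seed != b@config@seed ||
      a@config@nTrees != b@config@nTrees ||
      a@config@baseLearner != b@config@baseLearner)
    stop("combinePUEnsembles: incompatible configs")
  if (length(intersect(a@modelIndices, b@modelIndices)))
    stop("combinePUEnsembles: overlapping model indices")
  if (!identical(names(a@voteSum), names(b@voteSum)))
    stop("combinePUEnsembles: gene sets differ")
  labels <- metadata(a@scoreTable)$labels
  .buildEnsembleFit(a@voteSum + b@voteSum, a@importanceSum + b@importanceSum,
                    a@nModels + b@nModels, a@config,
                    c(a@modelIndices, b@modelIndices), labels)
}

#' Aggregate per-model Gini importance vectors
#'
#' Element-wise arithmetic mean of per-model mean-decrease-Gini vectors,
#' ranked by descending mean (ranks are a permutation of 1..p).
#'
#' @param perModelImportances list of equal-length named numeric vectors
#'   in a fixed feature order.
#' @return `DataFrame` with `feature`, `mean_gini_decrease`, `rank`.
#' @export
aggregateGiniImportance <- function(perModelImportances) {
  stopifnot(length(perModelImportances) >= 1)
  lens <- lengths(perModelImportances)
  if (length(unique(lens)) != 1L)
    stop("aggregateGiniImportance: importance vectors differ in length")
  nms <- names(perModelImportances[[1]])
  for (v in perModelImportances)
    if (!is.null(nms) && !identical(names(v), nms))
      stop("aggregateGiniImportance: feature order differs across models")
  m <- do.call(rbind, perModelImportances)
  mu <- colMeans(m)
  DataFrame(feature = if (is.null(nms)) paste0("f", seq_along(mu)) else nms,
            mean_gini_decrease = as.numeric(mu),
            rank = unname(rank(-mu, ties.method = "first")))
}
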