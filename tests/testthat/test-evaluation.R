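test_that("ROC AUC equals the Mann-Whitney pair statistic with a valid curve", {
  expect_equal(computeRocAuc(c(3, 4, 1, 2), c(1, 1, 0, 0))$auc, 1)
  expect_equal(computeRocAuc(rep(1, 10), rep(c(0, 1), 5))$auc, 0.5)
  # enumeration of the 4 positive-negative pairs: 3 wins / 4
  expect_equal(computeRocAuc(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0))$auc, 0.75)
  expect_error(computeRocAuc(1:3, c(1, 1, 1)), "at least one")

  set.seed(20)
  for (rep in 1:25) {
    n <- sample(5:60, 1)
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # heavy ties
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) == 0 || sum(labels) == n) next
    roc <- computeRocAuc(scores, labels)
    expect_identical(roc$auc, pairCountAuc(scores, labels))
    # curve: endpoints, monotonicity, trapezoid integral = AUC
    expect_equal(unlist(roc$curve[1, ]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(roc$curve[nrow(roc$curve), ]), c(fpr = 1, tpr = 1))
    expect_true(all(diff(roc$curve$fpr) >= 0), all(diff(roc$curve$tpr) >= 0))
    trap <- sum(diff(roc$curve$fpr) *
                  (head(roc$curve$tpr, -1) + tail(roc$curve$tpr, -1)) / 2)
    expect_equal(trap, roc$auc)
    # invariance under a strictly increasing transform
    expect_identical(computeRocAuc(exp(3 * scores), labels)$auc, roc$auc)
  }
})

test_that("ROC AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(4)
  scores <- round(runif(80), 2)
  labels <- rbinom(80, 1, 0.5)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(computeRocAuc(scores, labels)$auc, ref)
})

test_that("stratified folds partition both classes evenly", {
  y <- factor(rep(c("pos", "neg"), c(45, 185)), levels = c("neg", "pos"))
  set.seed(1)
  folds <- ioTargets:::.stratifiedFolds(y, 10)
  expect_length(folds, 230)
  expect_setequal(unique(folds), 1:10)           # a true partition
  tab <- table(folds, y)
  expect_true(all(tab[, "pos"] >= 4))
  expect_true(all(tab[, "neg"] >= 18))
})

test_that("fixed-negative CV separates signal, stays null-calibrated, and validates input", {
  scen <- makeSignalScenario(missingRate = 0.05)
  cfg <- ensembleConfig(nTrees = 60, seed = 3)
  cv <- crossvalFixedNegatives(scen$features, positives(scen$labels),
                               curatedNegatives(scen$labels), cfg)
  expect_identical(cv$scheme, "fixed_negatives")
  expect_gt(cv$mean_auc, 0.9)
  expect_identical(cv$mean_auc,
                   computeRocAuc(cv$pooled_prob, cv$labels)$auc)

  expect_error(crossvalFixedNegatives(scen$features, c("g00001", "g00002"),
                                      c("g00002", "g00003"), cfg),
               "overlap")

  # null: positives and negatives from one distribution
  nullGen <- generateFeatureTable(featureGenParams(
    nGenes = 200, nLatentPositives = 20, missingRate = 0, seed = 12))
  aucs <- vapply(1:4, function(s) {
    set.seed(s)
    ids <- sample(rownames(nullGen$features), 90)
    crossvalFixedNegatives(nullGen$features, ids[1:30], ids[31:90],
                           ensembleConfig(nTrees = 60, seed = s))$mean_auc
  }, numeric(1))
  expect_true(mean(aucs) > 0.35 && mean(aucs) < 0.65)

  # leave-one-out mode runs and returns a probability-scale AUC
  small <- makeSignalScenario(nGenes = 300, nLatentPositives = 60)
  loo <- crossvalFixedNegatives(small$features,
                                positives(small$labels)[1:10],
                                curatedNegatives(small$labels)[1:20],
                                ensembleConfig(nTrees = 40, seed = 2),
                                loo = TRUE)
  expect_true(loo$loo)
  expect_true(loo$mean_auc >= 0 && loo$mean_auc <= 1)
})

test_that("random-negative CV averages per-model AUCs under the ensemble seed schedule", {
  scen <- makeSignalScenario()
  cfg <- ensembleConfig(nTrees = 40, seed = 9)
  cv <- crossvalRandomNegatives(scen$features, scen$labels, cfg, nModels = 6)
  expect_identical(cv$scheme, "random_negatives_avg")
  expect_length(cv$per_model_auc, 6)
  expect_equal(cv$mean_auc, mean(cv$per_model_auc))
  expect_gt(cv$mean_auc, 0.8)  # strong signal (small 20v20 folds are noisy)
  # reproducible under the same config seed
  cv2 <- crossvalRandomNegatives(scen$features, scen$labels, cfg, nModels = 6)
  expect_identical(cv$per_model_auc, cv2$per_model_auc)
})

test_that("elastic-net ensemble mirrors the bagging protocol", {
  scen <- makeSignalScenario()
  en <- fitPUEnsemble(scen$features, scen$labels,
                      ensembleConfig(nModels = 8, seed = 13,
                                     baseLearner = "elastic_net_logistic",
                                     enAlpha = 0.5, enLambda = c(0.1, 0.01)))
  st <- scoreTable(en)
  expect_true(all(st$score >= 0 & st$score <= 1))

  # singleton grid: tuning returns exactly that pair
  x <- featureValues(scen$features)[c(positives(scen$labels),
                                      curatedNegatives(scen$labels)), ]
  y <- factor(rep(c("pos", "neg"), c(20, 40)), levels = c("neg", "pos"))
  set.seed(1)
  tuned <- ioTargets:::.tuneElasticNet(x, y, 0.5, 0.05)
  expect_equal(tuned$alpha, 0.5)
  expect_equal(tuned$lambda, 0.05)

  # a perfectly separating feature gives training AUC 1 at small lambda
  xs <- cbind(sep = c(1, 2, 3, -1, -2, -3), noise = rnorm(6))
  rownames(xs) <- paste0("g", 1:6)
  ys <- factor(rep(c("pos", "neg"), each = 3), levels = c("neg", "pos"))
  fitSep <- suppressWarnings(
    glmnet::glmnet(xs, ys, family = "binomial", alpha = 0.5, lambda = 1e-4))
  prob <- predict(fitSep, xs, type = "response")[, 1]
  expect_equal(computeRocAuc(prob, ys == "pos")$auc, 1)

  expect_error(fitElasticNetEnsemble(scen$features, scen$labels,
    ensembleConfig(enAlpha = numeric(0))), "empty tuning grid")
})

test_that("score comparison reports Pearson r with the t-transform p-value", {
  a <- setNames(c(1, 2, 3, 4), paste0("g", 1:4))
  expect_equal(compareScoreVectors(a, a)$pearson_r, 1)
  expect_equal(compareScoreVectors(a, setNames(-a + 10, names(a)))$pearson_r,
               -1)
  # closed-form Pearson on 4 points: r = 3/5
  b <- setNames(c(2, 1, 4, 3), names(a))
  cmp <- compareScoreVectors(a, b)
  expect_equal(cmp$pearson_r, 0.6)
  expect_identical(cmp$n, 4L)
  tstat <- 0.6 * sqrt(2 / (1 - 0.36))
  expect_equal(cmp$p_value, 2 * pt(-tstat, df = 2))
  expect_error(compareScoreVectors(a, setNames(rep(1, 4), names(a))),
               "constant")
  expect_error(compareScoreVectors(a, setNames(1:2, paste0("g", 1:2))),
               "fewer than 3")
})
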