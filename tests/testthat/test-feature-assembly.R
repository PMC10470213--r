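test_that("z-score standardization matches its definition and errors on degenerate input", {
  expect_equal(standardizeFeature(c(2, 4, 6)), c(-1, 0, 1))
  expect_error(standardizeFeature(c(5, 5, 5)), "zero variance")
  expect_error(standardizeFeature(c(3, NA, NA)), "at least 2")

  # independent two-pass mean/sd recomputation
  v <- c(1, 2, 3, 10)
  mu <- sum(v) / 4
  s <- sqrt(sum((v - mu)^2) / 3)
  z <- standardizeFeature(v)
  expect_equal(z, (v - mu) / s)
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)

  # missing entries preserved, and the inverse affine map recovers input
  set.seed(42)
  for (rep in 1:20) {
    x <- rnorm(30, mean = runif(1, -5, 5), sd = runif(1, 0.5, 3))
    x[sample(30, 5)] <- NA
    z <- standardizeFeature(x)
    expect_identical(is.na(z), is.na(x))
    obs <- x[!is.na(x)]
    expect_equal(z[!is.na(x)] * sd(obs) + mean(obs), obs)
  }

  # population-denominator convention
  zp <- standardizeFeature(c(2, 4, 6), denominator = "population")
  expect_equal(sd(c(2, 4, 6)) / sqrt(2 / 3), 2 / sqrt(2 / 3))
  expect_equal(zp, c(-1, 0, 1) * sqrt(3 / 2))
})

test_that("OMIM concept score is the per-gene sum of binary hits", {
  expect_identical(omimConceptScore(rbind(g1 = rep(0, 5)))[["g1"]], 0L)
  expect_identical(omimConceptScore(rbind(g1 = c(1, 0, 1, 1, 0)))[["g1"]], 3L)
  expect_error(omimConceptScore(rbind(g1 = c(1, 2))), "0 or 1")

  # naive double-loop oracle on random binary matrices up to 50x50
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(5:50, 1); m <- sample(3:50, 1)
    mat <- matrix(rbinom(n * m, 1, 0.3), n, m,
                  dimnames = list(paste0("g", 1:n), NULL))
    oracle <- integer(n)
    for (i in 1:n) for (j in 1:m) oracle[i] <- oracle[i] + mat[i, j]
    expect_identical(unname(omimConceptScore(mat)), oracle)
  }
})

test_that("feature assembly integrates sources over the gene universe", {
  s1 <- sourceTable("crispr",
                    data.frame(gene_id = c("a", "b", "c"), v = c(2, 4, 6)),
                    kind = "continuous_score")
  s2 <- sourceTable("mgi", data.frame(gene_id = c("b", "d"), v = c(1, 0)),
                    kind = "binary_annotation")
  s3 <- sourceTable("omim",
                    data.frame(gene_id = c("a", "c", "e"), v = c(3, 0, 2)),
                    kind = "count_matrix")
  ft <- assembleFeatureTable(list(s1, s2, s3), universe = letters[1:5])

  # hand-enumerated 5x3 grid: continuous standardized, others as-is
  expected <- cbind(crispr = c(-1, 0, 1, NA, NA),
                    mgi = c(NA, 1, NA, 0, NA),
                    omim = c(3, NA, 0, NA, 2))
  rownames(expected) <- letters[1:5]
  expect_equal(featureValues(ft), expected)
  expect_identical(missingMask(ft), is.na(expected))
  expect_identical(unname(featureKinds(ft)),
                   c("continuous_score", "binary_annotation", "count_matrix"))

  # gene absent from every source -> fully missing row
  ft6 <- assembleFeatureTable(list(s1, s2, s3), universe = letters[1:6])
  expect_true(all(missingMask(ft6)["f", ]))

  # permutation invariance: shuffling source row order yields same table
  s1b <- sourceTable("crispr",
                     data.frame(gene_id = c("c", "a", "b"), v = c(6, 2, 4)),
                     kind = "continuous_score")
  ftb <- assembleFeatureTable(list(s1b, s2, s3), universe = letters[1:5])
  expect_equal(featureValues(ftb), featureValues(ft))

  # duplicate feature names rejected; duplicate gene rows aggregated by
  # maximum magnitude with a warning
  expect_error(assembleFeatureTable(list(s1, s1)), "duplicate feature")
  expect_warning(
    sdup <- sourceTable("eqtl",
                        data.frame(gene_id = c("a", "a"), v = c(0.2, -0.9)),
                        kind = "effect_size"),
    "maximum-magnitude")
  expect_equal(sdup$values$v, -0.9)
})

test_that("missingness rule omits genes with strictly more than the threshold", {
  v <- matrix(rnorm(3 * 22), 3, 22,
              dimnames = list(c("complete", "six", "seven"), paste0("f", 1:22)))
  v["six", 1:6] <- NA
  v["seven", 1:7] <- NA
  ft <- featureTable(v)
  rep <- filterForPrediction(ft, maxMissing = 6)
  expect_setequal(rep$eligible_genes, c("complete", "six"))
  expect_setequal(rep$omitted_genes, "seven")
  expect_identical(rep$missing_counts[["seven"]], 7L)

  # partition property over random tables
  set.seed(3)
  for (rep_i in 1:10) {
    m <- matrix(rnorm(200), 20, 10,
                dimnames = list(paste0("g", 1:20), paste0("f", 1:10)))
    m[runif(200) < 0.4] <- NA
    fr <- filterForPrediction(featureTable(m), maxMissing = sample(0:10, 1))
    expect_length(intersect(fr$eligible_genes, fr$omitted_genes), 0)
    expect_setequal(c(fr$eligible_genes, fr$omitted_genes), rownames(m))
  }
})

test_that("median imputation fills exactly the missing cells", {
  v <- cbind(f1 = c(1, 2, 3, NA), f2 = c(0, 1, 1, 0))
  rownames(v) <- paste0("g", 1:4)
  ft <- imputeMissing(featureTable(v, kinds = c("continuous_score",
                                                "binary_annotation")))
  expect_equal(featureValues(ft)["g4", "f1"], 2)
  expect_true(missingMask(ft)["g4", "f1"])  # provenance retained

  # complete table returned unchanged
  ftc <- featureTable(matrix(1:4, 2, 2,
                             dimnames = list(c("g1", "g2"), c("f1", "f2"))))
  expect_identical(imputeMissing(ftc), ftc)

  # per-column median oracle on a random table with 30% missing
  set.seed(9)
  m <- matrix(rnorm(40), 10, 4,
              dimnames = list(paste0("g", 1:10), paste0("f", 1:4)))
  m[runif(40) < 0.3] <- NA
  imp <- featureValues(imputeMissing(featureTable(m)))
  for (j in 1:4) {
    med <- median(m[!is.na(m[, j]), j])
    expect_equal(unname(imp[is.na(m[, j]), j]),
                 rep(med, sum(is.na(m[, j]))))
    expect_equal(imp[!is.na(m[, j]), j], m[!is.na(m[, j]), j])
  }
  allNa <- matrix(NA_real_, 2, 1, dimnames = list(c("g1", "g2"), "f1"))
  expect_error(imputeMissing(featureTable(allNa)), "entirely missing")
})

test_that("feature table round-trips through TSV plus JSON sidecar", {
  gen <- generateFeatureTable(featureGenParams(
    nGenes = 40, nLatentPositives = 10, missingRate = 0.2, seed = 5))
  path <- tempfile(fileext = ".tsv")
  writeFeatureTable(gen$features, path)
  back <- readFeatureTable(path)
  expect_equal(featureValues(back), featureValues(gen$features))
  expect_identical(missingMask(back), missingMask(gen$features))
  expect_identical(featureKinds(back), featureKinds(gen$features))
})
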