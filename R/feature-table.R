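#' Construct a FeatureTable
#'
#' Bundles a genes x features numeric grid with an explicit missingness
#' mask and per-feature kind tags into a [FeatureTable-class]
#' (a SummarizedExperiment with assays `values` and `missing`).
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   features in columns (colnames = feature names). `NA` marks missing.
#' @param kinds character vector of feature kinds, one per column; one of
#'   `"continuous_score"`, `"binary_annotation"`, `"count_matrix"`,
#'   `"effect_size"`. Recycled if length 1.
#' @param missing optional logical matrix; defaults to `is.na(values)`.
#' @return a `FeatureTable`.
#' @examples
#' m <- matrix(rnorm(12), 4, 3,
#'             dimnames = list(paste0("g", 1:4), paste0("f", 1:3)))
#' m[1, 2] <- NA
#' ft <- featureTable(m, kinds = "continuous_score")
#' featureValues(ft)[1, 2]       # NA
#' missingMask(ft)[1, 2]         # TRUE
#' @export
featureTable <- function(values, kinds = "continuous_score", missing = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(missing)) missing <- is.na(values)
  missing <- matrix(as.logical(missing), nrow(values), ncol(values),
                    dimnames = dimnames(values))
  kinds <- rep_len(kinds, ncol(values))
  se <- SummarizedExperiment(
    assays = list(values = values, missing = missing),
    colData = DataFrame(kind = kinds, row.names = colnames(values)))
  new("FeatureTable", se)
}

#' @rdname featureTable
#' @param x a `FeatureTable`.
#' @export
setMethod("featureValues", "FeatureTable", function(x) assay(x, "values"))

#' @rdname featureTable
#' @export
setMethod("missingMask", "FeatureTable", function(x) assay(x, "missing"))

#' @rdname featureTable
#' @export
setMethod("featureKinds", "FeatureTable",
          function(x) stats::setNames(colData(x)$kind, colnames(x)))

#' @rdname featureTable
#' @export
setMethod("geneIds", "FeatureTable", function(x) rownames(x))

#' @rdname featureTable
#' @export
setMethod("isComplete", "FeatureTable",
          function(x) !anyNA(assay(x, "values")))

#' Z-score standardization of a feature vector
#'
#' Standardizes a numeric evidence vector as
#' `z = (value - mean) / (standard deviation)`, computed over the
#' non-missing entries; missing entries are preserved. The sd denominator
#' is the sample convention (n - 1) by default; the population convention
#' is selectable.
#'
#' @param values numeric vector, `NA` = missing.
#' @param denominator `"sample"` (n - 1, default) or `"population"` (n).
#' @return numeric vector of the same length; non-missing entries have
#'   mean 0 and unit sd, `NA` positions unchanged.
#' @examples
#' standardizeFeature(c(2, 4, 6))  # -1 0 1
#' @export
standardizeFeature <- function(values, denominator = c("sample", "population")) {
  denominator <- match.arg(denominator)
  obs <- values[!is.na(values)]
  if (length(obs) < 2L)
    stop("standardizeFeature: need at least 2 non-missing values")
  mu <- mean(obs)
  s <- stats::sd(obs)
  if (denominator == "population")
    s <- s * sqrt((length(obs) - 1) / length(obs))
  if (!is.finite(s) || s == 0)
    stop("standardizeFeature: zero variance among non-missing values")
  (values - mu) / s
}

#' OMIM-style concept-hit score
#'
#' Collapses a binary gene x concept association matrix into the per-gene
#' feature used by the model: the sum of concept hits for each gene.
#'
#' @param conceptHits binary matrix (genes x concepts), entries in {0, 1}.
#' @return named integer vector of row sums.
#' @examples
#' m <- rbind(g1 = c(1, 0, 1, 1, 0), g2 = c(0, 0, 0, 0, 0))
#' omimConceptScore(m)  # g1 = 3, g2 = 0
#' @export
omimConceptScore <- function(conceptHits) {
  conceptHits <- as.matrix(conceptHits)
  if (anyNA(conceptHits) || !all(conceptHits %in% c(0, 1)))
    stop("omimConceptScore: entries must all be 0 or 1")
  out <- as.integer(rowSums(conceptHits))
  names(out) <- rownames(conceptHits)
  out
}

#' Describe one evidence source
#'
#' A lightweight descriptor pairing a per-source gene table with its kind,
#' consumed by [assembleFeatureTable()]. Duplicate gene rows within a
#' source are aggregated by the maximum-magnitude value (with a warning).
#'
#' @param name short source identifier; prefixes feature names when the
#'   source has several value columns.
#' @param data data.frame whose first column (or a `gene_id` column) holds
#'   gene ids, remaining numeric columns the values.
#' @param kind one of `"continuous_score"`, `"binary_annotation"`,
#'   `"count_matrix"`, `"effect_size"`.
#' @return an object of class `SourceTable` (a list).
#' @export
sourceTable <- function(name, data, kind) {
  kind <- match.arg(kind, .FEATURE_KINDS)
  data <- as.data.frame(data)
  idcol <- if ("gene_id" %in% names(data)) "gene_id" else names(data)[1]
  gene <- as.character(data[[idcol]])
  if (any(!nzchar(gene)) || anyNA(gene))
    stop("sourceTable: empty gene ids in source '", name, "'")
  vals <- data[setdiff(names(data), idcol)]
  if (!ncol(vals)) stop("sourceTable: source '", name, "' has no value columns")
  vals[] <- lapply(vals, as.numeric)
  if (anyDuplicated(gene)) {
    warning("sourceTable: duplicate gene rows in '", name,
            "' aggregated by maximum-magnitude value")
    agg <- lapply(vals, function(v) {
      tapply(v, gene, function(x) {
        x <- x[!is.na(x)]
        if (!length(x)) NA_real_ else x[which.max(abs(x))]
      })
    })
    gene <- sort(unique(gene))
    vals <- as.data.frame(lapply(agg, function(a) as.numeric(a[gene])))
  }
  ok <- switch(kind,
    binary_annotation = all(unlist(vals) %in% c(0, 1, NA)),
    count_matrix = all(is.na(unlist(vals)) |
                         (unlist(vals) >= 0 & unlist(vals) %% 1 == 0)),
    TRUE)
  if (!isTRUE(ok))
    stop("sourceTable: values of '", name, "' violate kind '", kind, "'")
  structure(list(name = name, gene_id = gene,
                 values = as.data.frame(vals), kind = kind),
            class = "SourceTable")
}

#' Assemble the genes x features evidence matrix
#'
#' Integrates heterogeneous per-source gene tables into one
#' [FeatureTable-class] over a gene universe. Each value column of each
#' source becomes one feature; genes absent from a source are missing for
#' that source's features. Continuous-score sources are passed through
#' [standardizeFeature()] (computed over all supplied genes); binary,
#' count and effect-size features are carried as-is.
#'
#' @param sources list of [sourceTable()] objects.
#' @param universe character vector of gene ids defining the rows; default
#'   is the sorted union of all source genes.
#' @param standardizeContinuous logical; z-score continuous_score sources.
#' @return a `FeatureTable`.
#' @export
assembleFeatureTable <- function(sources, universe = NULL,
                                 standardizeContinuous = TRUE) {
  stopifnot(length(sources) >= 1)
  if (is.null(universe))
    universe <- sort(unique(unlist(lapply(sources, `[[`, "gene_id"))))
  if (anyDuplicated(universe)) stop("assembleFeatureTable: universe not unique")
  cols <- list(); kinds <- character(0)
  for (src in sources) {
    stopifnot(inherits(src, "SourceTable"))
    for (cn in names(src$values)) {
      fname <- if (ncol(src$values) > 1L) paste(src$name, cn, sep = ".")
               else src$name
      if (fname %in% names(cols))
        stop("assembleFeatureTable: duplicate feature name '", fname, "'")
      v <- rep(NA_real_, length(universe))
      idx <- match(src$gene_id, universe)
      keep <- !is.na(idx)
      v[idx[keep]] <- src$values[[cn]][keep]
      if (standardizeContinuous && src$kind == "continuous_score" &&
          sum(!is.na(v)) >= 2L && stats::sd(v, na.rm = TRUE) > 0)
        v <- standardizeFeature(v)
      cols[[fname]] <- v
      kinds[fname] <- src$kind
    }
  }
  values <- do.call(cbind, cols)
  rownames(values) <- universe
  featureTable(values, kinds = kinds)
}

#' Apply the missing-feature omission rule
#'
#' Partitions the genes of a feature table into those eligible for
#' prediction and those omitted because they have more than `maxMissing`
#' missing features (study rule: genes with more than 6 missing values are
#' omitted from the predictions; a gene with exactly `maxMissing` missing
#' features is retained).
#'
#' @param table a [FeatureTable-class].
#' @param maxMissing integer threshold, default 6.
#' @return a list of class `FilterReport` with `eligible_genes`,
#'   `omitted_genes`, `missing_counts` (named integer) and the threshold.
#' @export
filterForPrediction <- function(table, maxMissing = 6L) {
  stopifnot(is(table, "FeatureTable"), maxMissing >= 0)
  mc <- rowSums(missingMask(table))
  structure(list(
    eligible_genes = rownames(table)[mc <= maxMissing],
    omitted_genes = rownames(table)[mc > maxMissing],
    missing_counts = stats::setNames(as.integer(mc), rownames(table)),
    max_missing = as.integer(maxMissing)), class = "FilterReport")
}

#' @export
print.FilterReport <- function(x, ...) {
  cat(sprintf("FilterReport: %d eligible, %d omitted (> %d missing features)\n",
              length(x$eligible_genes), length(x$omitted_genes),
              x$max_missing))
  invisible(x)
}

#' Impute missing feature values
#'
#' Replaces every missing cell by the per-feature median over its
#' non-missing values; non-missing cells are unchanged and the missing
#' mask is retained as provenance. The learner requires complete inputs,
#' and the per-feature median is rank-preserving, learner-agnostic and
#' deterministic.
#'
#' @param table a [FeatureTable-class].
#' @param strategy currently only `"per_feature_median"`.
#' @return a complete `FeatureTable` (no `NA` in values).
#' @export
imputeMissing <- function(table, strategy = "per_feature_median") {
  strategy <- match.arg(strategy)
  v <- featureValues(table)
  if (!anyNA(v)) return(table)
  for (j in seq_len(ncol(v))) {
    nas <- is.na(v[, j])
    if (all(nas))
      stop("imputeMissing: feature '", colnames(v)[j], "' entirely missing")
    if (any(nas)) v[nas, j] <- stats::median(v[!nas, j])
  }
  featureTable(v, kinds = featureKinds(table), missing = missingMask(table))
}

#' Read and write feature tables and gene sets
#'
#' `readSourceTable` reads a tab-separated source file (header row, first
#' or `gene_id` column = gene ids, `NA` = missing) into a [sourceTable()].
#' `writeFeatureTable`/`readFeatureTable` round-trip a `FeatureTable` as a
#' TSV of values (`NA` for missing) plus a JSON sidecar with the feature
#' kinds and persistent missing mask. `readGeneSet` reads one gene id per
#' line.
#'
#' @param path file path.
#' @param name,kind passed to [sourceTable()].
#' @rdname featureIO
#' @export
readSourceTable <- function(path, name, kind) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  sourceTable(name, df, kind)
}

#' @param table a `FeatureTable` to serialize.
#' @rdname featureIO
#' @export
writeFeatureTable <- function(table, path) {
  v <- featureValues(table)
  df <- data.frame(gene_id = rownames(v), v, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(list(
    feature_kinds = as.list(featureKinds(table)),
    missing = apply(missingMask(table), 2, which, simplify = FALSE)),
    sidecar, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname featureIO
#' @export
readFeatureTable <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df$gene_id
  meta <- jsonlite::read_json(paste0(path, ".json"))
  kinds <- unlist(meta$feature_kinds)[colnames(v)]
  miss <- is.na(v)
  for (fn in names(meta$missing)) {
    idx <- unlist(meta$missing[[fn]])
    if (length(idx)) miss[idx, fn] <- TRUE
  }
  featureTable(v, kinds = kinds, missing = miss)
}

#' @rdname featureIO
#' @export
readGeneSet <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  unique(x[nzchar(x)])
}
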