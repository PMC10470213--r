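#' Rank candidate genes by I-O target probability score
#'
#' Restricts a score table to the candidate set and ranks by descending
#' score. Ties receive the minimum (competition) rank; the percentile is
#' rank / n (so the top gene of 1,362 candidates has percentile
#' 1/1362, i.e. the top 0.1%).
#'
#' @param scores a [PUEnsembleFit-class], score `DataFrame`/data.frame
#'   (columns `gene_id`, `score`), or named numeric vector.
#' @param candidateIds gene ids to rank; every id must be scored.
#' @return data.frame with `gene_id`, `score`, `rank`, `percentile`
#'   ordered by rank (ties by gene id).
#' @export
rankCandidates <- function(scores, candidateIds) {
  v <- .asScoreVector(scores)
  candidateIds <- unique(as.character(candidateIds))
  missing <- setdiff(candidateIds, names(v))
  if (length(missing))
    stop("rankCandidates: unscored candidate(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  s <- v[candidateIds]
  rk <- rank(-s, ties.method = "min")
  out <- data.frame(gene_id = candidateIds, score = as.numeric(s),
                    rank = as.integer(rk),
                    percentile = rk / length(s),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$rank, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hierarchically cluster the top-ranked candidates
#'
#' Agglomerative clustering of the feature profiles of the `nTop`
#' best-ranked candidates, cut into `k` clusters (the study cut its top
#' candidates into two subfamilies of 54 and 51 genes). Features are
#' z-standardized by default and genes are processed in a canonical
#' (sorted) order so the partition is invariant to input order; cluster
#' labels are renumbered by decreasing size (ties by first gene id).
#'
#' @param features a complete [FeatureTable-class] covering the ranked
#'   genes.
#' @param ranked output of [rankCandidates()].
#' @param nTop number of top-ranked genes to cluster (default 105).
#' @param k number of clusters (default 2); must not exceed `nTop`.
#' @param distMethod distance passed to [stats::dist()] (default
#'   `"euclidean"`).
#' @param linkage linkage passed to [stats::hclust()] (default
#'   `"ward.D2"`).
#' @param standardize z-score feature columns before clustering.
#' @return a list of class `ClusterAssignment`: `assignment` (data.frame
#'   `gene_id`, `cluster`), `tree` (the `hclust` object), `k`, and the
#'   parameters used.
#' @export
clusterTopCandidates <- function(features, ranked, nTop = 105L, k = 2L,
                                 distMethod = "euclidean",
                                 linkage = "ward.D2", standardize = TRUE) {
  stopifnot(is(features, "FeatureTable"), k >= 1L)
  if (nTop > nrow(ranked))
    stop("clusterTopCandidates: nTop exceeds the number of ranked genes")
  if (nTop < k)
    stop("clusterTopCandidates: fewer genes than clusters")
  top <- utils::head(ranked$gene_id, nTop)
  if (!all(top %in% rownames(features)))
    stop("clusterTopCandidates: ranked genes missing from features")
  X <- featureValues(features)[sort(top), , drop = FALSE]
  if (anyNA(X))
    stop("clusterTopCandidates: features incomplete; impute first")
  if (standardize) {
    keep <- apply(X, 2, stats::sd) > 0
    X <- scale(X[, keep, drop = FALSE])
  }
  hc <- stats::hclust(stats::dist(X, method = distMethod), method = linkage)
  raw <- stats::cutree(hc, k = k)
  # canonical labels: by decreasing cluster size, ties by first gene id
  sizes <- table(raw)
  firstGene <- vapply(names(sizes), function(l)
    min(names(raw)[raw == l]), character(1))
  ord <- order(-as.integer(sizes), firstGene)
  relabel <- stats::setNames(seq_along(ord), names(sizes)[ord])
  cluster <- as.integer(relabel[as.character(raw)])
  structure(list(
    assignment = data.frame(gene_id = names(raw), cluster = cluster,
                            row.names = NULL, stringsAsFactors = FALSE),
    tree = hc, k = as.integer(k),
    params = list(nTop = as.integer(nTop), distMethod = distMethod,
                  linkage = linkage, standardize = standardize)),
    class = "ClusterAssignment")
}

#' @export
print.ClusterAssignment <- function(x, ...) {
  sz <- table(x$assignment$cluster)
  cat(sprintf("ClusterAssignment: %d genes in %d clusters (%s)\n",
              nrow(x$assignment), x$k,
              paste(sprintf("n=%d", sz), collapse = ", ")))
  invisible(x)
}
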