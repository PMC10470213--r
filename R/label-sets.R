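#' Construct the label sets of the positive-unlabeled problem
#'
#' @param positives character, positive training gene ids (known I-O
#'   targets; study size 45).
#' @param universe character, all scoreable gene ids.
#' @param curatedNegatives character, curated negative ids (study size
#'   185), disjoint from `positives`.
#' @param candidates character, candidate gene ids to be ranked (study
#'   size 1,362).
#' @param provenance free-text origin note, e.g. the LD threshold that
#'   defined the candidates.
#' @return a [LabelSets-class].
#' @export
labelSets <- function(positives, universe, curatedNegatives = character(0),
                      candidates = character(0), provenance = character(0)) {
  new("LabelSets",
      positives = unique(as.character(positives)),
      curatedNegatives = unique(as.character(curatedNegatives)),
      candidates = unique(as.character(candidates)),
      universe = unique(as.character(universe)),
      provenance = as.character(provenance))
}

#' Accessors for LabelSets
#'
#' @param x a [LabelSets-class].
#' @name labelSets-accessors
#' @rdname labelSets
NULL

#' @rdname labelSets
#' @export
setMethod("positives", "LabelSets", function(x) x@positives)

#' @rdname labelSets
#' @export
setMethod("curatedNegatives", "LabelSets", function(x) x@curatedNegatives)

#' @rdname labelSets
#' @export
setMethod("candidates", "LabelSets", function(x) x@candidates)

#' @rdname labelSets
#' @export
setMethod("universe", "LabelSets", function(x) x@universe)

#' Set membership of each gene
#'
#' Tags every gene of `ids` with its most specific set: `positive`,
#' `curated_negative`, `candidate`, else `unlabeled`.
#'
#' @param labels a [LabelSets-class].
#' @param ids gene ids to tag; default the universe.
#' @return character vector, same length as `ids`.
#' @export
setMembership <- function(labels, ids = universe(labels)) {
  out <- rep("unlabeled", length(ids))
  out[ids %in% candidates(labels)] <- "candidate"
  out[ids %in% curatedNegatives(labels)] <- "curated_negative"
  out[ids %in% positives(labels)] <- "positive"
  out
}
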