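#' @rdname featureTable
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname featureTable
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' @rdname featureTable
#' @export
setGeneric("featureKinds", function(x) standardGeneric("featureKinds"))

#' @rdname featureTable
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname featureTable
#' @export
setGeneric("isComplete", function(x) standardGeneric("isComplete"))

#' @rdname labelSets
#' @export
setGeneric("positives", function(x) standardGeneric("positives"))

#' @rdname labelSets
#' @export
setGeneric("curatedNegatives", function(x) standardGeneric("curatedNegatives"))

#' @rdname labelSets
#' @export
setGeneric("candidates", function(x) standardGeneric("candidates"))

#' @rdname labelSets
#' @export
setGeneric("universe", function(x) standardGeneric("universe"))

#' @rdname fitPUEnsemble
#' @export
setGeneric("scoreTable", function(x) standardGeneric("scoreTable"))

#' @rdname fitPUEnsemble
#' @export
setGeneric("importanceTable", function(x) standardGeneric("importanceTable"))
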