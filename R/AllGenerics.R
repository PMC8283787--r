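#' @rdname SignatureCollection
#' @param x,object an object.
#' @export
setGeneric("signatureNames", function(x) standardGeneric("signatureNames"))

#' @rdname SignatureCollection
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname SignatureCollection
#' @export
setGeneric("signatureGroups", function(x) standardGeneric("signatureGroups"))

#' @rdname SignatureCollection
#' @export
setGeneric("collectionLabel", function(x) standardGeneric("collectionLabel"))

#' @rdname ReferenceMatrix
#' @param x,object an object.
#' @export
setGeneric("refMatrix", function(x) standardGeneric("refMatrix"))

#' Cell-type ids of a reference or fraction matrix
#' @param x a [ReferenceMatrix-class] or [CellFractionMatrix-class].
#' @return character vector of cell-type ids.
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))

#' @rdname CellFractionMatrix
#' @param x,object an object.
#' @export
setGeneric("fractions", function(x) standardGeneric("fractions"))

#' @rdname CellFractionMatrix
#' @export
setGeneric("fitStats", function(x) standardGeneric("fitStats"))

#' @rdname MutationMatrix
#' @param x,object an object.
#' @export
setGeneric("mutCounts", function(x) standardGeneric("mutCounts"))

#' @rdname MutationMatrix
#' @export
setGeneric("mutationCategory", function(x) standardGeneric("mutationCategory"))

#' @rdname MutationMatrix
#' @export
setGeneric("isBinarized", function(x) standardGeneric("isBinarized"))

#' @rdname ScoreMatrix
#' @param x,object an object.
#' @export
setGeneric("scoreValues", function(x) standardGeneric("scoreValues"))

#' @rdname ScoreMatrix
#' @export
setGeneric("methodTag", function(x) standardGeneric("methodTag"))
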