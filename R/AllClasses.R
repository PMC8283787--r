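#' @import methods
NULL

#' Collection of gene signatures
#'
#' Named gene sets (character vectors of gene symbols), each optionally
#' assigned to a category so signatures can be browsed and analysed in
#' thematic groups (tumor-microenvironment cells, metabolism, ...).
#'
#' @slot sets named list of character vectors; names are signature ids.
#' @slot categories character vector parallel to `sets`; `NA` or `""` for
#'   uncategorised signatures.
#' @slot label free-text provenance label (e.g. `"fixture"` for the small
#'   synthetic collection shipped with the package).
#'
#' @exportClass SignatureCollection
setClass("SignatureCollection",
  representation(sets = "list", categories = "character", label = "character"),
  prototype(sets = list(), categories = character(), label = "")
)

setValidity("SignatureCollection", function(object) {
  msgs <- character()
  nm <- names(object@sets)
  if (length(object@sets) > 0 && (is.null(nm) || anyNA(nm) || any(nm == "")))
    msgs <- c(msgs, "all signatures must be named")
  if (anyDuplicated(nm))
    msgs <- c(msgs, "duplicate signature names")
  if (length(object@categories) != length(object@sets))
    msgs <- c(msgs, "categories must be parallel to sets")
  if (any(vapply(object@sets, length, 1L) == 0L))
    msgs <- c(msgs, "empty gene sets are not allowed")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SignatureCollection
#'
#' @param sets named list of character vectors of gene symbols.
#' @param categories optional character vector (recycled `NA` if missing)
#'   assigning each set to a group.
#' @param label provenance label.
#' @return A [SignatureCollection-class] object.
#' @examples
#' sc <- SignatureCollection(list(Teff = c("CD8A", "GZMB"), Hypoxia = c("HIF1A", "VEGFA")))
#' signatureNames(sc)
#' @export
SignatureCollection <- function(sets, categories = NULL, label = "") {
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (is.null(categories)) categories <- rep(NA_character_, length(sets))
  categories <- as.character(categories)
  categories[!is.na(categories) & categories == ""] <- NA_character_
  new("SignatureCollection", sets = sets, categories = categories, label = label)
}

#' Cell-type reference basis for deconvolution
#'
#' Signature genes by cell types matrix `S` used in the linear mixture model
#' `m = S f`. The condition number of `S` is computed at construction and
#' stored in `methodMeta$condition_number` (an ill-conditioned basis makes
#' fractions unstable).
#'
#' @slot values numeric matrix, genes x cell types.
#' @slot scaleTag `"linear"` or `"log2"`.
#' @slot methodMeta list of free-form metadata (engine hint, provenance,
#'   condition number).
#'
#' @exportClass ReferenceMatrix
setClass("ReferenceMatrix",
  representation(values = "matrix", scaleTag = "character", methodMeta = "list")
)

setValidity("ReferenceMatrix", function(object) {
  v <- object@values
  msgs <- character()
  if (!is.numeric(v)) msgs <- c(msgs, "values must be numeric")
  if (ncol(v) < 2L) msgs <- c(msgs, "a reference needs at least 2 cell types")
  if (nrow(v) < 1L) msgs <- c(msgs, "a reference needs at least 1 gene")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msgs <- c(msgs, "gene and cell-type ids are required (dimnames)")
  else {
    if (anyDuplicated(rownames(v))) msgs <- c(msgs, "duplicate gene ids")
    if (anyDuplicated(colnames(v))) msgs <- c(msgs, "duplicate cell-type ids")
  }
  if (!object@scaleTag %in% c("linear", "log2"))
    msgs <- c(msgs, "scaleTag must be 'linear' or 'log2'")
  if (length(msgs)) msgs else TRUE
})

#' Construct a ReferenceMatrix
#'
#' @param values numeric matrix (genes x cell types) with dimnames.
#' @param scaleTag `"linear"` (default) or `"log2"`.
#' @param methodMeta list of metadata merged with the computed condition
#'   number.
#' @return A [ReferenceMatrix-class].
#' @export
ReferenceMatrix <- function(values, scaleTag = "linear", methodMeta = list()) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  methodMeta$condition_number <- tryCatch(kappa(values, exact = FALSE),
                                          error = function(e) NA_real_)
  new("ReferenceMatrix", values = values, scaleTag = scaleTag,
      methodMeta = methodMeta)
}

#' Estimated cell-type composition of bulk samples
#'
#' Cell types by samples matrix of estimated fractions (or unconstrained
#' abundance scores), with per-sample goodness-of-fit statistics.
#'
#' @slot values numeric matrix, cell types x samples.
#' @slot constrained logical; `TRUE` means every column lies on the unit
#'   simplex (non-negative, sums to one).
#' @slot fitStats data.frame with one row per sample (`rmse`, `pearson_r`,
#'   optionally `perm_p`); zero-row data.frame when the engine reports none.
#' @slot method character; the registry id or engine that produced the fit.
#'
#' @exportClass CellFractionMatrix
setClass("CellFractionMatrix",
  representation(values = "matrix", constrained = "logical",
                 fitStats = "data.frame", method = "character")
)

setValidity("CellFractionMatrix", function(object) {
  v <- object@values
  msgs <- character()
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msgs <- c(msgs, "cell-type and sample ids are required (dimnames)")
  if (isTRUE(object@constrained)) {
    if (any(v < 0)) msgs <- c(msgs, "constrained fractions must be non-negative")
    cs <- colSums(v)
    if (any(abs(cs - 1) > 1e-6))
      msgs <- c(msgs, "constrained fraction columns must sum to 1 (tol 1e-6)")
  }
  if (nrow(object@fitStats) > 0 && nrow(object@fitStats) != ncol(v))
    msgs <- c(msgs, "fitStats must have one row per sample")
  if (length(msgs)) msgs else TRUE
})

CellFractionMatrix <- function(values, constrained, fitStats = NULL,
                               method = NA_character_) {
  if (is.null(fitStats)) fitStats <- data.frame()
  new("CellFractionMatrix", values = values, constrained = constrained,
      fitStats = fitStats, method = method)
}

#' Per-sample mutation counts by gene
#'
#' Samples x genes integer matrix built from MAF records, possibly
#' binarized (mutated / wild type).
#'
#' @slot values integer matrix, samples x genes.
#' @slot categoryTag one of `"all"`, `"snp"`, `"indel"`, `"frameshift"`.
#' @slot binarized logical; `TRUE` once counts were thresholded to 0/1.
#'
#' @exportClass MutationMatrix
setClass("MutationMatrix",
  representation(values = "matrix", categoryTag = "character",
                 binarized = "logical")
)

setValidity("MutationMatrix", function(object) {
  v <- object@values
  msgs <- character()
  if (any(v < 0)) msgs <- c(msgs, "mutation counts must be non-negative")
  if (isTRUE(object@binarized) && !all(v %in% c(0L, 1L)))
    msgs <- c(msgs, "binarized matrix must contain only 0/1")
  if (!object@categoryTag %in% c("all", "snp", "indel", "frameshift"))
    msgs <- c(msgs, "unknown categoryTag")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msgs <- c(msgs, "sample and gene ids are required (dimnames)")
  if (length(msgs)) msgs else TRUE
})

#' Signature scores per sample
#'
#' Signatures x samples matrix of per-sample signature scores, tagged with
#' the scoring method that produced it.
#'
#' @slot values numeric matrix, signatures x samples.
#' @slot methodTag `"ssgsea"`, `"pca"`, `"zscore"` or `"integration"`.
#'
#' @exportClass ScoreMatrix
setClass("ScoreMatrix",
  representation(values = "matrix", methodTag = "character")
)

setValidity("ScoreMatrix", function(object) {
  v <- object@values
  msgs <- character()
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msgs <- c(msgs, "signature and sample ids are required (dimnames)")
  if (anyNA(v)) msgs <- c(msgs, "NA scores are not allowed (undefined scores must be dropped)")
  if (!object@methodTag %in% c("ssgsea", "pca", "zscore", "integration"))
    msgs <- c(msgs, "unknown methodTag")
  if (length(msgs)) msgs else TRUE
})

ScoreMatrix <- function(values, methodTag) {
  new("ScoreMatrix", values = values, methodTag = methodTag)
}
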