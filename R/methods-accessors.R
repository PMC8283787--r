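#' @rdname SignatureCollection
#' @export
setMethod("signatureNames", "SignatureCollection", function(x) names(x@sets))

#' @rdname SignatureCollection
#' @export
setMethod("geneSets", "SignatureCollection", function(x) x@sets)

#' @rdname SignatureCollection
#' @export
setMethod("signatureGroups", "SignatureCollection", function(x) {
  keep <- !is.na(x@categories)
  if (!any(keep)) return(list())
  split(names(x@sets)[keep], x@categories[keep])
})

#' @rdname SignatureCollection
#' @export
setMethod("collectionLabel", "SignatureCollection", function(x) x@label)

#' @rdname SignatureCollection
#' @export
setMethod("length", "SignatureCollection", function(x) length(x@sets))

#' @rdname SignatureCollection
#' @param i index (name or position).
#' @export
setMethod("[[", "SignatureCollection", function(x, i) x@sets[[i]])

setMethod("show", "SignatureCollection", function(object) {
  grp <- signatureGroups(object)
  cat("SignatureCollection with", length(object@sets), "signatures",
      if (length(grp)) paste0("in ", length(grp), " groups") else "(flat)",
      "\n")
  if (nzchar(object@label)) cat("  label:", object@label, "\n")
  nshow <- min(5L, length(object@sets))
  if (nshow > 0) {
    sizes <- vapply(object@sets[seq_len(nshow)], length, 1L)
    cat("  ", paste0(names(object@sets)[seq_len(nshow)], " (", sizes, ")",
                     collapse = ", "),
        if (length(object@sets) > nshow) ", ..." else "", "\n", sep = "")
  }
})

#' @rdname ReferenceMatrix
#' @export
setMethod("refMatrix", "ReferenceMatrix", function(x) x@values)

#' @rdname ReferenceMatrix
#' @export
setMethod("cellTypes", "ReferenceMatrix", function(x) colnames(x@values))

#' @rdname ReferenceMatrix
#' @export
setMethod("dim", "ReferenceMatrix", function(x) dim(x@values))

setMethod("show", "ReferenceMatrix", function(object) {
  cat("ReferenceMatrix:", nrow(object@values), "genes x",
      ncol(object@values), "cell types [", object@scaleTag, "scale ]\n")
  kn <- object@methodMeta$condition_number
  if (!is.null(kn)) cat("  condition number:", format(kn, digits = 4), "\n")
  cat("  cell types:", paste(utils::head(colnames(object@values), 8), collapse = ", "),
      if (ncol(object@values) > 8) ", ..." else "", "\n")
})

#' @rdname CellFractionMatrix
#' @export
setMethod("fractions", "CellFractionMatrix", function(x) x@values)

#' @rdname CellFractionMatrix
#' @export
setMethod("fitStats", "CellFractionMatrix", function(x) x@fitStats)

#' @rdname CellFractionMatrix
#' @export
setMethod("cellTypes", "CellFractionMatrix", function(x) rownames(x@values))

#' @rdname CellFractionMatrix
#' @export
setMethod("dim", "CellFractionMatrix", function(x) dim(x@values))

setMethod("show", "CellFractionMatrix", function(object) {
  cat("CellFractionMatrix:", nrow(object@values), "cell types x",
      ncol(object@values), "samples",
      if (object@constrained) "(simplex constrained)" else "(unconstrained)",
      "\n")
  if (!is.na(object@method)) cat("  method:", object@method, "\n")
  if (nrow(object@fitStats) > 0)
    cat("  fit stats: ", paste(colnames(object@fitStats), collapse = ", "),
        "; median rmse ", format(stats::median(object@fitStats$rmse), digits = 3),
        "\n", sep = "")
})

#' @rdname MutationMatrix
#' @export
setMethod("mutCounts", "MutationMatrix", function(x) x@values)

#' @rdname MutationMatrix
#' @export
setMethod("mutationCategory", "MutationMatrix", function(x) x@categoryTag)

#' @rdname MutationMatrix
#' @export
setMethod("isBinarized", "MutationMatrix", function(x) x@binarized)

#' @rdname MutationMatrix
#' @export
setMethod("dim", "MutationMatrix", function(x) dim(x@values))

setMethod("show", "MutationMatrix", function(object) {
  cat("MutationMatrix:", nrow(object@values), "samples x",
      ncol(object@values), "genes; category =", object@categoryTag,
      if (object@binarized) "(binary)" else "(counts)", "\n")
})

#' @rdname ScoreMatrix
#' @export
setMethod("scoreValues", "ScoreMatrix", function(x) x@values)

#' @rdname ScoreMatrix
#' @export
setMethod("methodTag", "ScoreMatrix", function(x) x@methodTag)

#' @rdname ScoreMatrix
#' @export
setMethod("dim", "ScoreMatrix", function(x) dim(x@values))

setMethod("show", "ScoreMatrix", function(object) {
  cat("ScoreMatrix [", object@methodTag, "]:", nrow(object@values),
      "signatures x", ncol(object@values), "samples\n")
})

# Accept either a ScoreMatrix or a plain signatures x samples matrix.
.score_input <- function(scores) {
  if (is(scores, "ScoreMatrix")) scores@values
  else {
    m <- as.matrix(scores)
    if (is.null(rownames(m)))
      rownames(m) <- paste0("feature", seq_len(nrow(m)))
    m
  }
}
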