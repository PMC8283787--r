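#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT: one set per line — name, description, then
#' the member genes. Duplicate genes within a line are collapsed; a
#' non-empty description field is stored as the set's category.
#'
#' @param path GMT file path.
#' @param label provenance label attached to the collection.
#' @return A [SignatureCollection-class].
#' @export
readGMT <- function(path, label = "") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  sets <- vector("list", length(lines))
  cats <- character(length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("GMT line ", i, " has fewer than 3 fields (name, description, genes...)")
    nms[i] <- f[1L]
    cats[i] <- f[2L]
    genes <- unique(f[-c(1L, 2L)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop("GMT line ", i, " has no genes")
    sets[[i]] <- genes
  }
  if (anyDuplicated(nms))
    stop("duplicate set names in GMT: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  names(sets) <- nms
  SignatureCollection(sets, categories = cats, label = label)
}

#' Write a SignatureCollection as GMT
#'
#' @param collection a [SignatureCollection-class].
#' @param path output file.
#' @export
writeGMT <- function(collection, path) {
  sets <- geneSets(collection)
  cats <- collection@categories
  cats[is.na(cats)] <- ""
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], cats[i], sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Packaged signature collection
#'
#' The small synthetic signature collection shipped with the package: 12
#' immuno-oncology style gene sets in 4 thematic groups, intended for
#' examples and tests. It is a fixture, not a curated resource — supply
#' your own GMT for real analyses.
#'
#' @return A [SignatureCollection-class] with label `"fixture"`.
#' @export
builtinSignatures <- function() {
  readGMT(system.file("extdata", "signatures_fixture.gmt", package = "tmekit"),
          label = "fixture")
}
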