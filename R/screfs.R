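# Deriving deconvolution references from cluster-labelled scRNA-seq data.
# Cells arrive with cluster labels (clustering itself is out of scope);
# counts are library-size normalised to counts-per-10k and log2(x+1)
# transformed before testing.

.sc_normalize <- function(counts) {
  ls <- colSums(counts)
  if (any(ls == 0)) stop("cells with zero total counts: ",
                         paste(utils::head(colnames(counts)[ls == 0], 5), collapse = ", "))
  sweep(counts, 2L, ls / 1e4, "/")
}

#' One-vs-rest cluster marker genes
#'
#' For every cluster and every gene, a two-sided Wilcoxon rank-sum test of
#' the cluster's cells against all other cells (on log2 counts-per-10k),
#' with Benjamini-Hochberg FDR across genes within each cluster. The
#' log2 fold change is the difference of mean log2 expression. Rows
#' failing the effect-size or FDR thresholds are flagged (`pass = FALSE`),
#' not removed, so the full testing landscape stays inspectable.
#'
#' @param counts non-negative matrix, genes x cells (raw counts or TPM).
#' @param clusters cluster label per cell (named by cell id, or in column
#'   order).
#' @param min_lfc minimum log2 fold change for a passing marker (default 1).
#' @param max_fdr maximum FDR for a passing marker (default 0.05).
#' @param min_cells smallest allowed cluster (default 3).
#' @return data.frame with columns `gene`, `cluster`, `log2_fc`, `p`,
#'   `fdr`, `pass`; one row per (gene, cluster).
#' @export
findMarkers <- function(counts, clusters, min_lfc = 1, max_fdr = 0.05,
                        min_cells = 3L) {
  counts <- as.matrix(counts)
  if (!is.null(names(clusters))) clusters <- clusters[colnames(counts)]
  if (length(clusters) != ncol(counts))
    stop("one cluster label per cell is required")
  cl <- factor(clusters)
  sizes <- table(cl)
  if (any(sizes < min_cells))
    stop("cluster(s) below min_cells = ", min_cells, ": ",
         paste(names(sizes)[sizes < min_cells], collapse = ", "))
  lg <- log2(.sc_normalize(counts) + 1)
  res <- list()
  for (lev in levels(cl)) {
    inc <- cl == lev
    xin <- lg[, inc, drop = FALSE]
    xout <- lg[, !inc, drop = FALSE]
    p <- numeric(nrow(lg))
    for (i in seq_len(nrow(lg)))
      p[i] <- ranksumTest(xin[i, ], xout[i, ])$p
    lfc <- rowMeans(xin) - rowMeans(xout)
    fdr <- .bh(p)
    res[[lev]] <- data.frame(gene = rownames(lg), cluster = lev,
                             log2_fc = lfc, p = p, fdr = fdr,
                             pass = fdr <= max_fdr & lfc >= min_lfc,
                             row.names = NULL, stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

#' Build a deconvolution reference from cluster markers
#'
#' Selects the `top_k` passing markers per cluster (ascending FDR, ties by
#' descending log2 fold change, then gene id) and averages each gene's
#' linear-scale library-size-normalised expression (counts-per-10k) over
#' the cells of every cluster, restricted to the union of selected
#' markers. Averaging on the linear scale keeps the reference consistent
#' with the linear mixture model used downstream.
#'
#' @param counts non-negative matrix, genes x cells (same matrix given to
#'   [findMarkers()]).
#' @param clusters cluster label per cell.
#' @param markers marker table from [findMarkers()].
#' @param top_k markers retained per cluster (default 50).
#' @return A [ReferenceMatrix-class] (linear scale) whose columns are the
#'   clusters; provenance recorded in `methodMeta`.
#' @export
buildReference <- function(counts, clusters, markers, top_k = 50L) {
  counts <- as.matrix(counts)
  if (!is.null(names(clusters))) clusters <- clusters[colnames(counts)]
  cl <- factor(clusters)
  passing <- markers[markers$pass, , drop = FALSE]
  chosen <- character()
  for (lev in levels(cl)) {
    sub <- passing[passing$cluster == lev, , drop = FALSE]
    if (nrow(sub) == 0L)
      stop("cluster '", lev, "' contributed no passing marker")
    sub <- sub[order(sub$fdr, -sub$log2_fc, sub$gene), , drop = FALSE]
    chosen <- union(chosen, utils::head(sub$gene, top_k))
  }
  norm <- .sc_normalize(counts)[chosen, , drop = FALSE]
  S <- sapply(levels(cl), function(lev)
    rowMeans(norm[, cl == lev, drop = FALSE]))
  ReferenceMatrix(S, scaleTag = "linear",
                  methodMeta = list(source = "scRNA cluster markers",
                                    top_k = top_k,
                                    n_cells = ncol(counts)))
}
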