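#' Single-sample GSEA signature scores
#'
#' Rank-based running-sum enrichment score computed independently for each
#' sample. Genes are ranked by expression in decreasing order (ties broken
#' deterministically by gene id); walking down the ranked list, the score
#' accumulates the difference between the weighted fraction of set genes
#' seen so far (weights are the rank values raised to `alpha`) and the
#' fraction of non-set genes seen so far:
#' \deqn{ES = \sum_i \left[ P_{in}(i) - P_{out}(i) \right]}
#' with \eqn{P_{in}(i) = \sum_{j \in set, j \le i} r_j^\alpha / \sum_{j \in
#' set} r_j^\alpha} and \eqn{P_{out}(i)} the running fraction of non-set
#' genes. Because only ranks enter, scores are invariant to any strictly
#' increasing transform of a sample's expression.
#'
#' @param expr numeric matrix, genes x samples, log-like scale.
#' @param collection a [SignatureCollection-class] (or named list of gene
#'   vectors).
#' @param alpha rank-weight exponent (default 0.25).
#' @param normalize divide all scores by the global score range
#'   (max - min over the whole matrix); default TRUE.
#' @param min_set_size smallest usable overlap between a set and the
#'   matrix genes (default 2). Sets below it, or covering every gene, are
#'   dropped with a warning.
#' @return A [ScoreMatrix-class], signatures x samples.
#' @export
scoreSsgsea <- function(expr, collection, alpha = 0.25, normalize = TRUE,
                        min_set_size = 2L) {
  expr <- as.matrix(expr)
  sets <- if (is(collection, "SignatureCollection")) geneSets(collection)
          else collection
  if (!length(sets)) stop("empty signature collection")
  genes <- rownames(expr)
  n <- length(genes)
  usable <- list()
  for (nm in names(sets)) {
    ov <- intersect(sets[[nm]], genes)
    if (length(ov) < min_set_size) {
      warning("set '", nm, "' dropped: only ", length(ov),
              " of its genes are in the matrix")
    } else if (length(ov) == n) {
      warning("set '", nm, "' dropped: covers every gene (no background)")
    } else {
      usable[[nm]] <- ov
    }
  }
  if (!length(usable)) stop("no usable signature after intersection with the matrix")

  inset <- vapply(usable, function(g) genes %in% g, logical(n))  # n x sets
  scores <- matrix(0, length(usable), ncol(expr),
                   dimnames = list(names(usable), colnames(expr)))
  for (j in seq_len(ncol(expr))) {
    ord <- order(-expr[, j], genes)          # ties: stable by gene id
    w <- (n:1)^alpha                         # rank value of position i is n-i+1
    ins <- inset[ord, , drop = FALSE]
    for (k in seq_len(ncol(ins))) {
      m <- ins[, k]
      p_in <- cumsum(w * m) / sum(w * m)
      p_out <- cumsum(!m) / sum(!m)
      scores[k, j] <- sum(p_in - p_out)
    }
  }
  if (normalize) {
    rng <- max(scores) - min(scores)
    if (rng > 0) scores <- scores / rng
  }
  ScoreMatrix(scores, "ssgsea")
}

# z-standardise the rows of the signature submatrix; returns NULL (with a
# warning) when fewer than `min_genes` usable genes remain.
.signature_zmatrix <- function(expr, genes, name, min_genes) {
  present <- intersect(genes, rownames(expr))
  if (length(present) < min_genes) {
    warning("signature '", name, "' dropped: ", length(present),
            " of its genes are in the matrix")
    return(NULL)
  }
  sub <- expr[present, , drop = FALSE]
  sds <- apply(sub, 1L, stats::sd)
  if (any(sds == 0)) {
    warning("signature '", name, "': ", sum(sds == 0),
            " zero-variance genes excluded")
    sub <- sub[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (nrow(sub) < min_genes) {
    warning("signature '", name, "' dropped: fewer than ", min_genes,
            " genes with variance")
    return(NULL)
  }
  (sub - rowMeans(sub)) / sds
}

#' First-principal-component signature score
#'
#' The signature genes are per-gene z-standardised and the samples'
#' coordinates on the first principal component of that submatrix are the
#' scores. The sign of a principal component is arbitrary, so the score is
#' oriented to correlate non-negatively with the per-sample mean of the
#' standardised signature genes; scores are centred (sum to zero).
#'
#' @param expr numeric matrix, genes x samples, log-like scale.
#' @param genes character vector of signature gene symbols.
#' @param name signature name used in messages.
#' @return named numeric vector of per-sample scores, or NULL when fewer
#'   than 2 usable genes remain.
#' @export
scorePCA <- function(expr, genes, name = "signature") {
  z <- .signature_zmatrix(as.matrix(expr), genes, name, min_genes = 2L)
  if (is.null(z)) return(NULL)
  pc <- stats::prcomp(t(z), center = FALSE, scale. = FALSE)
  s <- pc$x[, 1L]
  guide <- colMeans(z)
  if (sum(s * guide) < 0) s <- -s
  stats::setNames(as.numeric(s), colnames(expr))
}

#' Mean z-score signature score
#'
#' Per sample, the mean over the signature genes of the gene-standardised
#' expression \eqn{(x_{gj} - \bar x_g)/s_g}; zero-variance genes are
#' excluded.
#'
#' @inheritParams scorePCA
#' @param min_genes smallest usable signature (default 1).
#' @return named numeric vector of per-sample scores, or NULL when no
#'   usable gene remains.
#' @export
scoreZscore <- function(expr, genes, name = "signature", min_genes = 1L) {
  z <- .signature_zmatrix(as.matrix(expr), genes, name, min_genes = min_genes)
  if (is.null(z)) return(NULL)
  stats::setNames(colMeans(z), colnames(expr))
}

#' Score a signature collection by one or all methods
#'
#' Dispatches to [scoreSsgsea()], [scorePCA()] or [scoreZscore()];
#' `method = "integration"` runs all three and suffixes each signature id
#' with the method tag.
#'
#' @param expr numeric matrix, genes x samples, log-like scale.
#' @param collection a [SignatureCollection-class].
#' @param method one of `"ssgsea"`, `"pca"`, `"zscore"`, `"integration"`.
#' @param ... passed to the method (e.g. `alpha`, `normalize`).
#' @return A [ScoreMatrix-class].
#' @export
calculateSigScore <- function(expr, collection,
                              method = c("ssgsea", "pca", "zscore", "integration"),
                              ...) {
  method <- match.arg(method)
  if (is(collection, "SignatureCollection") && length(collection) == 0L)
    stop("empty signature collection")
  expr <- as.matrix(expr)
  if (method == "integration") {
    parts <- lapply(c("ssgsea", "pca", "zscore"), function(mth) {
      sm <- calculateSigScore(expr, collection, method = mth, ...)
      v <- scoreValues(sm)
      rownames(v) <- paste0(rownames(v), "_", mth)
      v
    })
    return(ScoreMatrix(do.call(rbind, parts), "integration"))
  }
  if (method == "ssgsea") return(scoreSsgsea(expr, collection, ...))
  scorer <- if (method == "pca") scorePCA else scoreZscore
  sets <- geneSets(collection)
  rows <- lapply(names(sets), function(nm) scorer(expr, sets[[nm]], name = nm))
  names(rows) <- names(sets)
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) stop("no signature could be scored")
  ScoreMatrix(do.call(rbind, rows), method)
}
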