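#' Convert raw counts to TPM
#'
#' Transcripts-per-million normalisation: each gene's count is divided by
#' its effective transcript length in kilobases, and the per-kilobase rates
#' of every sample are rescaled to sum to one million. Gene lengths come
#' from the annotation table (`length_bp`), matched to the matrix row ids
#' by `source_id` (falling back to `symbol` when no source id matches).
#'
#' @param counts numeric matrix of non-negative raw counts, genes x samples.
#' @param annotation data.frame as from [readGeneAnnotation()], with a
#'   `length_bp` column.
#' @return TPM matrix (every column sums to 1e6), with attribute
#'   `scale_tag = "tpm"`. Genes without a positive length are dropped with
#'   a warning.
#' @examples
#' cnt <- matrix(c(10, 10), 2, 1, dimnames = list(c("A", "B"), "S1"))
#' ann <- data.frame(source_id = c("A", "B"), symbol = c("A", "B"),
#'                   length_bp = c(1000, 2000))
#' count2tpm(cnt, ann)  # 666666.7 and 333333.3
#' @export
count2tpm <- function(counts, annotation) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!"length_bp" %in% colnames(annotation))
    stop("annotation needs a length_bp column for TPM conversion")
  key <- if (any(rownames(counts) %in% annotation$source_id)) "source_id" else "symbol"
  len <- annotation$length_bp[match(rownames(counts), annotation[[key]])]
  usable <- !is.na(len) & len > 0
  if (!any(usable)) stop("no gene in the matrix has a positive annotated length")
  if (!all(usable))
    warning(sum(!usable), " genes without a positive length dropped")
  m <- counts[usable, , drop = FALSE]
  rate <- m / (len[usable] / 1000)      # reads per kilobase
  denom <- colSums(rate)
  zero <- denom == 0
  if (any(zero))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(m)[zero], collapse = ", "))
  tpm <- sweep(rate, 2L, denom, "/") * 1e6
  attr(tpm, "scale_tag") <- "tpm"
  tpm
}

#' Annotate and deduplicate matrix rows
#'
#' Replaces row ids (probes, ENSEMBL ids, ...) by gene symbols using the
#' annotation table; rows without a mapping are dropped. When several rows
#' map to the same symbol, `dedup_rule = "max_mean"` keeps the row with the
#' largest mean across samples (the usual choice for intensity-like data)
#' and `"sum"` adds the rows (appropriate for counts split across
#' transcripts).
#'
#' @param m numeric matrix, rows keyed by `source_id`.
#' @param annotation data.frame with `source_id` and `symbol`.
#' @param dedup_rule `"max_mean"` (default) or `"sum"`.
#' @return matrix with unique symbol row ids.
#' @export
annoEset <- function(m, annotation, dedup_rule = c("max_mean", "sum")) {
  dedup_rule <- match.arg(dedup_rule)
  m <- as.matrix(m)
  sym <- annotation$symbol[match(rownames(m), annotation$source_id)]
  keep <- !is.na(sym) & sym != ""
  if (!any(keep)) stop("no matrix row maps to a symbol")
  if (!all(keep))
    message(sum(!keep), " unmapped rows dropped")
  m <- m[keep, , drop = FALSE]
  sym <- sym[keep]
  if (!anyDuplicated(sym)) {
    rownames(m) <- sym
    return(m)
  }
  if (dedup_rule == "sum") {
    out <- rowsum(m, group = sym)
    return(out[unique(sym), , drop = FALSE])
  }
  means <- rowMeans(m)
  ord <- order(sym, -means)      # within symbol, best row first
  first <- !duplicated(sym[ord])
  out <- m[ord[first], , drop = FALSE]
  rownames(out) <- sym[ord][first]
  out[unique(sym), , drop = FALSE]
}

#' Log-transform an expression matrix
#'
#' `mode = "log2"` applies `log2(x + 1)`; `"auto"` applies it only when the
#' matrix maximum exceeds `threshold` (linear-scale data such as TPM), a
#' heuristic for matrices of unknown provenance; `"none"` is the identity.
#'
#' @param m numeric matrix.
#' @param mode `"auto"`, `"log2"` or `"none"`.
#' @param threshold auto-detection cutoff on `max(m)` (default 50).
#' @return matrix, with `scale_tag` attribute `"log2"` when transformed.
#' @export
normalizeExpression <- function(m, mode = c("auto", "log2", "none"),
                                threshold = 50) {
  mode <- match.arg(mode)
  m <- as.matrix(m)
  if (mode == "none") return(m)
  if (mode == "auto" && max(m, na.rm = TRUE) <= threshold) return(m)
  if (any(m < 0)) stop("log2 transform requires non-negative values")
  out <- log2(m + 1)
  attr(out, "scale_tag") <- "log2"
  out
}

#' Remove batch effects from a log-scale matrix
#'
#' Location-scale batch adjustment on the log2 scale. Each gene is
#' standardised against its grand mean and pooled residual variance; the
#' per-batch location and scale of the standardised values are removed and
#' the grand mean/variance restored. With `empirical_bayes = TRUE` the
#' per-gene batch effects are shrunk toward the across-gene batch mean via
#' the standard parametric normal/inverse-gamma priors (delegated to
#' \code{sva::ComBat}); with `empirical_bayes = FALSE` the raw per-gene
#' estimates are used, which makes per-batch per-gene means exactly equal
#' after adjustment.
#'
#' Genes with zero variance inside every batch carry no usable scale
#' information and are passed through untouched.
#'
#' @param m numeric matrix on log2 scale, genes x samples.
#' @param batches batch labels: a vector named by sample id (or in column
#'   order), or a data.frame with `sample_id` and `batch` columns.
#' @param empirical_bayes shrink batch effects across genes (default TRUE).
#' @return adjusted matrix of the same shape.
#' @export
adjustBatches <- function(m, batches, empirical_bayes = TRUE) {
  m <- as.matrix(m)
  if (is.data.frame(batches)) {
    if (!all(c("sample_id", "batch") %in% colnames(batches)))
      stop("batch table needs sample_id and batch columns")
    batches <- stats::setNames(as.character(batches$batch),
                               as.character(batches$sample_id))
  }
  if (!is.null(names(batches))) {
    miss <- setdiff(colnames(m), names(batches))
    if (length(miss))
      stop("samples without batch label: ", paste(utils::head(miss, 5), collapse = ", "))
    batches <- batches[colnames(m)]
  } else if (length(batches) != ncol(m)) {
    stop("one batch label per sample is required")
  }
  b <- factor(batches)
  if (nlevels(b) < 2L) {
    warning("single batch: matrix returned unchanged")
    return(m)
  }
  sizes <- table(b)
  if (any(sizes < 2L))
    stop("every batch needs at least 2 samples (offending: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "), ")")

  # genes uninformative for scale: constant inside every batch
  within_var <- sapply(levels(b), function(l)
    apply(m[, b == l, drop = FALSE], 1L, stats::var))
  flat <- rowSums(within_var > 0) == 0L
  work <- m[!flat, , drop = FALSE]
  if (nrow(work) == 0L) return(m)

  adj <- if (empirical_bayes) {
    sva::ComBat(dat = work, batch = b, par.prior = TRUE, prior.plots = FALSE)
  } else {
    .batch_adjust_plain(work, b)
  }
  out <- m
  out[!flat, ] <- adj
  out
}

# Location-scale adjustment without shrinkage: per-gene batch means/SDs of
# the standardised data removed exactly.
.batch_adjust_plain <- function(m, b) {
  n <- ncol(m)
  lv <- levels(b)
  w <- as.numeric(table(b)[lv]) / n
  bmeans <- sapply(lv, function(l) rowMeans(m[, b == l, drop = FALSE]))
  alpha <- drop(bmeans %*% w)                    # size-weighted grand mean
  resid <- m - bmeans[, as.integer(b), drop = FALSE]
  sigma <- sqrt(rowSums(resid^2) / n)
  sigma[sigma == 0] <- 1
  z <- (m - alpha) / sigma
  out <- z
  for (l in lv) {
    cols <- b == l
    zb <- z[, cols, drop = FALSE]
    gamma <- rowMeans(zb)
    delta <- apply(zb, 1L, stats::sd)
    delta[delta == 0 | is.na(delta)] <- 1
    out[, cols] <- (zb - gamma) / delta
  }
  out * sigma + alpha
}
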