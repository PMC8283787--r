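#' Read a genes x samples expression matrix
#'
#' Reads a TSV (or CSV, by file extension) with gene ids in the first
#' column and sample ids in the header. Gzipped files are handled
#' transparently. Missing values are rejected by default because silent NA
#' propagation corrupts the rank statistics used downstream; with
#' `impute = "min"` each NA is replaced by its gene's minimum observed
#' value and all-missing genes are dropped.
#'
#' @param path file path (`.tsv`, `.txt`, `.csv`, optionally `.gz`).
#' @param impute `"error"` (default) or `"min"`.
#' @return numeric matrix, genes x samples.
#' @export
readExpression <- function(path, impute = c("error", "min")) {
  impute <- match.arg(impute)
  sep <- if (grepl("\\.csv(\\.gz)?$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  if (ncol(df) < 2L)
    stop("expression table needs a gene-id column plus at least one sample: ", path)
  ids <- as.character(df[[1L]])
  cn <- colnames(df)[-1L]          # before subsetting: `[.data.frame` repairs duplicates
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  colnames(m) <- cn
  .check_axis(rownames(m), "gene")
  .check_axis(colnames(m), "sample")
  if (anyNA(m)) {
    if (impute == "error")
      stop("missing values in ", path,
           " (", sum(is.na(m)), " cells); use impute = 'min' to impute")
    all_na <- rowSums(!is.na(m)) == 0L
    if (any(all_na)) {
      warning(sum(all_na), " all-missing genes dropped")
      m <- m[!all_na, , drop = FALSE]
    }
    for (i in which(rowSums(is.na(m)) > 0L)) {
      v <- m[i, ]
      v[is.na(v)] <- min(v, na.rm = TRUE)
      m[i, ] <- v
    }
  }
  m
}

.check_axis <- function(ids, what) {
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("empty ", what, " ids are not allowed")
  if (anyDuplicated(ids))
    stop("duplicate ", what, " ids: ",
         paste(utils::head(unique(ids[duplicated(ids)]), 5), collapse = ", "))
  invisible(TRUE)
}

#' Write a matrix as TSV with an id column
#'
#' @param m matrix with dimnames.
#' @param path output path.
#' @param id_col header for the first (row-id) column.
#' @export
writeMatrixTSV <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' TSV with columns `source_id`, `symbol` and (for TPM conversion)
#' `length_bp`; one row per source id.
#'
#' @param path file path.
#' @return data.frame with those columns.
#' @export
readGeneAnnotation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, comment.char = "")
  need <- c("source_id", "symbol")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("annotation is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$source_id))
    stop("annotation must have one row per source_id")
  df
}

#' Read a phenotype table
#'
#' TSV keyed by `sample_id` with any of: `group` (categorical), continuous
#' covariates, and survival columns `time` + `event` (0/1). `time` and
#' `event` must be present together.
#'
#' @param path file path.
#' @return data.frame with rownames set to sample ids.
#' @export
readPhenotype <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, comment.char = "")
  if (!"sample_id" %in% colnames(df)) stop("phenotype table needs a sample_id column")
  .check_axis(as.character(df$sample_id), "sample")
  if (xor("time" %in% colnames(df), "event" %in% colnames(df)))
    stop("survival columns 'time' and 'event' must be present together")
  rownames(df) <- df$sample_id
  df
}

#' Read cluster-labelled single-cell expression
#'
#' Accepts either a dense TSV (genes x cells) or a Matrix Market triplet
#' directory (`matrix.mtx`, `genes.tsv`, `barcodes.tsv`), plus a labels TSV
#' with columns `cell_id` and `cluster`.
#'
#' @param path TSV file or MTX directory.
#' @param labels_path labels TSV.
#' @return list with `counts` (dense matrix genes x cells) and `clusters`
#'   (named character vector, one label per cell).
#' @export
readSingleCell <- function(path, labels_path) {
  if (dir.exists(path)) {
    m <- as.matrix(Matrix::readMM(file.path(path, "matrix.mtx")))
    genes <- utils::read.table(file.path(path, "genes.tsv"), sep = "\t",
                               stringsAsFactors = FALSE)[[1L]]
    cells <- utils::read.table(file.path(path, "barcodes.tsv"), sep = "\t",
                               stringsAsFactors = FALSE)[[1L]]
    rownames(m) <- genes; colnames(m) <- cells
  } else {
    m <- readExpression(path)
  }
  lab <- utils::read.table(labels_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("cell_id", "cluster") %in% colnames(lab)))
    stop("labels need columns cell_id and cluster")
  cl <- stats::setNames(as.character(lab$cluster), as.character(lab$cell_id))
  missing <- setdiff(colnames(m), names(cl))
  if (length(missing))
    stop(length(missing), " cells have no cluster label, e.g. ", missing[1L])
  list(counts = m, clusters = cl[colnames(m)])
}
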