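# MAF handling and mutation-signature association. Only the TCGA dialect
# of the four mandatory columns is recognised (case-insensitive header
# match); column synonyms are deliberately not guessed.

.maf_required <- c("Hugo_Symbol", "Tumor_Sample_Barcode",
                   "Variant_Classification", "Variant_Type")

# standard non-silent classification list for --nonsynonymous-only
.nonsilent_classes <- c(
  "Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
  "Splice_Site", "Translation_Start_Site",
  "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins"
)

#' Read somatic mutations in MAF format
#'
#' Tab-separated MAF with `#` comment lines. The four mandatory columns
#' (`Hugo_Symbol`, `Tumor_Sample_Barcode`, `Variant_Classification`,
#' `Variant_Type`) are matched case-insensitively; unknown classification
#' strings are retained verbatim.
#'
#' @param path MAF file path.
#' @return data.frame of MAF records with canonical column names.
#' @export
readMAF <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE)
  hit <- match(tolower(.maf_required), tolower(colnames(df)))
  if (anyNA(hit))
    stop("MAF is missing mandatory column(s): ",
         paste(.maf_required[is.na(hit)], collapse = ", "))
  colnames(df)[hit] <- .maf_required
  df
}

#' Build a mutation matrix from MAF records
#'
#' Counts passing records per (sample, gene). Category filters:
#' `"snp"` keeps `Variant_Type == "SNP"`; `"indel"` keeps `Variant_Type`
#' in `INS`/`DEL`; `"frameshift"` keeps records whose
#' `Variant_Classification` starts with `"Frame_Shift"`; `"all"` keeps
#' everything. Samples listed in `sample_universe` but absent from the MAF
#' get all-zero rows. `binarize_at` thresholds counts to mutated (1) /
#' wild type (0).
#'
#' @param maf data.frame from [readMAF()] (or with the same columns).
#' @param category `"all"`, `"snp"`, `"indel"` or `"frameshift"`.
#' @param sample_universe optional character vector of sample ids to
#'   guarantee rows for.
#' @param binarize_at integer >= 1, or `NA` to keep counts (default 1:
#'   binary output).
#' @param nonsynonymous_only drop silent/non-coding records first using
#'   the standard non-silent classification list (default FALSE: the MAF
#'   is taken as given).
#' @return A [MutationMatrix-class], samples x genes.
#' @export
makeMutMatrix <- function(maf, category = c("all", "snp", "indel", "frameshift"),
                          sample_universe = NULL, binarize_at = 1L,
                          nonsynonymous_only = FALSE) {
  category <- match.arg(category)
  miss <- setdiff(.maf_required, colnames(maf))
  if (length(miss))
    stop("MAF is missing mandatory column(s): ", paste(miss, collapse = ", "))
  if (nonsynonymous_only)
    maf <- maf[maf$Variant_Classification %in% .nonsilent_classes, , drop = FALSE]
  keep <- switch(category,
    all = rep(TRUE, nrow(maf)),
    snp = maf$Variant_Type == "SNP",
    indel = maf$Variant_Type %in% c("INS", "DEL"),
    frameshift = startsWith(maf$Variant_Classification, "Frame_Shift"))
  maf <- maf[keep, , drop = FALSE]
  if (nrow(maf) == 0L) stop("no MAF record passes the '", category, "' filter")
  samples <- sort(unique(c(maf$Tumor_Sample_Barcode, sample_universe)))
  genes <- sort(unique(maf$Hugo_Symbol))
  m <- matrix(0L, length(samples), length(genes),
              dimnames = list(samples, genes))
  tab <- table(maf$Tumor_Sample_Barcode, maf$Hugo_Symbol)
  m[rownames(tab), colnames(tab)] <- as.integer(tab)
  binarized <- FALSE
  if (!is.na(binarize_at)) {
    m <- matrix(as.integer(m >= binarize_at), nrow(m), ncol(m),
                dimnames = dimnames(m))
    binarized <- TRUE
  }
  new("MutationMatrix", values = m, categoryTag = category,
      binarized = binarized)
}

#' Genes whose mutation status tracks a signature
#'
#' For every gene mutated in at least `min_freq` of the samples, a
#' two-sided Wilcoxon rank-sum test of the signature score in mutated vs
#' wild-type samples; effect size is the median score difference
#' (mutated - wild type). BH FDR across tested genes; rows sorted by
#' ascending p. Low-frequency genes are excluded and listed in the
#' `"excluded"` attribute.
#'
#' @param mut binarized [MutationMatrix-class].
#' @param scores one signature's scores, named by sample id.
#' @param min_freq minimum mutated fraction for a gene to be tested
#'   (default 0.05).
#' @return data.frame with `gene`, `n_mut`, `n_wt`, `statistic`, `p`,
#'   `fdr`, `effect`.
#' @export
findMutations <- function(mut, scores, min_freq = 0.05) {
  if (!isBinarized(mut)) stop("findMutations needs a binarized MutationMatrix")
  m <- mutCounts(mut)
  if (is.null(names(scores))) stop("scores must be named by sample id")
  ids <- intersect(rownames(m), names(scores))
  if (length(ids) < 4L) stop("too few samples shared between matrix and scores")
  m <- m[ids, , drop = FALSE]
  s <- scores[ids]
  freq <- colMeans(m)
  tested <- colnames(m)[freq >= min_freq & freq < 1]
  excluded <- setdiff(colnames(m), tested)
  if (!length(tested))
    stop("no gene mutated in >= ", min_freq, " of samples")
  if (length(excluded))
    message(length(excluded), " genes below min_freq excluded")
  rows <- lapply(tested, function(g) {
    mutated <- m[, g] == 1L
    rt <- ranksumTest(s[mutated], s[!mutated])
    data.frame(gene = g, n_mut = sum(mutated), n_wt = sum(!mutated),
               statistic = rt$statistic, p = rt$p,
               effect = stats::median(s[mutated]) - stats::median(s[!mutated]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- .bh(out$p)
  out <- out[order(out$p, out$gene), c("gene", "n_mut", "n_wt", "statistic",
                                       "p", "fdr", "effect")]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Mutation frequencies for oncoprint-style display
#'
#' Per-gene mutation frequencies overall and within two sample groups
#' (e.g. high/low halves of a signature score), for the `top_n` most
#' frequently mutated genes.
#'
#' @param mut binarized [MutationMatrix-class].
#' @param groups two-level labels (e.g. `"high"`/`"low"`) named by sample
#'   id, or in row order.
#' @param top_n number of genes to keep, by overall frequency (ties by
#'   gene id); larger than the gene count returns all genes.
#' @return data.frame with `gene`, `freq_overall`, and one `freq_<level>`
#'   column per group.
#' @export
oncoprintSummary <- function(mut, groups, top_n = 20L) {
  if (!isBinarized(mut)) stop("oncoprintSummary needs a binarized MutationMatrix")
  m <- mutCounts(mut)
  if (!is.null(names(groups))) {
    ids <- intersect(rownames(m), names(groups))
    m <- m[ids, , drop = FALSE]; groups <- groups[ids]
  } else if (length(groups) != nrow(m)) {
    stop("one group label per sample is required")
  }
  g <- factor(groups)
  if (any(table(g) == 0L) || nlevels(g) < 2L)
    stop("both groups must be non-empty")
  overall <- colMeans(m)
  ord <- order(-overall, colnames(m))
  keep <- utils::head(ord, top_n)
  out <- data.frame(gene = colnames(m)[keep],
                    freq_overall = overall[keep],
                    row.names = NULL, stringsAsFactors = FALSE)
  for (lev in levels(g))
    out[[paste0("freq_", lev)]] <- colMeans(m[g == lev, keep, drop = FALSE])
  out
}
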