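# Deterministic synthetic-data generators. Every generator seeds the RNG
# from its `seed` argument and restores the caller's RNG state, so the
# same arguments always yield bit-identical output regardless of context.

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulate a well-separated cell-type reference
#'
#' Log-normal baseline expression (log2-normal, mean `base_mean`, sd
#' `base_sd`) with a disjoint block of `markers_per_type` marker genes per
#' cell type shifted up by `marker_shift` log2 units in its own type. The
#' blocks make the columns distinguishable (pairwise correlation well
#' below 0.5), which is what identifiable deconvolution requires.
#'
#' @param n_genes total genes (must be at least `10 * n_cell_types`).
#' @param n_cell_types number of cell types (>= 2).
#' @param markers_per_type marker block size (default 20).
#' @param marker_shift log2 upshift of markers (default 4).
#' @param base_mean,base_sd log2-scale baseline parameters (default 3, 1).
#' @param seed RNG seed.
#' @return A [ReferenceMatrix-class] on linear scale.
#' @export
simReference <- function(n_genes = 200L, n_cell_types = 5L,
                         markers_per_type = 20L, marker_shift = 4,
                         base_mean = 3, base_sd = 1, seed = 1L) {
  if (n_cell_types < 2L) stop("need at least 2 cell types")
  if (n_genes < 10L * n_cell_types)
    stop("n_genes must be >= 10 * n_cell_types")
  if (markers_per_type * n_cell_types > n_genes)
    stop("marker blocks exceed the gene count")
  .with_seed(seed, {
    lg <- matrix(stats::rnorm(n_genes * n_cell_types, base_mean, base_sd),
                 n_genes, n_cell_types)
    for (k in seq_len(n_cell_types)) {
      block <- ((k - 1L) * markers_per_type + 1L):(k * markers_per_type)
      lg[block, k] <- lg[block, k] + marker_shift
    }
    dimnames(lg) <- list(sprintf("gene%04d", seq_len(n_genes)),
                         sprintf("cellType%d", seq_len(n_cell_types)))
    ReferenceMatrix(2^lg, scaleTag = "linear",
                    methodMeta = list(source = "simulation", seed = seed,
                                      markers_per_type = markers_per_type))
  })
}

#' Simulate fraction vectors on the simplex
#'
#' Symmetric Dirichlet draws (`alpha = 1`: uniform on the simplex).
#'
#' @param n_samples number of samples.
#' @param n_types number of cell types.
#' @param alpha Dirichlet concentration (default 1).
#' @param seed RNG seed.
#' @return matrix, cell types x samples; every column sums to 1.
#' @export
simFractions <- function(n_samples, n_types, alpha = 1, seed = 1L) {
  .with_seed(seed, {
    g <- matrix(stats::rgamma(n_types * n_samples, shape = alpha),
                n_types, n_samples)
    f <- sweep(g, 2L, colSums(g), "/")
    dimnames(f) <- list(sprintf("cellType%d", seq_len(n_types)),
                        sprintf("sample%03d", seq_len(n_samples)))
    f
  })
}

#' Simulate bulk mixtures from a reference
#'
#' Linear mixing `m = S f` plus additive Gaussian noise truncated at zero.
#'
#' @param reference a [ReferenceMatrix-class] (or genes x types matrix).
#' @param fractions cell types x samples matrix; every column must lie on
#'   the simplex (tolerance 1e-8).
#' @param noise_sd additive noise standard deviation (default 0).
#' @param seed RNG seed (only consumed when `noise_sd > 0`).
#' @return numeric matrix, genes x samples.
#' @export
simMixtures <- function(reference, fractions, noise_sd = 0, seed = 1L) {
  S <- if (is(reference, "ReferenceMatrix")) refMatrix(reference) else as.matrix(reference)
  f <- as.matrix(fractions)
  if (any(f < -1e-8) || any(abs(colSums(f) - 1) > 1e-8))
    stop("fraction columns must lie on the simplex (tolerance 1e-8)")
  if (nrow(f) != ncol(S)) stop("fractions rows must match reference cell types")
  m <- S %*% f
  if (noise_sd > 0)
    m <- .with_seed(seed,
      pmax(m + matrix(stats::rnorm(length(m), 0, noise_sd), nrow(m)), 0))
  if (is.null(colnames(m))) colnames(m) <- sprintf("sample%03d", seq_len(ncol(m)))
  m
}

#' Simulate cluster-labelled scRNA-seq counts
#'
#' Negative-binomial counts around log-normal per-gene baseline means,
#' with a disjoint block of planted marker genes per cluster whose mean is
#' multiplied by `2^marker_lfc` in that cluster. `markers_per_cluster = 0`
#' yields identically distributed clusters (a pure null).
#'
#' @param n_genes,n_clusters,cells_per_cluster simulation dimensions.
#' @param markers_per_cluster planted markers per cluster (default 20).
#' @param marker_lfc log2 fold change of planted markers (default 3).
#' @param dispersion negative-binomial size parameter (default 2).
#' @param seed RNG seed.
#' @return list with `counts` (genes x cells), `clusters` (named labels)
#'   and `markers` (named list of planted marker genes per cluster).
#' @export
simScrna <- function(n_genes = 500L, n_clusters = 3L, cells_per_cluster = 30L,
                     markers_per_cluster = 20L, marker_lfc = 3,
                     dispersion = 2, seed = 1L) {
  if (markers_per_cluster * n_clusters > n_genes)
    stop("marker blocks exceed the gene count")
  .with_seed(seed, {
    mu <- 2^stats::rnorm(n_genes, 2, 1)
    genes <- sprintf("gene%04d", seq_len(n_genes))
    n_cells <- n_clusters * cells_per_cluster
    cl <- rep(sprintf("cluster%d", seq_len(n_clusters)), each = cells_per_cluster)
    cells <- sprintf("cell%04d", seq_len(n_cells))
    names(cl) <- cells
    planted <- list()
    counts <- matrix(0L, n_genes, n_cells, dimnames = list(genes, cells))
    for (k in seq_len(n_clusters)) {
      muk <- mu
      if (markers_per_cluster > 0L) {
        block <- ((k - 1L) * markers_per_cluster + 1L):(k * markers_per_cluster)
        muk[block] <- muk[block] * 2^marker_lfc
        planted[[sprintf("cluster%d", k)]] <- genes[block]
      }
      idx <- which(cl == sprintf("cluster%d", k))
      counts[, idx] <- stats::rnbinom(n_genes * length(idx), mu = muk,
                                      size = dispersion)
    }
    list(counts = counts, clusters = cl, markers = planted)
  })
}

#' Simulate a toy MAF cohort
#'
#' Per gene, each sample is mutated independently with the gene's
#' Bernoulli rate; each mutation becomes one MAF record whose variant
#' type is drawn from `type_mix` (`SNP`, `INS`, `DEL`) and whose
#' classification is consistent with the type (missense for SNPs,
#' frame-shift or in-frame for indels).
#'
#' @param n_samples cohort size.
#' @param gene_rates named numeric vector of per-gene mutation rates in
#'   [0, 1].
#' @param type_mix named probabilities for `SNP`, `INS`, `DEL`.
#' @param frameshift_prob probability that an indel is frame-shifting
#'   (default 2/3, the non-multiple-of-three fraction).
#' @param seed RNG seed.
#' @return data.frame of MAF records (the four mandatory columns).
#' @export
simMAF <- function(n_samples = 50L, gene_rates,
                   type_mix = c(SNP = 0.6, INS = 0.2, DEL = 0.2),
                   frameshift_prob = 2 / 3, seed = 1L) {
  if (is.null(names(gene_rates)) || any(gene_rates < 0 | gene_rates > 1))
    stop("gene_rates must be named probabilities in [0, 1]")
  if (abs(sum(type_mix) - 1) > 1e-8 ||
      !all(names(type_mix) %in% c("SNP", "INS", "DEL")))
    stop("type_mix must be SNP/INS/DEL probabilities summing to 1")
  .with_seed(seed, {
    samples <- sprintf("S%03d", seq_len(n_samples))
    recs <- list()
    for (g in names(gene_rates)) {
      hit <- samples[stats::runif(n_samples) < gene_rates[[g]]]
      if (!length(hit)) next
      vt <- sample(names(type_mix), length(hit), replace = TRUE,
                   prob = type_mix)
      vc <- ifelse(vt == "SNP", "Missense_Mutation",
             ifelse(stats::runif(length(vt)) < frameshift_prob,
                    paste0("Frame_Shift_", ifelse(vt == "INS", "Ins", "Del")),
                    paste0("In_Frame_", ifelse(vt == "INS", "Ins", "Del"))))
      recs[[g]] <- data.frame(Hugo_Symbol = g, Tumor_Sample_Barcode = hit,
                              Variant_Classification = vc, Variant_Type = vt,
                              stringsAsFactors = FALSE)
    }
    if (!length(recs)) stop("no mutation was planted; raise gene_rates")
    out <- do.call(rbind, recs)
    rownames(out) <- NULL
    out
  })
}

#' Simulate phenotypes linked to a signature score
#'
#' `outcome = "binary"`: response drawn from a logistic model
#' `logit P(responder) = intercept + beta * score`. `outcome =
#' "survival"`: exponential event times with hazard `exp(beta * score)`
#' and independent uniform censoring on `[0, censor_max]` (`censor_max =
#' 3.2` gives roughly 30% censoring for a standard-normal score and
#' `beta = 0.7`).
#'
#' @param scores numeric vector named by sample id.
#' @param beta link coefficient (0 = null).
#' @param outcome `"survival"` or `"binary"`.
#' @param censor_max upper censoring bound (survival only).
#' @param intercept logistic intercept (binary only).
#' @param seed RNG seed.
#' @return data.frame keyed by sample id with either `group`
#'   (`responder`/`nonresponder`) or `time` + `event`.
#' @export
simPhenotype <- function(scores, beta = 0.7,
                         outcome = c("survival", "binary"),
                         censor_max = 3.2, intercept = 0, seed = 1L) {
  outcome <- match.arg(outcome)
  if (is.null(names(scores))) stop("scores must be named by sample id")
  if (censor_max <= 0) stop("censor_max must be positive")
  n <- length(scores)
  .with_seed(seed, {
    if (outcome == "binary") {
      p <- stats::plogis(intercept + beta * scores)
      grp <- ifelse(stats::runif(n) < p, "responder", "nonresponder")
      data.frame(sample_id = names(scores), group = grp,
                 row.names = names(scores), stringsAsFactors = FALSE)
    } else {
      t_event <- stats::rexp(n, rate = exp(beta * scores))
      t_cens <- stats::runif(n, 0, censor_max)
      data.frame(sample_id = names(scores),
                 time = pmin(t_event, t_cens),
                 event = as.integer(t_event <= t_cens),
                 row.names = names(scores), stringsAsFactors = FALSE)
    }
  })
}
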