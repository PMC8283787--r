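#' nu-SVR cell-fraction estimation
#'
#' CIBERSORT-style deconvolution: for each bulk sample a linear nu-support
#' vector regression of the standardised mixture on the reference columns
#' is fitted over a grid of `nu` values; the fit with the smallest
#' reconstruction RMSE wins. Negative coefficients are clamped to zero and
#' the remainder normalised to sum to one. Standardisation follows the
#' CIBERSORT convention: the mixture is z-scored per sample, the reference
#' as a whole.
#'
#' @param mixture numeric matrix, genes x samples (linear or log scale; the
#'   per-sample z-scoring absorbs global scale).
#' @param reference a [ReferenceMatrix-class] (or genes x cell types matrix).
#' @param nu_grid nu values to try (default `c(0.25, 0.5, 0.75)`).
#' @param n_perm number of gene-label permutations for the per-sample
#'   empirical p-value (0 = skip; use >= 100 for a meaningful p).
#' @param min_genes smallest allowed gene overlap between mixture and
#'   reference (default 20).
#' @param seed optional seed controlling the permutations.
#' @return A [CellFractionMatrix-class] with per-sample `rmse`,
#'   `pearson_r` and (when `n_perm > 0`) `perm_p` fit statistics.
#' @export
deconvSVR <- function(mixture, reference, nu_grid = c(0.25, 0.5, 0.75),
                      n_perm = 0L, min_genes = 20L, seed = NULL) {
  S <- if (is(reference, "ReferenceMatrix")) refMatrix(reference) else as.matrix(reference)
  if (ncol(S) < 2L) stop("reference must have at least 2 cell types")
  mixture <- as.matrix(mixture)
  shared <- intersect(rownames(mixture), rownames(S))
  if (length(shared) < min_genes)
    stop("only ", length(shared), " genes shared between mixture and reference (need >= ",
         min_genes, ")")
  X <- S[shared, , drop = FALSE]
  X <- (X - mean(X)) / stats::sd(X)
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  k <- ncol(X)
  out <- matrix(0, k, ncol(mixture), dimnames = list(colnames(X), colnames(mixture)))
  fs <- data.frame(rmse = numeric(ncol(mixture)), pearson_r = numeric(ncol(mixture)),
                   row.names = colnames(mixture))
  if (n_perm > 0L) fs$perm_p <- NA_real_
  for (j in seq_len(ncol(mixture))) {
    y <- mixture[shared, j]
    sdy <- stats::sd(y)
    if (sdy == 0) stop("sample ", colnames(mixture)[j], " has constant expression")
    y <- (y - mean(y)) / sdy
    best <- NULL
    for (nu in nu_grid) {
      cand <- .svr_fit(X, y, nu)
      if (is.null(best) || cand$rmse < best$rmse) { best <- cand; best$nu <- nu }
    }
    out[, j] <- best$f
    fs$rmse[j] <- best$rmse
    fs$pearson_r[j] <- best$r
    if (n_perm > 0L) {
      rp <- vapply(seq_len(n_perm), function(i) .svr_fit(X, sample(y), best$nu)$r,
                   numeric(1))
      fs$perm_p[j] <- mean(rp >= best$r)
    }
  }
  CellFractionMatrix(out, constrained = TRUE, fitStats = fs, method = "svr")
}

# one nu-SVR fit: clamp-normalised weights plus reconstruction stats
.svr_fit <- function(X, y, nu) {
  fit <- e1071::svm(x = X, y = y, type = "nu-regression", kernel = "linear",
                    nu = nu, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  w[w < 0] <- 0
  f <- if (sum(w) > 0) w / sum(w) else rep(1 / length(w), length(w))
  recon <- drop(X %*% f)
  list(f = f,
       rmse = sqrt(mean((recon - y)^2)),
       r = if (stats::sd(recon) > 0) stats::cor(recon, y) else 0)
}

#' Constrained least-squares cell-fraction estimation
#'
#' Per sample solves `min || S f - m ||^2` with non-negativity and,
#' depending on `sum_constraint`, a full simplex constraint
#' (`"equal"`, the default: fractions sum to one), an upper bound
#' (`"leq"`: fractions sum to at most one and the remainder is reported as
#' an `otherCells` row, for references that do not span the whole tissue),
#' or no sum constraint (`"none"`: non-negative regression only). The
#' quadratic programs are solved exactly (dual active-set method).
#'
#' @param mixture numeric matrix, genes x samples, same scale as the
#'   reference (typically linear).
#' @param reference a [ReferenceMatrix-class] or genes x cell types matrix.
#' @param sum_constraint `"equal"`, `"leq"` or `"none"`.
#' @return A [CellFractionMatrix-class]; `constrained` is TRUE for
#'   `"equal"`/`"leq"`.
#' @export
deconvLSEI <- function(mixture, reference,
                       sum_constraint = c("equal", "leq", "none")) {
  sum_constraint <- match.arg(sum_constraint)
  S <- if (is(reference, "ReferenceMatrix")) refMatrix(reference) else as.matrix(reference)
  if (ncol(S) < 2L) stop("reference must have at least 2 cell types")
  mixture <- as.matrix(mixture)
  shared <- intersect(rownames(mixture), rownames(S))
  if (length(shared) < ncol(S))
    stop("need at least as many shared genes (", length(shared),
         ") as cell types (", ncol(S), ")")
  S <- S[shared, , drop = FALSE]
  M <- mixture[shared, , drop = FALSE]
  kap <- kappa(S, exact = FALSE)
  if (!is.finite(kap) || kap > 1e8)
    warning("reference is (near) rank deficient; condition number ",
            format(kap, digits = 3))
  k <- ncol(S)
  D <- crossprod(S)
  ridge <- 1e-12 * mean(diag(D))
  Amat <- switch(sum_constraint,
    equal = cbind(rep(1, k), diag(k)),
    leq   = cbind(rep(-1, k), diag(k)),
    none  = diag(k))
  bvec <- switch(sum_constraint,
    equal = c(1, rep(0, k)),
    leq   = c(-1, rep(0, k)),
    none  = rep(0, k))
  meq <- if (sum_constraint == "equal") 1L else 0L

  ids <- colnames(S)
  if (sum_constraint == "leq") ids <- c(ids, "otherCells")
  out <- matrix(0, length(ids), ncol(M), dimnames = list(ids, colnames(M)))
  fs <- data.frame(rmse = numeric(ncol(M)), pearson_r = numeric(ncol(M)),
                   row.names = colnames(M))
  for (j in seq_len(ncol(M))) {
    m <- M[, j]
    sol <- tryCatch(
      quadprog::solve.QP(D, crossprod(S, m), Amat, bvec, meq = meq),
      error = function(e)
        quadprog::solve.QP(D + diag(ridge + 1e-10 * mean(diag(D)), k),
                           crossprod(S, m), Amat, bvec, meq = meq))
    f <- sol$solution
    f[f < 0 & f > -1e-9] <- 0
    f[f < 0] <- 0                      # active-set residue beyond jitter
    if (sum_constraint == "equal" && sum(f) > 0) f <- f / sum(f)
    recon <- drop(S %*% f)
    fs$rmse[j] <- sqrt(mean((recon - m)^2))
    fs$pearson_r[j] <- if (stats::sd(recon) > 0 && stats::sd(m) > 0)
      stats::cor(recon, m) else NA_real_
    out[seq_len(k), j] <- f
    if (sum_constraint == "leq") out[k + 1L, j] <- max(0, 1 - sum(f))
  }
  CellFractionMatrix(out, constrained = sum_constraint != "none",
                     fitStats = fs, method = "constrained_ls")
}

#' Marker-mean abundance scores
#'
#' MCP-counter style absolute abundance: each population's score is the
#' arithmetic mean of the log2 expression of its marker genes present in
#' the matrix. Scores are comparable across samples within a population,
#' not across populations, and carry no sum-to-one constraint.
#'
#' @param expr numeric matrix, genes x samples, log2 scale.
#' @param panels named list of marker gene vectors (or a
#'   [SignatureCollection-class]).
#' @return numeric matrix, populations x samples.
#' @export
scoreMarkerMean <- function(expr, panels) {
  expr <- as.matrix(expr)
  if (is(panels, "SignatureCollection")) panels <- geneSets(panels)
  if (!length(panels)) stop("empty marker panel list")
  rows <- list()
  for (nm in names(panels)) {
    present <- intersect(panels[[nm]], rownames(expr))
    miss <- length(panels[[nm]]) - length(present)
    if (!length(present)) {
      warning("population '", nm, "' dropped: no marker present")
      next
    }
    if (miss > 0) message("population '", nm, "': ", miss, " markers absent")
    rows[[nm]] <- colMeans(expr[present, , drop = FALSE])
  }
  if (!length(rows)) stop("no population has markers in the matrix")
  do.call(rbind, rows)
}

#' Default tumor-purity cosine coefficients
#'
#' The (a, b) constants of the cosine purity transform published with the
#' ESTIMATE method, fitted on TCGA Affymetrix data; their transfer to
#' RNA-seq TPM is approximate, which is why they are explicit configuration
#' rather than silently applied.
#'
#' @return named numeric vector `c(a = ..., b = ...)`.
#' @export
estimatePurityCoeffs <- function() c(a = 0.6049872018, b = 0.0001467884)

#' Stromal/immune enrichment and tumor purity
#'
#' ESTIMATE-style decomposition: stromal and immune scores are unnormalised
#' ssGSEA enrichment scores (`alpha = 0.25`), their sum is the combined
#' estimate score, and tumor purity is `cos(a + b * estimate)` clipped to
#' [0, 1].
#'
#' @param expr numeric matrix, genes x samples, log-like scale.
#' @param stromal_set,immune_set character vectors of gene symbols.
#' @param purity_coeffs named vector `c(a=, b=)`; defaults to
#'   [estimatePurityCoeffs()]. Set to `NULL` to refuse purity computation.
#' @return data.frame with one row per sample: `stromal`, `immune`,
#'   `estimate`, `purity`.
#' @export
estimateScores <- function(expr, stromal_set, immune_set,
                           purity_coeffs = estimatePurityCoeffs()) {
  if (is.null(purity_coeffs))
    stop("purity requested without coefficients; pass purity_coeffs = c(a=, b=)")
  if (!all(c("a", "b") %in% names(purity_coeffs)))
    stop("purity_coeffs must be a named vector with elements 'a' and 'b'")
  sm <- scoreSsgsea(expr, list(stromal = stromal_set, immune = immune_set),
                    alpha = 0.25, normalize = FALSE)
  v <- scoreValues(sm)
  if (!all(c("stromal", "immune") %in% rownames(v)))
    stop("stromal or immune set unusable on this matrix")
  est <- v["stromal", ] + v["immune", ]
  purity <- cos(purity_coeffs[["a"]] + purity_coeffs[["b"]] * est)
  data.frame(sample_id = colnames(v),
             stromal = v["stromal", ], immune = v["immune", ],
             estimate = est,
             purity = pmin(1, pmax(0, purity)),
             row.names = colnames(v), stringsAsFactors = FALSE)
}
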