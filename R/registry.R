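# Registry binding the eight published deconvolution method names to the
# four native engines. The registry carries no third-party reference data:
# each entry documents which user-supplied resource it needs.

.method_registry <- list(
  cibersort = list(engine = "svr",
                   requires = "reference matrix (TSV, genes x cell types)",
                   citation = "Newman et al., Nat Methods 2015"),
  estimate  = list(engine = "enrichment_purity",
                   requires = "stromal + immune gene sets (GMT)",
                   citation = "Yoshihara et al., Nat Commun 2013"),
  quantiseq = list(engine = "constrained_ls",
                   requires = "reference matrix (TSV, genes x cell types)",
                   citation = "Finotello et al., Genome Med 2019"),
  timer     = list(engine = "constrained_ls",
                   requires = "reference matrix (TSV, genes x cell types)",
                   citation = "Li et al., Genome Biol 2016"),
  ips       = list(engine = "enrichment_purity",
                   requires = "immunophenotype gene sets (GMT)",
                   citation = "Charoentong et al., Cell Rep 2017"),
  mcpcounter = list(engine = "marker_mean",
                    requires = "marker panels (GMT, one population per line)",
                    citation = "Becht et al., Genome Biol 2016"),
  xcell     = list(engine = "enrichment_purity",
                   requires = "cell-type gene sets (GMT) + optional spillover matrix (square TSV)",
                   citation = "Aran et al., Genome Biol 2017"),
  epic      = list(engine = "constrained_ls",
                   requires = "reference matrix (TSV, genes x cell types)",
                   citation = "Racle et al., eLife 2017")
)

#' List the registered deconvolution methods
#'
#' The shipped registry exposes the eight published method ids, each bound
#' to one of the four native engines (`svr`, `constrained_ls`,
#' `marker_mean`, `enrichment_purity`) and to the reference resource it
#' requires. No third-party reference data ships with the package.
#'
#' @return data.frame with columns `method`, `engine`, `requires`,
#'   `citation`.
#' @examples
#' deconvMethods()
#' @export
deconvMethods <- function() {
  data.frame(
    method = names(.method_registry),
    engine = vapply(.method_registry, `[[`, "", "engine"),
    requires = vapply(.method_registry, `[[`, "", "requires"),
    citation = vapply(.method_registry, `[[`, "", "citation"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Run a registered deconvolution method
#'
#' Dispatches a method id to its engine with method-specific defaults:
#' `cibersort` fits nu-SVR over the default nu grid; `quantiseq` solves the
#' full-simplex constrained least squares; `epic` solves the bounded
#' variant with an `otherCells` remainder column; `timer` solves
#' non-negative least squares without a sum constraint; `mcpcounter`
#' computes marker-mean scores; `estimate` computes stromal/immune
#' enrichment plus cosine purity; `ips` and `xcell` compute per-set ssGSEA
#' enrichment, `xcell` optionally followed by linear spillover
#' compensation.
#'
#' @param method_id one of the ids in [deconvMethods()].
#' @param expr numeric matrix, genes x samples, on the scale the resource
#'   expects (linear for regression engines, log2 for enrichment/marker
#'   engines).
#' @param resources named list: `reference` ([ReferenceMatrix-class] or
#'   matrix), `panels` / `gene_sets` ([SignatureCollection-class] or named
#'   list), `stromal_set`, `immune_set`, `spillover` (square matrix),
#'   `purity_coeffs`.
#' @param ... passed to the engine (e.g. `nu_grid`, `n_perm`, `seed`,
#'   `alpha`).
#' @return A [CellFractionMatrix-class] (regression engines) or a score
#'   table (matrix / data.frame) for the others; fraction results carry
#'   the method id.
#' @export
runMethod <- function(method_id, expr, resources = list(), ...) {
  if (!method_id %in% names(.method_registry))
    stop("unknown method '", method_id, "'; valid ids: ",
         paste(names(.method_registry), collapse = ", "))
  need_ref <- function() {
    if (is.null(resources$reference))
      stop("method '", method_id, "' needs resources$reference: ",
           .method_registry[[method_id]]$requires)
    resources$reference
  }
  res <- switch(method_id,
    cibersort = deconvSVR(expr, need_ref(), ...),
    quantiseq = deconvLSEI(expr, need_ref(), sum_constraint = "equal", ...),
    epic      = deconvLSEI(expr, need_ref(), sum_constraint = "leq", ...),
    timer     = deconvLSEI(expr, need_ref(), sum_constraint = "none", ...),
    mcpcounter = {
      if (is.null(resources$panels))
        stop("method 'mcpcounter' needs resources$panels: ",
             .method_registry$mcpcounter$requires)
      scoreMarkerMean(expr, resources$panels)
    },
    estimate = {
      if (is.null(resources$stromal_set) || is.null(resources$immune_set))
        stop("method 'estimate' needs resources$stromal_set and resources$immune_set: ",
             .method_registry$estimate$requires)
      estimateScores(expr, resources$stromal_set, resources$immune_set,
                     purity_coeffs = if (is.null(resources$purity_coeffs))
                       estimatePurityCoeffs() else resources$purity_coeffs)
    },
    ips = {
      if (is.null(resources$gene_sets))
        stop("method 'ips' needs resources$gene_sets: ",
             .method_registry$ips$requires)
      scoreValues(scoreSsgsea(expr, resources$gene_sets, ...))
    },
    xcell = {
      if (is.null(resources$gene_sets))
        stop("method 'xcell' needs resources$gene_sets (GMT) and optionally ",
             "resources$spillover (square TSV): ",
             .method_registry$xcell$requires)
      sc <- scoreValues(scoreSsgsea(expr, resources$gene_sets, ...))
      if (!is.null(resources$spillover)) {
        K <- as.matrix(resources$spillover)
        shared <- intersect(rownames(sc), rownames(K))
        if (length(shared) < 2L)
          stop("spillover matrix does not match score rows")
        sc <- sc[shared, , drop = FALSE]
        sc <- solve(K[shared, shared, drop = FALSE], sc)
        sc[sc < 0] <- 0
      }
      sc
    })
  if (is(res, "CellFractionMatrix")) res@method <- method_id
  res
}
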