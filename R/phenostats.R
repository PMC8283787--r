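# Batch association of signature scores / cell fractions / genes with
# phenotypes. Every operation defines one multiple-testing family (the
# batch call) and reports Benjamini-Hochberg FDR alongside raw p-values.

# inner-join a features x samples matrix with a phenotype table
.align_samples <- function(m, pheno) {
  ids <- intersect(colnames(m), rownames(pheno))
  if (!length(ids)) stop("no sample id shared between scores and phenotype")
  dropped <- ncol(m) - length(ids)
  if (dropped > 0) message(dropped, " samples without phenotype dropped")
  list(m = m[, ids, drop = FALSE], pheno = pheno[ids, , drop = FALSE])
}

#' Batch group comparison of features
#'
#' Tests every feature (signature, cell fraction, gene) against a
#' categorical phenotype. Two groups: two-sided Wilcoxon rank-sum (exact
#' enumeration when both groups have at most 10 samples, tie-corrected
#' normal approximation otherwise), with the rank-biserial correlation as
#' effect size. More than two groups: Kruskal-Wallis, with all pairwise
#' Wilcoxon tests (BH-adjusted within each feature) attached as the
#' `"pairwise"` attribute. FDR is BH across features.
#'
#' @param scores [ScoreMatrix-class] or features x samples matrix.
#' @param pheno data.frame with rownames = sample ids and the grouping
#'   column, or a vector of group labels named by sample id.
#' @param group_col name of the grouping column (default `"group"`).
#' @return data.frame with `feature`, `statistic`, `p`, `fdr`, `effect`,
#'   `n_per_group`.
#' @export
batchCompare <- function(scores, pheno, group_col = "group") {
  m <- .score_input(scores)
  if (!is.data.frame(pheno))
    pheno <- data.frame(group = pheno, row.names = names(pheno))
  if (!group_col %in% colnames(pheno))
    stop("phenotype has no column '", group_col, "'")
  al <- .align_samples(m, pheno)
  g <- factor(al$pheno[[group_col]])
  keep <- !is.na(g)
  g <- droplevels(g[keep]); x <- al$m[, keep, drop = FALSE]
  if (nlevels(g) < 2L) stop("grouping needs at least 2 levels")
  sizes <- table(g)
  if (any(sizes < 2L))
    stop("every group needs >= 2 samples (offending: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "), ")")
  two <- nlevels(g) == 2L
  rows <- lapply(rownames(x), function(f) {
    v <- x[f, ]
    if (two) {
      rt <- ranksumTest(v[g == levels(g)[1L]], v[g == levels(g)[2L]])
      data.frame(feature = f, statistic = rt$statistic, p = rt$p,
                 effect = rt$effect, stringsAsFactors = FALSE)
    } else {
      kw <- stats::kruskal.test(v, g)
      data.frame(feature = f, statistic = unname(kw$statistic),
                 p = kw$p.value, effect = NA_real_, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$fdr <- .bh(out$p)
  out$n_per_group <- paste(sizes, collapse = "/")
  out <- out[, c("feature", "statistic", "p", "fdr", "effect", "n_per_group")]
  if (!two) {
    prs <- utils::combn(levels(g), 2L)
    pw <- do.call(rbind, lapply(rownames(x), function(f) {
      v <- x[f, ]
      p <- apply(prs, 2L, function(ab)
        ranksumTest(v[g == ab[1L]], v[g == ab[2L]])$p)
      data.frame(feature = f, group_a = prs[1L, ], group_b = prs[2L, ],
                 p = p, fdr = .bh(p), stringsAsFactors = FALSE)
    }))
    attr(out, "pairwise") <- pw
  }
  out
}

#' Batch correlation of features with a continuous target
#'
#' Pearson, Spearman or partial (Pearson given covariates) correlation of
#' every feature with a continuous target — e.g. a clinical covariate, or
#' one gene's expression row to find signatures tracking that gene. The
#' partial correlation of x and y given Z is the correlation of their
#' residuals after least-squares projection on `[1, Z]`. FDR is BH across
#' features; zero-variance features are dropped (with a message) by
#' default.
#'
#' @param scores [ScoreMatrix-class] or features x samples matrix.
#' @param target numeric vector, named by sample id (or in column order).
#' @param method `"pearson"`, `"spearman"` or `"partial"`.
#' @param covariates numeric matrix/data.frame (samples x covariates),
#'   required for `"partial"`.
#' @return data.frame with `feature`, `statistic`, `p`, `fdr`, `effect`
#'   (the correlation estimate), `n`.
#' @export
batchCorrelation <- function(scores, target,
                             method = c("pearson", "spearman", "partial"),
                             covariates = NULL) {
  method <- match.arg(method)
  m <- .score_input(scores)
  if (!is.null(names(target))) {
    ids <- intersect(colnames(m), names(target))
    if (!length(ids)) stop("no sample id shared between scores and target")
    if (!is.null(covariates)) {
      covariates <- as.matrix(covariates)
      idx <- if (!is.null(rownames(covariates))) ids
             else match(ids, colnames(m))
      covariates <- covariates[idx, , drop = FALSE]
    }
    m <- m[, ids, drop = FALSE]; target <- target[ids]
  } else if (length(target) != ncol(m)) {
    stop("target length must match the number of samples")
  }
  n <- ncol(m)
  k <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (n < 3L + k) stop("need at least ", 3L + k, " samples")
  if (method == "partial" && k == 0L)
    stop("partial correlation needs covariates")
  Z <- if (k > 0L) cbind(1, as.matrix(covariates)) else NULL
  rows <- lapply(rownames(m), function(f) {
    v <- m[f, ]
    if (stats::sd(v) == 0) {
      message("feature '", f, "' has zero variance; dropped")
      return(NULL)
    }
    if (method == "partial") {
      rx <- stats::lsfit(Z, v, intercept = FALSE)$residuals
      ry <- stats::lsfit(Z, target, intercept = FALSE)$residuals
      r <- stats::cor(rx, ry)
      df <- n - 2L - k
      tval <- r * sqrt(df / (1 - r^2))
      data.frame(feature = f, statistic = tval,
                 p = 2 * stats::pt(-abs(tval), df), effect = r, n = n,
                 stringsAsFactors = FALSE)
    } else {
      ct <- suppressWarnings(stats::cor.test(v, target, method = method))
      data.frame(feature = f, statistic = unname(ct$statistic),
                 p = ct$p.value, effect = unname(ct$estimate), n = n,
                 stringsAsFactors = FALSE)
    }
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) stop("no feature with variance")
  out <- do.call(rbind, rows)
  out$fdr <- .bh(out$p)
  out[, c("feature", "statistic", "p", "fdr", "effect", "n")]
}

#' Batch univariate Cox survival association
#'
#' Fits a univariate Cox proportional-hazards model (Efron tie handling,
#' Newton-Raphson on the partial likelihood, via \pkg{survival}) for every
#' feature. `mode = "continuous"` standardises the feature so the hazard
#' ratio is per standard deviation; `mode = "median_cut"` dichotomises at
#' the median (high vs low). Hazard ratios, Wald confidence intervals and
#' p-values are reported with BH FDR across features; non-converging fits
#' are flagged, not dropped.
#'
#' @param scores [ScoreMatrix-class] or features x samples matrix.
#' @param pheno data.frame with rownames = sample ids and columns `time`
#'   (positive) and `event` (0/1).
#' @param mode `"continuous"` (default) or `"median_cut"`.
#' @param min_events smallest allowed number of events (default 10).
#' @return data.frame with `feature`, `hr`, `ci_low`, `ci_high`, `p`,
#'   `fdr`, `converged`.
#' @export
batchSurvival <- function(scores, pheno, mode = c("continuous", "median_cut"),
                          min_events = 10L) {
  mode <- match.arg(mode)
  m <- .score_input(scores)
  if (!all(c("time", "event") %in% colnames(pheno)))
    stop("phenotype needs 'time' and 'event' columns")
  al <- .align_samples(m, pheno)
  time <- al$pheno$time; event <- al$pheno$event
  if (any(time <= 0)) stop("survival times must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  if (sum(event) == 0) stop("no events in the cohort")
  if (sum(event) < min_events)
    stop("only ", sum(event), " events (< min_events = ", min_events, ")")
  srv <- survival::Surv(time, event)
  rows <- lapply(rownames(al$m), function(f) {
    v <- al$m[f, ]
    x <- if (mode == "continuous") {
      s <- stats::sd(v)
      if (s == 0) return(data.frame(feature = f, hr = NA_real_,
                                    ci_low = NA_real_, ci_high = NA_real_,
                                    p = NA_real_, converged = FALSE,
                                    stringsAsFactors = FALSE))
      (v - mean(v)) / s
    } else {
      as.numeric(v > stats::median(v))
    }
    fit <- tryCatch(survival::coxph(srv ~ x, ties = "efron"),
                    warning = function(w) NULL, error = function(e) NULL)
    if (is.null(fit) || !is.finite(stats::coef(fit)))
      return(data.frame(feature = f, hr = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p = NA_real_, converged = FALSE,
                        stringsAsFactors = FALSE))
    sm <- summary(fit)
    data.frame(feature = f,
               hr = unname(sm$conf.int[1L, "exp(coef)"]),
               ci_low = unname(sm$conf.int[1L, "lower .95"]),
               ci_high = unname(sm$conf.int[1L, "upper .95"]),
               p = unname(sm$coefficients[1L, "Pr(>|z|)"]),
               converged = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- NA_real_
  ok <- !is.na(out$p)
  out$fdr[ok] <- .bh(out$p[ok])
  out[, c("feature", "hr", "ci_low", "ci_high", "p", "fdr", "converged")]
}

# AUC by the rank formula (Mann-Whitney U / n1 n0, midranks for ties)
.auc_rank <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive); n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Batch ROC analysis of features against a binary outcome
#'
#' AUC for every feature by the rank (Mann-Whitney) formula with midrank
#' tie handling. Features whose raw AUC is below 0.5 are reported as
#' `1 - AUC` with an explicit `inverted` flag (never silently). DeLong
#' confidence intervals accompany each AUC, and `compare = TRUE` adds all
#' pairwise DeLong tests (BH-adjusted) as the `"pairwise"` attribute.
#' Results are sorted by AUC, descending.
#'
#' @param scores [ScoreMatrix-class] or features x samples matrix.
#' @param pheno data.frame (rownames = sample ids) with the binary
#'   grouping column, or a vector named by sample id.
#' @param group_col grouping column name (default `"group"`).
#' @param positive which level counts as positive; defaults to the second
#'   factor level.
#' @param compare add all-pairs DeLong comparisons (default FALSE).
#' @return data.frame with `feature`, `auc`, `ci_low`, `ci_high`,
#'   `inverted`; optionally attribute `"pairwise"` with `feature_a`,
#'   `feature_b`, `delta_auc`, `p`, `fdr`.
#' @export
sigROC <- function(scores, pheno, group_col = "group", positive = NULL,
                   compare = FALSE) {
  m <- .score_input(scores)
  if (!is.data.frame(pheno))
    pheno <- data.frame(group = pheno, row.names = names(pheno))
  al <- .align_samples(m, pheno)
  g <- factor(al$pheno[[group_col]])
  if (nlevels(g) != 2L) stop("ROC needs exactly 2 outcome levels")
  if (any(table(g) == 0L)) stop("one outcome class is empty")
  if (is.null(positive)) positive <- levels(g)[2L]
  pos <- g == positive
  x <- al$m
  rows <- lapply(rownames(x), function(f) {
    v <- x[f, ]
    a <- .auc_rank(v, pos)
    inverted <- a < 0.5
    vo <- if (inverted) -v else v
    ci <- tryCatch({
      ro <- pROC::roc(response = pos, predictor = vo, direction = "<",
                      levels = c(FALSE, TRUE), quiet = TRUE)
      # a degenerate (AUC = 1) curve yields the trivial 1-1 interval; the
      # accompanying pROC warning adds nothing in batch mode
      suppressWarnings(as.numeric(pROC::ci.auc(ro, method = "delong")))
    }, error = function(e) c(NA_real_, NA_real_, NA_real_))
    data.frame(feature = f, auc = if (inverted) 1 - a else a,
               ci_low = ci[1L], ci_high = ci[3L], inverted = inverted,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$auc, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  if (compare && nrow(out) > 1L) {
    rocs <- lapply(rownames(x), function(f) {
      v <- x[f, ]
      if (.auc_rank(v, pos) < 0.5) v <- -v
      pROC::roc(response = pos, predictor = v, direction = "<",
                levels = c(FALSE, TRUE), quiet = TRUE)
    })
    names(rocs) <- rownames(x)
    prs <- utils::combn(rownames(x), 2L)
    pw <- do.call(rbind, lapply(seq_len(ncol(prs)), function(i) {
      a <- prs[1L, i]; b <- prs[2L, i]
      p <- if (a == b) 1 else tryCatch(
        pROC::roc.test(rocs[[a]], rocs[[b]], method = "delong",
                       paired = TRUE)$p.value,
        error = function(e) NA_real_)
      data.frame(feature_a = a, feature_b = b,
                 delta_auc = as.numeric(pROC::auc(rocs[[a]])) -
                             as.numeric(pROC::auc(rocs[[b]])),
                 p = p, stringsAsFactors = FALSE)
    }))
    pw$fdr <- .bh(pw$p)
    attr(out, "pairwise") <- pw
  }
  out
}

#' Batch association of expression rows with a target
#'
#' Thin router: a categorical target sends the expression rows through
#' [batchCompare()], a continuous target through [batchCorrelation()].
#' Survival outcomes are refused with a pointer to [batchSurvival()].
#'
#' @param expr numeric matrix, genes x samples.
#' @param target vector named by sample id (factor/character = groups,
#'   numeric = continuous), or a data.frame — if it carries `time`/`event`
#'   columns an error directs to the survival routine.
#' @param ... passed through to the routed operation.
#' @return as the routed operation.
#' @export
geneLevelBatch <- function(expr, target, ...) {
  if (is.data.frame(target) && all(c("time", "event") %in% colnames(target)))
    stop("survival outcome detected: use batchSurvival()")
  if (is.numeric(target) && !is.factor(target))
    batchCorrelation(expr, target, ...)
  else
    batchCompare(expr, target, ...)
}
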