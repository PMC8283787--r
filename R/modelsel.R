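# Sparse risk-model construction: univariate screen -> bootstrap-stabilised
# L1 selection -> unpenalised refit. The L1 fits are glmnet coordinate
# descent (logistic or Cox), with the penalty chosen per resample by
# cross-validation.

.outcome_kind <- function(pheno) {
  if (all(c("time", "event") %in% colnames(pheno))) return("survival")
  if ("group" %in% colnames(pheno)) {
    if (length(unique(stats::na.omit(pheno$group))) != 2L)
      stop("binary screening needs exactly 2 outcome levels")
    return("binary")
  }
  stop("phenotype has neither a 'group' column nor 'time'/'event' columns")
}

#' Univariate feature screening
#'
#' Routes each feature through [batchCompare()] (binary outcome) or
#' [batchSurvival()] (survival outcome) and flags features with
#' FDR at most `max_fdr` as candidates for model construction.
#'
#' @param scores [ScoreMatrix-class] or features x samples matrix.
#' @param pheno data.frame (rownames = sample ids) with either a 2-level
#'   `group` column or `time`/`event` columns.
#' @param max_fdr candidate threshold (default 0.05).
#' @param ... passed to the routed batch operation.
#' @return data.frame with `feature`, `univariate_p`, `univariate_fdr`,
#'   `candidate`.
#' @export
univariateScreen <- function(scores, pheno, max_fdr = 0.05, ...) {
  kind <- .outcome_kind(pheno)
  res <- if (kind == "binary") batchCompare(scores, pheno, ...)
         else batchSurvival(scores, pheno, ...)
  out <- data.frame(feature = res$feature, univariate_p = res$p,
                    univariate_fdr = res$fdr, stringsAsFactors = FALSE)
  out$candidate <- !is.na(out$univariate_fdr) & out$univariate_fdr <= max_fdr
  attr(out, "outcome") <- kind
  out
}

#' Bootstrap-stabilised L1 feature selection
#'
#' For each of `B` bootstrap resamples an L1-penalised model (logistic for
#' binary outcomes, Cox for survival) is fitted on the candidate features,
#' with the penalty chosen by cross-validation within the resample (1-SE
#' rule, favouring sparse stable supports). A
#' feature's `boot_freq` is the fraction of resamples in which its
#' coefficient is nonzero; features with `boot_freq` at or above the
#' stability threshold enter an unpenalised refit whose coefficients are
#' the final weights.
#'
#' @param scores [ScoreMatrix-class] or features x samples matrix.
#' @param pheno phenotype data.frame as in [univariateScreen()].
#' @param candidates character vector of candidate feature ids.
#' @param B number of bootstrap resamples (default 200; `B = 1` is allowed
#'   but warned about).
#' @param stability selection threshold on `boot_freq` (default 0.7).
#' @param seed optional seed making the whole selection reproducible.
#' @return data.frame with `feature`, `boot_freq`, `selected`,
#'   `final_weight` (0 for unselected features).
#' @export
bootstrapSelect <- function(scores, pheno, candidates, B = 200L,
                            stability = 0.7, seed = NULL) {
  m <- .score_input(scores)
  missing <- setdiff(candidates, rownames(m))
  if (length(missing))
    stop("candidate feature(s) not in the score matrix: ",
         paste(missing, collapse = ", "))
  kind <- .outcome_kind(pheno)
  al <- .align_samples(m[candidates, , drop = FALSE], pheno)
  X <- t(al$m)
  n <- nrow(X)
  if (B < 1L) stop("B must be >= 1")
  if (B == 1L) warning("B = 1 gives a degenerate stability estimate")
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  if (kind == "binary") {
    y <- factor(al$pheno$group)
    ok_draw <- function(idx) nlevels(droplevels(y[idx])) == 2L
  } else {
    y <- survival::Surv(al$pheno$time, al$pheno$event)
    ok_draw <- function(idx) sum(al$pheno$event[idx]) >= 2L
  }
  if (length(candidates) == 1L) {
    warning("single candidate: selection skipped, weight from univariate fit")
    w <- .refit_weights(X, al$pheno, kind, candidates)
    return(data.frame(feature = candidates, boot_freq = 1, selected = TRUE,
                      final_weight = unname(w), stringsAsFactors = FALSE))
  }
  family <- if (kind == "binary") "binomial" else "cox"
  hits <- stats::setNames(numeric(length(candidates)), candidates)
  for (b in seq_len(B)) {
    idx <- NULL
    for (try in 1:5) {
      cand_idx <- sample.int(n, n, replace = TRUE)
      if (ok_draw(cand_idx)) { idx <- cand_idx; break }
    }
    if (is.null(idx)) stop("could not draw a non-degenerate resample in 5 attempts")
    yb <- if (kind == "binary") y[idx] else y[idx, ]
    cvfit <- glmnet::cv.glmnet(X[idx, , drop = FALSE], yb, family = family,
                               nfolds = 5L)
    co <- stats::coef(cvfit, s = "lambda.1se")   # 1-SE rule: sparser, stabler
    nz <- rownames(co)[as.vector(co != 0)]
    hits[intersect(nz, candidates)] <- hits[intersect(nz, candidates)] + 1
  }
  freq <- hits / B
  selected <- freq >= stability
  weights <- stats::setNames(numeric(length(candidates)), candidates)
  if (any(selected))
    weights[names(which(selected))] <-
      .refit_weights(X[, selected, drop = FALSE], al$pheno, kind,
                     names(which(selected)))
  data.frame(feature = candidates, boot_freq = unname(freq),
             selected = unname(selected), final_weight = unname(weights),
             stringsAsFactors = FALSE)
}

.refit_weights <- function(X, pheno, kind, features) {
  df <- as.data.frame(X)
  colnames(df) <- make.names(features)
  if (kind == "binary") {
    df$.y <- factor(pheno$group)
    fit <- stats::glm(.y ~ ., data = df, family = stats::binomial())
    co <- stats::coef(fit)[-1L]
  } else {
    srv <- survival::Surv(pheno$time, pheno$event)
    fit <- survival::coxph(srv ~ ., data = df)
    co <- stats::coef(fit)
  }
  stats::setNames(unname(co), features)
}

#' Linear risk score
#'
#' `score_j = sum_i w_i x_ij` over the weighted features. Every weighted
#' feature must be present in the score matrix — missing features are an
#' error, never silently zero-filled.
#'
#' @param weights named numeric vector of feature weights.
#' @param scores [ScoreMatrix-class] or features x samples matrix.
#' @return named numeric vector, one risk score per sample.
#' @export
riskScore <- function(weights, scores) {
  m <- .score_input(scores)
  missing <- setdiff(names(weights), rownames(m))
  if (length(missing))
    stop("feature(s) missing from the score matrix: ",
         paste(missing, collapse = ", "))
  drop(weights %*% m[names(weights), , drop = FALSE])
}
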