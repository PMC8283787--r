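# Independent oracles used across the suite. Each re-derives a quantity by
# a route different from the package implementation (naive enumeration,
# grid search, closed forms) so agreement is informative.

# AUC by brute-force pair counting (ties count one half)
oracle_auc <- function(score, positive) {
  pos <- score[positive]; neg <- score[!positive]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# one-covariate partial correlation, closed form
oracle_partial_r <- function(x, y, z) {
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

# naive ssGSEA running sum, written as an explicit walk over the ranked
# list (no vectorised cumsums)
oracle_ssgsea <- function(x, set, alpha) {
  genes <- names(x)
  ord <- genes[order(-x, genes)]
  n <- length(ord)
  rv <- n:1
  denom_in <- sum(rv[ord %in% set]^alpha)
  n_out <- sum(!ord %in% set)
  score <- 0; acc_in <- 0; acc_out <- 0
  for (i in seq_len(n)) {
    if (ord[i] %in% set) acc_in <- acc_in + rv[i]^alpha
    else acc_out <- acc_out + 1
    score <- score + acc_in / denom_in - acc_out / n_out
  }
  score
}

# simplex grid search for 2-type least squares, with local refinement
oracle_lsei_2type <- function(S, m, step = 1e-3) {
  rss <- function(t) sum((S %*% c(t, 1 - t) - m)^2)
  grid <- seq(0, 1, by = step)
  t0 <- grid[which.min(vapply(grid, rss, 1))]
  opt <- optimize(rss, c(max(0, t0 - step), min(1, t0 + step)), tol = 1e-12)
  c(opt$minimum, 1 - opt$minimum)
}

# coarse simplex grid search for 3 types (barycentric grid + refinement)
oracle_lsei_3type <- function(S, m, step = 5e-3) {
  best <- NULL; best_rss <- Inf
  for (a in seq(0, 1, by = step)) for (b in seq(0, 1 - a, by = step)) {
    f <- c(a, b, 1 - a - b)
    r <- sum((S %*% f - m)^2)
    if (r < best_rss) { best_rss <- r; best <- f }
  }
  # local refinement around the grid optimum
  obj <- function(p) {
    f <- c(p, 1 - sum(p))
    if (any(f < 0)) return(1e9)
    sum((S %*% f - m)^2)
  }
  opt <- optim(best[1:2], obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  c(opt$par, 1 - sum(opt$par))
}

# Monte-Carlo permutation rank-sum p (two-sided around the mean), used as
# an oracle in the presence of ties where wilcox.test abandons exactness
oracle_ranksum_perm <- function(x, y, n_perm = 40000, seed = 11) {
  set.seed(seed)
  n1 <- length(x); v <- c(x, y); r <- rank(v)
  mu <- n1 * (length(v) + 1) / 2
  obs <- abs(sum(r[seq_len(n1)]) - mu)
  hits <- replicate(n_perm, abs(sum(sample(r, n1)) - mu) >= obs - 1e-9)
  mean(hits)
}

# hand-written Cox log partial likelihood for an untied, uncensored sample
# with a single covariate; 1-D maximisation is the oracle for the fit
oracle_cox_loglik <- function(beta, time, x) {
  ord <- order(time)
  x <- x[ord]
  ll <- 0
  for (i in seq_along(x)) {
    risk <- x[i:length(x)]
    ll <- ll + beta * x[i] - log(sum(exp(beta * risk)))
  }
  ll
}

# shared small fixtures ------------------------------------------------

toy_expr <- function(n_genes = 30, n_samples = 12, seed = 42) {
  set.seed(seed)
  m <- matrix(2^rnorm(n_genes * n_samples, 4, 1), n_genes, n_samples,
              dimnames = list(sprintf("g%02d", 1:n_genes),
                              sprintf("s%02d", 1:n_samples)))
  log2(m + 1)
}

toy_maf_path <- function()
  system.file("extdata", "toy_synthetic.maf", package = "tmekit")
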