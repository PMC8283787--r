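test_that("exact rank-sum branch matches enumeration and handles ties", {
  rt <- ranksumTest(c(1, 2, 3), c(4, 5, 6))
  expect_true(rt$exact)
  expect_equal(rt$p, 0.1, tolerance = 1e-12)     # 2 extreme of 20 assignments
  # degenerate ties
  expect_equal(ranksumTest(c(2, 2, 2), c(2, 2, 2))$p, 1)
  # tie-free small samples agree with wilcox.test's exact distribution
  set.seed(51)
  for (rep in 1:15) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    expect_equal(ranksumTest(x, y)$p,
                 wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-10)
  }
  # tied small samples agree with the Monte-Carlo permutation oracle
  for (rep in 1:5) {
    x <- sample(1:4, 7, replace = TRUE)
    y <- sample(1:4, 6, replace = TRUE)
    expect_lt(abs(ranksumTest(x, y)$p - oracle_ranksum_perm(x, y)), 0.02)
  }
  # large-sample approximation close to the exact answer at the boundary
  x <- rnorm(11); y <- rnorm(11)
  expect_false(ranksumTest(x, y)$exact)
  expect_lt(abs(ranksumTest(x, y)$p -
                wilcox.test(x, y, exact = TRUE)$p.value), 0.02)
})

test_that("batchCompare routes two-group and multi-group designs", {
  m <- toy_expr(6, 12)
  grp <- setNames(rep(c("A", "B"), each = 6), colnames(m))
  res <- batchCompare(m, grp)
  expect_equal(nrow(res), 6)
  expect_true(all(res$fdr >= res$p - 1e-12))
  expect_equal(res$n_per_group[1], "6/6")
  # BH is p.adjust
  expect_equal(res$fdr, p.adjust(res$p, "BH"))

  g3 <- setNames(rep(c("A", "B", "C"), each = 4), colnames(m))
  res3 <- batchCompare(m, g3)
  expect_equal(nrow(res3), 6)                       # one KW row per feature
  pw <- attr(res3, "pairwise")
  expect_equal(nrow(pw), 6 * 3)
  # KW statistic matches stats::kruskal.test
  kw <- kruskal.test(m[2, ], factor(g3))
  expect_equal(res3$statistic[2], unname(kw$statistic), tolerance = 1e-12)
  expect_equal(res3$p[2], kw$p.value, tolerance = 1e-12)

  expect_error(batchCompare(m, setNames(rep("A", 12), colnames(m))), "2 levels")
  expect_error(batchCompare(m, setNames(rep("x", 3), c("q1", "q2", "q3"))),
               "no sample id shared")
})

test_that("batchCorrelation matches closed forms and is rank-invariant", {
  set.seed(52)
  n <- 30
  x <- rnorm(n)
  m <- rbind(f1 = x, f2 = rnorm(n), f3 = 2 * x + 1)
  colnames(m) <- paste0("s", 1:n)
  y <- setNames(2 * x + 1, colnames(m))
  res <- batchCompare_dummy <- batchCorrelation(m, y, method = "pearson")
  expect_equal(res$effect[res$feature == "f3"], 1, tolerance = 1e-12)
  expect_equal(res$effect[res$feature == "f1"], 1, tolerance = 1e-12)

  # partial correlation equals the one-covariate closed form
  z <- x + rnorm(n, 0, 0.5)
  pres <- batchCorrelation(m, y, method = "partial",
                           covariates = matrix(z, ncol = 1))
  for (f in rownames(m))
    expect_equal(pres$effect[pres$feature == f],
                 oracle_partial_r(m[f, ], y, z), tolerance = 1e-10)

  # spearman rows unchanged by monotone transform of the target
  sp1 <- batchCorrelation(m, y, method = "spearman")
  sp2 <- batchCorrelation(m, exp(y / 4), method = "spearman")
  expect_equal(sp1$effect, sp2$effect, tolerance = 1e-12)

  flat <- rbind(m, f4 = rep(1, n))
  expect_message(dres <- batchCorrelation(flat, y), "zero variance")
  expect_false("f4" %in% dres$feature)
})

test_that("Cox fit matches the 1-D partial-likelihood oracle", {
  set.seed(53)
  n <- 40
  x <- rep(c(0, 1), each = n / 2)
  t_ev <- rexp(n, exp(0.8 * x))
  t_ev <- t_ev + seq_len(n) * 1e-9          # guarantee no ties
  fit <- survival::coxph(survival::Surv(t_ev, rep(1, n)) ~ x, ties = "efron")
  beta_oracle <- optimize(function(b) oracle_cox_loglik(b, t_ev, x),
                          c(-4, 4), maximum = TRUE)$maximum
  expect_equal(unname(coef(fit)), beta_oracle, tolerance = 1e-4)

  # batchSurvival reproduces the same univariate fit (median_cut on x)
  m <- matrix(x, 1, n, dimnames = list("f", paste0("s", 1:n)))
  ph <- data.frame(time = t_ev, event = rep(1, n),
                   row.names = paste0("s", 1:n))
  bs <- batchSurvival(m, ph, mode = "median_cut")
  expect_equal(log(bs$hr), beta_oracle, tolerance = 1e-4)
})

test_that("batchSurvival recovers planted hazards and validates input", {
  set.seed(54)
  n <- 400
  s <- rnorm(n)
  names(s) <- paste0("p", 1:n)
  ph <- simPhenotype(s, beta = 0.7, outcome = "survival", seed = 55)
  m <- rbind(signal = s, noise = setNames(rnorm(n), names(s)))
  res <- batchSurvival(m, ph, mode = "continuous")
  expect_lt(abs(log(res$hr[res$feature == "signal"]) - 0.7), 0.15)
  expect_lt(abs(log(res$hr[res$feature == "noise"])), 0.2)
  expect_true(all(res$ci_low <= res$hr & res$hr <= res$ci_high))
  expect_true(all(res$hr > 0))

  ph0 <- ph; ph0$event <- 0
  expect_error(batchSurvival(m, ph0), "no events")
  ph2 <- ph; ph2$event[-(1:5)] <- 0
  expect_error(batchSurvival(m, ph2), "min_events")
})

test_that("AUC equals the brute-force pair oracle and orientation is explicit", {
  set.seed(56)
  for (rep in 1:10) {
    n <- sample(10:30, 1)
    sc <- sample(1:6, n, replace = TRUE)        # plenty of ties
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (sum(pos) == 0 || sum(!pos) == 0) next
    expect_equal(tmekit:::.auc_rank(sc, pos), oracle_auc(sc, pos),
                 tolerance = 1e-12)
  }
  m <- matrix(c(1:10, 10:1), 2, 10, byrow = TRUE,
              dimnames = list(c("up", "down"), paste0("s", 1:10)))
  grp <- setNames(rep(c("neg", "pos"), each = 5), colnames(m))
  res <- sigROC(m, grp)
  expect_equal(res$auc, c(1, 1))               # perfect separators both ways
  expect_equal(res$inverted[res$feature == "down"], TRUE)
  expect_equal(res$inverted[res$feature == "up"], FALSE)
  expect_true(all(res$auc >= 0.5))
  expect_equal(res$auc, sort(res$auc, decreasing = TRUE))
})

test_that("DeLong comparisons include the self-comparison identity", {
  set.seed(57)
  n <- 40
  grp <- setNames(rep(c("a", "b"), each = n / 2), paste0("s", 1:n))
  sig <- c(rnorm(n / 2), rnorm(n / 2, 1.5))
  m <- rbind(f1 = sig, f1copy = sig, f2 = rnorm(n))
  colnames(m) <- names(grp)
  res <- sigROC(m, grp, compare = TRUE)
  pw <- attr(res, "pairwise")
  expect_false(is.null(pw))
  self_like <- pw[pw$feature_a == "f1" & pw$feature_b == "f1copy", ]
  expect_equal(self_like$delta_auc, 0, tolerance = 1e-12)
  expect_true(all(pw$fdr >= pw$p - 1e-12))
  expect_error(sigROC(m, setNames(rep("a", n), colnames(m))), "2 outcome levels")
})

test_that("geneLevelBatch routes by target type", {
  m <- toy_expr(4, 10)
  bin <- setNames(rep(c("A", "B"), each = 5), colnames(m))
  expect_equal(colnames(geneLevelBatch(m, bin))[1], "feature")
  num <- setNames(rnorm(10), colnames(m))
  expect_true("effect" %in% colnames(geneLevelBatch(m, num)))
  surv_df <- data.frame(time = 1:10, event = rep(1, 10))
  expect_error(geneLevelBatch(m, surv_df), "batchSurvival")
})
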