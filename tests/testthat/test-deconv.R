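test_that("LSEI recovers exact mixtures against the grid-search oracle", {
  set.seed(30)
  S <- matrix(2^rnorm(40 * 2, 4, 1), 40, 2,
              dimnames = list(paste0("g", 1:40), c("t1", "t2")))
  m <- S %*% c(0.3, 0.7)
  rownames(m) <- rownames(S); colnames(m) <- "mix"
  est <- fractions(deconvLSEI(m, S))[, 1]
  expect_equal(unname(est), c(0.3, 0.7), tolerance = 1e-6)
  expect_equal(unname(est), oracle_lsei_2type(S, m), tolerance = 1e-6)

  # 3-type problem vs barycentric grid + refinement oracle
  S3 <- matrix(2^rnorm(60 * 3, 4, 1), 60, 3,
               dimnames = list(paste0("g", 1:60), c("a", "b", "c")))
  f3 <- c(0.2, 0.35, 0.45)
  m3 <- S3 %*% f3; colnames(m3) <- "mix"
  est3 <- fractions(deconvLSEI(m3, S3))[, 1]
  expect_equal(unname(est3), f3, tolerance = 1e-6)
  expect_equal(unname(est3), oracle_lsei_3type(S3, m3), tolerance = 1e-4)

  # exact basis match
  m2 <- S[, 2, drop = FALSE]; colnames(m2) <- "mix"
  expect_equal(unname(fractions(deconvLSEI(m2, S))[, 1]), c(0, 1),
               tolerance = 1e-8)
})

test_that("LSEI output satisfies constraints and intersection semantics", {
  ref <- simReference(seed = 3)
  f <- simFractions(8, 5, seed = 4)
  m <- simMixtures(ref, f, noise_sd = 2, seed = 5)
  res <- deconvLSEI(m, ref)
  fr <- fractions(res)
  expect_true(all(fr >= 0))
  expect_equal(unname(colSums(fr)), rep(1, 8), tolerance = 1e-6)
  # extra mixture genes absent from the reference change nothing
  extra <- rbind(m, matrix(50, 5, 8,
                           dimnames = list(paste0("alien", 1:5), colnames(m))))
  expect_equal(fractions(deconvLSEI(extra, ref)), fr, tolerance = 1e-10)
  # permuting reference columns permutes rows identically
  S <- refMatrix(ref)
  perm <- c(3, 1, 5, 2, 4)
  fr2 <- fractions(deconvLSEI(m, S[, perm]))
  expect_equal(fr2, fr[perm, ], tolerance = 1e-8)
  expect_error(deconvLSEI(m[1:3, ], ref), "shared genes")
})

test_that("LSEI sum-constraint variants: bounded (epic-like) and none (timer-like)", {
  ref <- simReference(seed = 6)
  S <- refMatrix(ref)
  # mixture with only 60% explained by the reference
  f <- simFractions(5, 5, seed = 7) * 0.6
  m <- S %*% f
  res <- deconvLSEI(m, ref, sum_constraint = "leq")
  fr <- fractions(res)
  expect_true("otherCells" %in% rownames(fr))
  expect_equal(unname(colSums(fr)), rep(1, 5), tolerance = 1e-6)
  expect_equal(unname(fr["otherCells", ]), rep(0.4, 5), tolerance = 1e-4)
  resn <- deconvLSEI(m, ref, sum_constraint = "none")
  expect_false(resn@constrained)
  expect_equal(unname(colSums(fractions(resn))), rep(0.6, 5), tolerance = 1e-4)
})

test_that("SVR deconvolution recovers dominant and mixed compositions", {
  ref <- simReference(seed = 7)
  S <- refMatrix(ref)
  # mixture = column 3 plus mild noise: type 3 dominates
  set.seed(8)
  m <- S[, 3] + rnorm(nrow(S), 0, 0.05)
  m <- matrix(pmax(m, 0), ncol = 1, dimnames = list(rownames(S), "mix"))
  est <- fractions(deconvSVR(m, ref))
  expect_gte(est["cellType3", 1], 0.9)

  f <- simFractions(10, 5, seed = 9)
  mm <- simMixtures(ref, f, noise_sd = 0)
  res <- deconvSVR(mm, ref)
  pr <- vapply(1:10, function(j) cor(f[, j], fractions(res)[, j]), 1)
  expect_true(all(pr >= 0.95))
  # fractions are simplex-constrained; fit stats present
  expect_true(all(fractions(res) >= 0))
  expect_equal(unname(colSums(fractions(res))), rep(1, 10), tolerance = 1e-6)
  expect_false("perm_p" %in% colnames(fitStats(res)))   # n_perm = 0
})

test_that("SVR permutation p-values are present, bounded and deterministic", {
  ref <- simReference(n_genes = 100, seed = 10)
  f <- simFractions(2, 5, seed = 11)
  m <- simMixtures(ref, f, noise_sd = 0.05, seed = 12)
  r1 <- deconvSVR(m, ref, n_perm = 25, seed = 99)
  r2 <- deconvSVR(m, ref, n_perm = 25, seed = 99)
  expect_true(all(fitStats(r1)$perm_p >= 0 & fitStats(r1)$perm_p <= 1))
  expect_identical(fitStats(r1), fitStats(r2))
  # structured mixtures should beat their permutations
  expect_true(all(fitStats(r1)$perm_p <= 0.1))
  expect_error(deconvSVR(m[1:10, ], ref), "shared")
})

test_that("SVR and LSEI agree on clean well-conditioned mixtures", {
  ref <- simReference(seed = 13)
  f <- simFractions(6, 5, seed = 14)
  m <- simMixtures(ref, f, noise_sd = 0)
  a <- fractions(deconvSVR(m, ref))
  b <- fractions(deconvLSEI(m, ref))
  expect_lt(mean(abs(a - b)), 0.05)
})

test_that("marker-mean scores follow log2 shifts and monotone dominance", {
  panel <- list(pop1 = c("m1", "m2", "m3"))
  ex <- matrix(log2(c(2^5, 2^5, 2^5, 2^6, 2^6, 2^6)), 3, 2,
               dimnames = list(c("m1", "m2", "m3"), c("A", "B")))
  sc <- scoreMarkerMean(ex, panel)
  expect_equal(unname(sc["pop1", ]), c(5, 6))        # constant 2^c -> c
  # doubling linear expression adds exactly 1
  expect_equal(unname(scoreMarkerMean(ex + 1, panel)["pop1", ]),
               unname(sc["pop1", ]) + 1)
  expect_true(sc["pop1", "B"] > sc["pop1", "A"])     # dominance
  expect_warning(
    sc2 <- scoreMarkerMean(ex, list(pop1 = "m1", ghost = "zz")),
    "dropped")
  expect_equal(rownames(sc2), "pop1")
})

test_that("estimate scores decompose into stromal + immune and cosine purity", {
  ex <- toy_expr(40, 6)
  stromal <- rownames(ex)[1:6]; immune <- rownames(ex)[7:12]
  res <- estimateScores(ex, stromal, immune)
  expect_equal(res$estimate, res$stromal + res$immune, tolerance = 1e-12)
  expect_true(all(res$purity >= 0 & res$purity <= 1))
  # estimate score of -a/b maps to purity cos(0) = 1
  co <- estimatePurityCoeffs()
  expect_equal(cos(co[["a"]] + co[["b"]] * (-co[["a"]] / co[["b"]])), 1)
  expect_error(estimateScores(ex, stromal, immune, purity_coeffs = NULL),
               "purity")

  # planted immune upregulation raises the immune score
  ex2 <- ex
  ex2[immune, 1] <- ex2[immune, 1] + 4
  res2 <- estimateScores(ex2, stromal, immune)
  expect_gt(res2$immune[1], res2$immune[2])
})

test_that("the registry exposes eight methods bound to four engines", {
  reg <- deconvMethods()
  expect_setequal(reg$method, c("cibersort", "estimate", "quantiseq", "timer",
                                "ips", "mcpcounter", "xcell", "epic"))
  expect_equal(nrow(reg), 8)
  expect_true(all(reg$engine %in% c("svr", "constrained_ls", "marker_mean",
                                    "enrichment_purity")))
  expect_error(runMethod("foo", matrix(1)), "cibersort")
})

test_that("runMethod dispatches engines with method-specific defaults", {
  ref <- simReference(n_genes = 100, seed = 15)
  f <- simFractions(4, 5, seed = 16)
  m <- simMixtures(ref, f, noise_sd = 0)
  cf <- runMethod("cibersort", m, list(reference = ref))
  expect_s4_class(cf, "CellFractionMatrix")
  expect_true(cf@constrained)
  expect_equal(cf@method, "cibersort")
  qf <- runMethod("quantiseq", m, list(reference = ref))
  expect_equal(unname(colSums(fractions(qf))), rep(1, 4), tolerance = 1e-6)
  tf <- runMethod("timer", m, list(reference = ref))
  expect_false(tf@constrained)
  ef <- runMethod("epic", m, list(reference = ref))
  expect_true("otherCells" %in% rownames(fractions(ef)))

  lg <- log2(m + 1)
  panels <- list(p1 = rownames(m)[1:5], p2 = rownames(m)[21:25])
  mc <- runMethod("mcpcounter", lg, list(panels = panels))
  expect_equal(rownames(mc), c("p1", "p2"))
  expect_error(runMethod("mcpcounter", lg, list()), "panels")
  expect_error(runMethod("xcell", lg, list()), "gene-set|gene_sets|GMT")
  xs <- runMethod("xcell", lg,
                  list(gene_sets = list(a = rownames(m)[1:5],
                                        b = rownames(m)[30:40])))
  expect_equal(rownames(xs), c("a", "b"))
  es <- runMethod("estimate", lg,
                  list(stromal_set = rownames(m)[1:6],
                       immune_set = rownames(m)[10:16]))
  expect_true(all(c("stromal", "immune", "estimate", "purity") %in% colnames(es)))
})
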