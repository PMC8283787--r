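test_that("readGMT parses, deduplicates and validates", {
  p <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("SetA\tTME\tG1\tG2", "SetB\t\tG1\tG1\tG2"), p)
  sc <- readGMT(p)
  expect_s4_class(sc, "SignatureCollection")
  expect_equal(signatureNames(sc), c("SetA", "SetB"))
  expect_equal(sc[["SetA"]], c("G1", "G2"))
  expect_length(sc[["SetB"]], 2)                       # dedup within line
  expect_equal(signatureGroups(sc), list(TME = "SetA")) # empty cat dropped

  p2 <- withr::local_tempfile(fileext = ".gmt")
  writeLines("SetC\tdesc", p2)
  expect_error(readGMT(p2), "line 1")
  p3 <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S\tx\tG1\tG2", "S\tx\tG3\tG4"), p3)
  expect_error(readGMT(p3), "duplicate set names")
})

test_that("GMT round trip preserves the collection", {
  sc <- builtinSignatures()
  p <- withr::local_tempfile(fileext = ".gmt")
  writeGMT(sc, p)
  sc2 <- readGMT(p, label = collectionLabel(sc))
  expect_equal(geneSets(sc2), geneSets(sc))
  expect_equal(signatureGroups(sc2), signatureGroups(sc))
})

test_that("ssGSEA matches the hand-enumerated running sum", {
  # 4-gene worked example: ranks A>B>C>D, set {A,B}, alpha 1
  expr <- matrix(c(4, 3, 2, 1), 4, 1,
                 dimnames = list(c("A", "B", "C", "D"), "S1"))
  sm <- scoreSsgsea(expr, list(ab = c("A", "B")), alpha = 1, normalize = FALSE)
  expect_equal(unname(scoreValues(sm)[1, 1]), 4 / 7 + 1 + 1 / 2 + 0,
               tolerance = 1e-12)

  # random <= 8-gene toys against the naive walk oracle
  set.seed(10)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    x <- setNames(rnorm(n), paste0("g", seq_len(n)))
    k <- sample(1:(n - 1), 1)
    set <- sample(names(x), k)
    alpha <- sample(c(0.25, 0.5, 1), 1)
    got <- scoreValues(scoreSsgsea(matrix(x, ncol = 1,
                                          dimnames = list(names(x), "s")),
                                   list(s1 = set), alpha = alpha,
                                   normalize = FALSE, min_set_size = 1))[1, 1]
    expect_equal(got, oracle_ssgsea(x, set, alpha), tolerance = 1e-10)
  }
})

test_that("ssGSEA is rank-based and picks top genes for singletons", {
  ex <- toy_expr(20, 6)
  sets <- list(a = rownames(ex)[1:5], b = rownames(ex)[6:12])
  base <- scoreValues(scoreSsgsea(ex, sets, normalize = FALSE))
  # strictly increasing transform of one sample leaves its scores unchanged
  ex2 <- ex; ex2[, 3] <- exp(ex2[, 3] / 2)
  tr <- scoreValues(scoreSsgsea(ex2, sets, normalize = FALSE))
  expect_equal(tr[, 3], base[, 3], tolerance = 1e-12)

  # among all singleton sets the sample's top gene scores highest
  singles <- setNames(as.list(rownames(ex)), rownames(ex))
  ss <- scoreValues(scoreSsgsea(ex, singles, normalize = FALSE,
                                min_set_size = 1))
  for (j in c(1, 4)) {
    top <- rownames(ex)[which.max(ex[, j])]
    expect_equal(rownames(ss)[which.max(ss[, j])], top)
  }
})

test_that("ssGSEA drops unusable sets and normalises globally", {
  ex <- toy_expr(15, 5)
  expect_warning(
    sm <- scoreSsgsea(ex, list(ok = rownames(ex)[1:4], gone = c("nope", "nada")),
                      normalize = FALSE),
    "dropped")
  expect_equal(rownames(scoreValues(sm)), "ok")
  expect_warning(scoreSsgsea(ex, list(all = rownames(ex), ok = rownames(ex)[1:3]),
                             normalize = FALSE),
                 "every gene")
  nm <- scoreValues(scoreSsgsea(ex, list(a = rownames(ex)[1:4],
                                         b = rownames(ex)[5:9]),
                                normalize = TRUE))
  expect_equal(max(nm) - min(nm), 1, tolerance = 1e-12)
})

test_that("PCA scores recover a planted latent signal with stable sign", {
  set.seed(21)
  n <- 40
  s <- rnorm(n)
  genes <- t(sapply(1:10, function(i) s + rnorm(n, 0, 0.3)))
  dimnames(genes) <- list(paste0("sig", 1:10), paste0("smp", 1:n))
  filler <- matrix(rnorm(20 * n), 20, n,
                   dimnames = list(paste0("f", 1:20), colnames(genes)))
  ex <- rbind(genes, filler)
  sc <- scorePCA(ex, rownames(genes))
  expect_gte(cor(sc, s), 0.95)
  expect_lt(abs(sum(sc)), 1e-8)                    # centred
  expect_identical(sc, scorePCA(ex, rownames(genes)))  # deterministic

  # rank-1 case: identical rows give the shared z-profile up to scale
  ex2 <- rbind(matrix(rep(ex[1, ], 3), 3, n, byrow = TRUE,
                      dimnames = list(c("r1", "r2", "r3"), colnames(ex))),
               filler)
  sc2 <- scorePCA(ex2, c("r1", "r2", "r3"))
  zprof <- (ex[1, ] - mean(ex[1, ])) / sd(ex[1, ])
  expect_gt(cor(sc2, zprof), 0.9999)
})

test_that("z-score scoring equals the mean z-profile and handles edge sets", {
  ex <- toy_expr(12, 8)
  single <- scoreZscore(ex, rownames(ex)[1])
  expect_equal(unname(single),
               unname((ex[1, ] - mean(ex[1, ])) / sd(ex[1, ])),
               tolerance = 1e-12)
  expect_lt(abs(mean(scoreZscore(ex, rownames(ex)[1:5]))), 1e-10)
  # k identical rows behave like the single-gene case
  ex2 <- ex; ex2[2, ] <- ex2[1, ]; ex2[3, ] <- ex2[1, ]
  expect_equal(scoreZscore(ex2, rownames(ex2)[1:3]), scoreZscore(ex2, rownames(ex2)[1]),
               tolerance = 1e-12)
  # affine per-gene rescaling is absorbed by standardisation
  ex3 <- ex * 3 + 100
  expect_equal(scoreZscore(ex3, rownames(ex)[1:5]),
               scoreZscore(ex, rownames(ex)[1:5]), tolerance = 1e-10)
})

test_that("calculateSigScore dispatches and integrates", {
  ex <- toy_expr(30, 10)
  coll <- SignatureCollection(list(s1 = rownames(ex)[1:6],
                                   s2 = rownames(ex)[7:14],
                                   s3 = rownames(ex)[15:20]))
  z <- calculateSigScore(ex, coll, "zscore")
  expect_equal(methodTag(z), "zscore")
  expect_equal(scoreValues(z)["s2", ],
               scoreZscore(ex, coll[["s2"]]), tolerance = 1e-12)
  integ <- calculateSigScore(ex, coll, "integration")
  expect_equal(nrow(scoreValues(integ)), 3 * length(coll))
  expect_true(all(c("s1_ssgsea", "s1_pca", "s1_zscore") %in%
                  rownames(scoreValues(integ))))
  expect_error(calculateSigScore(ex, coll, "bogus"))
  expect_error(calculateSigScore(ex, SignatureCollection(list()), "zscore"),
               "empty")
})
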