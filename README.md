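# tmekit

Immuno-oncology analysis of bulk transcriptomes: who is in the tumor
microenvironment (TME), how active are the relevant gene programs, and do
they track clinical outcomes?

`tmekit` is aimed at computational biologists working with bulk RNA-seq
(or microarray) cohorts, with or without companion single-cell data. It
covers the pipeline from a raw count matrix to interpretable statistics:

* **Preprocessing** — TPM conversion (`count2tpm`), symbol annotation with
  deduplication (`annoEset`), log transformation, ComBat-style batch
  adjustment (`adjustBatches`).
* **Signature scoring** — per-sample scores for arbitrary gene-set
  collections (GMT) by single-sample GSEA, first principal component, or
  mean z-score (`calculateSigScore`).
* **TME deconvolution** — the linear mixing model *m = S f*: cell-type
  fractions by linear nu-SVR (CIBERSORT-family) or exact
  simplex-constrained least squares, marker-mean abundance scores, and
  stromal/immune enrichment with cosine tumor purity, behind a registry
  of eight published method names (`deconvMethods`, `runMethod`). All
  reference resources are user-supplied; none are bundled.
* **scRNA-derived references** — one-vs-rest Wilcoxon cluster markers
  (`findMarkers`) and signature-matrix construction (`buildReference`)
  so bulk cohorts can be deconvolved against single-cell-defined
  populations.
* **Phenotype statistics** — batch Wilcoxon/Kruskal–Wallis group tests,
  (partial) correlations, univariate Cox hazard ratios, and ROC/AUC
  comparison with DeLong tests, all BH-FDR controlled (`batchCompare`,
  `batchCorrelation`, `batchSurvival`, `sigROC`).
* **Mutation analysis** — MAF to mutation matrix (`makeMutMatrix`),
  mutation–signature association (`findMutations`), oncoprint-style
  frequency summaries.
* **Risk models** — univariate screening, bootstrap-stabilised L1
  selection, and linear risk scores (`univariateScreen`,
  `bootstrapSelect`, `riskScore`).
* **Synthetic data** — deterministic generators with known ground truth
  (`simReference`, `simMixtures`, `simScrna`, `simMAF`, `simPhenotype`)
  so every stage runs and tests offline.

The central statistics are implemented in-package where the convention
matters (ssGSEA running sum, exact-under-ties Wilcoxon, rank-formula AUC,
constrained least squares) and delegated to the standard packages where
they are the established tool (`survival` for Cox, `glmnet` for L1 paths,
`sva::ComBat` for empirical-Bayes batch shrinkage, `pROC` for DeLong,
`e1071` for nu-SVR, `quadprog` for the quadratic programs).

## Worked example

Simulate a 5-type reference, mix 20 bulk samples at known fractions with
noise, then recover the composition and score marker signatures:

```r
library(tmekit)

ref   <- simReference(n_genes = 200, n_cell_types = 5, seed = 7)
truth <- simFractions(n_samples = 20, n_types = 5, seed = 8)
mix   <- simMixtures(ref, truth, noise_sd = 0.05, seed = 9)

fit <- deconvLSEI(mix, ref)      # simplex-constrained least squares
fit
#> CellFractionMatrix: 5 cell types x 20 samples (simplex constrained)
#>   method: constrained_ls
#>   fit stats: rmse, pearson_r; median rmse 0.0486
round(fractions(fit)[, 1:4], 3)
#>           sample001 sample002 sample003 sample004
#> cellType1     0.086     0.571     0.018     0.183
#> cellType2     0.158     0.018     0.295     0.479
#> cellType3     0.193     0.017     0.402     0.064
#> cellType4     0.410     0.113     0.032     0.016
#> cellType5     0.154     0.281     0.253     0.257
```

Each column is a sample's estimated composition (non-negative, summing
to one); at this noise level the estimates match the generating fractions
to within about 0.001. Scoring the planted type-1 marker block as a
signature tracks the type-1 fraction:

```r
lg   <- normalizeExpression(mix, "auto")      # log2(x+1), auto-detected
sets <- SignatureCollection(list(Type1_markers = rownames(mix)[1:20],
                                 Type2_markers = rownames(mix)[21:40]))
sm <- calculateSigScore(lg, sets, method = "ssgsea")
round(scoreValues(sm)[, 1:4], 3)
#>               sample001 sample002 sample003 sample004
#> Type1_markers     0.329     0.746     0.004     0.543
#> Type2_markers     0.379    -0.098     0.594     0.679
cor(scoreValues(sm)["Type1_markers", ], truth["cellType1", ])
#> [1] 0.839
```

Higher enrichment of a cell type's markers means more of that cell type;
the rank-based score correlates 0.84 with the true fraction here. From a
score you can go on to survival or response association
(`batchSurvival`, `sigROC`), mutation association (`findMutations`), or
model building (`bootstrapSelect`).

A thin command-line front end wraps the same functions
(`inst/scripts/tmekit.R`; see `--help`), writing a JSON run manifest next
to every output.

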