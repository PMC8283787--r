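---
title: "tmekit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tmekit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmekit)
```

# Scope

`tmekit` analyses the tumor microenvironment (TME) from bulk expression
data: it scores gene signatures per sample, estimates cell-type
composition by reference-based deconvolution (including references derived
from cluster-labelled scRNA-seq), associates signatures with clinical
phenotypes (group tests, correlations, survival, ROC), links mutation
status to signatures, and builds sparse risk models. Every stage is
testable offline through deterministic synthetic-data generators. This
vignette records the models, the tunable parameters, and the design
choices made where the methodology was genuinely open.

# Preprocessing

**TPM conversion.** For gene $g$ with effective transcript length
$\ell_g$ (kilobases) and count $c_{gj}$ in sample $j$,
$\mathrm{TPM}_{gj} = \frac{c_{gj}/\ell_g}{\sum_h c_{hj}/\ell_h}\times 10^6$,
so every column sums to $10^6$ and per-sample sequencing depth cancels.
Lengths come from a user-supplied annotation table (`length_bp`); the
package does not parse GTFs, and it takes no position on the
longest-isoform vs union-exon length definition — the annotation carries
whichever the user prefers. Genes without a positive length are dropped
with a warning; a sample with all-zero counts is an error, because its
TPM column would be undefined.

**Annotation.** `annoEset()` maps probe/ENSEMBL ids to symbols and
resolves duplicate symbols by keeping the row with the largest mean
(`max_mean`, sensible for intensity-like data) or summing rows (`sum`,
sensible for counts split across transcripts). `max_mean` is the default.

**Log scale.** Downstream scoring assumes a log-like scale.
`normalizeExpression(mode = "auto")` applies $\log_2(x+1)$ only when the
matrix maximum exceeds 50 — a heuristic separating linear-scale TPM from
already-logged data; the threshold is a visible argument precisely because
it is a heuristic.

**Batch adjustment.** `adjustBatches()` fits the usual location-scale
batch model on the log scale: standardise each gene against its grand mean
and pooled residual variance, remove each batch's location and scale in
standardised units, restore the grand parameters. With
`empirical_bayes = TRUE` the per-gene batch effects are shrunk across
genes by the standard parametric normal/inverse-gamma priors — this
branch delegates to `sva::ComBat`, which implements exactly that
estimator. With `empirical_bayes = FALSE` the raw per-gene estimates are
removed, which makes per-batch per-gene means *exactly* equal afterwards
(the package asserts this to $10^{-8}$).

A numerical-design note: no location-scale adjustment can return the
literal batch-free matrix when planted effects are one-sided, because the
grand mean and pooled variance are estimated from the corrupted data and
absorb part of the planted effect — the model is identifiable only up to
the pooled scale. The recovery test therefore plants *balanced* effects
(opposite location shifts, reciprocal scale factors around the consensus)
at large batch sizes, where recovery to 0.05 RMSE is achievable and
actually informative. Genes with zero variance inside every batch carry
no scale information and pass through untouched.

# Signature scoring

Three per-sample scorers share one contract (signatures × samples matrix
out, undefined scores dropped with a warning, never silent NAs):

**ssGSEA.** Genes are ranked per sample in decreasing expression (ties
broken by gene id, so repeated runs are bit-identical); walking down the
ranked list the score accumulates
$\sum_i \left[P_{\mathrm{in}}(i) - P_{\mathrm{out}}(i)\right]$, where
$P_{\mathrm{in}}$ weights set genes by their rank value to the power
$\alpha$ (default $0.25$, the convention of the single-sample GSEA
literature) and $P_{\mathrm{out}}$ is the running fraction of non-set
genes. Only ranks enter, so any strictly increasing transform of a
sample's expression leaves its scores unchanged — the suite verifies this
and checks the walk against a naive enumeration oracle on small toys
(the 4-gene worked example with $\alpha = 1$ and set $\{A, B\}$ gives
$4/7 + 1 + 1/2 + 0 = 2.0714$). `normalize = TRUE` divides all scores by
the global score range; whether such normalisation should be global or
per-signature is a genuinely open convention, so the global choice is a
flag, not a constant.

**PCA.** The signature submatrix is per-gene z-standardised and the score
is the samples' coordinate on the first principal component. A principal
component's sign is arbitrary; the score is oriented to correlate
non-negatively with the mean standardised signature expression, making
output deterministic. No bit-compatibility with any published
PCA-signature implementation is claimed.

**Z-score.** The per-sample mean of gene-standardised expression.
Zero-variance genes are excluded (they carry no contrast); both PCA and
z-scores are therefore invariant to per-gene affine rescaling.

`calculateSigScore()` dispatches one method or, with
`method = "integration"`, all three with method-suffixed row names.
`min_set_size = 2` because PCA needs two genes.

The packaged collection returned by `builtinSignatures()` is a 12-set,
4-group synthetic fixture (so examples and tests run offline) and is
labelled `"fixture"`; real analyses should load a curated GMT.

# Deconvolution

The linear mixing model is $m = S f$: a bulk profile is a
fraction-weighted sum of cell-type reference profiles. Four native
engines sit behind a registry of the eight published method names
(`cibersort`, `estimate`, `quantiseq`, `timer`, `ips`, `mcpcounter`,
`xcell`, `epic`); the registry binds a name to an engine plus the
*user-supplied* reference resource it needs. No third-party reference
matrix (LM22, TIL10, the xCell set collection, …) ships with the package,
and no bit-compatibility with the published pipelines is claimed — the
names document which algorithm family and defaults are applied.

**nu-SVR (`deconvSVR`).** Per sample, a linear $\nu$-support-vector
regression of the standardised mixture on the reference columns, over
$\nu \in \{0.25, 0.5, 0.75\}$; the fit minimising reconstruction RMSE
wins; negative weights are clamped and the rest normalised to the
simplex. Standardisation follows the CIBERSORT convention the method
derives from: mixture z-scored per sample, reference as a whole. An
optional permutation p-value shuffles gene labels (`n_perm` ≥ 100
recommended) and reports the fraction of permutations whose
reconstruction correlation reaches the observed one.

**Constrained least squares (`deconvLSEI`).** Per sample,
$\min_f \lVert S f - m \rVert^2$ subject to $f \ge 0$ and, per
`sum_constraint`: `"equal"` ($\sum f = 1$, the default), `"leq"`
($\sum f \le 1$, remainder reported as `otherCells` — for references that
do not span the tissue, as in EPIC-style tumor-content analyses), or
`"none"` (non-negative regression only, the TIMER-style relative score).
The quadratic programs are solved exactly by the dual active-set method
(`quadprog`); jitter in $(-10^{-9}, 0)$ is snapped to zero. Noiseless
identifiable mixtures are recovered to $10^{-6}$ (checked against a
simplex grid-search oracle). A near-singular reference triggers a warning
with its condition number, which is also computed at construction of
every `ReferenceMatrix`.

**Marker means (`scoreMarkerMean`).** MCP-counter-style abundance: the
mean log2 expression of a population's markers. Scores are comparable
across samples within a population only — no sum-to-one.

**Enrichment + purity (`estimateScores`).** Stromal and immune ssGSEA
scores ($\alpha = 0.25$, unnormalised), their sum, and tumor purity
$\cos(a + b \cdot \mathrm{estimate})$ clipped to $[0,1]$. The default
$(a, b)$ are the constants published with the ESTIMATE method, fitted on
Affymetrix data; their transfer to RNA-seq TPM is approximate, so they
are explicit configuration (`estimatePurityCoeffs()`) rather than a
hidden constant. `xcell`-style runs add an optional linear spillover
correction given a user-supplied square spillover matrix; without one the
engine is plain per-set ssGSEA. CIBERSORT's absolute mode is deliberately
not implemented; fractions are relative.

# References from scRNA-seq

Cluster labels are *inputs* (clustering is out of scope).
`findMarkers()` normalises to counts-per-10k, applies $\log_2(x+1)$, and
runs a one-vs-rest two-sided Wilcoxon rank-sum per gene and cluster —
the dominant convention for cluster markers — with BH FDR within each
cluster. Rows failing `min_lfc` (default 1) or `max_fdr` (default 0.05)
are flagged, not removed. `buildReference()` takes the `top_k` (default
50) passing markers per cluster (ascending FDR, ties by larger fold
change, then gene id) and averages *linear-scale* normalised expression
per cluster — linear, because the downstream mixture model is linear in
expression. The end-to-end property — simulate labelled cells, find
markers, build the reference, mix pseudobulk at known proportions,
deconvolve — recovers proportions with per-sample Pearson ≥ 0.9 across
seeds.

# Association statistics

One batch call defines one multiple-testing family; every operation
reports BH FDR next to raw p-values (uncorrected batch p-values would be
indefensible).

**Rank-sum testing.** The package's Wilcoxon (`ranksumTest`) enumerates
the full permutation distribution of the rank sum whenever both groups
have ≤ 10 observations — midranks make this exact under ties, where
`stats::wilcox.test` abandons exactness — and otherwise uses the normal
approximation with tie-corrected variance and continuity correction. The
exact branch is validated against `wilcox.test`'s exact distribution
(tie-free) and a Monte-Carlo permutation oracle (ties). Two-group designs
report the rank-biserial correlation as effect size; more than two groups
get Kruskal–Wallis plus pairwise rank-sum tests.

**Correlation.** Pearson, Spearman, or partial correlation — the
correlation of residuals after projecting both variables on $[1, Z]$,
validated against the one-covariate closed form. Taking the target to be
one gene's expression row turns this into "signatures tracking a gene"
(e.g. lncRNA) analysis.

**Survival.** Univariate Cox proportional hazards per feature, fitted by
Newton–Raphson on the partial likelihood with Efron tie handling via the
`survival` package (Efron over Breslow as the better default).
`continuous` mode standardises the feature so the hazard ratio is per SD;
`median_cut` dichotomises at the median. An independent 1-D
golden-section oracle on a hand-written partial likelihood pins the fit
in the suite; a planted log-HR of 0.7 at $n = 500$ with ~30% uniform
censoring is recovered within ±0.15 with Wald CI coverage inside
[0.92, 0.98] over 200 replicates.

**ROC.** AUC by the rank (Mann–Whitney) formula with midranks, equal to
brute-force pair counting (verified up to $n = 30$ including ties).
Features with raw AUC below 0.5 are reported as $1 - \mathrm{AUC}$ with
an explicit `inverted` flag — never silently. DeLong intervals and
(optionally) all-pairs DeLong comparisons come from `pROC`; a bootstrap
comparison is left unimplemented as the paired-design alternative.
Results are sorted by AUC descending.

**Mutations.** MAF records (TCGA column dialect, case-insensitive header
match, no synonym guessing) become sample × gene count matrices filtered
by category (`snp`, `indel`, `frameshift` — classification prefix
`Frame_Shift` —, or `all`), optionally binarized. Silent variants are
*not* excluded by default (no exclusion is assumed); a
`nonsynonymous_only` flag applies the standard non-silent list.
`findMutations()` tests the signature score in mutated vs wild-type
carriers per gene (same rank-sum machinery; internal consistency with
`batchCompare` is asserted), keeping genes mutated in ≥ `min_freq`
(default 0.05, logged) of samples.

# Model construction

The screen → stability-selection → refit design is the package's own
(the module's intent, feature selection and robust biomarker
identification, admits many instantiations): univariate screening flags
candidates at `max_fdr`; `bootstrapSelect()` refits an L1-penalised model
(logistic or Cox, via `glmnet`) on each of `B` bootstrap resamples with
the penalty chosen per resample by cross-validation under the 1-SE rule
(the sparser, stability-oriented choice — the minimising penalty admits
too many null features); features appearing in ≥ 70% of resamples are
refit unpenalised to give the final weights. `riskScore()` is the plain
linear combination and refuses silently zero-filling missing features.

In the evaluation simulation, three true features among nulls carry
per-feature effect 1.5 on the logistic scale; this puts the *true*
predictor's AUC near 0.90, so the held-out AUC ≥ 0.85 bound measures
estimation loss rather than colliding with the Bayes limit (with unit
effects the true predictor itself only reaches AUC ≈ 0.84).

# Synthetic data: what it does and does not emulate

The generators are pure functions of their seed (RNG state is saved and
restored, outputs are bit-identical across calls):

* `simReference()` — log-normal baseline with disjoint marker blocks
  (+4 log2 by default) per cell type: well-separated columns (pairwise
  correlation < 0.5), the identifiable regime.
* `simMixtures()` — exact linear mixing plus truncated Gaussian noise;
  fraction columns are validated on the simplex to $10^{-8}$.
* `simScrna()` — negative-binomial counts (size 2) with planted marker
  blocks; `markers_per_cluster = 0` gives a pure null for type-I checks.
* `simMAF()` — per-gene Bernoulli mutation with an SNP/INS/DEL type mix
  and classification consistent with type.
* `simPhenotype()` — logistic response or exponential survival with
  hazard $\exp(\beta \cdot \mathrm{score})$ under uniform censoring;
  `censor_max = 3.2` yields ≈ 30% censoring for a standard-normal score
  at $\beta = 0.7$ (calibrated once to that stated condition).

These fixtures deliberately lack real-transcriptome features: gene–gene
correlation beyond the planted blocks, mRNA-content differences between
cell types, dropout structure in the single-cell counts, platform batch
idiosyncrasies. Passing tests therefore demonstrate algorithmic
correctness under the declared model, not biological validity on any
particular cohort — reference quality remains the dominant driver of
real-data deconvolution accuracy.

# Problem sizes and numerical conventions

The test suite and the acceptance script run the simulations at moderate
sizes chosen as the package's reference settings: 5-type/200-gene
references with 50 mixtures; 2–3-cluster single-cell sets of 25–30 cells
per cluster; 1000-feature null panels over 10–20 seeds; 200 survival
replicates at $n = 500$. Tolerances follow the operation: $10^{-6}$ for
exact constrained least squares and TPM column sums, $10^{-8}$ for
batch-mean equality, machine-level agreement for closed-form oracles.
Ties are always broken deterministically (gene id order); fraction
jitter in $(-10^{-9}, 0)$ is snapped to zero; degenerate inputs (empty
groups, zero-variance features, all-zero samples) error or drop loudly,
never silently.

# Command line

`inst/scripts/tmekit.R` exposes the pipeline as subcommands (`prep`,
`score`, `deconv`, `scref`, `assoc`, `surv`, `roc`, `mut`, `model`,
`simulate`). Every run writes a JSON manifest next to its output —
command, options, seed, input MD5 hashes, package version, timestamp —
and all randomness flows from `--seed`, so deterministic commands
reproduce bit-identically. Floats are written at 6 significant digits
unless `--full-precision` is given; a YAML config may supply any flag,
with explicit flags winning.
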