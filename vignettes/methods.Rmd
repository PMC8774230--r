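---
title: "Methods: consensus density-based embedding and ROC signature selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus density-based embedding and ROC signature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and the design
choices behind them — what is estimated, under which assumptions, which
knobs matter, and what a green test does and does not establish.

## 1. The problem and the stated world

Chromophobe renal cell carcinoma (chRCC, malignant) and renal oncocytoma
(RO, benign) overlap histologically; bulk transcriptomes separate them.
The package's pipeline assumes gene- or probe-level log2 expression from
several studies ("batches") with uneven class composition, and no access
to the original repositories at analysis time. Everything is therefore
exercised on a synthetic world with planted ground truth.

The generator's defaults *are* the stated world, chosen once:

| parameter | default | why |
|---|---|---|
| batch composition | 6/7/12, 4/4/5, 15/15/0, 10/10/0, 18/0/0 (chRCC/RO/N) | the five-study discovery meta-dataset (106 arrays: 53/36/17) |
| `n_genes` | 3000 | desk-scale stand-in for the ~16k-gene post-merge universe; large enough for 1000-gene subsampling, small enough for minute-scale tests |
| `frac_de` | 0.10 | plants ~300 chRCC-vs-RO genes, the order of the published |FC| ≥ 2 stage |
| `fc_range` | (2, 56) linear | the published signature's fold changes span ~2.8–55x |
| baseline | Normal(8, 1.5²) log2 | typical microarray intensity summaries |
| `noise_sd` | 1.0 log2 | realistic residual spread; implies ~96% of planted genes reach population AUROC ≥ 0.9 via Φ(Δ/σ√2) |
| `batch_loc_sd` | 1.0 log2 | strong inter-study shifts, so batch variance exceeds histology variance before correction (the published QC picture) |
| `batch_scale_shape` | 25 (Inf = off) | unit-mean inverse-gamma variance multipliers, ±20% spread |
| probes/gene | 1–3 | one faithful probe plus degraded extras |
| RNA-seq platform | NB counts, dispersion 0.15, log2-CPM | merges with arrays after standardization |

Degraded probes implement three failure modes, each punished by exactly
one component of the probe score: low signal (−4 log2 units → poor
coverage), inflated noise (×3 SD → poor robustness), and cross-mapped
annotation (two genes → specificity 0.5). Cross-mapped probes mix two
transcripts *and* carry 2× noise: a cross-hybridizing probe is noisier
than a clean one, and without that term the half-and-half mixture would
average away noise and implausibly beat faithful probes for dim genes.

What the generator does **not** emulate: probe sequence effects, spatial
artifacts, RNA-seq library-composition biases beyond a scalar size
factor, correlated gene modules, or tumor purity gradients. A green test
therefore establishes algorithmic correctness and calibration on an
idealized-but-noisy world, not clinical performance.

## 2. Preprocessing

**Probe collapse.** `score_probes()` uses
specificity = 1/#genes, coverage = fraction of samples above the
study-wide 25th percentile, robustness = mean/(SD + 0.01); the product
ranks probes and `select_best_probes()` keeps the winner per gene, ties
going to the lexicographically smallest probe id so results are
independent of input order.

**Log-scale detection.** If the 99th percentile exceeds 30, the matrix is
treated as raw intensities and `log2(x+1)` applied; log2 summaries rarely
exceed ~20 while raw intensities run to the hundreds. The operation is
idempotent and refuses negative raw values.

**Batch correction.** Parametric empirical-Bayes location/scale
adjustment. Per gene: a least-squares fit with batch indicators plus
histology dummies (protecting biology from absorption into batch terms —
the default, switchable), standardization by the pooled residual
variance, per-batch method-of-moments priors (normal for the location
effect γ, inverse-gamma for the variance multiplier δ²), then one-step
conditional posterior means and back-transformation. The classic tool
iterates the two conditional updates; at these shrinkage strengths the
one-step and iterated solutions agree far below the noise floor, and the
one-step form is exactly specifiable. Corollary worth knowing:
re-adjusting adjusted data re-estimates priors and re-shrinks, so
"idempotence" holds only up to shrinkage noise (observed max ~0.2 at
noise SD 1), not to machine precision.

**Batch audit.** Because "the batches dominate PC1–2" is a visual claim,
it is made assertable: R² of the batch (and histology) grouping on the
first two PCs of gene-standardized data. On the surrogate, batch R² >
histology R² before adjustment and the order reverses after.

## 3. The DBU consensus classifier

Each iteration draws `gene_count = 1000` genes without replacement,
embeds samples into 2-D with UMAP (`n_neighbors = 20`, `min_dist = 0.01`,
Manhattan — the grid-search winners; `uwot` provides the optimizer behind
the `embed_2d()` contract, single-threaded and seeded for bit
reproducibility), and clusters the embedding with DBSCAN. `eps` comes
from the k-distance elbow (max perpendicular distance to the chord of the
sorted k-distance curve) rather than a fixed 2.0, because embedding
scales vary across iterations; `min_pts = 5`.

Cluster labels are arbitrary per iteration, so each partition is aligned
to a reference — the first iteration yielding ≥ 2 clusters — by solving
the assignment problem on the contingency table (Hungarian algorithm via
`clue`; clusters with no overlap, or beyond the reference's count, get
fresh ids). The published method compares groups across iterations
without stating a correspondence rule; the assignment formulation is
order-independent and optimal for total overlap, and a greedy fallback
would only differ on pathological ties.

Voting: a sample's support is the modal aligned group's share of the
iterations where the sample was *not* noise; the threshold is inclusive
(≥ 0.70). Removing noise iterations from the denominator means a few
failed embeddings cannot force ambiguity; `strict_denominator = TRUE`
restores the conservative reading. Supports, the iteration matrix, and a
co-clustering frequency matrix (times together / times both non-noise)
are all returned; concordance with histology maps groups by majority
composition, excludes normal samples, and reports accuracy both without
and with ambiguous samples in the denominator, since the published 97.75%
does not say which it is.

## 4. Differential expression and the signature cascade

`moderated_t_test()` implements empirical-Bayes variance shrinkage: the
distribution of log sample variances is moment-matched to a scaled
inverse-chi-square prior by digamma/trigamma inversion (Newton), giving
prior df `d0` and location `s0²`; posterior variances
`(d0·s0² + d·s²)/(d0 + d)` feed a t statistic on `d0 + d` df. The limits
are exact: `d0 = 0` reproduces the ordinary two-sample t, `d0 = ∞` the
common-variance t; on heterogeneous-variance data the estimates agree
with `limma` to 1e-10 (used purely as an independent oracle in tests —
the implementation here is self-contained). BH adjustment is the step-up
with enforced monotonicity, tested against a brute-force oracle exactly.

Per-gene ROC profiling evaluates percentiles 1–99 of the pooled values as
candidate cutpoints. The positive class is the *higher-mean* class per
gene: the published per-gene metrics are not consistent with any single
fixed positive class, so direction is carried per gene in all outputs.
The optimum cutpoint maximizes accuracy, ties broken by larger Youden's J
then smaller cutpoint. Note one consequence of the percentile grid:
accuracy is piecewise constant between data values, so the reported
optimum is one representative of an interval of equally good cutpoints.

The cascade applies, in order: BH-adjusted p < 0.05, linear |FC| ≥ 2,
AUROC ≥ 0.9, then the joint screen (sens > 0.91, spec > 0.91,
AUROC > 0.92, accuracy > 0.92); stages are nested by construction.
Survivors are ranked by a weighted priority: z-scored |log2 FC|, breadth
(the count of percentile cutpoints whose accuracy exceeds the accuracy
threshold — the package's operationalization of "significant at more
inter-percentile fold change", which the source phrase leaves ambiguous),
and a user-supplied relevance weight standing in for manual literature
prioritization (default 0). All-zero weights fall back to AUROC then
adjusted p then gene id. `evaluate_signature()` transfers the panel to
new data via per-gene cutpoint votes (majority; ties reported ambiguous)
alongside the hierarchical-clustering route (average linkage on
1 − Pearson correlation, 2-cut).

## 5. Preranked enrichment

The running-sum statistic increments by `|stat|^weight` (normalized by the
set total) on members and decrements `1/(N − m)` otherwise; the ES is the
extremum of largest magnitude. The null permutes gene labels of the
statistic — equivalently random same-size sets — which is simpler than
the multilevel split scheme of the reference tool but exactly specifiable
and calibrated at desk scale (random sets reject at ~5% at p = 0.05).
p-values use the +1-corrected one-sided count on the observed sign; NES
divides the ES by the mean |null ES| of the same sign; set-size bounds
default to the conventional 5–500. The ranking statistic from the DE
stage is the signed moderated t (the source does not state its metric).

## 6. Reproducibility and numerical choices

One master seed drives everything through `derive_seed(master, label)`, a
small deterministic hash; per-iteration seeds, the gene-set sampler, the
permutation null and the generator's gene/batch/study streams are all
independent streams of it, so any stage can be re-run in isolation
bit-identically. Gene-level truth depends only on
(seed, `n_genes`, `frac_de`, `fc_range`), which is what lets discovery
and validation surrogates share planted biology.

Degenerate inputs are handled explicitly: constant genes are flagged
(AUROC 0.5, no optimum), constant sample profiles are an error naming the
sample, all-identical points make the k-distance curve an error, a single
batch passes through correction unchanged, and confounded batch/covariate
designs fail with the cross-table printed. Numerical floors: variance
1e-12 in the EB steps, intra-cluster distance 1e-8 in the separation
score.

## 7. Known limitations

Desk-scale stand-ins, not reproductions: the published discovery/validation
accuracies, probe counts and pathway tables depend on external data and
are deliberately out of scope. The ensemble's reference partition is the
first iteration with ≥ 2 clusters; a co-clustering spectral alternative
would remove that (mild) dependence but is not the default. The
enrichment null is gene-label permutation, which ignores inter-gene
correlation; on real data its p-values are anti-conservative to an
unknown degree. The synthetic RNA-seq platform models library size only
as a scalar.
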