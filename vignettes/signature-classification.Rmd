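---
title: "Classifying bulk tumors by single-cell cluster signatures"
author: "CellSigScore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying bulk tumors by single-cell cluster signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CellSigScore)
```

## The question and the method

A dissociated tissue profiled by droplet scRNA-seq yields a genes × cells
UMI count matrix in which unsupervised clustering delineates the tissue's
cell types. Each cluster's identity can be summarized by a *gene
signature*: the genes most strongly and specifically up-regulated in that
cluster relative to all other cells. Given such signatures and a cohort of
bulk tumor expression profiles, one can ask which cell type each tumor's
transcriptome most resembles — a proxy for the tumor's dominant or
originating cell type. CellSigScore implements this end to end for the
breast-tissue / breast-cancer setting: derive cluster signatures from
single cells, score every tumor against every signature with a
single-sample enrichment statistic, assign each tumor its top-scoring
cluster, cross-tabulate assignments against ER/PR/HER2 receptor subtypes,
and compare overall survival between assignment groups.

## Single-cell stage

**QC.** Cells detecting more than `maxGenes` genes (default 6500) are
removed as probable cell aggregates, and cells with a mitochondrial count
fraction above `maxMito` (default 0.1) as probable dead cells. Both
thresholds are strict inequalities — a cell exactly at the boundary is
retained — and the mitochondrial gene set is identified by a configurable
symbol prefix (default `MT-`) because mitochondrial gene lists differ
between annotation builds. The filter is idempotent.

**Normalization.** Counts are scaled within each cell to counts per
10,000 and transformed with `log1p`. The log base is natural: the
published description of this step says only "log-transformed", and the
natural log with pseudocount 1 is the convention of the single-cell
toolkits this pipeline mirrors. Zero counts map exactly to zero, and the
transform is invertible: `expm1` followed by rescaling recovers each
cell's count fractions to floating-point accuracy.

**Dimensionality reduction.** 2000 highly variable genes are selected by
a binned dispersion-versus-mean criterion (dispersion = variance/mean of
the log-normalized values, z-scored within 20 mean-expression bins), each
gene is centered and scaled with scaled values clipped at ±10, and the
cells are embedded in the first 10 principal components. Component signs
are fixed (largest-magnitude loading positive), so the embedding is
deterministic. The HVG count and PC count are configuration, not
constants; 10 PCs is the published choice, 2000 HVGs a standard default
since none was published. For general real-valued matrices that are not
nonnegative expression (where var/mean is meaningless) HVG selection
falls back to plain variance ranking.

**Clustering.** A k-nearest-neighbor graph (k = 20, Euclidean in PC
space) is reweighted by the Jaccard overlap of neighbor sets, pruned
below 1/15, and partitioned by Louvain modularity optimization at
resolution 0.8. The published analysis names shared-nearest-neighbor
clustering but no parameters; these defaults are the ones its toolkit
ships and are exposed as arguments. Cluster labels are renumbered by
decreasing size — cluster 0 is always the largest — with size ties broken
by original community id and announced with a warning, so relabeling is a
pure permutation of cluster contents.

## Marker signatures

For each cluster, every gene is tested one-vs-rest with a two-sided
Wilcoxon rank-sum test. Tie handling uses mid-ranks. When both groups
have at most eight cells the p-value comes from exact enumeration of the
conditional permutation distribution of the rank sum; beyond that, the
tie-corrected normal approximation with continuity correction is used.
The split exists because the normal approximation, while accurate where
the test has any power, can be off by more than 0.1 in absolute p at such
tiny group sizes — small enough clusters deserve exact answers, and the
enumeration is cheap there. Effect size is the average log fold change
`ln((mean(expm1(x_in)) + 1) / (mean(expm1(x_out)) + 1))`, computed on
de-logged means with a pseudocount, matching the toolkit convention since
no formula was published. P-values are Bonferroni-corrected per cluster;
a signature keeps genes with adjusted p < 0.05 and positive fold change,
sorted by decreasing fold change (ties by ascending p, then symbol, so
output is deterministic), truncated at 100 genes. No detection-fraction
prefilter or fold-change floor is applied by default because none was
published; both are available as arguments. A cluster with no significant
positive markers yields an empty set plus a warning rather than
disappearing silently.

## The enrichment statistic

Scoring a tumor against a signature uses a from-scratch implementation of
the gene set variation analysis statistic, in three steps.

1. **Kernel CDF.** For gene $i$ with values $x_{i1},\dots,x_{in}$ across
   samples, $z_{ij} = \frac{1}{n}\sum_w \Phi\!\big((x_{ij} -
   x_{iw})/h_i\big)$ with Gaussian bandwidth $h_i = s_i/4$. This is the
   continuous-input (Gaussian kernel) form, appropriate because the bulk
   input is log-scale expression. It is invariant to per-gene positive
   affine transforms, so unit choices per gene cancel. A constant gene
   ($s_i = 0$) carries no ranking information and is assigned $z = 0.5$
   with a logged count rather than erroring.
2. **Symmetrized ranks.** Within each sample genes are ordered by
   decreasing $z$ (ties broken by input gene order — a stable,
   deterministic rule), giving rank $\tau_{ij}$, and folded:
   $r_{ij} = |p/2 - \tau_{ij}|$.
3. **Weighted KS walk.** Walking the ordered genes,
   $$\nu(\ell) = \frac{\sum_{i \le \ell,\, i \in \gamma}
   r_i^{\tau w}}{\sum_{i \in \gamma} r_i^{\tau w}} -
   \frac{\#\{i \le \ell,\, i \notin \gamma\}}{p - |\gamma|}.$$
   With `mode = "max_diff"` (the default used by the classification
   pipeline) the score is $\max_\ell \nu + \min_\ell \nu$; with
   `mode = "max_dev"` it is the deviation of largest magnitude. Both lie
   in $[-1, +1]$. If every set gene sits exactly at the fold point
   ($r = 0$, possible only for tiny sets in even-sized universes), the
   in-set weights degenerate to $0/0$; the statistic is then defined with
   uniform in-set weights, which keeps the walk well-defined without
   changing any non-degenerate score.

Signature genes absent from the expression matrix are intersected out and
counted per set (symbol matching is case-sensitive with no alias
resolution, because no identifier mapping was published); a set with no
genes present is an error naming the set. The gene universe $p$ is
whatever the input matrix contains — scores depend on it, which is why
the `GsvaScores` object records it.

## Classification, cross-tabs, survival

Each tumor takes the cluster of its maximum score; exact ties are flagged
and broken toward the lowest cluster label. Receptor status maps to
subtype as ER+HER2−, ER+HER2+, ER−HER2+, and TNBC (ER−PR−HER2−); every
other combination — unknowns included, and the rare ER−PR+HER2− pattern —
is `unknown`, excluded from subtype cross-tabs but retained in all-tumor
coverage. PR enters only the TNBC rule, since subtype assignment
otherwise keys on ER and HER2 staining.

Survival comparisons use the product-limit estimator (censorings at an
event time count as at risk there), the log-rank test as the full
quadratic form $(O-E)^\top V^{-}(O-E)$ on the hypergeometric
variance–covariance matrix with df = G−1, and the 1-df log-rank trend
test with equally spaced scores in cluster-label order. The quadratic
form (rather than the simpler $\sum (O-E)^2/E$) was chosen so that the
two-group statistic exactly equals the squared trend statistic with
scores (0, 1), a consistency property the test suite asserts. Hazard
ratios are Mantel–Haenszel, $\mathrm{HR} = (O_a/E_a)/(O_b/E_b)$ with CI
$\exp(\ln \mathrm{HR} \pm 1.96\sqrt{1/E_a + 1/E_b})$ — the
log-rank-based estimator common in clinical reporting tools, preferred
here over Cox regression because it needs no iterative fitting and
satisfies exact reciprocity. A Cox option is deliberately out of scope.

Percentages in report tables round half-up to one decimal (`roundHalfUp`)
because that is how clinical tables are printed; base `round`'s
half-to-even rule would disagree with printed values at .05 boundaries.

## What the simulators emulate

`simulateSingleCells` draws negative-binomial UMI counts for K discrete
cell types: a log-normal baseline expression profile, per-type marker
blocks with mean multiplied by `exp(markerLogFC)`, log-normal library
sizes, and a single shared dispersion (default 0.5) — the simplest model
with the overdispersion the QC and normalization stages assume. A fixed
block of 13 `MT-`-prefixed genes carries `fracMito` (default 0.05) of
baseline expression mass, emulating the mitochondrial content of healthy
cells; 13 is the protein-coding/rRNA gene count of the human
mitochondrial genome. "Aggregate" cells are sums of two sampled cells —
not a mechanistic doublet model, just enough to inflate detected-gene
counts past the QC ceiling. Default type proportions follow the strongly
uneven cluster-size distribution observed in a published 3193-cell
breast-tissue experiment (24.1% down to 1.0%), and the default effect
size is `log(4)`.

`simulateBulk` makes each tumor a purity-weighted mixture of one
generating type's log2 profile and the mean profile plus Gaussian noise
(defaults: purity 0.8, noise sd 1 — a strongly dominant component with
substantial sample-level noise). Survival is exponential with per-type
hazard multipliers, chosen for its closed-form hazard ratios, which makes
parameter-recovery tests exact in expectation; censoring is an
independent exponential with one global rate calibrated so the marginal
censoring probability at the mean hazard is `censorRate` (default 0.3).
The default subtype rule assigns the first half of types ER+PR+HER2−,
one type each to ER+HER2+ and ER−HER2+, and the rest triple-negative,
echoing clinical prevalence ordering.

Neither simulator attempts batch effects, ambient RNA, cell-cycle
structure, doublet transcriptomics, copy number, read-level sequencing
noise, or non-proportional hazards. Tests passing on these simulations
therefore demonstrate that the pipeline recovers the structure it models
— discrete types with planted markers, mixture tumors with exponential
survival — not that it is robust to every artifact of real tissue data.
All randomness in a simulator call flows through one seeded stream and
the global RNG state is restored on exit, so identical seeds give
bit-identical outputs.

## Problem sizes used by the validation suite

The test suite validates the scoring walk against brute-force oracles on
random instances of up to 50 genes, Wilcoxon p-values against exact
enumeration at group sizes up to 8, and the full pipeline on a
1200-cell, 2000-gene, 10-type simulation with 50 planted markers per type
at `log(8)` effect, followed by 200 purity-0.8 tumors; survival
calibration uses 500 null replicates of 80 tumors and hazard-ratio
recovery 400 tumors with a true 3× hazard. These sizes give the recovery
checks comfortable statistical headroom while keeping a full run around
two minutes.

## Known limitations

* Gene identifiers are matched as exact symbols; signature genes missing
  from a bulk matrix are counted and reported, never remapped.
* The enrichment score depends on the gene universe of the supplied
  matrix; comparing scores across matrices with different universes is
  not meaningful.
* The Mantel–Haenszel hazard ratio is attenuated toward the null
  relative to the Cox MLE for large effects; its recovery band in the
  tests reflects that.
* Louvain clustering is stochastic across vertex orderings; the seed
  argument pins it, but different seeds can legitimately differ on
  borderline cells.
* The relative-expression scale behind published per-cluster summary
  tables is a reporting choice of their authors; `clusterGeneSummary`
  reports on the declared normalized-log scale and leaves any further
  rescaling to the caller, and fold ratios are computed from table
  values, not re-derived.
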