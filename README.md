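# CellSigScore

Which cell type does a bulk tumor's transcriptome most resemble? In
tissues profiled by droplet scRNA-seq, unsupervised clustering delineates
the constituent cell types, and each cluster can be summarized by its
top differentially expressed genes. CellSigScore turns that observation
into a classification pipeline for bulk tumor cohorts (built for the
breast-tissue / breast-cancer setting, usable for any tissue): derive
per-cluster gene signatures from single cells, score every tumor against
every signature with a single-sample enrichment statistic, assign each
tumor its highest-scoring cluster, cross-tabulate assignments against
ER/PR/HER2 receptor subtypes, and compare overall survival between
assignment groups with Kaplan–Meier, log-rank (including the trend
variant) and Mantel–Haenszel hazard-ratio statistics.

The package is aimed at computational biologists who have (a) a
CellRanger-style UMI count triplet (`matrix.mtx` + `barcodes.tsv` +
`features.tsv`) or any genes × cells count matrix, and (b) a bulk
log-expression matrix with a clinical table (receptor status,
overall-survival time and event flag). Seeded simulators for both data
types, with ground-truth cell types, markers and hazards, make every
stage testable without external downloads.

## The statistic at the core

Tumor-versus-signature scoring is a from-scratch implementation of the
gene set variation analysis (GSVA) enrichment score:

1. **Kernel CDF**: per gene *i*, with values *x*<sub>i1</sub>…*x*<sub>in</sub>
   across samples,
   *z*<sub>ij</sub> = (1/n) Σ<sub>w</sub> Φ((*x*<sub>ij</sub> − *x*<sub>iw</sub>)/*h*<sub>i</sub>),
   Gaussian bandwidth *h*<sub>i</sub> = *s*<sub>i</sub>/4.
2. **Symmetrized ranks**: per sample, genes are ordered by decreasing
   *z* (rank τ) and folded about the list middle, *r* = |p/2 − τ|.
3. **Weighted KS walk**: over the ordered genes,
   ν(ℓ) = Σ<sub>i≤ℓ, i∈γ</sub> *r*<sub>i</sub><sup>τw</sup> / Σ<sub>i∈γ</sub> *r*<sub>i</sub><sup>τw</sup> −
   #{i≤ℓ, i∉γ}/(p − |γ|); the score is max ν + min ν (`max_diff`, the
   default) or the largest-magnitude deviation (`max_dev`), bounded in
   [−1, +1].

Upstream, markers come from one-vs-rest Wilcoxon rank-sum tests (exact
enumeration for tiny groups, tie-corrected normal approximation
otherwise) with Bonferroni correction, sorted by average log fold change
and truncated to 100-gene signatures. Downstream, survival uses the
product-limit estimator, the full variance–covariance log-rank quadratic
form, and HR = (O₁/E₁)/(O₂/E₂) with
CI = exp(ln HR ± 1.96 √(1/E₁ + 1/E₂)). The methods vignette
(`vignettes/signature-classification.Rmd`) documents every formula,
default and degenerate-case rule.

## Worked example

Simulate a 3-type tissue, recover clusters and signatures, classify 100
simulated tumors, and test survival (type 3 carries a 3× hazard):

```r
library(CellSigScore)
library(SummarizedExperiment)

params <- ScSimParams(nCells = 600, nGenes = 1000, kTypes = 3,
                      typeProps = c(0.5, 0.3, 0.2), markersPerType = 50,
                      markerLogFC = log(8), nAggregate = 10, seed = 42)
sce <- simulateSingleCells(params)
sce <- qcFilter(sce, maxGenes = 900, maxMito = 0.1)   # drops aggregates
sce <- normalizeCounts(sce)
emb <- pcaEmbed(sce, nPcs = 10, nHvg = 500)
clusters <- snnCluster(emb, kNeighbors = 20, resolution = 0.8, seed = 1)
clusterSummaryTable(clusters)
#>   cluster nCells percent
#> 1       0    286    47.3
#> 2       1    194    32.1
#> 3       2    125    20.7
```

Cluster labels are ordered by size, largest first, and the percent
column sums to 100 up to rounding. Markers and signatures:

```r
markers <- findClusterMarkers(sce, clusters)
signatures <- buildSignatures(markers, maxGenes = 100, alpha = 0.05)
signatures
#> SignatureCollection with 3 gene sets
#>   cluster0: 50 genes
#>   cluster1: 50 genes
#>   cluster2: 51 genes
#>   backed by 3000 marker-statistic rows
```

Each signature recovers essentially the 50 planted marker genes of its
type. Score simulated tumors (purity 0.8, log2-scale noise sd 1) and
classify:

```r
bulk <- simulateBulk(BulkSimParams(nTumors = 100, purity = 0.8, noiseSD = 1,
                                   subtypeRule = defaultSubtypeRule(3),
                                   hazardMultipliers = c(1, 1, 3), seed = 7),
                     typeProfilesFromCells(sce))
scores <- gsvaScores(assay(bulk), signatures)
scores
#> GsvaScores: 3 gene sets x 100 samples (mode max_diff , tau 1 )
#>   gene universe: 1000 genes
#>   score range: -0.614 ..  0.720

records <- buildTumorRecords(assignClusters(scores), colData(bulk))
coverageReport(records, subset = c("cluster0", "cluster1"))$table
#>    cluster  n percent
#> 1 cluster0 29      29
#> 2 cluster1 39      39
#> 3 cluster2 32      32
```

All 100 tumors classify to the cluster of their generating type, so the
receptor cross-tab is diagonal (the 3-type default rule has no
triple-negative type, hence the warning):

```r
subtypeCrosstab(records)
#>          cluster0 cluster1 cluster2
#> ER+HER2-      100        0        0
#> ER+HER2+        0      100        0
#> ER-HER2+        0        0      100
```

Survival separates the high-hazard group:

```r
survivalByCluster(records, reference = "cluster0")
#> Log-rank test: 3 groups
#>          observed expected
#> cluster0       19 22.59873
#> cluster1       24 30.15017
#> cluster2       26 16.25110
#> chi-square = 8.018 on 2 df, p = 0.01815
#> trend chi-square = 4.964 on 1 df, p = 0.02588
#> Hazard ratios vs cluster cluster0 :
#>   cluster1 : Mantel-Haenszel HR = 0.9618 (95% CI 0.526-1.758)
#>   cluster2 : Mantel-Haenszel HR = 1.9004 (95% CI 1.051-3.436)
```

Cluster 2 tumors (the 3× hazard type) show excess observed events and an
elevated hazard ratio; at n = 100 the Mantel–Haenszel estimate is
attenuated relative to the true 3×, as expected of the O/E estimator.

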