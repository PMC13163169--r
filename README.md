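# nestwgcna

Two-stage (nested) weighted gene co-expression network analysis for bulk
transcriptomes, for researchers who need both the broad modules that track
major cell types or processes **and** the compact gene sets corresponding to
subprocesses hidden inside them.

## The method

Stage one builds a co-expression network from the coefficient of
determination,

```
a_ij = corr(gene_i, gene_j)^2        (fixed soft threshold, beta = 2)
d_ij = 1 - a_ij
```

embeds the genes with UMAP (treating `d` as precomputed distances, with
`n_components ≈ log2(N) + 1` for `N` samples, `n_neighbors = 2 ·
min_cluster_size`, `min_samples = min_cluster_size / 2`) and clusters the
embedding with HDBSCAN. The resulting **coarse-grained modules (CGMs)**
reflect major co-expression programs; genes in no dense region stay
unassigned (label `-1`).

Stage two extracts each CGM's **core** — the maximum *weighted k-core* of
the complete graph on its genes weighted by `a_ij`, i.e. the largest `k`
such that every retained gene keeps total within-subgraph edge weight ≥ `k`
— and removes the core's signal from all module genes: genes whose Spearman
correlation with the core eigengene (first principal component of the core
submatrix) exceeds 0.9 form a normalization set whose per-sample mean
expression divides every gene (with self-exclusion for the set's own genes,
and a coefficient-of-variation filter between two normalization passes).
Re-running network inference on the normalized module yields
**fine-grained modules (FGMs)**: gene sets that stay co-expressed after the
dominant factor is gone, interpretable as subprocesses or cell subsets.
FGM activity per sample can then be scored raw or relative to its CGM core
(mean z-scored log2 expression difference) and median-dichotomized for
downstream survival or response analyses.

The package also provides the evaluation machinery around the pipeline:
bootstrap and cross-dataset clustering stability (ARI, AMI, V-measure), a
transcription-factor co-regulation odds ratio ("knowledge score") with an
exact hypergeometric test, and a calibrated synthetic-data generator with
planted hierarchical structure (module factors, nested sub-factors,
housekeeping hubs, noise genes) so that every stage is testable without
access to clinical cohorts.

UMAP, HDBSCAN and the agreement metrics are implemented inside the package
and cross-checked against the reference implementations; all stochastic
steps are seeded and single-threaded, so a full run is byte-reproducible.

## Worked example

```r
library(nestwgcna)

## 1750 genes x 150 samples: 4 planted modules + housekeeping + noise genes
ds <- generate_synthetic(scenario("default", seed = 1))

asn <- detect_cgms(ds$expr, min_cluster_size = 50, seed = 1)
asn
#> module_assignment [CGM]: 1750 genes, 5 modules, 369 unassigned
round(compare_clusterings(asn, ds$truth_cgm), 3)
#>       ari       ami v_measure
#>     0.741     0.797     0.798

log_expr <- expr_matrix(log2(ds$expr$values + 1), "log")
adj  <- compute_adjacency(log_expr)
g0   <- module_genes(asn, 0)
core <- extract_core(g0, adj)
length(core) / length(g0)      # core = 202 of 361 genes (56%)

fg <- infer_fgms(ds$expr, g0, core, fgm_min_cluster_size = 15,
                 seed = 1, rho_threshold = 0.6)
vapply(fg$fgm_gene_sets, length, 1L)
#> FGM_0 FGM_1 FGM_2 FGM_3
#>    76    44    43    42
fg$normalization
#> normalization_result: 125 initial INGS, 109 final INGS, 150 samples

sc <- score_module(ds$expr, fg$fgm_gene_sets$FGM_0, core_genes = core)
head(sc, 3)
#>   sample_id    raw normalized
#> 1      S001 0.0440      0.537
#> 2      S002 0.0711     -0.307
#> 3      S003 0.5447     -0.274
table(dichotomize_scores(sc))
#> high  low
#>   75   75
```

The detected modules recover the planted module genes almost perfectly
(ARI ≥ 0.96 over planted genes; the 0.74 above counts the unstructured
genes, some of which attach to clusters). Three of the FGMs (44/43/42
genes) are the three planted 40-gene sub-factor blocks of module 0,
invisible at the coarse level; `rho_threshold` is lowered to 0.6 here
because at this scenario's noise level no gene reaches a Spearman
correlation of 0.9 with the eigengene. For an end-to-end run that writes
GMT/TSV/JSON outputs use `run_full(run_config(...))`, or the CLI:

```sh
Rscript inst/scripts/nestwgcna.R run --input expr.tsv --out results/ --seed 1
```

(subcommands: `run`, `simulate`, `core`, `fgm`, `stability`, `kscore`,
`score`).

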