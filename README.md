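# bcdist — Batch-Corrected Distance for longitudinal single-cell data

Batch effects — systematic technical differences between separately
processed samples — distort distance-based clustering and embedding of
single-cell RNA-seq data. In longitudinal or spatially resolved designs the
standard integration tools over-correct: they cannot tell developmental
change between time points from technical drift, and remove both.

`bcdist` implements the **Batch-Corrected Distance (BCD)**, a
Mahalanobis-type metric that exploits *temporal/spatial locality*: batch
effects are roughly uniform across samples, while biological differences
grow with separation in time or space, so differences between adjacent
samples are disproportionately technical. BCD replaces the covariance in

d(i, j) = sqrt( (x_i − x_j)ᵀ Σ̃⁻¹ (x_i − x_j) )

with one built from deviations of each cell to the centroids m_j of *other*
batches, weighted by a Gaussian kernel on the sample labels:

Σ̃ = Σ_i Σ_{j : i ∉ C_j} W_ij (x_i − m_j)(x_i − m_j)ᵀ,
W_ij = exp( −‖τ_i − t_j‖² / (2 l²) )

Deviations toward temporally proximal batches dominate Σ̃ and are shrunk by
its inverse. With W ≡ 1 this degrades to the Qi–Davidson
alternative-clustering metric. The inverse Cholesky factor of Σ̃ whitens the
data, so any Euclidean-distance-based method (k-NN graphs, Leiden
clustering, UMAP) runs unchanged on the whitened embedding. Cost is
O(nk² + k³) on k PCs — no pairwise matrix needed.

The package also ships the synthetic validation benchmark (a 7-node
branching differentiation tree sampled as 7 samples over 4 days, with
additive batch effects on a susceptible gene subset and Poisson counts) and
the standard preprocessing pipeline (sum-to-one normalization, highly
variable gene selection, scaling, PCA) feeding the metric.

## Worked example

```r
library(bcdist)

bench <- simulate_benchmark(seed = 1)        # 3,500 cells x 200 genes, 7 samples
bench
#> Synthetic differentiation benchmark: 3500 cells x 200 genes, 7 samples over days 1-4

eu <- run_benchmark_analysis(bench, "euclidean", seed = 1)  # 150 HVGs, 30 PCs
bc <- run_benchmark_analysis(bench, "bcd", seed = 1)        # + whitening, l = 1

pure <- bench$metadata$cell_type %in% rownames(bench$profiles)
ev <- function(r) evaluate_clustering(r$clusters[pure],
                                      bench$metadata$cell_type[pure],
                                      bench$metadata$sample_id[pure])
c(ari_euclidean = ev(eu)$ari, ari_bcd = ev(bc)$ari)
#> ari_euclidean       ari_bcd
#>     0.5506979     0.9152065
```

Euclidean preprocessing yields 14 clusters: each terminal cell type
(A1/A2/B1/B2) splits into two per-sample clusters (batch-mixing entropy 0
within each type). The identical pipeline with the BCD whitening step finds
7 clusters matching the 7 true cell types — ARI 0.92 vs 0.55 — with the two
same-day replicates perfectly mixed inside each terminal type (entropy 1.0).

For arbitrary data, use the pieces directly:

```r
norm <- normalize_counts(counts)                      # rows sum to 1
hvg  <- select_hvg(norm, 2000)
emb  <- scale_and_pca(norm[, hvg], n_pcs = 30)$scores
d    <- bcd_pairwise(emb, meta$sample, cell_times = meta$day, length_scale = 1)
# or keep it implicit and Euclidean-compatible:
res  <- run_bcd_pipeline(counts, meta, metric = "bcd",
                         sample_col = "sample", time_cols = c("week", "location"))
```

Vector labels mix time and space (e.g. weeks plus a 0/2/4 location coding);
the numeric coding defines the geometry. A thin command-line front end with
`simulate`, `run` and `distances` subcommands is in `inst/cli/bcd.R`.

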