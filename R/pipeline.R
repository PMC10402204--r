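#' Sum-to-one normalization of a count matrix
#'
#' Divides each cell's counts by its total so every row sums to one. Cells
#' with zero total counts are dropped (with a message reporting how many).
#' Optionally applies `log(1 + scale_factor * x)` afterwards; the default is
#' the plain sum-to-one protocol with no log transform.
#'
#' @param counts N x G non-negative matrix (cells x genes).
#' @param log_transform apply the log1p transform after normalization.
#' @param scale_factor multiplier inside the log (default 1e4), ignored
#'   unless `log_transform` is TRUE.
#' @return normalized matrix (possibly fewer rows); attribute
#'   `"dropped_cells"` holds the number of removed zero-count cells.
#' @export
normalize_counts <- function(counts, log_transform = FALSE,
                             scale_factor = 1e4) {
  x <- as.matrix(counts)
  storage.mode(x) <- "double"
  if (any(x < 0)) stop("counts must be non-negative")
  tot <- rowSums(x)
  drop <- tot == 0
  if (all(drop)) stop("all cells have zero total counts")
  if (any(drop)) {
    message("dropping ", sum(drop), " cell(s) with zero total counts")
    x <- x[!drop, , drop = FALSE]
    tot <- tot[!drop]
  }
  x <- x / tot
  if (log_transform) x <- log1p(scale_factor * x)
  attr(x, "dropped_cells") <- sum(drop)
  x
}

#' Highly variable gene selection (simplified variance-stabilizing ranking)
#'
#' Ranks genes by standardized variance: a mean--variance trend is estimated
#' by binned medians of log10 variance against log10 mean (a local-regression
#'-free stand-in for the usual VST trend fit), each gene's values are
#' z-scored against its trend-expected standard deviation, clipped at
#' sqrt(N), and the variance of the clipped z-scores is the ranking
#' statistic. Deterministic; ties broken by gene order.
#'
#' @param x N x G normalized expression matrix.
#' @param n_hvg number of genes to keep.
#' @param n_bins number of equal-count mean bins for the trend (default 20).
#' @return integer vector of `n_hvg` gene column indices, in decreasing order
#'   of standardized variance.
#' @export
select_hvg <- function(x, n_hvg, n_bins = 20) {
  x <- as.matrix(x)
  G <- ncol(x)
  if (n_hvg > G) stop("n_hvg (", n_hvg, ") exceeds the number of genes (", G, ")")
  n <- nrow(x)
  mu <- colMeans(x)
  v <- (colSums(x^2) - n * mu^2) / (n - 1)
  v[v < 0] <- 0
  std_var <- numeric(G)
  ok <- v > 0 & mu > 0
  if (any(ok)) {
    lm_ <- log10(mu[ok])
    lv <- log10(v[ok])
    n_bins <- max(1L, min(n_bins, sum(ok)))
    bins <- cut(rank(lm_, ties.method = "first"),
                breaks = n_bins, labels = FALSE)
    bin_mu <- tapply(lm_, bins, stats::median)
    bin_lv <- tapply(lv, bins, stats::median)
    exp_lv <- if (n_bins == 1L) rep(bin_lv, sum(ok)) else {
      stats::approx(bin_mu, bin_lv, xout = lm_, rule = 2)$y
    }
    exp_sd <- sqrt(10^exp_lv)
    clip <- sqrt(n)
    z <- sweep(sweep(x[, ok, drop = FALSE], 2L, mu[ok], "-"), 2L, exp_sd, "/")
    z[z > clip] <- clip
    z[z < -clip] <- -clip
    zmu <- colMeans(z)
    std_var[ok] <- (colSums(z^2) - n * zmu^2) / (n - 1)
  }
  order(-std_var, seq_len(G))[seq_len(n_hvg)]
}

#' Per-gene scaling and principal component analysis
#'
#' Standardizes each gene to mean zero and unit standard deviation
#' (zero-variance genes are set to all zeros with a warning), then projects
#' onto the top principal components. Component signs are fixed by making
#' the largest-magnitude loading of each component positive, so the result
#' is fully deterministic.
#'
#' @param x N x G normalized (and HVG-subset) expression matrix.
#' @param n_pcs number of principal components (default 30).
#' @return list with `scores` (N x n_pcs embedding), `rotation` (G x n_pcs
#'   loadings), `sdev` (component standard deviations), `center`, `scale`.
#' @export
scale_and_pca <- function(x, n_pcs = 30) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n_pcs > min(n - 1L, ncol(x))) {
    stop("n_pcs (", n_pcs, ") exceeds min(N - 1, G) = ", min(n - 1L, ncol(x)))
  }
  mu <- colMeans(x)
  sd_ <- apply(x, 2L, stats::sd)
  zero_var <- sd_ == 0
  if (any(zero_var)) {
    warning(sum(zero_var), " zero-variance gene(s) set to 0 before PCA")
    sd_[zero_var] <- 1
  }
  z <- sweep(sweep(x, 2L, mu, "-"), 2L, sd_, "/")
  z[, zero_var] <- 0
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE, rank. = n_pcs)
  rot <- pc$rotation
  flip <- apply(rot, 2L, function(col) col[which.max(abs(col))] < 0)
  rot[, flip] <- -rot[, flip]
  scores <- z %*% rot
  rownames(scores) <- rownames(x)
  list(scores = scores, rotation = rot, sdev = pc$sdev[seq_len(n_pcs)],
       center = mu, scale = sd_)
}

#' k-nearest-neighbor graph from an embedding
#'
#' Undirected union-kNN graph on Euclidean distances in the given space.
#'
#' @param y N x k embedding (whitened for BCD, raw PCs for Euclidean).
#' @param k number of neighbors (default 15).
#' @return an undirected `igraph` graph with N vertices.
#' @export
knn_graph <- function(y, k = 15) {
  y <- as.matrix(y)
  n <- nrow(y)
  if (k >= n) stop("k must be smaller than the number of cells")
  d <- as.matrix(stats::dist(y))
  nn <- t(apply(d, 1L, function(row) order(row)[2:(k + 1L)]))
  edges <- cbind(rep(seq_len(n), each = k), as.vector(t(nn)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::simplify(g)
}

#' Leiden community clustering of a neighbor graph
#'
#' Modularity-objective Leiden clustering; deterministic for a fixed seed.
#'
#' @param graph igraph graph from [knn_graph()].
#' @param resolution resolution parameter (default 1).
#' @param seed RNG seed for the algorithm's refinement step.
#' @return integer vector of cluster memberships.
#' @export
cluster_graph <- function(graph, resolution = 1, seed = 1) {
  with_seed(seed, {
    cl <- igraph::cluster_leiden(graph, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 5)
    igraph::membership(cl)
  })
}

#' Two-dimensional UMAP layout
#'
#' Nonlinear 2-D embedding of the (whitened) space for visualization.
#' Requires the `uwot` package; layout coordinates are for plotting only and
#' feed no quantitative result.
#'
#' @param y N x k embedding.
#' @param n_neighbors,min_dist UMAP parameters.
#' @param seed RNG seed.
#' @return N x 2 coordinate matrix.
#' @export
umap_layout <- function(y, n_neighbors = 15, min_dist = 0.3, seed = 1) {
  if (!requireNamespace("uwot", quietly = TRUE)) {
    stop("the 'uwot' package is required for UMAP layouts")
  }
  with_seed(seed, {
    coords <- uwot::umap(as.matrix(y), n_neighbors = n_neighbors,
                         min_dist = min_dist, n_threads = 1)
    dimnames(coords) <- list(rownames(y), c("UMAP1", "UMAP2"))
    coords
  })
}

#' End-to-end BCD (or Euclidean baseline) analysis pipeline
#'
#' Standard single-cell protocol feeding the metric: sum-to-one
#' normalization, highly variable gene selection, per-gene scaling, PCA,
#' then -- for `metric = "bcd"` -- whitening of the PC scores with the
#' batch-corrected covariance, a k-NN graph in the (whitened) space, Leiden
#' clustering, and optionally a UMAP layout. With `metric = "euclidean"` the
#' whitening step is the identity, giving the uncorrected baseline on
#' exactly the same preprocessing.
#'
#' @param counts N x G count matrix (cells x genes).
#' @param metadata data.frame aligned with the rows of `counts`; must
#'   contain `sample_col` and `time_cols`.
#' @param metric `"bcd"` or `"euclidean"`.
#' @param sample_col metadata column naming each cell's sample; each sample
#'   is one batch.
#' @param time_cols metadata column(s) holding the numeric temporal and/or
#'   spatial labels (e.g. `"day"`, or `c("week", "location")`).
#' @param n_hvg,n_pcs,log_transform preprocessing settings (see
#'   [select_hvg()], [scale_and_pca()], [normalize_counts()]).
#' @param length_scale,normalize,ridge metric settings (see
#'   [corrected_covariance()]).
#' @param knn_k,resolution graph and clustering settings.
#' @param layout also compute a UMAP layout (needs `uwot`).
#' @param seed RNG seed for clustering (and layout).
#' @return object of class `"bcd_pipeline"`: list with `embedding` (PC
#'   scores), `whitened`, `covariance` (`NULL` for Euclidean), `graph`,
#'   `clusters`, `layout` (or `NULL`), `hvg` (gene indices), `metadata`
#'   (zero-count cells removed), `config`.
#' @export
run_bcd_pipeline <- function(counts, metadata,
                             metric = c("bcd", "euclidean"),
                             sample_col = "sample_id", time_cols = "day",
                             n_hvg = 2000, n_pcs = 30, log_transform = FALSE,
                             length_scale = 1, normalize = TRUE, ridge = NULL,
                             knn_k = 15, resolution = 1, layout = FALSE,
                             seed = 1) {
  metric <- match.arg(metric)
  missing_cols <- setdiff(c(sample_col, time_cols), colnames(metadata))
  if (length(missing_cols) > 0) {
    stop("metadata is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(metadata) != nrow(counts)) {
    stop("metadata and counts describe different numbers of cells")
  }
  norm <- normalize_counts(counts, log_transform = log_transform)
  if (attr(norm, "dropped_cells") > 0) {
    kept <- rownames(norm)
    metadata <- metadata[match(kept, rownames(counts)), , drop = FALSE]
  }
  hvg <- select_hvg(norm, n_hvg = min(n_hvg, ncol(norm)))
  pca <- scale_and_pca(norm[, hvg, drop = FALSE], n_pcs = n_pcs)
  emb <- pca$scores
  cov <- NULL
  if (metric == "bcd") {
    tau <- as.matrix(metadata[, time_cols, drop = FALSE])
    cov <- corrected_covariance(
      emb, metadata[[sample_col]],
      weights = locality_weights(
        tau, batch_times_from_cells(tau, metadata[[sample_col]]),
        length_scale = length_scale),
      normalize = normalize, ridge = ridge)
    whitened <- bcd_transform(emb, cov)
  } else {
    whitened <- emb
  }
  graph <- knn_graph(whitened, k = knn_k)
  clusters <- cluster_graph(graph, resolution = resolution, seed = seed)
  coords <- if (layout) umap_layout(whitened, seed = seed) else NULL
  structure(
    list(embedding = emb, whitened = whitened, covariance = cov,
         graph = graph, clusters = as.integer(clusters), layout = coords,
         hvg = hvg, metadata = metadata,
         config = list(metric = metric, sample_col = sample_col,
                       time_cols = time_cols, n_hvg = n_hvg, n_pcs = n_pcs,
                       log_transform = log_transform,
                       length_scale = length_scale, knn_k = knn_k,
                       resolution = resolution, seed = seed)),
    class = "bcd_pipeline"
  )
}

#' @export
print.bcd_pipeline <- function(x, ...) {
  cat("BCD pipeline run (metric:", x$config$metric, ")\n")
  cat("  cells:", nrow(x$embedding), "| HVGs:", length(x$hvg),
      "| PCs:", ncol(x$embedding),
      "| clusters:", length(unique(x$clusters)), "\n")
  invisible(x)
}

#' Analyze the synthetic benchmark with the reference configuration
#'
#' Runs [run_bcd_pipeline()] on a benchmark object with the configuration
#' used for the simulated-data analysis: 150 highly variable genes, 30
#' principal components, length scale 1, sample = batch, day as the time
#' label.
#'
#' @param bench a `"bcd_benchmark"` object from [simulate_benchmark()].
#' @param metric `"bcd"` or `"euclidean"`.
#' @param ... further arguments to [run_bcd_pipeline()].
#' @param seed RNG seed for clustering.
#' @return a `"bcd_pipeline"` object.
#' @export
run_benchmark_analysis <- function(bench, metric = c("bcd", "euclidean"),
                                   seed = 1, ...) {
  stopifnot(inherits(bench, "bcd_benchmark"))
  run_bcd_pipeline(bench$counts, bench$metadata, metric = match.arg(metric),
                   sample_col = "sample_id", time_cols = "day",
                   n_hvg = 150, n_pcs = 30, length_scale = 1,
                   seed = seed, ...)
}
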