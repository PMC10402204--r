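#' Quantitative evaluation of a clustering against ground truth
#'
#' Two complementary views of batch-correction quality:
#' \itemize{
#'   \item `ari`: Adjusted Rand Index between the clustering and the
#'     ground-truth cell-type labels (chance-corrected agreement, 1 =
#'     identical partitions).
#'   \item `type_entropy`: for each ground-truth type, the normalized
#'     Shannon entropy of the sample composition of its cells *within the
#'     type's majority cluster*. 1 means the samples contributing that type
#'     are perfectly mixed inside one cluster; values near 0 mean the
#'     majority cluster is dominated by a single sample (the batch-split
#'     failure mode). Normalization is by log of the number of distinct
#'     samples in which the type occurs; types confined to one sample give
#'     `NA`.
#'   \item `split_by_sample`: for each type, whether its cells' per-sample
#'     majority clusters disagree (only samples contributing at least
#'     `min_cells` cells of the type are considered) -- i.e. whether the
#'     type is split into different clusters by sample.
#' }
#'
#' @param clusters cluster assignment per cell.
#' @param labels ground-truth cell-type label per cell.
#' @param samples sample/batch id per cell.
#' @param min_cells minimum cells of a type in a sample for that sample to
#'   count in the split test (default 10).
#' @return list with `ari` (scalar), `type_entropy` (named numeric), and
#'   `split_by_sample` (named logical).
#' @export
evaluate_clustering <- function(clusters, labels, samples, min_cells = 10) {
  n <- length(clusters)
  if (length(labels) != n || length(samples) != n) {
    stop("clusters, labels and samples must have equal length")
  }
  clusters <- as.character(clusters)
  labels <- as.character(labels)
  samples <- as.character(samples)
  ari <- mclust::adjustedRandIndex(clusters, labels)
  types <- sort(unique(labels))
  ent <- vapply(types, function(t) {
    idx <- labels == t
    n_samp <- length(unique(samples[idx]))
    if (n_samp < 2L) return(NA_real_)
    maj <- names(sort(table(clusters[idx]), decreasing = TRUE))[1]
    inside <- idx & clusters == maj
    p <- table(samples[inside])
    p <- p / sum(p)
    h <- -sum(ifelse(p > 0, p * log(p), 0))
    h / log(n_samp)
  }, numeric(1))
  split <- vapply(types, function(t) {
    idx <- labels == t
    per_sample <- table(samples[idx])
    use <- names(per_sample)[per_sample >= min_cells]
    if (length(use) < 2L) return(FALSE)
    majs <- vapply(use, function(s) {
      cl <- clusters[idx & samples == s]
      names(sort(table(cl), decreasing = TRUE))[1]
    }, character(1))
    length(unique(majs)) > 1L
  }, logical(1))
  list(ari = ari, type_entropy = ent, split_by_sample = split)
}
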