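#' Batch centroids
#'
#' Arithmetic mean of the embedding rows within each batch.
#'
#' @param x n x k numeric matrix (cells x features).
#' @param batch factor or vector of per-cell batch assignments; every batch
#'   must be non-empty.
#' @return B x k matrix, rows named and ordered by `levels(factor(batch))`.
#' @export
batch_centroids <- function(x, batch) {
  x <- check_embedding(x)
  b <- as.factor(batch)
  if (length(b) != nrow(x)) stop("batch must have one entry per row of x")
  if (anyNA(b)) stop("batch assignments contain NA")
  counts <- tabulate(b, nbins = nlevels(b))
  if (any(counts == 0L)) {
    stop("empty batch(es): ", paste(levels(b)[counts == 0L], collapse = ", "))
  }
  m <- rowsum(x, b) / counts
  rownames(m) <- levels(b)
  m
}

#' Batch-corrected covariance and whitening transform
#'
#' Builds the covariance
#' \deqn{\tilde\Sigma = \sum_i \sum_{j : i \notin C_j}
#'   W_{ij} (x_i - m_j)(x_i - m_j)^\top}
#' from the deviations of each cell to the centroids \eqn{m_j} of the *other*
#' batches, weighted by the locality weights W (own-batch terms are excluded).
#' With `weights = NULL` all weights are one and \eqn{\tilde\Sigma} is the
#' Qi--Davidson alternative-clustering covariance. The upper Cholesky factor
#' R of the ridged matrix (\eqn{\tilde\Sigma + \epsilon I = R^\top R}) gives
#' the whitener \eqn{T = R^{-1}}: Euclidean distances between rows of
#' \code{x \%*\% T} equal the Mahalanobis form under \eqn{\tilde\Sigma}.
#'
#' The computation is organised per batch (centroid subtraction plus one
#' weighted cross-product), so the cost is O(nBk^2 + k^3) with no n^2 term.
#'
#' @param x n x k numeric matrix, typically PC scores (see [scale_and_pca()]).
#' @param batch per-cell batch assignment; at least 2 batches (with a single
#'   batch every cell belongs to every \eqn{C_j} and the sum is empty).
#' @param weights optional n x B locality weight matrix from
#'   [locality_weights()], columns in `levels(factor(batch))` order. `NULL`
#'   means all ones.
#' @param normalize divide \eqn{\tilde\Sigma} by the total weight mass
#'   \eqn{\sum_{i, j: i \notin C_j} W_{ij}} (default TRUE) so its scale, and
#'   hence the meaning of `ridge`, does not grow with n and B.
#' @param ridge non-negative value added to the diagonal before factorization;
#'   default `1e-8 * mean(diag(sigma))`. The unridged sigma can be singular
#'   (rank-deficient deviations); a pseudoinverse is deliberately not used
#'   because it would alter the metric's null space silently.
#' @return object of class `"bcd_cov"`: list with elements `sigma` (k x k,
#'   symmetric PSD), `whitener` (k x k upper-triangular, apply as
#'   `x %*% whitener`), `ridge`, `total_weight`, `normalized`.
#' @seealso [bcd_transform()], [bcd_pairwise()]
#' @export
corrected_covariance <- function(x, batch, weights = NULL, normalize = TRUE,
                                 ridge = NULL) {
  x <- check_embedding(x)
  n <- nrow(x)
  k <- ncol(x)
  b <- as.factor(batch)
  if (length(b) != n) stop("batch must have one entry per row of x")
  B <- nlevels(b)
  if (B < 2L) {
    stop("batch-corrected covariance undefined with a single batch: ",
         "every cell is excluded from every term of the sum")
  }
  m <- batch_centroids(x, b)
  if (is.null(weights)) {
    weights <- matrix(1, n, B)
  }
  weights <- as.matrix(weights)
  if (!all(dim(weights) == c(n, B))) {
    stop("weights must be an n x B matrix (", n, " x ", B, ")")
  }
  if (any(!is.finite(weights)) || any(weights < 0)) {
    stop("weights must be finite and non-negative")
  }
  # mask own-batch entries: Eq. excludes i in C_j
  w <- weights
  w[cbind(seq_len(n), as.integer(b))] <- 0
  sigma <- matrix(0, k, k)
  for (j in seq_len(B)) {
    wj <- w[, j]
    use <- wj > 0
    if (!any(use)) next
    dev <- sweep(x[use, , drop = FALSE], 2L, m[j, ], "-")
    sigma <- sigma + crossprod(dev * sqrt(wj[use]))
  }
  total_weight <- sum(w)
  if (normalize) {
    if (total_weight <= 0) stop("total locality weight mass is zero")
    sigma <- sigma / total_weight
  }
  sigma <- (sigma + t(sigma)) / 2  # enforce exact symmetry
  if (is.null(ridge)) ridge <- 1e-8 * mean(diag(sigma))
  if (!is.numeric(ridge) || length(ridge) != 1L || !is.finite(ridge) ||
      ridge < 0) {
    stop("ridge must be a single non-negative number")
  }
  ridged <- sigma + diag(ridge, k)
  R <- tryCatch(chol(ridged), error = function(e) {
    stop("Cholesky factorization of the ridged covariance failed (",
         conditionMessage(e),
         "); the corrected covariance is numerically singular - raise `ridge`",
         call. = FALSE)
  })
  structure(
    list(sigma = sigma, whitener = backsolve(R, diag(k)), ridge = ridge,
         total_weight = total_weight, normalized = normalize,
         batch_levels = levels(b)),
    class = "bcd_cov"
  )
}

#' @export
print.bcd_cov <- function(x, ...) {
  cat("Batch-corrected covariance (", nrow(x$sigma), " x ", ncol(x$sigma),
      ")\n", sep = "")
  cat("  batches:", length(x$batch_levels),
      "| ridge:", format(x$ridge),
      "| weight-normalized:", x$normalized, "\n")
  ev <- eigen(x$sigma, symmetric = TRUE, only.values = TRUE)$values
  cat("  eigenvalue range: [", format(min(ev)), ",", format(max(ev)), "]\n")
  invisible(x)
}

#' Whiten an embedding with a batch-corrected covariance
#'
#' Applies the inverse-Cholesky whitener so that Euclidean distances between
#' the returned rows equal the Mahalanobis distances under the ridged
#' \eqn{\tilde\Sigma}.
#'
#' @param x n x k matrix; k must match the covariance.
#' @param cov a `"bcd_cov"` object from [corrected_covariance()].
#' @return n x k whitened matrix (same dimnames as `x`).
#' @export
bcd_transform <- function(x, cov) {
  x <- check_embedding(x)
  if (!inherits(cov, "bcd_cov")) stop("cov must be a 'bcd_cov' object")
  k <- ncol(cov$whitener)
  if (ncol(x) != k) {
    stop("feature dimension mismatch: x has ", ncol(x),
         " columns but the covariance is ", k, " x ", k)
  }
  y <- x %*% cov$whitener
  dimnames(y) <- dimnames(x)
  y
}

#' Pairwise Batch-Corrected Distances
#'
#' Convenience composition: locality weights from the labels, corrected
#' covariance, whitening, then Euclidean distances in the whitened space.
#' The result is a true metric (a Euclidean distance on transformed
#' coordinates): symmetric, zero diagonal, triangle inequality.
#'
#' @inheritParams corrected_covariance
#' @param cell_times,batch_times time/space labels as in [locality_weights()];
#'   `batch_times = NULL` derives them from the cells via
#'   [batch_times_from_cells()]. If `cell_times` is also `NULL`, all weights
#'   are one (Qi--Davidson limit).
#' @param length_scale Gaussian kernel length scale l (default 1, the value
#'   used throughout the reference analyses).
#' @return n x n symmetric distance matrix.
#' @export
bcd_pairwise <- function(x, batch, cell_times = NULL, batch_times = NULL,
                         length_scale = 1, normalize = TRUE, ridge = NULL) {
  x <- check_embedding(x)
  b <- as.factor(batch)
  w <- NULL
  if (!is.null(cell_times)) {
    if (is.null(batch_times)) {
      batch_times <- batch_times_from_cells(cell_times, b)
    }
    w <- locality_weights(cell_times, batch_times, length_scale)
  }
  cv <- corrected_covariance(x, b, weights = w, normalize = normalize,
                             ridge = ridge)
  y <- bcd_transform(x, cv)
  as.matrix(stats::dist(y))
}

# shared input checks for embedding matrices
check_embedding <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) < 1L || ncol(x) < 1L) stop("x must have at least 1 row and column")
  if (any(!is.finite(x))) stop("x contains non-finite values")
  x
}
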