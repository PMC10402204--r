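# Independent brute-force oracles and random-instance generators.
# These deliberately use naive nested loops (O(n * B * k^2) scalar ops with
# explicit outer products) so they share no code path with the package's
# vectorized implementation.

# quadruple-nested evaluation of the batch-excluding weighted covariance:
# sum over cells i, batches j with i not in C_j, and entries (a, b)
brute_force_sigma <- function(x, batch, w = NULL, normalize = FALSE) {
  b <- as.factor(batch)
  n <- nrow(x)
  k <- ncol(x)
  B <- nlevels(b)
  if (is.null(w)) w <- matrix(1, n, B)
  m <- matrix(0, B, k)
  for (j in seq_len(B)) {
    idx <- which(as.integer(b) == j)
    for (a in seq_len(k)) m[j, a] <- mean(x[idx, a])
  }
  sigma <- matrix(0, k, k)
  total <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(B)) {
      if (as.integer(b)[i] == j) next
      d <- x[i, ] - m[j, ]
      for (a in seq_len(k)) {
        for (bb in seq_len(k)) {
          sigma[a, bb] <- sigma[a, bb] + w[i, j] * d[a] * d[bb]
        }
      }
      total <- total + w[i, j]
    }
  }
  if (normalize) sigma <- sigma / total
  sigma
}

# scalar evaluation of the Mahalanobis quadratic form sqrt(d' S^-1 d)
quadform_distance <- function(xi, xj, sigma) {
  d <- xi - xj
  sqrt(drop(t(d) %*% solve(sigma) %*% d))
}

# random core-module instance: n cells, k features, B non-empty batches,
# optional scalar time labels shared within batches
random_instance <- function(n, k, B, with_times = FALSE) {
  batch <- factor(c(seq_len(B), sample.int(B, n - B, replace = TRUE)))
  x <- matrix(rnorm(n * k), n, k)
  out <- list(x = x, batch = batch)
  if (with_times) {
    bt <- matrix(runif(B, 0, 5), B, 1)
    out$batch_times <- bt
    out$cell_times <- bt[as.integer(batch), , drop = FALSE]
  }
  out
}
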