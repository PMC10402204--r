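test_that("batch centroids are per-batch feature means", {
  x <- rbind(c(0, 0), c(2, 2), c(5, 1))
  m <- batch_centroids(x, c("g1", "g1", "g2"))
  expect_equal(unname(m["g1", ]), c(1, 1))
  expect_equal(unname(m["g2", ]), c(5, 1))   # single-cell batch = that cell
  # random instance against an independent per-batch loop
  set.seed(21)
  inst <- random_instance(6, 3, 2)
  m <- batch_centroids(inst$x, inst$batch)
  for (j in levels(inst$batch)) {
    expect_equal(unname(m[j, ]),
                 colMeans(inst$x[inst$batch == j, , drop = FALSE]))
  }
  expect_error(batch_centroids(x, factor(c("g1", "g1", "g1"),
                                         levels = c("g1", "g2"))), "empty")
})

test_that("corrected covariance matches hand evaluation on a 2-cell instance", {
  # cells 0 and 2 in their own batches, unit weights, unnormalized:
  # centroids are the cells themselves, sigma = (0-2)^2 + (2-0)^2 = 8
  x <- matrix(c(0, 2), ncol = 1)
  cv <- corrected_covariance(x, c(1, 2), normalize = FALSE)
  expect_equal(drop(cv$sigma), 8)
  # normalized by the total weight mass (2 cross terms)
  cv_n <- corrected_covariance(x, c(1, 2), normalize = TRUE)
  expect_equal(drop(cv_n$sigma), 4)
  expect_equal(cv_n$total_weight, 2)
})

test_that("corrected covariance equals the brute-force double sum", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(6:30, 1)
    k <- sample(2:5, 1)
    B <- sample(2:4, 1)
    inst <- random_instance(n, k, B, with_times = TRUE)
    w <- locality_weights(inst$cell_times, inst$batch_times,
                          length_scale = runif(1, 0.5, 2))
    for (normalize in c(FALSE, TRUE)) {
      cv <- corrected_covariance(inst$x, inst$batch, weights = w,
                                 normalize = normalize)
      ref <- brute_force_sigma(inst$x, inst$batch, w, normalize = normalize)
      expect_equal(cv$sigma, ref, tolerance = 1e-12)
    }
  }
})

test_that("unit weights reproduce the alternative-clustering covariance", {
  # W == 1 degrades the metric to the Qi-Davidson construction: the
  # brute-force unweighted loop is the independent reference
  set.seed(32)
  inst <- random_instance(30, 4, 3)
  cv <- corrected_covariance(inst$x, inst$batch, weights = NULL,
                             normalize = FALSE)
  ref <- brute_force_sigma(inst$x, inst$batch, w = NULL, normalize = FALSE)
  expect_lt(max(abs(cv$sigma - ref)), 1e-10)
  # equal labels make every weight one, so the labelled path agrees too
  w1 <- locality_weights(rep(2, 30), rep(2, 3))
  cvw <- corrected_covariance(inst$x, inst$batch, weights = w1,
                              normalize = FALSE)
  expect_equal(cvw$sigma, ref, tolerance = 1e-12)
})

test_that("covariance is symmetric positive semidefinite across instances", {
  set.seed(33)
  for (rep in 1:200) {
    n <- sample(5:50, 1)
    k <- sample(1:8, 1)
    B <- sample(2:min(5, n), 1)
    inst <- random_instance(n, k, B, with_times = TRUE)
    w <- locality_weights(inst$cell_times, inst$batch_times, 1)
    cv <- corrected_covariance(inst$x, inst$batch, weights = w)
    expect_lt(max(abs(cv$sigma - t(cv$sigma))), 1e-10 * max(1, max(abs(cv$sigma))))
    ev <- eigen(cv$sigma, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10 * max(abs(ev)))
  }
})

test_that("degenerate data yields a zero covariance, rescued only by ridging", {
  x <- matrix(1, 8, 3)  # all cells identical
  expect_error(corrected_covariance(x, rep(1:2, 4), ridge = 0), "singular")
  cv <- corrected_covariance(x, rep(1:2, 4), ridge = 1e-6)
  expect_equal(cv$sigma, matrix(0, 3, 3))
  expect_equal(cv$whitener, diag(3) / sqrt(1e-6), tolerance = 1e-8)
})

test_that("invalid batch structure and weights are rejected", {
  x <- matrix(rnorm(12), 6, 2)
  expect_error(corrected_covariance(x, rep(1, 6)), "single batch")
  expect_error(corrected_covariance(x, rep(1:2, 3),
                                    weights = matrix(1, 3, 2)), "n x B")
  expect_error(corrected_covariance(x, rep(1:2, 3),
                                    weights = matrix(-1, 6, 2)), "non-negative")
  expect_error(corrected_covariance(x, rep(1:2, 3), ridge = -1), "ridge")
  xbad <- x; xbad[1, 1] <- NA
  expect_error(corrected_covariance(xbad, rep(1:2, 3)), "non-finite")
})

test_that("covariance cost grows linearly in the number of cells", {
  # no n^2 term: quadrupling n should roughly quadruple the runtime
  k <- 30
  B <- 5
  timing <- function(n) {
    x <- matrix(rnorm(n * k), n, k)
    batch <- rep(seq_len(B), length.out = n)
    median(vapply(1:5, function(i) {
      system.time(corrected_covariance(x, batch))[["elapsed"]]
    }, numeric(1)))
  }
  set.seed(41)
  t1 <- timing(5000)
  t4 <- timing(20000)
  expect_lt(t4 / t1, 8)
  expect_gt(t4 / t1, 2)
})
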