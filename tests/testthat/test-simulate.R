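test_that("ideal profiles respect the differentiation tree geometry", {
  prof <- make_ideal_profiles(n_genes = 200, seed = 7)
  expect_equal(dim(prof), c(7L, 200L))
  expect_equal(rownames(prof), c("S", "A", "B", "A1", "A2", "B1", "B2"))
  expect_true(all(prof >= 0))
  expect_true(all(dist(prof) > 0))   # distinct rows
  d <- as.matrix(dist(prof))
  # parent-child pairs are closer than leaves on different branches
  tree <- cell_type_tree()
  pc <- mapply(function(p, q) d[p, q], tree$parent, tree$child)
  cross <- c(d["A1", "B1"], d["A1", "B2"], d["A2", "B1"], d["A2", "B2"])
  expect_true(max(pc) < min(cross))
  # determinism and the degenerate zero-separation control
  expect_identical(prof, make_ideal_profiles(n_genes = 200, seed = 7))
  flat <- make_ideal_profiles(n_genes = 10, separation = 0, seed = 7)
  expect_equal(max(dist(flat)), 0)
  expect_error(make_ideal_profiles(n_genes = 3), "at least 7")
})

test_that("profile mixing is the stated convex combination", {
  prof <- rbind(S = c(1, 1), A = c(2, 0), A1 = c(0, 2))
  expect_equal(mix_profile(prof, "A", "A1", 1), c(2, 0))
  expect_equal(mix_profile(prof, "A", "A1", 0), c(0, 2))
  expect_equal(mix_profile(prof, "A", "A1", 0.5), c(1, 1))
  expect_equal(unname(mix_profile(prof, "A", "A1", c(0.25, 0.75))),
               rbind(c(0.5, 1.5), c(1.5, 0.5)))
  expect_error(mix_profile(prof, "A", "A1", 1.2), "theta")
  expect_error(mix_profile(prof, "A", "Z", 0.5), "unknown")
})

test_that("states are labelled by the ambiguity band around theta = 0.5", {
  expect_equal(label_state("A", "A1", 0.5), "A->A1")
  expect_equal(label_state("A", "A1", 1.0), "A")
  expect_equal(label_state("A", "A1", 0.1), "A1")
  expect_equal(label_state("A", "A1", c(0.8, 0.75, 0.25, 0.2)),
               c("A", "A->A1", "A->A1", "A1"))
  expect_equal(label_state("S", "B", 0.3, ambiguity_band = c(0.4, 0.6)), "B")
})

test_that("the default design follows the 7-sample longitudinal layout", {
  des <- benchmark_design()
  samples <- unique(des[, c("sample_id", "day")])
  expect_equal(nrow(samples), 7L)
  expect_equal(as.vector(table(samples$day)), c(1L, 2L, 2L, 2L))
  expect_equal(as.numeric(tapply(des$fraction, des$sample_id, sum)),
               rep(1, 7), tolerance = 1e-12)
  # theta ranges progress toward the child end over the days
  expect_true(all(des$theta_lo[des$day == 1 & des$group == "S"] == 0.9))
  expect_true(all(des$theta_hi[des$day == 4 & des$group == "T"] == 0.25))
})

test_that("benchmark generation is deterministic and correctly shaped", {
  b1 <- simulate_benchmark(n_cells_per_sample = 60, seed = 99)
  b2 <- simulate_benchmark(n_cells_per_sample = 60, seed = 99)
  expect_identical(b1$counts, b2$counts)
  expect_identical(b1$metadata, b2$metadata)
  b3 <- simulate_benchmark(n_cells_per_sample = 60, seed = 100)
  expect_false(identical(b1$counts, b3$counts))
  expect_equal(dim(b1$counts), c(7L * 60L, 200L))
  expect_true(all(b1$counts >= 0))
  expect_type(b1$counts[1, 1], "integer")
  # every sample's cells share one day
  expect_equal(nrow(unique(b1$metadata[, c("sample_id", "day")])), 7L)
})

test_that("cell allocation reproduces the design fractions exactly", {
  b <- simulate_benchmark(n_cells_per_sample = 400, seed = 5)
  md <- b$metadata
  # day-1 sample: 80% cells on near-pure-S states, 20% early transitional
  d1 <- md[md$day == 1, ]
  expect_equal(nrow(d1), 400L)
  expect_equal(sum(d1$theta >= 0.9), 320L)
  expect_equal(sum(d1$theta < 0.9), 80L)
  # day-4 samples: half transitional, half terminal per sample
  for (s in unique(md$sample_id[md$day == 4])) {
    d4 <- md[md$sample_id == s, ]
    expect_equal(sum(d4$theta <= 0.25), 200L)
    expect_equal(sum(d4$theta > 0.25), 200L)
  }
})

test_that("batch shifts hit susceptible genes only, and visibly so", {
  b <- simulate_benchmark(n_cells_per_sample = 500, batch_sd = 3, seed = 13)
  expect_equal(length(b$susceptible_genes), 40L)  # 20% of 200
  expect_true(all(b$shifts[, -b$susceptible_genes] == 0))
  # same-day replicate samples differ in susceptible-gene means but not
  # (beyond noise) in unaffected genes
  md <- b$metadata
  s_day2 <- unique(md$sample_id[md$day == 2])
  m1 <- colMeans(b$counts[md$sample_id == s_day2[1], ])
  m2 <- colMeans(b$counts[md$sample_id == s_day2[2], ])
  se <- sqrt((apply(b$counts[md$sample_id == s_day2[1], ], 2, var) +
              apply(b$counts[md$sample_id == s_day2[2], ], 2, var)) / 500)
  z <- abs(m1 - m2) / pmax(se, 1e-9)
  sus <- b$susceptible_genes
  expect_gt(mean(z[sus]), 5 * mean(z[-sus]))
  expect_lt(stats::median(z[-sus]), 3)
})

test_that("counts are Poisson around the interpolated rates", {
  # zero noise, zero batch effect, fixed theta: empirical gene means over
  # many cells sit within Monte-Carlo error of the mixed rate vector
  prof <- make_ideal_profiles(n_genes = 50, seed = 3)
  des <- data.frame(sample_id = c("s1", "s2"), day = 1, group = "fix",
                    parent = "A", child = "A1",
                    theta_lo = 0.3, theta_hi = 0.3, fraction = 1)
  b <- simulate_benchmark(design = des, profiles = prof,
                          n_cells_per_sample = 2000,
                          batch_sd = 0, noise_sd = 0, seed = 17)
  rate <- mix_profile(prof, "A", "A1", 0.3)
  emp <- colMeans(b$counts)
  se <- sqrt(rate / nrow(b$counts))
  expect_true(all(abs(emp - rate) <= 4 * pmax(se, 1e-9)))
  expect_lt(mean(abs(emp - rate) / pmax(se, 1e-9)), 1.5)
})

test_that("degenerate simulator inputs are rejected", {
  expect_error(simulate_benchmark(noise_sd = -1), "noise_sd")
  expect_error(simulate_benchmark(design = benchmark_design()[0, ]), "empty")
  bad <- benchmark_design()
  bad$fraction <- bad$fraction * 2
  expect_error(simulate_benchmark(design = bad), "sum to 1")
})
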