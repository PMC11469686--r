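test_that("consistency is 1 for positive multiples of one vector and 0 for orthogonal replicates", {
  v <- c(3, 4)                 # norms 5, 10, 15 are exact in floating point
  perfect <- consistency(rbind(v, 2 * v, 3 * v))
  expect_identical(perfect$avgsim, 1)
  expect_identical(perfect$n_replicates, 3L)
  ortho <- consistency(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  expect_identical(ortho$avgsim, 0)
  # the literal all-pairs formula instead gives 1/n in the orthogonal case
  expect_equal(consistency(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                           include_self = TRUE)$avgsim, 1 / 3)
})

test_that("consistency matches hand enumeration of the three unordered pairs", {
  x <- rbind(c(1, 0), c(0, 1), c(1, 1))
  expected <- (0 + 1 / sqrt(2) + 1 / sqrt(2)) / 3
  expect_equal(consistency(x)$avgsim, expected, tolerance = 1e-12)
})

test_that("consistency matches a pair-enumeration oracle on random replicates", {
  withr::local_seed(21)
  x <- matrix(rnorm(8 * 5), 8, 5)
  oracle <- {
    vals <- c()
    for (i in 1:7) for (j in (i + 1):8) {
      vals <- c(vals, cosine_of(x[i, ], x[j, ]))
    }
    mean(vals)
  }
  expect_equal(consistency(x)$avgsim, oracle, tolerance = 1e-10)
})

test_that("consistency rejects degenerate input and is scale invariant", {
  expect_error(consistency(matrix(1, 1, 3)), "fewer than 2")
  expect_error(consistency(rbind(c(1, 1), c(0, 0))), "zero-norm")
  withr::local_seed(22)
  x <- matrix(rnorm(12), 4, 3)
  y <- x; y[2, ] <- 5 * y[2, ]
  expect_equal(consistency(x)$avgsim, consistency(y)$avgsim,
               tolerance = 1e-12)
})

test_that("energy distance is exactly zero on identical samples and symmetric", {
  withr::local_seed(23)
  x <- matrix(rnorm(6 * 4), 6, 4)
  y <- matrix(rnorm(9 * 4), 9, 4)
  expect_identical(energy_distance(x, x), 0)
  expect_equal(energy_distance(x, y), energy_distance(y, x),
               tolerance = 1e-12)
  expect_gt(energy_distance(x, y + 2), 0)
})

test_that("energy distance closed forms: singletons and a 1-d hand evaluation", {
  x <- matrix(c(1, 2, 2), 1, 3)
  y <- matrix(c(4, 6, 2), 1, 3)
  expect_equal(magnitude(x, y)$energy, 2 * sqrt(9 + 16 + 0))
  # X = {0, 2}, Y = {1, 3}: cross mean = (1+3+1+1)/4 * 2 = 3,
  # within means = (0+2+2+0)/4 = 1 each, so E = 3 - 1 - 1 = 1
  expect_equal(energy_distance(matrix(c(0, 2)), matrix(c(1, 3))), 1.0)
})

test_that("energy distance matches a full double-sum loop oracle", {
  withr::local_seed(24)
  x <- matrix(rnorm(5 * 3), 5, 3)
  y <- matrix(rnorm(7 * 3), 7, 3)
  ed <- function(a, b) sqrt(sum((a - b)^2))
  s_xy <- 0
  for (i in 1:5) for (j in 1:7) s_xy <- s_xy + ed(x[i, ], y[j, ])
  s_xx <- 0
  for (i in 1:5) for (j in 1:5) s_xx <- s_xx + ed(x[i, ], x[j, ])
  s_yy <- 0
  for (i in 1:7) for (j in 1:7) s_yy <- s_yy + ed(y[i, ], y[j, ])
  oracle <- 2 * s_xy / 35 - s_xx / 25 - s_yy / 49
  expect_equal(energy_distance(x, y), oracle, tolerance = 1e-10)
})

test_that("permutation p-values clamp at 1/K, cap at 1, and count ties as exceedances", {
  null <- as.numeric(1:1000)
  expect_equal(permutation_pvalue(2000, null), 0.001)
  expect_equal(permutation_pvalue(0, null), 1.0)
  # observed at the empirical median of 1000 distinct values
  expect_equal(permutation_pvalue(500.5, null), 0.5)
  # ties count as exceedances (>= comparison)
  expect_equal(permutation_pvalue(1000, null), 0.001)
  expect_equal(permutation_pvalue(999, null), 0.002)
  expect_error(permutation_pvalue(1, 1:999), "at least 1000")
  expect_equal(permutation_pvalue(5, 1:10, k_min = 10), 0.6)
})

test_that("signal benchmark fractions match an independent per-gene loop", {
  sim <- simulate_screen(sim_config(n_genes = 40, n_unexpressed = 60,
                                    n_complexes = 0, dims = 8,
                                    n_batches = 2, controls_per_batch = 25,
                                    batch_shift_scale = 0,
                                    batch_scale_spread = 0,
                                    effect_scale = 0.6, seed = 31))
  um <- sim$units
  rep_ <- signal_benchmark(um, alpha = 0.05, k_min = 50L)
  ctl <- um$features[um$is_control, ]
  genes_of <- function(expr) {
    unique(um$perturbation[!um$is_control & um$is_expressed %in% expr])
  }
  loop_stats <- function(gene) {
    x <- um$features[um$perturbation == gene, , drop = FALSE]
    c(consistency(x)$avgsim, energy_distance(x, ctl))
  }
  null <- vapply(genes_of(FALSE), loop_stats, numeric(2))
  frac <- sapply(1:2, function(m) {
    p <- vapply(genes_of(TRUE), function(g) {
      max(sum(null[m, ] >= loop_stats(g)[m]), 1) / ncol(null)
    }, numeric(1))
    mean(p < 0.05)
  })
  expect_equal(rep_$summary$fraction_consistency, frac[1])
  expect_equal(rep_$summary$fraction_magnitude, frac[2])
  expect_equal(rep_$summary$K_magnitude, 60L)
  # per-gene statistics agree with the loop
  g1 <- genes_of(TRUE)[1]
  row <- rep_$results[rep_$results$gene == g1 &
                        rep_$results$metric == "magnitude", ]
  expect_equal(row$statistic, loop_stats(g1)[2], tolerance = 1e-10)
})

test_that("signal benchmark errors without unexpressed-gene perturbations", {
  sim <- simulate_screen(sim_config(n_genes = 10, n_unexpressed = 0,
                                    n_complexes = 0, dims = 4,
                                    n_batches = 1, controls_per_batch = 10,
                                    seed = 32))
  expect_error(signal_benchmark(sim$units), "unexpressed")
})

test_that("signal benchmark enforces the minimum null size", {
  sim <- simulate_screen(sim_config(n_genes = 10, n_unexpressed = 20,
                                    n_complexes = 0, dims = 4,
                                    n_batches = 1, controls_per_batch = 10,
                                    seed = 33))
  expect_error(signal_benchmark(sim$units), "at least 1000")
  expect_s3_class(signal_benchmark(sim$units, k_min = 20L),
                  "signal_report")
})
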