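test_that("PCA on rank-deficient input assigns ~zero variance past the rank", {
  withr::local_seed(1)
  a <- rnorm(10); b <- rnorm(10)
  um <- toy_units(cbind(a, b, a + b), perturbation = letters[1:10])
  out <- embed_pca(um, k = 3)
  ev <- attr(out, "explained_variance")
  expect_lt(ev[3], 1e-10)
  expect_error(embed_pca(um, k = 4), "attainable rank")
})

test_that("all 128 principal components can be retained on 128-dim input", {
  withr::local_seed(2)
  um <- toy_units(matrix(rnorm(150 * 128), 150, 128),
                  perturbation = sprintf("g%03d", 1:150))
  out <- embed_pca(um, k = 128)
  expect_equal(n_dims(out), 128L)
  expect_equal(sum(attr(out, "explained_variance")), 1, tolerance = 1e-8)
})

test_that("PCA projection/back-projection matches an eigendecomposition oracle", {
  withr::local_seed(3)
  x <- matrix(rnorm(50), 10, 5)
  um <- toy_units(x, perturbation = letters[1:10])
  k <- 3
  out <- embed_pca(um, k = k)
  fit <- attr(out, "pca")
  recon <- out$features %*% t(fit$rotation) +
    matrix(fit$center, 10, 5, byrow = TRUE)
  # oracle: eigendecomposition of the sample covariance, rank-k reconstruction
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  v <- eigen(crossprod(xc) / 9, symmetric = TRUE)$vectors[, 1:k]
  recon_oracle <- xc %*% v %*% t(v) + matrix(ctr, 10, 5, byrow = TRUE)
  expect_equal(unname(recon), unname(recon_oracle), tolerance = 1e-10)
})

test_that("PCA sign convention makes the largest-magnitude loading positive", {
  withr::local_seed(4)
  um <- toy_units(matrix(rnorm(80), 20, 4), perturbation = letters[1:20])
  rot <- attr(embed_pca(um, k = 4), "pca")$rotation
  for (j in 1:4) expect_gt(rot[which.max(abs(rot[, j])), j], 0)
})

test_that("range filter keeps the inclusive bounds and drops outside values", {
  counts <- c(49, 50, 125, 350, 351)
  um <- toy_units(matrix(rnorm(10), 5, 2), perturbation = letters[1:5],
                  qc = data.frame(Nuclei_Number_Object_Number = counts))
  out <- apply_filters(um, list(
    filter_range("Nuclei_Number_Object_Number", 50, 350)))
  expect_equal(out$qc$Nuclei_Number_Object_Number, c(50, 125, 350))
  expect_equal(attr(out, "filter_log")$removed_units, 2L)
})

test_that("drop_columns removes exactly the prefixed feature columns", {
  x <- matrix(rnorm(20), 5, 4)
  colnames(x) <- c("Image_a", "Cells_b", "Image_c", "Nuclei_d")
  um <- toy_units(x, perturbation = letters[1:5])
  out <- apply_filters(um, list(filter_drop_columns("Image_")))
  expect_identical(colnames(out$features), c("Cells_b", "Nuclei_d"))
})

test_that("robust Gaussian outlier filter removes a planted extreme unit", {
  withr::local_seed(5)
  x <- matrix(rnorm(1000 * 3), 1000, 3)
  colnames(x) <- paste0("ImageQuality_MeanIntensity_", c("r", "g", "b"))
  x[123, ] <- x[123, ] + 10    # 10-sigma outlier
  um <- toy_units(x, perturbation = sprintf("g%04d", 1:1000))
  out <- apply_filters(um, list(
    filter_robust_outliers("ImageQuality_MeanIntensity", 0.01)))
  expect_equal(n_units(out), 990L)
  expect_false("unit_000123" %in% out$unit_ids)
  # Mahalanobis oracle with the plain sample mean/covariance agrees that
  # the planted unit is the most extreme one
  d2 <- mahalanobis(x, colMeans(x), cov(x))
  expect_equal(which.max(d2), 123L)
})

test_that("per-batch control centering/scaling standardizes controls in every batch", {
  withr::local_seed(6)
  um <- toy_units(matrix(rnorm(200 * 4, mean = 3, sd = 2), 200, 4),
                  perturbation = c(rep("CTRL", 60),
                                   sprintf("g%03d", 1:140)),
                  batch = rep(c("B1", "B2"), 100),
                  is_control = c(rep(TRUE, 60), rep(FALSE, 140)))
  out <- align_center_scale(um, "per_batch", "controls")
  for (b in c("B1", "B2")) {
    ctl <- out$features[out$is_control & out$batch == b, ]
    expect_equal(unname(colMeans(ctl)), rep(0, 4), tolerance = 1e-9)
    expect_equal(unname(apply(ctl, 2, sd)), rep(1, 4), tolerance = 1e-9)
  }
})

test_that("global scope equals per-batch scope when there is a single batch", {
  withr::local_seed(7)
  um <- toy_units(matrix(rnorm(40), 10, 4),
                  perturbation = c(rep("CTRL", 4), letters[1:6]),
                  is_control = c(rep(TRUE, 4), rep(FALSE, 6)))
  expect_equal(align_center_scale(um, "global", "controls")$features,
               align_center_scale(um, "per_batch", "controls")$features)
})

test_that("non-controls get the same per-batch parameters as controls (hand oracle)", {
  # batch B1 controls: (0, 2) -> mean 1, sd sqrt(2); query unit 3 -> (3-1)/sqrt(2)
  um <- toy_units(matrix(c(0, 2, 3, 4, 8, 10), 6, 1),
                  perturbation = c("CTRL", "CTRL", "q1", "CTRL", "CTRL", "q2"),
                  batch = c("B1", "B1", "B1", "B2", "B2", "B2"),
                  is_control = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE))
  out <- align_center_scale(um, "per_batch", "controls")
  expect_equal(out$features[3, 1], (3 - 1) / sqrt(2))
  # batch B2 controls: (4, 8) -> mean 6, sd sqrt(8); query 10 -> 4/sqrt(8)
  expect_equal(out$features[6, 1], (10 - 6) / sqrt(8))
})

test_that("alignment errors name the offending batch or feature", {
  um <- toy_units(matrix(1:8, 4, 2), perturbation = c("CTRL", "a", "b", "c"),
                  batch = c("B1", "B1", "B2", "B2"),
                  is_control = c(TRUE, FALSE, FALSE, FALSE))
  expect_error(align_center_scale(um), "B1.*B2|B2.*B1")
  um2 <- toy_units(cbind(c(1, 1, 1, 1), c(1, 2, 3, 4)),
                   perturbation = c("CTRL", "CTRL", "CTRL", "a"),
                   is_control = c(TRUE, TRUE, TRUE, FALSE))
  expect_error(align_center_scale(um2), "zero standard deviation")
})

test_that("inverse square-root whitening matches the diagonal closed form", {
  w <- perturbmap:::.inv_sqrtm(diag(c(4, 1)))
  expect_equal(w, diag(c(0.5, 1)), tolerance = 1e-5)
  expect_equal(perturbmap:::.inv_sqrtm(diag(2)), diag(2), tolerance = 1e-5)
})

test_that("TVN whitens per-batch control covariance to near identity", {
  withr::local_seed(8)
  n_ctl <- 500
  mk_batch <- function(shift, chol_f) {
    ctl <- matrix(rnorm(n_ctl * 3), n_ctl, 3) %*% chol_f +
      matrix(shift, n_ctl, 3, byrow = TRUE)
    qry <- matrix(rnorm(20 * 3), 20, 3) %*% chol_f +
      matrix(shift, 20, 3, byrow = TRUE)
    rbind(ctl, qry)
  }
  b1 <- mk_batch(c(5, 0, -2), chol(matrix(c(4, 1, 0, 1, 2, 0.5, 0, 0.5, 1), 3)))
  b2 <- mk_batch(c(-1, 3, 0), chol(matrix(c(1, -0.5, 0, -0.5, 3, 0, 0, 0, 2), 3)))
  um <- toy_units(rbind(b1, b2),
                  perturbation = rep(c(rep("CTRL", n_ctl),
                                       sprintf("g%02d", 1:20)), 2),
                  batch = rep(c("B1", "B2"), each = n_ctl + 20),
                  is_control = rep(c(rep(TRUE, n_ctl), rep(FALSE, 20)), 2))
  out <- align_tvn(um)
  for (b in c("B1", "B2")) {
    cv <- cov(out$features[out$is_control & out$batch == b, ])
    expect_lt(max(abs(cv - diag(3))), 0.05)
  }
})

test_that("TVN on a single batch leaves whitened controls and is affine", {
  withr::local_seed(9)
  x <- matrix(rnorm(300 * 2), 300, 2)
  # three collinear query points to check the affine (line-preserving) property
  line <- rbind(c(0, 0), c(1, 2), c(2, 4))
  um <- toy_units(rbind(x, line),
                  perturbation = c(rep("CTRL", 300), "a", "b", "c"),
                  is_control = c(rep(TRUE, 300), rep(FALSE, 3)))
  out <- align_tvn(um)
  cv <- cov(out$features[out$is_control, ])
  expect_equal(cv, diag(2), tolerance = 1e-4, ignore_attr = TRUE)
  p <- out$features[301:303, ]
  expect_equal(p[2, ] - p[1, ], (p[3, ] - p[1, ]) / 2, tolerance = 1e-9)
})

test_that("mean aggregation matches arithmetic and a per-group loop oracle", {
  um1 <- toy_units(matrix(c(0, 2, 0, 4), 2, 2), perturbation = c("g1", "g1"))
  m1 <- aggregate_mean(um1)
  expect_equal(unname(m1$vectors["g1", ]), c(1, 2))
  withr::local_seed(10)
  x <- matrix(rnorm(48), 12, 4)
  g <- sample(c("a", "b", "c"), 12, replace = TRUE)
  ctl <- c(rep(TRUE, 2), rep(FALSE, 10))
  um <- toy_units(x, perturbation = ifelse(ctl, "CTRL", g), is_control = ctl)
  m <- aggregate_mean(um)
  for (gene in unique(g[!ctl])) {
    rows <- which(!ctl & g == gene)
    oracle <- colSums(x[rows, , drop = FALSE]) / length(rows)
    expect_equal(unname(m$vectors[gene, ]), unname(oracle))
  }
  expect_false("CTRL" %in% m$genes)
  expect_equal(m$provenance$n_replicates[["a"]], sum(!ctl & g == "a"))
})

test_that("cosine relating reproduces closed forms and flags zero vectors", {
  v <- rbind(a = c(1, 0), b = c(1, 0), c = c(0, 1), d = c(1, 1))
  s <- relate_cosine(aggregated_map(v))
  expect_equal(s["a", "b"], 1)
  expect_equal(s["a", "c"], 0)
  expect_equal(s["a", "d"], 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(unname(diag(s)), rep(1, 4))
  bad <- aggregated_map(rbind(a = c(1, 0), dead = c(0, 0)))
  expect_error(relate_cosine(bad), "dead")
})

test_that("cosine similarities are invariant to positive rescaling of one gene", {
  withr::local_seed(11)
  v <- matrix(rnorm(20), 5, 4, dimnames = list(letters[1:5], NULL))
  s1 <- relate_cosine(aggregated_map(v))
  v[3, ] <- 7.3 * v[3, ]
  s2 <- relate_cosine(aggregated_map(v))
  expect_equal(unclass(s1), unclass(s2), tolerance = 1e-12)
})

test_that("an all-pass-through pipeline reproduces relate(aggregate(units))", {
  withr::local_seed(12)
  um <- toy_units(matrix(rnorm(40), 10, 4),
                  perturbation = rep(c("g1", "g2", "g3", "g4", "g5"), 2))
  cfg <- pipeline_config(embed = "none", align = "none")
  res <- run_pipeline(um, cfg)
  expect_equal(unclass(res$sim),
               unclass(relate_cosine(aggregate_mean(um))))
})

test_that("a preset pipeline equals its manual stage composition", {
  sim <- simulate_screen(sim_config(n_genes = 30, n_unexpressed = 0,
                                    n_complexes = 2, complex_size = 5,
                                    dims = 8, n_batches = 2,
                                    controls_per_batch = 30, seed = 13))
  res <- run_pipeline(sim$units, pipeline_preset("PCA-CS", k = 8, seed = 1))
  manual <- relate_cosine(aggregate_mean(align_center_scale(
    embed_pca(sim$units, k = 8), "per_batch", "controls")))
  expect_equal(unclass(res$sim), unclass(manual), tolerance = 1e-12)
})

test_that("identical seeds give bit-identical pipeline outputs", {
  sim <- simulate_screen(sim_config(n_genes = 20, n_unexpressed = 0,
                                    n_complexes = 0, dims = 6,
                                    n_batches = 2, controls_per_batch = 20,
                                    seed = 14))
  r1 <- run_pipeline(sim$units, pipeline_preset("PCA-TVN", k = 6, seed = 5))
  r2 <- run_pipeline(sim$units, pipeline_preset("PCA-TVN", k = 6, seed = 5))
  expect_identical(r1$map$vectors, r2$map$vectors)
  expect_identical(unclass(r1$sim), unclass(r2$sim))
})

test_that("pipeline configs read from YAML reject unknown keys", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("embed: pca", "k: 4", "align: tvn"), path)
  cfg <- read_pipeline_config(path)
  expect_equal(cfg$k, 4L)
  expect_equal(cfg$align, "tvn")
  writeLines(c("embed: pca", "alignn: tvn"), path)
  expect_error(read_pipeline_config(path), "alignn")
})
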