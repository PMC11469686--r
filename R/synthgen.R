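#' Configuration for the synthetic-screen generator
#'
#' Defines the statistical structure the generator emulates: per-gene
#' true effect vectors (with planted gene clusters inducing correlated
#' effects), replicate units spread over batches, per-batch affine
#' artifacts (an additive offset plus a symmetric positive-definite
#' covariance coloring), control units carrying batch artifacts and
#' noise only, and unexpressed genes with zero true effect.
#'
#' Defaults describe a high-quality arrayed screen: 128-dimensional
#' embeddings, four replicate units per gene over six batches, a
#' replicate signal-to-noise ratio giving within-gene cosines around
#' 0.75, batch offsets far larger than measurement noise, and planted
#' complexes whose member effects share a latent direction (within-
#' complex effect cosines around 0.9).
#'
#' @param n_genes expressed (perturbed) genes.
#' @param n_unexpressed unexpressed genes (zero true effect); may be 0.
#' @param n_complexes planted gene clusters; may be 0.
#' @param complex_size members per planted cluster
#'   (`n_complexes * complex_size <= n_genes`).
#' @param effect_scale Euclidean norm of every expressed gene's true
#'   effect vector.
#' @param dims embedding dimensionality.
#' @param n_batches number of batches.
#' @param replicates_per_gene replicate units per gene, each assigned a
#'   random batch.
#' @param controls_per_batch control units per batch. For TVN alignment
#'   this should comfortably exceed `dims` so batch-control covariances
#'   are well-conditioned.
#' @param batch_shift_scale per-feature standard deviation of the
#'   additive batch offset.
#' @param batch_scale_spread magnitude of the per-batch covariance
#'   coloring (0 = identity coloring; the diagonal-scaling artifact is
#'   the special case of a diagonal coloring).
#' @param noise_sd per-coordinate standard deviation of the isotropic
#'   Gaussian unit noise.
#' @param complex_jitter gene-specific jitter around a cluster's shared
#'   latent direction, relative to the direction's unit norm.
#' @param seed master seed; all draws come from named sub-streams so
#'   results are fully deterministic.
#' @export
sim_config <- function(n_genes = 1000L, n_unexpressed = 1000L,
                       n_complexes = 20L, complex_size = 12L,
                       effect_scale = 2, dims = 128L, n_batches = 6L,
                       replicates_per_gene = 4L,
                       controls_per_batch = 384L,
                       batch_shift_scale = 0.5,
                       batch_scale_spread = 0.3, noise_sd = 0.1,
                       complex_jitter = 0.35, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_unexpressed = as.integer(n_unexpressed),
              n_complexes = as.integer(n_complexes),
              complex_size = as.integer(complex_size),
              effect_scale = effect_scale, dims = as.integer(dims),
              n_batches = as.integer(n_batches),
              replicates_per_gene = as.integer(replicates_per_gene),
              controls_per_batch = as.integer(controls_per_batch),
              batch_shift_scale = batch_shift_scale,
              batch_scale_spread = batch_scale_spread,
              noise_sd = noise_sd, complex_jitter = complex_jitter,
              seed = as.integer(seed))
  with(cfg, {
    if (n_genes < 1L || dims < 1L || n_batches < 1L ||
        replicates_per_gene < 1L || controls_per_batch < 1L ||
        complex_size < 2L) {
      .stop_fmt("sim_config: counts must be positive (complex_size >= 2)")
    }
    if (n_unexpressed < 0L || n_complexes < 0L) {
      .stop_fmt("sim_config: n_unexpressed and n_complexes must be >= 0")
    }
    if (n_complexes * complex_size > n_genes) {
      .stop_fmt("sim_config: n_complexes * complex_size (%d) exceeds n_genes (%d)",
                n_complexes * complex_size, n_genes)
    }
    if (effect_scale < 0 || batch_shift_scale < 0 ||
        batch_scale_spread < 0 || noise_sd <= 0) {
      .stop_fmt("sim_config: scales must be nonnegative and noise_sd positive")
    }
  })
  structure(cfg, class = "sim_config")
}

.unit_vector <- function(d) {
  v <- stats::rnorm(d)
  v / sqrt(sum(v^2))
}

# symmetric positive-definite coloring matrix around the identity
.batch_coloring <- function(d, spread) {
  if (spread == 0) return(diag(d))
  s <- matrix(stats::rnorm(d * d, sd = 1 / sqrt(d)), d, d)
  s <- (s + t(s)) / 2
  a <- diag(d) + spread * s
  eg <- eigen(a, symmetric = TRUE)
  vals <- pmax(eg$values, 0.1)   # keep the coloring well-conditioned
  eg$vectors %*% (t(eg$vectors) * vals)
}

#' Simulate a synthetic perturbation screen with known ground truth
#'
#' Generates a [unit_matrix()] together with the planted complex
#' catalog and the within-complex pair set, so every benchmark in the
#' package can be evaluated against a known answer. Each complex gets a
#' shared latent direction; member genes' effects are the normalized
#' sum of that direction and gene-specific jitter, scaled to
#' `effect_scale`. Non-complex expressed genes get independent random
#' directions; unexpressed genes have zero effect. A unit embedding is
#' `A_b %*% (effect + noise) + shift_b` for its batch `b`; controls
#' carry batch artifacts and noise only.
#'
#' @param config a [sim_config()].
#' @return list of class `perturb_sim` with elements `units`
#'   ([unit_matrix()]), `catalog` ([complex_catalog()]), `pairs`
#'   ([annotation_set()] of planted within-complex pairs), `effects`
#'   (true effect matrix, genes x dims) and `config`.
#' @export
simulate_screen <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  d <- config$dims
  genes <- sprintf("GENE%05d", seq_len(config$n_genes))
  unexpr <- if (config$n_unexpressed > 0L)
    sprintf("UNEXP%05d", seq_len(config$n_unexpressed)) else character()

  # planted complexes: disjoint member sets drawn from the expressed genes
  members <- withr::with_seed(
    substream_seed(config$seed, "complex_membership"), {
      if (config$n_complexes > 0L) {
        picked <- sample(genes, config$n_complexes * config$complex_size)
        split(picked, rep(seq_len(config$n_complexes),
                          each = config$complex_size))
      } else list()
    })
  names(members) <- if (length(members))
    sprintf("CPLX%03d", seq_along(members)) else character()
  catalog <- complex_catalog(members)

  # true effect directions
  effects <- withr::with_seed(substream_seed(config$seed, "effects"), {
    e <- matrix(0, config$n_genes + config$n_unexpressed, d,
                dimnames = list(c(genes, unexpr), NULL))
    in_complex <- character()
    for (nm in names(members)) {
      u <- .unit_vector(d)
      for (g in members[[nm]]) {
        v <- u + config$complex_jitter * .unit_vector(d)
        e[g, ] <- v / sqrt(sum(v^2))
      }
      in_complex <- c(in_complex, members[[nm]])
    }
    for (g in setdiff(genes, in_complex)) e[g, ] <- .unit_vector(d)
    e * config$effect_scale
  })

  # batch artifacts: additive offset + symmetric PD covariance coloring
  batches <- sprintf("B%03d", seq_len(config$n_batches))
  artifacts <- withr::with_seed(
    substream_seed(config$seed, "batch_artifacts"), {
      lapply(batches, function(b) list(
        shift = stats::rnorm(d, sd = config$batch_shift_scale),
        coloring = .batch_coloring(d, config$batch_scale_spread)))
    })
  names(artifacts) <- batches

  all_pert <- c(genes, unexpr)
  n_pert_units <- length(all_pert) * config$replicates_per_gene
  n_ctrl_units <- config$n_batches * config$controls_per_batch
  pert_label <- rep(all_pert, each = config$replicates_per_gene)
  unit_batch <- withr::with_seed(
    substream_seed(config$seed, "batch_assignment"),
    sample(batches, n_pert_units, replace = TRUE))
  ctrl_batch <- rep(batches, each = config$controls_per_batch)

  perturbation <- c(pert_label, rep("CONTROL", n_ctrl_units))
  batch <- c(unit_batch, ctrl_batch)
  is_control <- c(rep(FALSE, n_pert_units), rep(TRUE, n_ctrl_units))
  is_expressed <- c(pert_label %in% genes, rep(NA, n_ctrl_units))

  n_total <- n_pert_units + n_ctrl_units
  x <- withr::with_seed(substream_seed(config$seed, "noise"), {
    noise <- matrix(stats::rnorm(n_total * d, sd = config$noise_sd),
                    n_total, d)
    base <- noise
    base[seq_len(n_pert_units), ] <-
      base[seq_len(n_pert_units), ] + effects[pert_label, , drop = FALSE]
    base
  })
  for (b in batches) {
    idx <- which(batch == b)
    art <- artifacts[[b]]
    x[idx, ] <- x[idx, , drop = FALSE] %*% art$coloring +
      matrix(art$shift, length(idx), d, byrow = TRUE)
  }
  colnames(x) <- sprintf("feat_%03d", seq_len(d))

  units <- unit_matrix(x, perturbation, batch, is_control, is_expressed)
  structure(list(units = units, catalog = catalog,
                 pairs = complexes_to_pairs(catalog, "planted_complexes"),
                 effects = effects, config = config),
            class = "perturb_sim")
}

#' @export
print.perturb_sim <- function(x, ...) {
  cat(sprintf(
    "perturb_sim: %d expressed + %d unexpressed genes, %d complexes, %d units\n",
    x$config$n_genes, x$config$n_unexpressed, x$config$n_complexes,
    n_units(x$units)))
  invisible(x)
}

#' Write a simulated screen to files
#'
#' Writes the unit table, the planted complex catalog and the planted
#' pair list so command-line runs can be file-driven.
#'
#' @param sim a `perturb_sim` from [simulate_screen()].
#' @param dir output directory (created if needed).
#' @return invisible named vector of written paths.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(units = file.path(dir, "units.tsv"),
             complexes = file.path(dir, "complexes.tsv"),
             pairs = file.path(dir, "planted_pairs.tsv"))
  write_unit_matrix(sim$units, paths[["units"]])
  write_complex_catalog(sim$catalog, paths[["complexes"]])
  data.table::fwrite(sim$pairs$pairs, paths[["pairs"]], sep = "\t",
                     quote = FALSE)
  invisible(paths)
}
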