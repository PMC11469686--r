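#' Replicate consistency (average pairwise cosine similarity)
#'
#' The consistency statistic of a perturbation: the mean cosine
#' similarity over all pairs of its replicate unit embeddings. By
#' default self-pairs are excluded, so the statistic is 0 for mutually
#' orthogonal replicates and 1 when all replicates share an orientation;
#' `include_self = TRUE` restores the literal all-pairs mean (which is
#' `1/n`, not 0, in the orthogonal case).
#'
#' @param x numeric matrix of replicate embeddings (rows), or a
#'   [unit_matrix()] subset.
#' @param include_self include `i == j` pairs in the average.
#' @return a list with `avgsim` and `n_replicates`.
#' @export
consistency <- function(x, include_self = FALSE) {
  if (inherits(x, "unit_matrix")) x <- x$features
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L) {
    .stop_fmt("consistency is undefined for fewer than 2 replicates (got %d)", n)
  }
  norms <- .row_norms(x)
  zero <- which(norms == 0)
  if (length(zero)) {
    .stop_fmt("zero-norm replicate unit at row %d", zero[1])
  }
  s <- tcrossprod(x / norms)
  avg <- if (include_self) mean(s) else mean(s[upper.tri(s)])
  list(avgsim = avg, n_replicates = n)
}

#' Two-sample energy distance
#'
#' The perturbation magnitude statistic: the energy distance between the
#' replicate units of a perturbation and the negative-control units,
#' \deqn{E = \frac{2}{n_1 n_2}\sum_{i,j}\|x_i - y_j\|
#'         - \frac{1}{n_1^2}\sum_{i,j}\|x_i - x_j\|
#'         - \frac{1}{n_2^2}\sum_{i,j}\|y_i - y_j\|,}
#' with Euclidean norms and full double sums. It is zero when the two
#' samples are identical and positive between non-identical
#' distributions, measuring effect size in the embedding space.
#'
#' @param x,y numeric matrices (or `unit_matrix` subsets): query units
#'   and control units.
#' @return a list with `energy`, `n_query` and `n_control`.
#' @export
magnitude <- function(x, y) {
  if (inherits(x, "unit_matrix")) x <- x$features
  if (inherits(y, "unit_matrix")) y <- y$features
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) < 1L || nrow(y) < 1L) .stop_fmt("empty sample")
  e <- energy_distance(x, y)
  list(energy = e, n_query = nrow(x), n_control = nrow(y))
}

#' @rdname magnitude
#' @param yy_mean optional precomputed mean within-`y` pairwise distance
#'   (including zero diagonal terms); lets callers reuse the control
#'   term across many query genes.
#' @export
energy_distance <- function(x, y, yy_mean = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (identical(unname(x), unname(y))) return(0)
  mxy <- mean(.cross_dist(x, y))
  mxx <- mean(.self_dist(x))
  myy <- if (is.null(yy_mean)) mean(.self_dist(y)) else yy_mean
  2 * mxy - mxx - myy
}

#' Empirical-null permutation p-value
#'
#' Compares an observed statistic to an empirical null distribution
#' built from unexpressed-gene perturbations:
#' `p = max(#{null >= observed}, 1) / K`. Ties count as exceedances and
#' the count is clamped at 1, so p-values lie in `[1/K, 1]` and are
#' never zero. A representative null requires at least `k_min`
#' unexpressed genes (default 1000).
#'
#' @param observed observed statistic for the query gene.
#' @param null numeric vector of the same statistic over unexpressed
#'   genes.
#' @param k_min minimum required null size.
#' @return the p-value.
#' @export
permutation_pvalue <- function(observed, null, k_min = 1000L) {
  k <- length(null)
  if (k < k_min) {
    .stop_fmt("null distribution has %d values; at least %d unexpressed genes are required",
              k, k_min)
  }
  max(sum(null >= observed), 1L) / k
}

#' Perturbation-signal benchmark
#'
#' For every expressed gene, computes the consistency (avgsim) and
#' magnitude (energy distance to controls) statistics and assigns each a
#' permutation p-value against the empirical null formed by the same
#' statistic over unexpressed genes (computed by the identical code
#' path). Reports the fraction of expressed genes significant at
#' `alpha` for each metric and for both jointly.
#'
#' @param units a [unit_matrix()] with aligned unit-level features,
#'   control units, and expressed/unexpressed labels.
#' @param alpha significance threshold on the raw permutation p-value.
#' @param k_min minimum number of unexpressed genes for the null.
#' @param include_self passed to [consistency()].
#' @return an object of class `signal_report`: list with `results` (one
#'   row per gene x metric) and `summary` (significant fractions, alpha,
#'   K).
#' @export
signal_benchmark <- function(units, alpha = 0.05, k_min = 1000L,
                             include_self = FALSE) {
  if (all(is.na(units$is_expressed[!units$is_control]))) {
    .stop_fmt("schema error: is_expressed labels are required for the signal benchmark")
  }
  ctrl_idx <- which(units$is_control)
  if (length(ctrl_idx) < 1L) .stop_fmt("no control units for the magnitude null")
  pert_idx <- which(!units$is_control)
  by_gene <- split(pert_idx, units$perturbation[pert_idx])
  gene_expressed <- vapply(by_gene, function(i) units$is_expressed[i][1],
                           logical(1))
  expressed_genes <- names(by_gene)[gene_expressed %in% TRUE]
  unexpressed_genes <- names(by_gene)[gene_expressed %in% FALSE]
  if (!length(unexpressed_genes)) {
    .stop_fmt("this dataset includes no unexpressed-gene perturbations; perturbation signal benchmarks cannot be calculated")
  }
  y <- units$features[ctrl_idx, , drop = FALSE]
  yy_mean <- mean(.self_dist(y))
  gene_stats <- function(g) {
    x <- units$features[by_gene[[g]], , drop = FALSE]
    c(avgsim = if (nrow(x) >= 2L) consistency(x, include_self)$avgsim else NA_real_,
      energy = energy_distance(x, y, yy_mean = yy_mean))
  }
  null_stats <- vapply(unexpressed_genes, gene_stats, numeric(2))
  obs_stats <- vapply(expressed_genes, gene_stats, numeric(2))
  null_avgsim <- null_stats["avgsim", ]
  null_avgsim <- null_avgsim[!is.na(null_avgsim)]
  null_energy <- null_stats["energy", ]
  p_cons <- vapply(obs_stats["avgsim", ], function(s) {
    if (is.na(s)) NA_real_ else permutation_pvalue(s, null_avgsim, k_min)
  }, numeric(1))
  p_mag <- vapply(obs_stats["energy", ], function(s) {
    permutation_pvalue(s, null_energy, k_min)
  }, numeric(1))
  results <- rbind(
    data.frame(gene = expressed_genes, metric = "consistency",
               statistic = unname(obs_stats["avgsim", ]),
               p_value = unname(p_cons), stringsAsFactors = FALSE),
    data.frame(gene = expressed_genes, metric = "magnitude",
               statistic = unname(obs_stats["energy", ]),
               p_value = unname(p_mag), stringsAsFactors = FALSE))
  results$significant <- !is.na(results$p_value) & results$p_value < alpha
  sig_cons <- results$significant[results$metric == "consistency"]
  sig_mag <- results$significant[results$metric == "magnitude"]
  structure(list(
    results = results,
    summary = list(
      n_expressed = length(expressed_genes),
      K_consistency = length(null_avgsim),
      K_magnitude = length(null_energy),
      alpha = alpha,
      fraction_consistency = mean(sig_cons),
      fraction_magnitude = mean(sig_mag),
      fraction_both = mean(sig_cons & sig_mag))),
    class = "signal_report")
}

#' @export
print.signal_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "signal_report: %d expressed genes, K = %d\n  significant (p < %.3g): consistency %.1f%%, magnitude %.1f%%, both %.1f%%\n",
    s$n_expressed, s$K_magnitude, s$alpha,
    100 * s$fraction_consistency, 100 * s$fraction_magnitude,
    100 * s$fraction_both))
  invisible(x)
}

#' Write a signal report to delimited files
#'
#' Per-gene rows go to `<path>`; the summary record to
#' `<path>.summary.json`.
#'
#' @param report a `signal_report`.
#' @param path output path for the per-gene table.
#' @export
write_signal_report <- function(report, path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  data.table::fwrite(report$results, path, sep = sep, quote = FALSE)
  jsonlite::write_json(report$summary, paste0(path, ".summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
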