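# Shared fixture builders for the test suite. Everything is generated in
# code; no fixture files on disk.

# small unit matrix with explicit features and metadata
toy_units <- function(features, perturbation, batch = "B1",
                      is_control = FALSE, is_expressed = NULL, qc = NULL) {
  features <- as.matrix(features)
  n <- nrow(features)
  unit_matrix(features, rep_len(perturbation, n), rep_len(batch, n),
              rep_len(is_control, n), is_expressed, qc = qc)
}

# similarity matrix from an explicit symmetric matrix with gene names
make_sim <- function(values, genes = sprintf("g%02d", seq_len(nrow(values)))) {
  values <- as.matrix(values)
  rownames(values) <- colnames(values) <- genes
  diag(values) <- 1
  similarity_matrix(values)
}

# similarity matrix from per-gene vectors (rows)
sim_from_vectors <- function(vectors,
                             genes = sprintf("g%02d", seq_len(nrow(vectors)))) {
  rownames(vectors) <- genes
  relate_cosine(aggregated_map(vectors))
}

# independent cosine oracle used by several tests
cosine_of <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# type-7 (linear interpolation) percentile, written out long-hand so the
# recall tests do not lean on stats::quantile
percentile_type7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

# study conditions for the alignment-ordering benchmarks: strong additive
# batch offsets and covariance coloring relative to measurement noise,
# at desk scale (32 dims, 120 genes, six 12-member complexes)
ordering_sim_config <- function(seed) {
  sim_config(n_genes = 120, n_unexpressed = 0, n_complexes = 6,
             complex_size = 12, dims = 32, n_batches = 6,
             controls_per_batch = 200, effect_scale = 0.5,
             batch_shift_scale = 1.0, batch_scale_spread = 1.0,
             noise_sd = 0.3, seed = seed)
}
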