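#' Percentile-tail recall of annotated gene pairs
#'
#' The relationship benchmark: computes the distribution of all
#' off-diagonal pairwise cosine similarities among the map's genes
#' (each unordered pair counted once; self-links excluded), cuts it at
#' the `tail` and `1 - tail` empirical percentiles
#' (linear-interpolation definition), and calls a pair "predicted" when
#' its cosine falls strictly below the lower cut or strictly above the
#' upper cut. Recall is the percentage of annotated pairs that are
#' predicted, with the denominator restricted to annotated pairs whose
#' genes are both present in the map. A random, uninformative map is
#' expected to score `2 * tail * 100` (10% at the default tails).
#'
#' @param sim a [similarity_matrix()].
#' @param ann an [annotation_set()].
#' @param tail fraction cut from each side of the similarity
#'   distribution, in (0, 0.5); default 0.05.
#' @return data.frame with `source`, `recall_percent`, `n_eval_pairs`,
#'   `lower_cut`, `upper_cut`.
#' @export
recall <- function(sim, ann, tail = 0.05) {
  stopifnot(tail > 0, tail < 0.5)
  genes <- sim_genes(sim)
  vals <- sim[upper.tri(sim)]
  cuts <- stats::quantile(vals, c(tail, 1 - tail), type = 7, names = FALSE)
  ia <- match(ann$pairs$gene_a, genes)
  ib <- match(ann$pairs$gene_b, genes)
  keep <- !is.na(ia) & !is.na(ib)
  if (!any(keep)) {
    .stop_fmt("no annotated pairs from '%s' have both genes in the map",
              ann$source_name)
  }
  v <- sim[cbind(ia[keep], ib[keep])]
  predicted <- v < cuts[1] | v > cuts[2]
  data.frame(source = ann$source_name,
             recall_percent = 100 * mean(predicted),
             n_eval_pairs = sum(keep),
             lower_cut = cuts[1], upper_cut = cuts[2],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Recall against several annotation sources
#'
#' One [recall()] row per source; the percentile cuts are recomputed
#' from the same similarity distribution for each call, so results are
#' directly comparable across sources.
#'
#' @param sim a [similarity_matrix()].
#' @param sources list of [annotation_set()] objects.
#' @param tail passed to [recall()].
#' @export
benchmark_all <- function(sim, sources, tail = 0.05) {
  if (!length(sources)) .stop_fmt("benchmark_all needs >= 1 source")
  do.call(rbind, lapply(sources, function(s) recall(sim, s, tail)))
}

#' Replicate-subsampling noise-sensitivity analysis
#'
#' For each subsampling level, draws the requested number of replicate
#' units per gene (genes with fewer replicates fall back to all
#' available, with a log count), rebuilds the map with the given
#' pipeline, and computes recall for every annotation source. The draw
#' is repeated `repeats` times (default 3) and the mean and standard
#' deviation over repeats are reported per level and source.
#'
#' @param units a [unit_matrix()].
#' @param config a [pipeline_config()].
#' @param sources list of [annotation_set()] objects.
#' @param levels integer vector of replicates-per-gene sampling levels.
#' @param repeats random redraws per level.
#' @param seed master seed; per-level, per-repeat child seeds are
#'   derived from it.
#' @param tail passed to [recall()].
#' @return a list with `detail` (level x repeat x source rows) and
#'   `summary` (mean/sd per level and source), class
#'   `noise_sensitivity`.
#' @export
noise_sensitivity <- function(units, config, sources, levels,
                              repeats = 3L, seed = 1L, tail = 0.05) {
  stopifnot(length(levels) >= 1L, repeats >= 1L)
  pert_idx <- which(!units$is_control)
  by_gene <- split(pert_idx, units$perturbation[pert_idx])
  ctrl_idx <- which(units$is_control)
  detail <- list()
  for (lev in levels) {
    for (r in seq_len(repeats)) {
      child <- substream_seed(seed, sprintf("noise_l%d_r%d", lev, r))
      keep <- withr::with_seed(child, {
        unlist(lapply(by_gene, function(idx) {
          if (length(idx) <= lev) idx else sample(idx, lev)
        }), use.names = FALSE)
      })
      n_short <- sum(lengths(by_gene) < lev)
      sub <- units[sort(c(keep, ctrl_idx))]
      res <- run_pipeline(sub, config)
      rows <- benchmark_all(res$sim, sources, tail)
      rows <- cbind(data.frame(level = lev, repeat_ = r,
                               n_genes_short = n_short), rows)
      detail[[length(detail) + 1L]] <- rows
    }
  }
  detail <- do.call(rbind, detail)
  agg_mean <- stats::aggregate(recall_percent ~ level + source, detail, mean)
  agg_sd <- stats::aggregate(recall_percent ~ level + source, detail,
                             stats::sd)
  summary <- merge(agg_mean, agg_sd, by = c("level", "source"),
                   suffixes = c("_mean", "_sd"))
  summary <- summary[order(summary$source, summary$level), , drop = FALSE]
  rownames(summary) <- NULL
  structure(list(detail = detail, summary = summary),
            class = "noise_sensitivity")
}

#' @export
print.noise_sensitivity <- function(x, ...) {
  cat("noise_sensitivity (mean recall over repeats):\n")
  print(x$summary)
  invisible(x)
}
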