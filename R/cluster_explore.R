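#' Identify gene clusters (protein complexes) captured by a map
#'
#' For each catalog cluster with at least `min_genes` members present in
#' the map, compares the cosine-similarity distribution of within-
#' cluster member pairs (self-links excluded, each unordered pair once)
#' to the distribution of (member, non-member) pairs — the "negative"
#' distribution — with a two-sided two-sample Kolmogorov-Smirnov test
#' (asymptotic p-value). Clusters with `p < alpha` are flagged as
#' identified. Clusters with fewer mapped members are reported but not
#' evaluated.
#'
#' @param sim a [similarity_matrix()].
#' @param catalog a [complex_catalog()].
#' @param min_genes minimum mapped members for evaluation (default 10).
#' @param alpha identification threshold on the KS p-value (default
#'   0.01).
#' @return data.frame with one row per complex: `complex`, `n_in_map`,
#'   `evaluated`, `ks_statistic`, `p_value`, `identified`.
#' @export
identify_complexes <- function(sim, catalog, min_genes = 10L,
                               alpha = 0.01) {
  if (!length(catalog$complexes)) .stop_fmt("empty complex catalog")
  genes <- sim_genes(sim)
  if (length(genes) < min_genes + 1L) {
    .stop_fmt("map has %d genes; need more than min_genes = %d",
              length(genes), min_genes)
  }
  rows <- lapply(names(catalog$complexes), function(nm) {
    mem <- intersect(catalog$complexes[[nm]], genes)
    n_in <- length(mem)
    if (n_in < min_genes) {
      return(data.frame(complex = nm, n_in_map = n_in, evaluated = FALSE,
                        ks_statistic = NA_real_, p_value = NA_real_,
                        identified = NA, stringsAsFactors = FALSE))
    }
    w <- sim[mem, mem, drop = FALSE]
    within <- w[upper.tri(w)]
    out <- setdiff(genes, mem)
    cross <- as.vector(sim[mem, out, drop = FALSE])
    ks <- suppressWarnings(stats::ks.test(within, cross,
                                          alternative = "two.sided",
                                          exact = FALSE))
    data.frame(complex = nm, n_in_map = n_in, evaluated = TRUE,
               ks_statistic = unname(ks$statistic),
               p_value = ks$p.value,
               identified = ks$p.value < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Top cosine-similarity neighbors of a gene
#'
#' The `k` genes with the highest cosine similarity to the query,
#' in descending order, the query itself excluded. Ties are broken
#' lexicographically for determinism.
#'
#' @param sim a [similarity_matrix()].
#' @param gene query gene label (case-sensitive).
#' @param k number of neighbors (default 25).
#' @return character vector of gene labels, with similarities in the
#'   `"similarity"` attribute.
#' @export
top_neighbors <- function(sim, gene, k = 25L) {
  genes <- sim_genes(sim)
  if (!gene %in% genes) .stop_fmt("gene '%s' is not in the map", gene)
  if (k >= length(genes)) {
    .stop_fmt("k = %d must be smaller than the number of genes (%d)",
              k, length(genes))
  }
  s <- sim[gene, ]
  s <- s[names(s) != gene]
  ord <- order(-s, names(s))
  out <- names(s)[ord][seq_len(k)]
  attr(out, "similarity") <- unname(s[ord][seq_len(k)])
  out
}

#' Intersection of two neighbor lists
#'
#' @param list_a,list_b character vectors of gene labels.
#' @return the order-independent set intersection.
#' @export
overlap_neighbors <- function(list_a, list_b) {
  sort(intersect(unique(list_a), unique(list_b)))
}

#' Hypergeometric gene-set enrichment with Bonferroni correction
#'
#' Tests each collection term for over-representation in a query gene
#' set using an upper-tail hypergeometric test on the map's gene
#' universe. Only terms with at least `min_term_size` genes in the
#' universe are evaluated, and the Bonferroni denominator is the number
#' of evaluated terms. Terms with corrected `p < alpha` are flagged
#' significant.
#'
#' @param query_genes character vector; must be a subset of `universe`.
#' @param collection named list of gene sets (e.g., from [read_gmt()]).
#' @param universe character vector of genes in the map.
#' @param min_term_size minimum term size in the universe (default 10).
#' @param alpha threshold on the corrected p-value (default 0.01).
#' @return data.frame sorted by raw p-value: `term`,
#'   `term_size_in_map`, `overlap`, `raw_p`, `corrected_p`,
#'   `significant`.
#' @export
enrich <- function(query_genes, collection, universe,
                   min_term_size = 10L, alpha = 0.01) {
  query_genes <- unique(query_genes)
  universe <- unique(universe)
  if (!length(query_genes)) .stop_fmt("empty query gene set")
  outside <- setdiff(query_genes, universe)
  if (length(outside)) {
    .stop_fmt("query gene(s) not in the universe: %s",
              paste(utils::head(outside, 5L), collapse = ", "))
  }
  n_univ <- length(universe)
  n_query <- length(query_genes)
  term_in_map <- lapply(collection, intersect, universe)
  eval_idx <- which(lengths(term_in_map) >= min_term_size)
  if (!length(eval_idx)) {
    .stop_fmt("no terms with >= %d genes in the map", min_term_size)
  }
  n_eval <- length(eval_idx)
  rows <- lapply(eval_idx, function(i) {
    m <- length(term_in_map[[i]])
    x <- length(intersect(term_in_map[[i]], query_genes))
    raw_p <- stats::phyper(x - 1L, m, n_univ - m, n_query,
                           lower.tail = FALSE)
    data.frame(term = names(collection)[i], term_size_in_map = m,
               overlap = x, raw_p = raw_p,
               corrected_p = min(1, raw_p * n_eval),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$corrected_p < alpha
  out <- out[order(out$raw_p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
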