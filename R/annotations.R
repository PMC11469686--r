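#' Annotation set of unordered gene pairs
#'
#' A deduplicated set of unordered gene pairs from one relationship
#' source (protein-complex memberships, pathway interactions, scored
#' protein links). Pairs are stored in canonical order
#' (lexicographically smaller label first); self-pairs are dropped.
#' Gene labels are case-preserved and matched case-sensitively.
#'
#' @param gene_a,gene_b character vectors of equal length, or `gene_a`
#'   may be a two-column data.frame/matrix.
#' @param source_name label identifying the annotation source.
#' @export
annotation_set <- function(gene_a, gene_b = NULL,
                           source_name = "annotation") {
  if (is.null(gene_b)) {
    ab <- as.data.frame(gene_a)
    stopifnot(ncol(ab) >= 2L)
    gene_b <- as.character(ab[[2L]])
    gene_a <- as.character(ab[[1L]])
  }
  gene_a <- trimws(as.character(gene_a))
  gene_b <- trimws(as.character(gene_b))
  stopifnot(length(gene_a) == length(gene_b))
  keep <- gene_a != gene_b & gene_a != "" & gene_b != ""
  a <- pmin(gene_a[keep], gene_b[keep])
  b <- pmax(gene_a[keep], gene_b[keep])
  dup <- duplicated(paste(a, b, sep = "\r"))
  structure(list(source_name = source_name,
                 pairs = data.frame(gene_a = a[!dup], gene_b = b[!dup],
                                    stringsAsFactors = FALSE)),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set '%s': %d unordered gene pairs\n",
              x$source_name, n_pairs(x)))
  invisible(x)
}

#' Number of pairs in an annotation set
#' @param ann an [annotation_set()].
#' @export
n_pairs <- function(ann) nrow(ann$pairs)

#' Read a scored edge list and threshold it into an annotation set
#'
#' For StringDB-style protein-links files: keeps edges with
#' `score >= score_threshold`, drops self-edges, and deduplicates
#' unordered pairs (edges listed in both orientations collapse to one).
#'
#' @param path delimited edge-list file.
#' @param score_threshold minimum score kept (e.g., 950 for
#'   high-confidence StringDB links).
#' @param columns named character vector mapping roles `gene_a`,
#'   `gene_b`, `score` to column names in the file.
#' @param source_name label for the resulting set.
#' @export
read_scored_edges <- function(path, score_threshold,
                              columns = c(gene_a = "gene_a",
                                          gene_b = "gene_b",
                                          score = "score"),
                              source_name = basename(path)) {
  dt <- data.table::fread(path, data.table = FALSE, showProgress = FALSE)
  missing_cols <- columns[!columns %in% names(dt)]
  if (length(missing_cols)) {
    .stop_fmt("schema error: column(s) not found in %s: %s", path,
              paste(missing_cols, collapse = ", "))
  }
  score <- dt[[columns[["score"]]]]
  if (!is.numeric(score)) .stop_fmt("schema error: score column '%s' is not numeric",
                                    columns[["score"]])
  keep <- score >= score_threshold
  annotation_set(dt[[columns[["gene_a"]]]][keep],
                 dt[[columns[["gene_b"]]]][keep], source_name)
}

#' Gene-cluster (protein-complex) catalog
#'
#' A named list of member gene vectors. Complexes may overlap; member
#' lists are deduplicated.
#'
#' @param complexes named list, complex name -> character vector of
#'   member genes.
#' @export
complex_catalog <- function(complexes) {
  stopifnot(is.list(complexes), !is.null(names(complexes)),
            all(names(complexes) != ""))
  complexes <- lapply(complexes, function(m) unique(as.character(m)))
  structure(list(complexes = complexes), class = "complex_catalog")
}

#' @export
print.complex_catalog <- function(x, ...) {
  cat(sprintf("complex_catalog: %d complexes (sizes %d-%d)\n",
              length(x$complexes), min(lengths(x$complexes)),
              max(lengths(x$complexes))))
  invisible(x)
}

#' Read a complex catalog from a two-column (complex, gene) table
#'
#' @param path delimited file with complex-name and gene columns.
#' @param columns column names for the complex and gene roles.
#' @export
read_complex_catalog <- function(path,
                                 columns = c(complex = "complex",
                                             gene = "gene")) {
  dt <- data.table::fread(path, data.table = FALSE, showProgress = FALSE)
  missing_cols <- columns[!columns %in% names(dt)]
  if (length(missing_cols)) {
    .stop_fmt("schema error: column(s) not found in %s: %s", path,
              paste(missing_cols, collapse = ", "))
  }
  complex_catalog(split(as.character(dt[[columns[["gene"]]]]),
                        dt[[columns[["complex"]]]]))
}

#' Write a complex catalog as a two-column table
#' @param catalog a [complex_catalog()].
#' @param path output path.
#' @export
write_complex_catalog <- function(catalog, path) {
  out <- data.frame(
    complex = rep(names(catalog$complexes), lengths(catalog$complexes)),
    gene = unlist(catalog$complexes, use.names = FALSE),
    stringsAsFactors = FALSE)
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  data.table::fwrite(out, path, sep = sep, quote = FALSE)
  invisible(path)
}

#' Union of all within-complex pairs across a catalog
#'
#' Expands every complex into its unordered member pairs and collapses
#' duplicates across complexes — the standard construction of a
#' relationship benchmark from a complex catalog.
#'
#' @param catalog a [complex_catalog()].
#' @param source_name label for the resulting set.
#' @export
complexes_to_pairs <- function(catalog, source_name = "complexes") {
  a <- character(); b <- character()
  for (members in catalog$complexes) {
    if (length(members) < 2L) next
    pr <- utils::combn(sort(members), 2L)
    a <- c(a, pr[1L, ]); b <- c(b, pr[2L, ])
  }
  annotation_set(a, b, source_name)
}

#' Overlap of annotation sources by multiplicity
#'
#' Counts, for each multiplicity m, how many unique unordered pairs
#' appear in exactly m and in at least m of the given sources.
#'
#' @param sources list of [annotation_set()] objects (>= 2).
#' @return data.frame with columns `multiplicity`, `n_exact`,
#'   `n_at_least`.
#' @export
source_overlap <- function(sources) {
  if (length(sources) < 2L) .stop_fmt("source_overlap needs >= 2 sources")
  keys <- lapply(sources, function(s)
    paste(s$pairs$gene_a, s$pairs$gene_b, sep = "\r"))
  tab <- table(unlist(keys))
  m <- seq_along(sources)
  n_exact <- vapply(m, function(i) sum(tab == i), integer(1))
  n_at_least <- rev(cumsum(rev(n_exact)))
  data.frame(multiplicity = m, n_exact = n_exact, n_at_least = n_at_least)
}

#' Read a gene-set collection from a GMT file
#'
#' GMT is tab-separated: term, description, then member genes. Returns a
#' named list of member vectors with descriptions in the
#' `"descriptions"` attribute.
#'
#' @param path GMT file.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) {
    .stop_fmt("malformed GMT line %d: fewer than 3 tab-separated fields",
              bad[1])
  }
  terms <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(terms)) {
    .stop_fmt("duplicate GMT term: %s", terms[duplicated(terms)][1])
  }
  sets <- lapply(parts, function(p) unique(p[-c(1L, 2L)]))
  names(sets) <- terms
  attr(sets, "descriptions") <-
    stats::setNames(vapply(parts, `[[`, character(1), 2L), terms)
  sets
}

#' Write a gene-set collection to a GMT file
#' @param sets named list of gene vectors.
#' @param path output path.
#' @param descriptions optional named descriptions (defaults to `"NA"`).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  desc <- if (is.null(descriptions)) rep("NA", length(sets)) else
    descriptions[names(sets)]
  lines <- mapply(function(term, d, members)
    paste(c(term, d, members), collapse = "\t"),
    names(sets), desc, sets)
  writeLines(lines, path)
  invisible(path)
}
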