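#' Unit-level perturbation matrix
#'
#' The central container for unit-level screen readouts: one row per
#' perturbation unit (a well in arrayed screens, a cell in pooled
#' single-cell screens), numeric feature columns, and per-unit metadata
#' (perturbation label, batch, control flag, expressed flag). Optional
#' QC columns (e.g., intensity metrics, object counts) ride along and
#' can be targeted by filter rules without being part of the embedding.
#'
#' @param features numeric matrix, units x dimensions; no missing values.
#' @param perturbation character vector of perturbation labels (gene
#'   symbol or a control tag), one per unit. Matched case-sensitively.
#' @param batch character vector of batch labels, one per unit.
#' @param is_control logical flag per unit. Controls are identified by
#'   this flag only, never by label string matching.
#' @param is_expressed logical flag per unit; meaningful only for
#'   non-control units (forced to `NA` for controls). `NULL` means
#'   unknown for all units.
#' @param unit_ids unique unit identifiers; generated when `NULL`.
#' @param qc optional data.frame of named numeric QC columns.
#' @return an object of class `unit_matrix`.
#' @export
unit_matrix <- function(features, perturbation, batch, is_control,
                        is_expressed = NULL, unit_ids = NULL, qc = NULL) {
  features <- as.matrix(features)
  if (!is.numeric(features)) {
    .stop_fmt("feature matrix must be numeric")
  }
  if (anyNA(features)) {
    .stop_fmt("feature matrix contains missing values")
  }
  n <- nrow(features)
  if (is.null(colnames(features))) {
    colnames(features) <- sprintf("feat_%03d", seq_len(ncol(features)))
  }
  perturbation <- as.character(perturbation)
  batch <- as.character(batch)
  is_control <- as.logical(is_control)
  if (length(perturbation) != n || length(batch) != n ||
      length(is_control) != n) {
    .stop_fmt("metadata length does not match the number of units (%d)", n)
  }
  if (anyNA(perturbation) || anyNA(batch) || anyNA(is_control)) {
    .stop_fmt("perturbation, batch and is_control must have no missing values")
  }
  if (is.null(is_expressed)) {
    is_expressed <- rep(NA, n)
  }
  is_expressed <- as.logical(is_expressed)
  if (length(is_expressed) != n) {
    .stop_fmt("is_expressed length does not match the number of units (%d)", n)
  }
  is_expressed[is_control] <- NA
  if (is.null(unit_ids)) {
    unit_ids <- sprintf("unit_%06d", seq_len(n))
  }
  unit_ids <- as.character(unit_ids)
  if (anyDuplicated(unit_ids)) {
    .stop_fmt("unit_ids must be unique")
  }
  rownames(features) <- unit_ids
  if (!is.null(qc)) {
    qc <- as.data.frame(qc)
    if (nrow(qc) != n) .stop_fmt("qc table must have one row per unit")
    rownames(qc) <- unit_ids
  }
  structure(
    list(features = features, unit_ids = unit_ids,
         perturbation = perturbation, batch = batch,
         is_control = is_control, is_expressed = is_expressed, qc = qc),
    class = "unit_matrix")
}

#' @export
print.unit_matrix <- function(x, ...) {
  cat(sprintf(
    "unit_matrix: %d units x %d dimensions | %d perturbations, %d batches, %d controls\n",
    n_units(x), n_dims(x), length(unique(x$perturbation[!x$is_control])),
    length(unique(x$batch)), sum(x$is_control)))
  invisible(x)
}

#' Number of units / feature dimensions
#' @param x a `unit_matrix`.
#' @export
n_units <- function(x) nrow(x$features)

#' @rdname n_units
#' @export
n_dims <- function(x) ncol(x$features)

#' Subset a unit matrix by unit (row) index
#'
#' @param x a `unit_matrix`.
#' @param i integer or logical row index.
#' @param ... unused.
#' @export
`[.unit_matrix` <- function(x, i, ...) {
  unit_matrix(x$features[i, , drop = FALSE], x$perturbation[i], x$batch[i],
              x$is_control[i], x$is_expressed[i], x$unit_ids[i],
              if (is.null(x$qc)) NULL else x$qc[i, , drop = FALSE])
}

#' Replace the feature matrix, keeping metadata
#'
#' Used by pipeline stages that transform features row-for-row.
#'
#' @param x a `unit_matrix`.
#' @param features replacement numeric matrix with `n_units(x)` rows.
#' @export
set_features <- function(x, features) {
  features <- as.matrix(features)
  if (nrow(features) != n_units(x)) {
    .stop_fmt("replacement features must keep one row per unit")
  }
  unit_matrix(features, x$perturbation, x$batch, x$is_control,
              x$is_expressed, x$unit_ids, x$qc)
}

#' Default column-role schema for unit tables
#'
#' Maps table columns to roles. Columns not claimed by a role and not
#' matching a QC prefix are treated as numeric feature columns.
#'
#' @param perturbation,batch,is_control,is_expressed,unit_id column names
#'   for each role; `is_expressed` and `unit_id` may be `NULL` (absent).
#' @param qc_prefix character vector of prefixes marking QC columns.
#' @export
unit_schema <- function(perturbation = "perturbation", batch = "batch",
                        is_control = "is_control",
                        is_expressed = "is_expressed",
                        unit_id = "unit_id",
                        qc_prefix = character()) {
  list(perturbation = perturbation, batch = batch, is_control = is_control,
       is_expressed = is_expressed, unit_id = unit_id, qc_prefix = qc_prefix)
}

.parse_flag <- function(x, column) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("true", "t", "1", "yes")] <- TRUE
  out[v %in% c("false", "f", "0", "no")] <- FALSE
  out[v %in% c("na", "")] <- NA
  bad <- which(is.na(out) & !v %in% c("na", ""))
  if (length(bad)) {
    .stop_fmt("column '%s': cannot interpret value '%s' (row %d) as a flag",
              column, v[bad[1]], bad[1])
  }
  out
}

#' Read a unit-level table from a delimited file
#'
#' The on-disk interchange format is a delimited table with a declared
#' schema mapping columns to roles; every column not claimed by a role
#' (and not matching a QC prefix) is a numeric feature column. Rows with
#' missing feature values are dropped with a warning so that a corrupt
#' row does not abort a large load.
#'
#' @param path path to a CSV/TSV table (delimiter sniffed).
#' @param schema a role mapping from [unit_schema()].
#' @return a validated [unit_matrix()].
#' @export
read_unit_matrix <- function(path, schema = unit_schema()) {
  if (!file.exists(path)) .stop_fmt("unit table not found: %s", path)
  dt <- data.table::fread(path, data.table = FALSE, showProgress = FALSE)
  mandatory <- c(perturbation = schema$perturbation, batch = schema$batch,
                 is_control = schema$is_control)
  missing_cols <- mandatory[!mandatory %in% names(dt)]
  if (length(missing_cols)) {
    .stop_fmt("schema error: mandatory column(s) not found in %s: %s",
              path, paste(missing_cols, collapse = ", "))
  }
  role_cols <- unlist(schema[c("perturbation", "batch", "is_control",
                               "is_expressed", "unit_id")], use.names = FALSE)
  role_cols <- role_cols[role_cols %in% names(dt)]
  qc_cols <- character()
  for (p in schema$qc_prefix) {
    qc_cols <- c(qc_cols, names(dt)[startsWith(names(dt), p)])
  }
  qc_cols <- setdiff(unique(qc_cols), role_cols)
  feat_cols <- setdiff(names(dt), c(role_cols, qc_cols))
  if (!length(feat_cols)) .stop_fmt("no feature columns found in %s", path)
  feats <- dt[feat_cols]
  for (cn in feat_cols) {
    v <- feats[[cn]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & trimws(v) != "" &
                     tolower(trimws(v)) != "na")
      if (length(bad)) {
        .stop_fmt("parse error: non-numeric feature value '%s' at row %d, column '%s'",
                  v[bad[1]], bad[1], cn)
      }
      feats[[cn]] <- num
    }
  }
  feats <- as.matrix(feats)
  keep <- !apply(is.na(feats), 1L, any)
  if (!all(keep)) {
    warning(sprintf("dropped %d row(s) with missing feature values",
                    sum(!keep)), call. = FALSE)
  }
  dt <- dt[keep, , drop = FALSE]
  feats <- feats[keep, , drop = FALSE]
  expressed <- if (!is.null(schema$is_expressed) &&
                   schema$is_expressed %in% names(dt)) {
    .parse_flag(dt[[schema$is_expressed]], schema$is_expressed)
  } else NULL
  ids <- if (!is.null(schema$unit_id) && schema$unit_id %in% names(dt)) {
    as.character(dt[[schema$unit_id]])
  } else NULL
  qc <- if (length(qc_cols)) dt[qc_cols] else NULL
  unit_matrix(feats, dt[[schema$perturbation]], dt[[schema$batch]],
              .parse_flag(dt[[schema$is_control]], schema$is_control),
              expressed, ids, qc)
}

# format doubles so the decimal text round-trips bit-exactly
.fmt_double <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  gsub(" ", "", out, fixed = TRUE)
}

#' Write a unit-level table to a delimited file
#'
#' Numeric features are written with 17 significant digits so a
#' write/read round trip reproduces them bit-exactly.
#'
#' @param units a `unit_matrix`.
#' @param path output path (`.tsv` or `.csv`; extension picks delimiter).
#' @export
write_unit_matrix <- function(units, path) {
  out <- data.frame(unit_id = units$unit_ids,
                    perturbation = units$perturbation,
                    batch = units$batch,
                    is_control = units$is_control,
                    is_expressed = units$is_expressed,
                    stringsAsFactors = FALSE)
  if (!is.null(units$qc)) {
    qc <- units$qc
    for (cn in names(qc)) {
      if (is.double(qc[[cn]])) qc[[cn]] <- .fmt_double(qc[[cn]])
    }
    out <- cbind(out, qc)
  }
  fm <- units$features
  fchr <- as.data.frame(apply(fm, 2L, .fmt_double, simplify = FALSE))
  out <- cbind(out, fchr)
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  data.table::fwrite(out, path, sep = sep, quote = FALSE)
  invisible(path)
}

#' Aggregated perturbation map
#'
#' One embedding vector per perturbed gene, the result of the
#' embed/filter/align/aggregate stages. Row names are the gene universe.
#'
#' @param vectors numeric matrix genes x dimensions with unique,
#'   non-empty row names.
#' @param provenance named list describing how the map was built
#'   (pipeline stages, parameters, seed, replicate counts).
#' @export
aggregated_map <- function(vectors, provenance = list()) {
  vectors <- as.matrix(vectors)
  g <- rownames(vectors)
  if (is.null(g) || any(g == "")) .stop_fmt("map rows must be named by gene")
  if (anyDuplicated(g)) {
    .stop_fmt("duplicate gene labels in map: %s",
              paste(unique(g[duplicated(g)]), collapse = ", "))
  }
  if (any(apply(is.na(vectors), 1L, all))) {
    .stop_fmt("map contains all-missing rows")
  }
  structure(list(genes = g, vectors = vectors, provenance = provenance),
            class = "aggregated_map")
}

#' @export
print.aggregated_map <- function(x, ...) {
  cat(sprintf("aggregated_map: %d genes x %d dimensions\n",
              length(x$genes), ncol(x$vectors)))
  invisible(x)
}

#' Write / read an aggregated map with its provenance sidecar
#'
#' The map is a delimited table (gene label column + feature columns);
#' provenance is stored next to it in `<path>.meta.json`.
#'
#' @param map an [aggregated_map()].
#' @param path output path for the table.
#' @export
write_aggregated_map <- function(map, path) {
  dir_ok <- dir.exists(dirname(path))
  if (!dir_ok) .stop_fmt("cannot write map: directory does not exist (%s)",
                         dirname(path))
  fchr <- as.data.frame(apply(map$vectors, 2L, .fmt_double, simplify = FALSE))
  out <- cbind(data.frame(gene = map$genes, stringsAsFactors = FALSE), fchr)
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  data.table::fwrite(out, path, sep = sep, quote = FALSE)
  jsonlite::write_json(map$provenance, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_aggregated_map
#' @export
read_aggregated_map <- function(path) {
  dt <- data.table::fread(path, data.table = FALSE, showProgress = FALSE)
  vec <- as.matrix(dt[-1L])
  rownames(vec) <- as.character(dt[[1L]])
  meta_path <- paste0(path, ".meta.json")
  prov <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else list()
  aggregated_map(vec, prov)
}

#' Symmetric cosine-similarity matrix over a gene universe
#'
#' @param values symmetric numeric matrix with values in `[-1, 1]` and
#'   row/column names giving the gene universe.
#' @export
similarity_matrix <- function(values) {
  values <- as.matrix(values)
  g <- rownames(values)
  if (is.null(g) || !identical(g, colnames(values))) {
    .stop_fmt("similarity matrix must have matching row/column gene names")
  }
  if (max(abs(values - t(values))) > 1e-8) {
    .stop_fmt("similarity matrix is not symmetric")
  }
  if (min(values) < -1 - 1e-8 || max(values) > 1 + 1e-8) {
    .stop_fmt("cosine similarities must lie in [-1, 1]")
  }
  values <- (values + t(values)) / 2
  values <- .clamp(values, -1, 1)
  structure(values, class = c("similarity_matrix", "matrix"))
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("similarity_matrix: %d genes\n", nrow(x)))
  invisible(x)
}

#' Genes covered by a similarity matrix
#' @param sim a `similarity_matrix`.
#' @export
sim_genes <- function(sim) rownames(sim)
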