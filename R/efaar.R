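#' Principal-component embedding of unit-level features
#'
#' Computes PCA via the eigendecomposition of the feature covariance so
#' that all `ncol` components exist even when the fit set has fewer rows
#' than features. The sign of each component is fixed so that its
#' largest-magnitude loading is positive, making results reproducible
#' across linear-algebra backends.
#'
#' @param units a [unit_matrix()].
#' @param k number of principal components to retain.
#' @param fit_on fit the rotation on `"all"` units or on `"controls"`
#'   only (the latter is the typical-variation convention).
#' @param scale_per_batch center and scale every feature within each
#'   batch (using all units in the batch) before fitting; the standard
#'   preprocessing for PCA maps of batched screens.
#' @return a `unit_matrix` whose features are the top-`k` PC scores; the
#'   fitted rotation, center and eigenvalues are attached as attribute
#'   `"pca"`, and explained-variance fractions as
#'   `attr(, "explained_variance")`.
#' @export
embed_pca <- function(units, k, fit_on = c("all", "controls"),
                      scale_per_batch = FALSE) {
  fit_on <- match.arg(fit_on)
  x <- units$features
  if (scale_per_batch) {
    for (b in unique(units$batch)) {
      idx <- which(units$batch == b)
      mu <- colMeans(x[idx, , drop = FALSE])
      sdv <- apply(x[idx, , drop = FALSE], 2L, stats::sd)
      zero <- which(sdv == 0)
      if (length(zero)) {
        .stop_fmt("zero standard deviation in feature '%s' (batch '%s')",
                  colnames(x)[zero[1]], b)
      }
      x[idx, ] <- sweep(sweep(x[idx, , drop = FALSE], 2L, mu), 2L, sdv, "/")
    }
  }
  fit_idx <- if (fit_on == "controls") which(units$is_control) else
    seq_len(nrow(x))
  if (fit_on == "controls" && length(fit_idx) < 2L) {
    .stop_fmt("embed_pca(fit_on = 'controls') needs >= 2 control units")
  }
  attainable <- min(length(fit_idx), ncol(x))
  if (k < 1L || k > attainable) {
    .stop_fmt("k = %d exceeds the attainable rank %d (min of fit units and dimensions)",
              k, attainable)
  }
  xf <- x[fit_idx, , drop = FALSE]
  ctr <- colMeans(xf)
  xc <- sweep(xf, 2L, ctr)
  cv <- crossprod(xc) / max(1L, nrow(xc) - 1L)
  eg <- eigen(cv, symmetric = TRUE)
  rot <- eg$vectors
  # sign convention: largest-magnitude loading of each component positive
  for (j in seq_len(ncol(rot))) {
    i_max <- which.max(abs(rot[, j]))
    if (rot[i_max, j] < 0) rot[, j] <- -rot[, j]
  }
  evals <- pmax(eg$values, 0)
  scores <- sweep(x, 2L, ctr) %*% rot[, seq_len(k), drop = FALSE]
  colnames(scores) <- sprintf("PC%03d", seq_len(k))
  out <- set_features(units, scores)
  attr(out, "pca") <- list(rotation = rot[, seq_len(k), drop = FALSE],
                           center = ctr, eigenvalues = evals)
  attr(out, "explained_variance") <-
    if (sum(evals) > 0) evals[seq_len(k)] / sum(evals) else rep(0, k)
  out
}

#' Filter rules for unit-level QC
#'
#' Rules are applied in the declared order by [apply_filters()].
#'
#' * `filter_robust_outliers()` fits a robust Gaussian
#'   (minimum-covariance-determinant location/scatter) to the selected
#'   columns and removes the declared fraction of units with the lowest
#'   Gaussian density, i.e., the largest robust Mahalanobis distance.
#' * `filter_range()` keeps units whose column value lies within
#'   `[low, high]` (inclusive by default).
#' * `filter_drop_columns()` removes feature columns whose names start
#'   with a prefix (e.g., whole-image features).
#'
#' @param selector substring matched against feature and QC column names
#'   (fixed, case-sensitive); all matching columns are used jointly.
#' @param contamination fraction of units to remove, in (0, 0.5).
#' @param column exact feature or QC column name.
#' @param low,high inclusive bounds kept by `filter_range`.
#' @param inclusive keep boundary values (default) or use strict bounds.
#' @param prefix feature-column name prefix to drop.
#' @name filter_rules
NULL

#' @rdname filter_rules
#' @export
filter_robust_outliers <- function(selector, contamination = 0.01) {
  stopifnot(contamination > 0, contamination < 0.5)
  structure(list(kind = "robust_gaussian_outlier", selector = selector,
                 contamination = contamination), class = "filter_rule")
}

#' @rdname filter_rules
#' @export
filter_range <- function(column, low, high, inclusive = TRUE) {
  stopifnot(low <= high)
  structure(list(kind = "range", column = column, low = low, high = high,
                 inclusive = inclusive), class = "filter_rule")
}

#' @rdname filter_rules
#' @export
filter_drop_columns <- function(prefix) {
  structure(list(kind = "drop_columns", prefix = prefix),
            class = "filter_rule")
}

# pull a units x p matrix of the columns matched by a selector,
# searching feature columns first, then QC columns
.select_columns <- function(units, selector, exact = FALSE) {
  pick <- function(nms) {
    if (exact) nms[nms == selector] else
      nms[grepl(selector, nms, fixed = TRUE)]
  }
  f_hit <- pick(colnames(units$features))
  q_hit <- if (!is.null(units$qc)) pick(names(units$qc)) else character()
  if (!length(f_hit) && !length(q_hit)) {
    .stop_fmt("filter selector '%s' matches no feature or QC column", selector)
  }
  cbind(units$features[, f_hit, drop = FALSE],
        if (length(q_hit)) as.matrix(units$qc[q_hit]))
}

#' Apply QC filter rules to a unit matrix
#'
#' Rules execute in list order; counts of removed units/columns are
#' recorded in the `"filter_log"` attribute of the result.
#'
#' @param units a [unit_matrix()].
#' @param rules list of rules from [filter_rules].
#' @return the filtered `unit_matrix`.
#' @export
apply_filters <- function(units, rules) {
  log <- list()
  for (rule in rules) {
    if (!inherits(rule, "filter_rule")) .stop_fmt("not a filter rule")
    removed_units <- 0L
    removed_cols <- 0L
    if (rule$kind == "robust_gaussian_outlier") {
      z <- .select_columns(units, rule$selector)
      n <- nrow(z)
      fit <- MASS::cov.rob(z, method = "mcd")
      d2 <- stats::mahalanobis(z, fit$center, fit$cov)
      k <- round(n * rule$contamination)
      if (k > 0L) {
        drop_idx <- order(d2, decreasing = TRUE)[seq_len(k)]
        units <- units[-drop_idx]
        removed_units <- k
      }
    } else if (rule$kind == "range") {
      v <- drop(.select_columns(units, rule$column, exact = TRUE))
      keep <- if (rule$inclusive) v >= rule$low & v <= rule$high else
        v > rule$low & v < rule$high
      removed_units <- sum(!keep)
      units <- units[keep]
    } else if (rule$kind == "drop_columns") {
      hit <- startsWith(colnames(units$features), rule$prefix)
      removed_cols <- sum(hit)
      if (removed_cols == ncol(units$features)) {
        .stop_fmt("drop_columns('%s') would remove every feature column",
                  rule$prefix)
      }
      if (removed_cols > 0L) {
        units <- set_features(units, units$features[, !hit, drop = FALSE])
      }
    } else {
      .stop_fmt("unknown filter rule kind '%s'", rule$kind)
    }
    if (n_units(units) == 0L) {
      .stop_fmt("all units filtered: rule '%s' left no units", rule$kind)
    }
    log[[length(log) + 1L]] <- data.frame(
      rule = rule$kind, removed_units = removed_units,
      removed_columns = removed_cols, stringsAsFactors = FALSE)
  }
  attr(units, "filter_log") <- do.call(rbind, log)
  units
}

#' Center and scale features by reference units
#'
#' The standard control-anchored alignment: every feature is shifted and
#' scaled by the mean and standard deviation of the reference units,
#' either within each batch or over the global pool.
#'
#' @param units a [unit_matrix()].
#' @param scope `"per_batch"` (default) or `"global"`.
#' @param reference `"controls"` (default) or `"all"` units.
#' @return the aligned `unit_matrix`.
#' @export
align_center_scale <- function(units, scope = c("per_batch", "global"),
                               reference = c("controls", "all")) {
  scope <- match.arg(scope)
  reference <- match.arg(reference)
  x <- units$features
  groups <- if (scope == "per_batch") split(seq_len(nrow(x)), units$batch)
    else list(all = seq_len(nrow(x)))
  ref_of <- function(idx) {
    if (reference == "controls") idx[units$is_control[idx]] else idx
  }
  short <- names(groups)[vapply(groups, function(i) length(ref_of(i)) < 2L,
                                logical(1))]
  if (length(short)) {
    .stop_fmt("fewer than 2 reference units in batch(es): %s",
              paste(short, collapse = ", "))
  }
  for (g in names(groups)) {
    idx <- groups[[g]]
    ref <- ref_of(idx)
    mu <- colMeans(x[ref, , drop = FALSE])
    sdv <- apply(x[ref, , drop = FALSE], 2L, stats::sd)
    zero <- which(sdv == 0)
    if (length(zero)) {
      .stop_fmt("zero standard deviation in feature '%s' (scope '%s')",
                colnames(x)[zero[1]], g)
    }
    x[idx, ] <- sweep(sweep(x[idx, , drop = FALSE], 2L, mu), 2L, sdv, "/")
  }
  set_features(units, x)
}

# symmetric inverse principal square root with ridge regularization
.inv_sqrtm <- function(cv, eps_rel = 1e-6, context = "") {
  ridge <- eps_rel * mean(diag(cv))
  cv <- cv + diag(ridge, nrow(cv))
  eg <- eigen(cv, symmetric = TRUE)
  if (min(eg$values) <= 0) {
    .stop_fmt("covariance numerically singular beyond regularization%s",
              context)
  }
  eg$vectors %*% (t(eg$vectors) / sqrt(eg$values))
}

#' Typical-variation normalization (TVN) with per-batch CORAL
#'
#' Control-anchored alignment of both first- and second-order batch
#' structure: (1) center/scale every feature by the global control mean
#' and standard deviation; (2) fit PCA on the control units only
#' (all components kept, dimension-preserving) and project all units;
#' (3) center/scale the projected scores by the global control
#' statistics; (4) per batch, correlation alignment (CORAL): center by
#' the batch-control mean and whiten by the inverse principal square
#' root of the batch-control covariance, so that each batch's controls
#' become approximately white in a common frame.
#'
#' @param units a [unit_matrix()] with >= 2 controls globally and per
#'   batch.
#' @param eps_rel ridge added to covariances before the matrix square
#'   root, relative to the mean diagonal; small control counts per batch
#'   make these covariances ill-conditioned.
#' @return the aligned `unit_matrix`.
#' @export
align_tvn <- function(units, eps_rel = 1e-6) {
  ctrl <- which(units$is_control)
  if (length(ctrl) < 2L) .stop_fmt("align_tvn needs >= 2 control units")
  per_batch_ctrl <- split(ctrl, units$batch[ctrl])
  all_batches <- unique(units$batch)
  short <- setdiff(all_batches, names(per_batch_ctrl))
  short <- c(short, names(per_batch_ctrl)[
    lengths(per_batch_ctrl) < 2L])
  if (length(short)) {
    .stop_fmt("fewer than 2 control units in batch(es): %s",
              paste(short, collapse = ", "))
  }
  # (1) global control center/scale of input features
  units <- align_center_scale(units, scope = "global",
                              reference = "controls")
  # (2) control-fit PCA, all components kept
  units <- embed_pca(units, k = n_dims(units), fit_on = "controls")
  x <- units$features
  # (3) global control center/scale of the PC scores
  mu <- colMeans(x[ctrl, , drop = FALSE])
  sdv <- apply(x[ctrl, , drop = FALSE], 2L, stats::sd)
  zero <- which(sdv == 0)
  if (length(zero)) {
    .stop_fmt("zero control variance in component '%s' after control PCA; rank-deficient controls",
              colnames(x)[zero[1]])
  }
  x <- sweep(sweep(x, 2L, mu), 2L, sdv, "/")
  # (4) per-batch CORAL: center by batch controls, whiten their covariance
  for (b in all_batches) {
    idx <- which(units$batch == b)
    bc <- intersect(idx, ctrl)
    mu_b <- colMeans(x[bc, , drop = FALSE])
    cv_b <- stats::cov(x[bc, , drop = FALSE])
    w <- .inv_sqrtm(cv_b, eps_rel,
                    context = sprintf(" in batch '%s'", b))
    x[idx, ] <- sweep(x[idx, , drop = FALSE], 2L, mu_b) %*% w
  }
  out <- set_features(units, x)
  attr(out, "pca") <- attr(units, "pca")
  out
}

#' Aggregate replicate units into one vector per perturbation
#'
#' Coordinate-wise mean of the aligned embeddings over all units sharing
#' a perturbation label; control units are excluded from the gene
#' universe. Genes are ordered lexicographically.
#'
#' @param units a [unit_matrix()].
#' @return an [aggregated_map()] whose provenance records replicate
#'   counts per gene.
#' @export
aggregate_mean <- function(units) {
  keep <- !units$is_control
  if (!any(keep)) .stop_fmt("no non-control units to aggregate")
  x <- units$features[keep, , drop = FALSE]
  g <- units$perturbation[keep]
  counts <- table(g)
  sums <- rowsum(x, group = g)          # rows sorted by group label
  vec <- sums / as.vector(counts[rownames(sums)])
  aggregated_map(vec, provenance = list(
    aggregate = "mean",
    n_replicates = stats::setNames(as.integer(counts), names(counts))))
}

#' Pairwise cosine similarities between aggregated embeddings
#'
#' @param map an [aggregated_map()]; zero-norm vectors are an error
#'   (they indicate degenerate upstream filtering), never silent `NaN`.
#' @return a [similarity_matrix()].
#' @export
relate_cosine <- function(map) {
  norms <- .row_norms(map$vectors)
  zero <- which(norms == 0)
  if (length(zero)) {
    .stop_fmt("zero-norm aggregated vector(s): %s",
              paste(map$genes[zero], collapse = ", "))
  }
  nrm <- map$vectors / norms
  s <- tcrossprod(nrm)
  s <- .clamp((s + t(s)) / 2, -1, 1)
  diag(s) <- 1
  similarity_matrix(s)
}

#' Pipeline configuration for map building
#'
#' Describes one EFAAR pipeline: the embedding, the ordered filter
#' rules, the alignment, and the (fixed) aggregation/relating choices.
#'
#' @param embed `"none"` or `"pca"`.
#' @param k retained principal components when `embed = "pca"`.
#' @param pca_fit_on `"all"` or `"controls"` (see [embed_pca()]).
#' @param pca_scale_per_batch center/scale features within each batch
#'   (all units) before the PCA fit.
#' @param filters ordered list of rules from [filter_rules]; applied
#'   before embedding.
#' @param align `"none"`, `"center_scale"` or `"tvn"`.
#' @param cs_scope,cs_reference passed to [align_center_scale()] when
#'   `align = "center_scale"`.
#' @param aggregate only `"mean"` is supported.
#' @param relate only `"cosine"` is supported.
#' @param seed integer recorded in provenance and set before execution.
#' @export
pipeline_config <- function(embed = c("pca", "none"), k = 128L,
                            pca_fit_on = "all",
                            pca_scale_per_batch = FALSE,
                            filters = list(),
                            align = c("none", "center_scale", "tvn"),
                            cs_scope = "per_batch",
                            cs_reference = "controls",
                            aggregate = "mean", relate = "cosine",
                            seed = 1L) {
  embed <- match.arg(embed)
  align <- match.arg(align)
  stopifnot(identical(aggregate, "mean"), identical(relate, "cosine"),
            k >= 1L)
  structure(list(embed = embed, k = as.integer(k), pca_fit_on = pca_fit_on,
                 pca_scale_per_batch = pca_scale_per_batch,
                 filters = filters, align = align, cs_scope = cs_scope,
                 cs_reference = cs_reference, aggregate = aggregate,
                 relate = relate, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Named pipeline presets
#'
#' The standard pipelines for batched screens: `"PCA"` (plain PCA of
#' the raw features, no alignment), `"PCA-CS"` (PCA followed by
#' per-batch control centering/scaling of the scores), `"PCA-TVN"`
#' (PCA followed by typical-variation normalization), and the
#' `"Raw-CS"` / `"Raw-TVN"` counterparts that skip the PCA embedding.
#' Set `scale_per_batch = TRUE` for the variant that centers/scales
#' all units within each batch before the PCA fit, used for some
#' image-based screens.
#'
#' @param name preset name.
#' @param k retained principal components for the PCA presets.
#' @param seed recorded in provenance.
#' @param scale_per_batch per-batch center/scale (all units) of the
#'   features before the PCA fit.
#' @export
pipeline_preset <- function(name = c("PCA", "PCA-CS", "PCA-TVN",
                                     "Raw-CS", "Raw-TVN"),
                            k = 128L, seed = 1L,
                            scale_per_batch = FALSE) {
  name <- match.arg(name)
  switch(name,
    "PCA" = pipeline_config(embed = "pca", k = k,
                            pca_scale_per_batch = scale_per_batch,
                            align = "none", seed = seed),
    "PCA-CS" = pipeline_config(embed = "pca", k = k,
                               pca_scale_per_batch = scale_per_batch,
                               align = "center_scale", seed = seed),
    "PCA-TVN" = pipeline_config(embed = "pca", k = k,
                                pca_scale_per_batch = scale_per_batch,
                                align = "tvn", seed = seed),
    "Raw-CS" = pipeline_config(embed = "none", align = "center_scale",
                               seed = seed),
    "Raw-TVN" = pipeline_config(embed = "none", align = "tvn", seed = seed))
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; filter rules are
#' given as a list of `{kind: ..., ...}` records.
#'
#' @param path YAML file.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    .stop_fmt("unknown pipeline config key(s): %s",
              paste(bad, collapse = ", "))
  }
  if (!is.null(raw$filters)) {
    raw$filters <- lapply(raw$filters, function(fr) {
      kind <- fr$kind
      if (is.null(kind)) .stop_fmt("filter rule without a 'kind' key")
      switch(kind,
        robust_gaussian_outlier = filter_robust_outliers(
          fr$selector, fr$contamination %||% 0.01),
        range = filter_range(fr$column, fr$low, fr$high,
                             fr$inclusive %||% TRUE),
        drop_columns = filter_drop_columns(fr$prefix),
        .stop_fmt("unknown filter rule kind '%s'", kind))
    })
  }
  do.call(pipeline_config, raw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# serializable description of a config, for provenance records
.config_provenance <- function(config) {
  list(embed = config$embed,
       k = if (config$embed == "pca") config$k else NULL,
       pca_fit_on = config$pca_fit_on,
       pca_scale_per_batch = config$pca_scale_per_batch,
       filters = lapply(config$filters, function(r) unclass(r)),
       align = config$align,
       cs_scope = config$cs_scope, cs_reference = config$cs_reference,
       aggregate = config$aggregate, relate = config$relate,
       seed = config$seed)
}

#' Run a full EFAAR pipeline
#'
#' Executes filter, embed, align, aggregate and relate in order on a
#' unit matrix, and records the full configuration (plus explained
#' variance and filter log where applicable) in the map's provenance.
#'
#' @param units a [unit_matrix()].
#' @param config a [pipeline_config()].
#' @return a list with elements `map` ([aggregated_map()]) and `sim`
#'   ([similarity_matrix()]).
#' @export
run_pipeline <- function(units, config) {
  stopifnot(inherits(config, "pipeline_config"))
  prov <- list(pipeline = .config_provenance(config))
  withr::with_seed(config$seed, {
    if (length(config$filters)) {
      units <- apply_filters(units, config$filters)
      prov$filter_log <- attr(units, "filter_log")
    }
    if (config$embed == "pca") {
      units <- embed_pca(units, k = config$k, fit_on = config$pca_fit_on,
                         scale_per_batch = config$pca_scale_per_batch)
      prov$explained_variance <- attr(units, "explained_variance")
    }
    units <- switch(config$align,
      none = units,
      center_scale = align_center_scale(units, scope = config$cs_scope,
                                        reference = config$cs_reference),
      tvn = align_tvn(units))
    map <- aggregate_mean(units)
    map$provenance <- c(prov, map$provenance)
    sim <- relate_cosine(map)
  })
  list(map = map, sim = sim, units = units)
}
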