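# Normalization, variable-gene selection, embedding, clustering plumbing and
# marker-score cell-type annotation.

#' Library-size normalize and log-transform counts
#'
#' Standard 10x-style normalization: each cell's counts are scaled to
#' `scale_factor` total, then `log2(1 + x)` transformed. Entry for count c in
#' a cell of total T is `log2(1 + scale_factor * c / T)`, so the result is
#' invariant to per-cell sequencing depth.
#'
#' @param counts a [count_matrix()].
#' @param scale_factor target per-cell total (default 10,000).
#' @return an `expr_matrix`: dense cells x genes matrix of log2 expression
#'   with attribute `scale_factor`.
#' @export
normalize_log <- function(counts, scale_factor = 1e4) {
  assert_scalar_number(scale_factor, "scale_factor", lower = 0,
                       strict_lower = TRUE)
  totals <- Matrix::rowSums(counts)
  zero <- totals <= 0
  if (any(zero)) {
    lrx_format_error(sprintf("cell(s) with zero total count: %s",
                             paste(rownames(counts)[zero], collapse = ", ")))
  }
  x <- as.matrix(counts) * (scale_factor / totals)
  expr <- log1p(x) / log(2)
  dimnames(expr) <- dimnames(counts)
  structure(expr, scale_factor = scale_factor,
            class = c("expr_matrix", "matrix", "array"))
}

#' Select highly variable genes
#'
#' Genes ranked by variance of log expression (descending); ties broken by
#' symbol order.
#'
#' @param expr an `expr_matrix` from [normalize_log()].
#' @param n number of genes to return (default 2000).
#' @return character vector of gene symbols, length `n`.
#' @export
select_hvg <- function(expr, n = 2000L) {
  if (n > ncol(expr)) {
    lrx_config_error(sprintf("n = %d exceeds gene count %d", n, ncol(expr)))
  }
  v <- gene_var(expr)
  ord <- order(-v, colnames(expr))
  colnames(expr)[ord][seq_len(n)]
}

# column (per-gene) variance without forming a centered copy per gene
gene_var <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  (colSums(x^2) - n * mu^2) / (n - 1)
}

#' Principal-component embedding on variable genes
#'
#' Genes are centered and unit-scaled before the decomposition; zero-variance
#' genes cannot be scaled and are dropped with a warning. Components are
#' ordered by explained variance.
#'
#' @param expr an `expr_matrix`.
#' @param hvg gene symbols to use (e.g. from [select_hvg()]).
#' @param n_components number of components (<= min(cells, genes used)).
#' @return cells x n_components score matrix with attribute `sdev`.
#' @export
embed_pca <- function(expr, hvg = colnames(expr), n_components = 20L) {
  hvg <- intersect(hvg, colnames(expr))
  x <- unclass(expr)[, hvg, drop = FALSE]
  v <- gene_var(x)
  if (all(v <= 0)) lrx_config_error("all selected genes are constant")
  if (any(v <= 0)) {
    lrx_log("warn", "dropping %d constant gene(s) before PCA", sum(v <= 0))
    x <- x[, v > 0, drop = FALSE]
  }
  if (n_components > min(dim(x))) {
    lrx_config_error("n_components exceeds min(cells, genes)")
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE, rank. = n_components)
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  attr(scores, "sdev") <- pc$sdev[seq_len(n_components)]
  scores
}

#' Cluster cells by k-means on an embedding
#'
#' Deterministic plumbing for the pipeline's cluster slot; externally
#' computed labels can be supplied anywhere a clustering is accepted.
#'
#' @param embedding cells x components matrix (e.g. from [embed_pca()]).
#' @param k number of clusters.
#' @param seed integer seed for the k-means initialization.
#' @return integer cluster labels named by cell id.
#' @export
cluster_cells <- function(embedding, k, seed = 1L) {
  set.seed(seed)
  km <- stats::kmeans(embedding, centers = k, nstart = 10L, iter.max = 100L)
  stats::setNames(km$cluster, rownames(embedding))
}

#' Default marker map
#'
#' Literature marker panels used to recognize the cell types this pipeline
#' cares about: EPCAM/SOX4/MDK for tumor cells, SFTPD/AGR3/FOLR1 for
#' alveolar/epithelial cells, and CD163/LYZ, FCER1A, ELANE to split myeloid
#' cells into macrophages, Langerhans cells and granulocytes.
#'
#' @return named list of marker gene vectors.
#' @export
default_marker_map <- function() {
  list(tumor_cells = c("EPCAM", "SOX4", "MDK"),
       epithelial = c("SFTPD", "AGR3", "FOLR1"),
       macrophage = c("CD163", "LYZ"),
       langerhans = "FCER1A",
       granulocyte = "ELANE")
}

#' Read a marker map from TSV
#' @param path TSV with columns `cell_type`, `gene`.
#' @return named list of marker gene vectors.
#' @export
read_marker_map <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("cell_type", "gene") %in% names(tab))) {
    lrx_format_error("marker file must have 'cell_type' and 'gene' columns")
  }
  split(normalize_symbols(tab$gene), tab$cell_type)
}

#' Assign cell types to clusters by marker scoring
#'
#' For every cluster and cell type, the score is the mean — over that type's
#' marker genes — of the cluster-mean expression standardized per gene across
#' clusters. A cluster is labeled with the argmax type when the best score
#' reaches `min_score`, otherwise `"unassigned"`. Ties are broken by
#' type-name order with a warning. Marker genes absent from the matrix are
#' skipped with a log line; a type whose markers are all absent is skipped.
#'
#' @param expr an `expr_matrix`.
#' @param clusters cluster label per cell (named by cell id, or in matrix
#'   row order).
#' @param markers named list of marker gene vectors (see
#'   [default_marker_map()]).
#' @param min_score minimum standardized score to assign a label
#'   (default 0.5).
#' @return data.frame with columns cell, cluster, cell_type.
#' @export
annotate_clusters <- function(expr, clusters, markers = default_marker_map(),
                              min_score = 0.5) {
  cells <- rownames(expr)
  if (!is.null(names(clusters))) {
    if (!all(cells %in% names(clusters))) {
      lrx_config_error("every cell must have a cluster label")
    }
    clusters <- clusters[cells]
  } else if (length(clusters) != length(cells)) {
    lrx_config_error("every cell must have a cluster label")
  }
  cl <- as.character(clusters)
  cl_levels <- sort(unique(cl))
  # cluster-mean expression for the union of marker genes
  all_markers <- unique(normalize_symbols(unlist(markers)))
  present <- intersect(all_markers, colnames(expr))
  absent <- setdiff(all_markers, present)
  if (length(absent)) {
    lrx_log("warn", "marker gene(s) absent from matrix, skipped: %s",
            paste(absent, collapse = ", "))
  }
  cm <- t(vapply(cl_levels, function(g)
    colMeans(unclass(expr)[cl == g, present, drop = FALSE]),
    numeric(length(present))))
  if (length(present) == 1L) cm <- matrix(cm, ncol = 1L,
                                          dimnames = list(cl_levels, present))
  z <- scale(cm)                       # standardize per gene across clusters
  z[, attr(z, "scaled:scale") == 0] <- 0
  z[is.na(z)] <- 0

  types <- names(markers)
  score <- matrix(NA_real_, nrow = length(cl_levels), ncol = length(types),
                  dimnames = list(cl_levels, types))
  for (ty in types) {
    mk <- intersect(normalize_symbols(markers[[ty]]), present)
    if (!length(mk)) {
      lrx_log("warn", "all markers absent for type '%s'; type skipped", ty)
      next
    }
    score[, ty] <- rowMeans(z[, mk, drop = FALSE])
  }
  label <- vapply(seq_along(cl_levels), function(i) {
    s <- score[i, ]
    if (all(is.na(s))) return("unassigned")
    best <- max(s, na.rm = TRUE)
    if (best < min_score) return("unassigned")
    hits <- types[!is.na(s) & s == best]
    if (length(hits) > 1L) {
      lrx_log("warn", "cluster %s: score tie between %s; taking %s",
              cl_levels[i], paste(hits, collapse = ", "), sort(hits)[1L])
      hits <- sort(hits)
    }
    hits[1L]
  }, character(1))
  names(label) <- cl_levels
  data.frame(cell = cells, cluster = cl, cell_type = unname(label[cl]),
             stringsAsFactors = FALSE)
}

#' Summarize cohort composition
#'
#' Counts and percentages (one decimal) per group, e.g. cells per sample type
#' or per assigned cell type.
#'
#' @param annotation a data.frame with one row per cell.
#' @param by column to group on (default `"sample_type"`).
#' @return data.frame with columns group, count, percentage.
#' @export
summarize_composition <- function(annotation, by = "sample_type") {
  if (!nrow(annotation)) lrx_config_error("empty annotation")
  if (!by %in% names(annotation)) {
    lrx_config_error(sprintf("no column '%s' in annotation", by))
  }
  tab <- table(annotation[[by]])
  data.frame(group = names(tab), count = as.integer(tab),
             percentage = round(100 * as.integer(tab) / sum(tab), 1),
             stringsAsFactors = FALSE)
}

#' Subcluster a cell subset
#'
#' Re-runs variable-gene selection, PCA and k-means on the given cells only;
#' used to split tumor-associated macrophages into subtypes (default 4).
#'
#' @param expr an `expr_matrix`.
#' @param cells cell ids to subcluster.
#' @param k number of subclusters (default 4).
#' @param n_hvg variable genes to use (capped at the gene count).
#' @param n_components PCA components.
#' @param seed integer seed.
#' @return integer subcluster labels named by cell id.
#' @export
subcluster_cells <- function(expr, cells, k = 4L, n_hvg = 500L,
                             n_components = 10L, seed = 1L) {
  sub <- unclass(expr)[cells, , drop = FALSE]
  class(sub) <- c("expr_matrix", "matrix", "array")
  n_hvg <- min(n_hvg, ncol(sub))
  hvg <- select_hvg(sub, n_hvg)
  emb <- embed_pca(sub, hvg, n_components = min(n_components, length(cells) - 1L,
                                                n_hvg))
  cluster_cells(emb, k = k, seed = seed)
}
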