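# Gene-set scoring: module z-scores, pathway contrasts, macrophage
# polarization coordinates, permutation-null interaction scores, and
# hypergeometric over-representation.

#' Per-cell module score for a gene set
#'
#' Each set gene's log expression is z-standardized across the given cells;
#' a cell's score is the mean z over the set. Constant genes carry no signal
#' and are excluded with a warning. Scores are mean-zero over the cell
#' population by construction.
#'
#' @param expr an `expr_matrix`.
#' @param cells cell ids to score over.
#' @param gene_set gene symbols; must intersect the matrix genes.
#' @return named numeric vector of per-cell scores.
#' @export
module_score <- function(expr, cells, gene_set) {
  gene_set <- unique(normalize_symbols(gene_set))
  present <- intersect(gene_set, colnames(expr))
  if (!length(present)) lrx_config_error("gene set does not intersect matrix")
  x <- unclass(expr)[cells, present, drop = FALSE]
  v <- gene_var(x)
  if (any(v <= 0)) {
    lrx_log("warn", "excluding %d constant gene(s) from module score",
            sum(v <= 0))
    x <- x[, v > 0, drop = FALSE]
    if (!ncol(x)) lrx_config_error("all set genes constant over these cells")
  }
  z <- scale(x)
  stats::setNames(rowMeans(z), cells)
}

#' Compare pathway activity between two cell groups
#'
#' For every set in the collection, module scores are computed over the union
#' of the two groups, the difference of group means is reported with a Welch
#' t-test, and q-values come from Benjamini-Hochberg over the sets. Sets with
#' no genes in the matrix are dropped with a warning.
#'
#' @param expr an `expr_matrix`.
#' @param cells_A,cells_B disjoint cell id sets.
#' @param collection named list of gene sets (e.g. from [read_gmt()]).
#' @return data.frame: set, n_genes, delta_score (mean A minus mean B), t, p,
#'   q.
#' @export
compare_pathways <- function(expr, cells_A, cells_B, collection) {
  if (length(intersect(cells_A, cells_B))) {
    lrx_config_error("cell groups overlap")
  }
  rows <- lapply(names(collection), function(nm) {
    sc <- tryCatch(module_score(expr, c(cells_A, cells_B), collection[[nm]]),
                   lrx_config_error = function(e) NULL)
    if (is.null(sc)) {
      lrx_log("warn", "set '%s' dropped: no usable genes", nm)
      return(NULL)
    }
    a <- sc[cells_A]; b <- sc[cells_B]
    tt <- stats::t.test(a, b)          # Welch by default
    data.frame(set = nm,
               n_genes = length(intersect(normalize_symbols(collection[[nm]]),
                                          colnames(expr))),
               delta_score = mean(a) - mean(b),
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(set = character(0), n_genes = integer(0),
                      delta_score = numeric(0), t = numeric(0),
                      p = numeric(0), q = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out$q <- bh_adjust(pmax(out$p, .Machine$double.xmin))
  rownames(out) <- NULL
  out
}

#' Polarization coordinates per macrophage subtype
#'
#' Computes per-cell module scores for each axis set (M1, M2,
#' pro-inflammatory, anti-inflammatory) over all cells in the subtype map,
#' then averages within each subtype, giving one coordinate row per subtype.
#' Empty subtypes are dropped with a warning.
#'
#' @param expr an `expr_matrix`.
#' @param subtype_map named vector: cell id -> subtype label.
#' @param axes named list of gene sets; names become the coordinate columns
#'   (conventionally M1, M2, pro, anti).
#' @return data.frame with a `subtype` column plus one column per axis.
#' @export
polarization_scores <- function(expr, subtype_map,
                                axes) {
  cells <- names(subtype_map)
  if (is.null(cells)) lrx_config_error("subtype_map must be named by cell id")
  keep <- !is.na(subtype_map)
  if (any(!keep)) {
    lrx_log("warn", "dropping %d cell(s) without subtype", sum(!keep))
    subtype_map <- subtype_map[keep]; cells <- cells[keep]
  }
  subs <- sort(unique(as.character(subtype_map)))
  scores <- lapply(axes, function(set) module_score(expr, cells, set))
  out <- data.frame(subtype = subs, stringsAsFactors = FALSE)
  for (ax in names(axes)) {
    out[[ax]] <- vapply(subs, function(s)
      mean(scores[[ax]][subtype_map == s]), numeric(1))
  }
  rownames(out) <- NULL
  out
}

#' Permutation-null ligand-receptor interaction score
#'
#' The observed score is the product of the mean normalized ligand expression
#' over sender cells and the mean receptor expression over receiver cells.
#' The null permutes subtype labels over the union of participating cells
#' `n_perm` times; the p-value is the add-one estimator
#' `(1 + #\{perm >= obs\}) / (n_perm + 1)`, hence always at least
#' `1/(n_perm + 1)`.
#'
#' @param expr an `expr_matrix`.
#' @param sender_cells,receiver_cells non-empty cell id vectors for the two
#'   subtypes.
#' @param ligand,receptor gene symbols present in the matrix.
#' @param n_perm number of label permutations (default 1000).
#' @param seed integer seed; results are bit-reproducible for a fixed seed.
#' @return list: ligand, receptor, score, p, n_perm, seed.
#' @export
interaction_score <- function(expr, sender_cells, receiver_cells,
                              ligand, receptor, n_perm = 1000L, seed = 1L) {
  ligand <- normalize_symbols(ligand); receptor <- normalize_symbols(receptor)
  for (g in c(ligand, receptor)) {
    if (!g %in% colnames(expr)) {
      lrx_config_error(sprintf("gene '%s' absent from matrix", g))
    }
  }
  if (!length(sender_cells) || !length(receiver_cells)) {
    lrx_config_error("both subtypes must be non-empty")
  }
  lig <- unclass(expr)[c(sender_cells, receiver_cells), ligand]
  rec <- unclass(expr)[c(sender_cells, receiver_cells), receptor]
  ns <- length(sender_cells)
  n <- length(lig)
  obs <- mean(lig[seq_len(ns)]) * mean(rec[(ns + 1):n])
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n)
    mean(lig[idx[seq_len(ns)]]) * mean(rec[idx[(ns + 1):n]])
  }, numeric(1))
  p <- (1 + sum(perm >= obs)) / (n_perm + 1)
  list(ligand = ligand, receptor = receptor, score = obs, p = p,
       n_perm = as.integer(n_perm), seed = as.integer(seed))
}

#' Score every pair between a sender and receiver subtype
#'
#' Convenience wrapper running [interaction_score()] over the rows of a pair
#' table for one sender/receiver subtype combination.
#'
#' @param expr an `expr_matrix`.
#' @param subtype_map named vector: cell id -> subtype label.
#' @param pairs data.frame with ligand, receptor columns.
#' @param sender,receiver subtype labels.
#' @param n_perm,seed forwarded to [interaction_score()]; the seed is offset
#'   per pair so draws are independent yet reproducible.
#' @return data.frame: ligand, receptor, sender, receiver, score, p.
#' @export
interaction_table <- function(expr, subtype_map, pairs, sender, receiver,
                              n_perm = 1000L, seed = 1L) {
  s_cells <- names(subtype_map)[subtype_map == sender]
  r_cells <- names(subtype_map)[subtype_map == receiver]
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    res <- interaction_score(expr, s_cells, r_cells,
                             pairs$ligand[i], pairs$receptor[i],
                             n_perm = n_perm, seed = seed + i - 1L)
    data.frame(ligand = res$ligand, receptor = res$receptor,
               sender = sender, receiver = receiver,
               score = res$score, p = res$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Hypergeometric over-representation test
#'
#' Upper-tail probability of observing at least the realized overlap between
#' a hit list and an annotated set drawn from a finite universe.
#'
#' @param hits gene set of interest (must be contained in `universe`).
#' @param universe background gene set.
#' @param annotated genes carrying the annotation (must be contained in
#'   `universe`).
#' @return list with `overlap` and `p`.
#' @export
ora_hypergeometric <- function(hits, universe, annotated) {
  hits <- unique(normalize_symbols(hits))
  universe <- unique(normalize_symbols(universe))
  annotated <- unique(normalize_symbols(annotated))
  if (length(setdiff(hits, universe))) {
    lrx_config_error("hits must be a subset of the universe")
  }
  if (length(setdiff(annotated, universe))) {
    lrx_config_error("annotated set must be a subset of the universe")
  }
  ov <- length(intersect(hits, annotated))
  p <- stats::phyper(ov - 1, length(annotated),
                     length(universe) - length(annotated), length(hits),
                     lower.tail = FALSE)
  list(overlap = ov, p = p)
}
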