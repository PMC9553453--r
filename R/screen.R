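# The core ligand-receptor screen: concordant autocrine pairs, cross-
# population paracrine pairs, bulk Spearman filtering, network construction.

#' Screening configuration
#'
#' @param rho_min Spearman threshold; a pair passes when rho is strictly
#'   greater (default 0.3).
#' @param alpha FDR threshold carried to DE calls (default 0.05).
#' @param fc_min log2 fold-change floor carried to DE calls (default 0.25).
#' @param abs_rho compare `|rho|` rather than signed rho against `rho_min`
#'   (default FALSE: signed, the package's reading of positive coexpression).
#' @return a `screen_config` list.
#' @export
screen_config <- function(rho_min = 0.3, alpha = 0.05, fc_min = 0.25,
                          abs_rho = FALSE) {
  if (rho_min <= 0 || rho_min >= 1) {
    lrx_config_error("rho_min must lie in (0, 1)")
  }
  structure(list(rho_min = rho_min, alpha = alpha, fc_min = fc_min,
                 abs_rho = isTRUE(abs_rho)), class = "screen_config")
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Ranks use average ties; rho is the Pearson correlation of the rank
#' vectors; the p-value comes from the t approximation with n - 2 degrees of
#' freedom. A constant input has no rank ordering and raises a distinct
#' condition (`lrx_constant_error`) so callers can drop the pair.
#'
#' @param x,y equal-length finite numeric vectors, length >= 3.
#' @return list with elements `rho` and `p`.
#' @export
spearman_rho <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 3) {
    lrx_config_error("inputs must have equal length >= 3")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    lrx_config_error("inputs must be finite")
  }
  rx <- rank(x); ry <- rank(y)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sx <- sum(dx^2); sy <- sum(dy^2)
  if (sx == 0 || sy == 0) {
    lrx_error("lrx_constant_error", "constant input: Spearman rho undefined")
  }
  rho <- sum(dx * dy) / sqrt(sx * sy)
  rho <- max(-1, min(1, rho))
  if (abs(rho) == 1) {
    p <- .Machine$double.xmin
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = max(p, .Machine$double.xmin))
}

.empty_pairset <- function() {
  data.frame(ligand = character(0), receptor = character(0),
             context = character(0), direction = character(0),
             rho = numeric(0), rho_p = numeric(0),
             passed_filter = logical(0), stringsAsFactors = FALSE)
}

.pairset <- function(ligand, receptor, context, direction) {
  data.frame(ligand = ligand, receptor = receptor, context = context,
             direction = direction, rho = NA_real_, rho_p = NA_real_,
             passed_filter = FALSE, stringsAsFactors = FALSE)
}

#' Select concordant autocrine ligand-receptor pairs
#'
#' A pair enters the autocrine set when its ligand and receptor are
#' concurrently upregulated (direction `up`) or concurrently downregulated
#' (`down`) in the same differential-expression contrast. Pairs with either
#' gene absent from the DE table are skipped with a logged count.
#'
#' @param de a [de_table()] result.
#' @param pairs ligand-receptor reference (columns ligand, receptor).
#' @param context label recorded on the rows (default `"autocrine_tumor"`).
#' @return a PairSet data.frame (rho columns unset until bulk filtering).
#' @export
classify_autocrine_pairs <- function(de, pairs, context = "autocrine_tumor") {
  dl <- de$direction[match(pairs$ligand, de$gene)]
  dr <- de$direction[match(pairs$receptor, de$gene)]
  absent <- is.na(dl) | is.na(dr)
  if (any(absent)) {
    lrx_log("info", "%d pair(s) skipped: gene not in DE table", sum(absent))
  }
  keep <- !absent & ((dl == "up" & dr == "up") | (dl == "down" & dr == "down"))
  if (!any(keep)) return(.empty_pairset())
  .pairset(pairs$ligand[keep], pairs$receptor[keep], context,
           ifelse(dl[keep] == "up", "up", "down"))
}

#' Select paracrine ligand-receptor pairs across two populations
#'
#' A pair enters the paracrine set when the ligand is upregulated in the
#' sender population's contrast and the receptor is upregulated in the
#' receiver population's contrast (the screen uses upregulated genes only).
#'
#' @param de_sender DE table for the sender population (ligand side).
#' @param de_receiver DE table for the receiver population (receptor side).
#' @param pairs ligand-receptor reference table.
#' @param context label, e.g. `"paracrine_mac_to_tumor"` (macrophage DE for
#'   ligands, tumor DE for receptors) or `"paracrine_tumor_to_mac"`.
#' @return a PairSet data.frame, all rows direction `up`.
#' @export
classify_paracrine_pairs <- function(de_sender, de_receiver, pairs,
                                     context = "paracrine_mac_to_tumor") {
  dl <- de_sender$direction[match(pairs$ligand, de_sender$gene)]
  dr <- de_receiver$direction[match(pairs$receptor, de_receiver$gene)]
  absent <- is.na(dl) | is.na(dr)
  if (any(absent)) {
    lrx_log("info", "%d pair(s) skipped: gene not in DE table", sum(absent))
  }
  keep <- !absent & dl == "up" & dr == "up"
  if (!any(keep)) return(.empty_pairset())
  .pairset(pairs$ligand[keep], pairs$receptor[keep], context, "up")
}

#' Filter a pair set by bulk coexpression
#'
#' For each pair, the Spearman correlation of ligand and receptor expression
#' across all bulk samples is computed; a pair passes when rho is strictly
#' greater than `rho_min` (signed by default, `|rho|` with `abs_rho`). Pairs
#' with a gene missing from the bulk matrix, or with constant expression,
#' keep a missing rho and fail the filter, with a logged count.
#'
#' @param pairs a PairSet from the classify step.
#' @param bulk a [bulk_cohort()].
#' @param cfg a [screen_config()].
#' @return the PairSet with rho, rho_p and passed_filter filled in.
#' @export
filter_pairs_by_bulk <- function(pairs, bulk, cfg = screen_config()) {
  if (!nrow(pairs)) return(pairs)
  n_missing <- 0L; n_constant <- 0L
  for (i in seq_len(nrow(pairs))) {
    l <- pairs$ligand[i]; r <- pairs$receptor[i]
    if (!(l %in% colnames(bulk)) || !(r %in% colnames(bulk))) {
      n_missing <- n_missing + 1L
      next
    }
    res <- tryCatch(spearman_rho(bulk[, l], bulk[, r]),
                    lrx_constant_error = function(e) NULL)
    if (is.null(res)) {
      n_constant <- n_constant + 1L
      next
    }
    pairs$rho[i] <- res$rho
    pairs$rho_p[i] <- res$p
    crit <- if (cfg$abs_rho) abs(res$rho) else res$rho
    pairs$passed_filter[i] <- crit > cfg$rho_min
  }
  if (n_missing) lrx_log("info", "%d pair(s) missing from bulk matrix",
                         n_missing)
  if (n_constant) lrx_log("warn", "%d pair(s) dropped: constant bulk profile",
                          n_constant)
  pairs
}

#' Build the crosstalk network from passed pairs
#'
#' Collapses the passed pairs to a simple graph with one node per gene (role
#' `both` when a gene acts as ligand in one pair and receptor in another) and
#' edge weight equal to the bulk Spearman rho. Hub genes are the `top_k`
#' nodes by degree, ties broken by summed incident edge weight then symbol
#' order.
#'
#' @param pairs a filtered PairSet; only rows with `passed_filter` are used.
#' @param top_k number of hub genes to report (default 10).
#' @return list with data.frames `nodes` (gene, role, degree), `edges`
#'   (ligand, receptor, weight, direction, context) and `hubs` (gene,
#'   degree).
#' @export
build_network <- function(pairs, top_k = 10L) {
  passed <- pairs[pairs$passed_filter %in% TRUE, , drop = FALSE]
  passed <- passed[!duplicated(passed[, c("ligand", "receptor")]), ,
                   drop = FALSE]
  if (!nrow(passed)) {
    return(list(nodes = data.frame(gene = character(0), role = character(0),
                                   degree = integer(0),
                                   stringsAsFactors = FALSE),
                edges = data.frame(ligand = character(0),
                                   receptor = character(0),
                                   weight = numeric(0),
                                   direction = character(0),
                                   context = character(0),
                                   stringsAsFactors = FALSE),
                hubs = data.frame(gene = character(0), degree = integer(0),
                                  stringsAsFactors = FALSE)))
  }
  genes <- sort(unique(c(passed$ligand, passed$receptor)))
  role <- vapply(genes, function(g) {
    is_l <- g %in% passed$ligand; is_r <- g %in% passed$receptor
    if (is_l && is_r) "both" else if (is_l) "ligand" else "receptor"
  }, character(1))
  degree <- vapply(genes, function(g)
    sum(passed$ligand == g) + sum(passed$receptor == g), integer(1))
  wsum <- vapply(genes, function(g)
    sum(passed$rho[passed$ligand == g | passed$receptor == g]), numeric(1))
  nodes <- data.frame(gene = genes, role = unname(role),
                      degree = unname(degree), stringsAsFactors = FALSE)
  edges <- data.frame(ligand = passed$ligand, receptor = passed$receptor,
                      weight = passed$rho, direction = passed$direction,
                      context = passed$context, stringsAsFactors = FALSE)
  ord <- order(-degree, -wsum, genes)
  hubs <- data.frame(gene = genes[ord], degree = unname(degree[ord]),
                     stringsAsFactors = FALSE)
  hubs <- utils::head(hubs, top_k)
  rownames(hubs) <- NULL
  list(nodes = nodes, edges = edges, hubs = hubs)
}

#' Export a crosstalk network
#'
#' Writes the edge list as TSV and, optionally, a minimal GraphML file for
#' network viewers.
#'
#' @param network result of [build_network()].
#' @param edge_path TSV output path.
#' @param graphml_path optional GraphML output path.
#' @return `edge_path`, invisibly.
#' @export
export_network <- function(network, edge_path, graphml_path = NULL) {
  utils::write.table(network$edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(graphml_path)) {
    nodes <- network$nodes; edges <- network$edges
    esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x))
    con <- file(graphml_path, "w")
    on.exit(close(con))
    writeLines(c(
      '<?xml version="1.0" encoding="UTF-8"?>',
      '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
      '<key id="role" for="node" attr.name="role" attr.type="string"/>',
      '<key id="weight" for="edge" attr.name="weight" attr.type="double"/>',
      '<graph edgedefault="directed">'), con)
    for (i in seq_len(nrow(nodes))) {
      writeLines(sprintf('<node id="%s"><data key="role">%s</data></node>',
                         esc(nodes$gene[i]), nodes$role[i]), con)
    }
    for (i in seq_len(nrow(edges))) {
      writeLines(sprintf(
        '<edge source="%s" target="%s"><data key="weight">%g</data></edge>',
        esc(edges$ligand[i]), esc(edges$receptor[i]), edges$weight[i]), con)
    }
    writeLines(c("</graph>", "</graphml>"), con)
  }
  invisible(edge_path)
}
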