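# Shared fixture builders. Everything is generated in code; no stored data.

# tiny dense count matrix with given values (cells x genes)
tiny_counts <- function(values, cells = sprintf("c%d", seq_len(nrow(values))),
                        genes = sprintf("G%d", seq_len(ncol(values)))) {
  count_matrix(values, cell_ids = cells, gene_symbols = genes)
}

# expression matrix straight from numeric values (already on the log2 scale),
# bypassing normalization — for unit tests that need exact entries
raw_expr <- function(values, cells = sprintf("c%d", seq_len(nrow(values))),
                     genes = sprintf("G%d", seq_len(ncol(values)))) {
  m <- as.matrix(values)
  dimnames(m) <- list(cells, toupper(genes))
  structure(m, scale_factor = 1e4,
            class = c("expr_matrix", "matrix", "array"))
}

# small two-population cohort for DE / scoring tests
small_sim <- function(seed = 1L, n_cells = 120L, n_genes = 300L,
                      n_up = 5L, n_dn = 3L, de_fc = 4) {
  sim_config(
    seed = seed, n_genes = n_genes,
    populations = data.frame(
      name = c("tumor_cells", "epithelial"),
      n_cells = n_cells, sample_type = c("tumor", "normal"),
      stringsAsFactors = FALSE),
    n_marker_genes_per_type = 5L, marker_fc = 4,
    n_de_lr_pairs_up = n_up, n_de_lr_pairs_down = n_dn, de_fc = de_fc,
    n_bulk_samples = 120L, n_prognostic_genes = 4L)
}

cells_of <- function(ann, pop) ann$cell[ann$population == pop]

# bare pair set rows (classification output shape) for filter/network tests
.pairset_for_test <- function(ligand, receptor, context = "autocrine_tumor",
                              direction = "up") {
  n <- length(ligand)
  data.frame(ligand = ligand, receptor = receptor,
             context = rep_len(context, n),
             direction = rep_len(direction, n),
             rho = rep(NA_real_, n), rho_p = rep(NA_real_, n),
             passed_filter = rep(FALSE, n), stringsAsFactors = FALSE)
}

# hand-built DE table rows for screen-logic tests
mk_de <- function(genes, directions) {
  n <- length(genes)
  data.frame(gene = genes, log2fc = ifelse(directions == "up", 1,
                                           ifelse(directions == "down", -1, 0)),
             stat = rep(10, n), df = rep(2L, n), p = rep(0.001, n),
             q = rep(0.001, n), pct_A = rep(0.5, n), pct_B = rep(0.5, n),
             direction = directions, stringsAsFactors = FALSE)
}
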