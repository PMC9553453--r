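#' Construct and validate a cells-by-genes count matrix
#'
#' The pipeline's raw-count container: a dense or sparse non-negative integer
#' matrix with unique cell barcodes as rownames and unique upper-cased gene
#' symbols as colnames.
#'
#' @param values cells x genes matrix (base or `Matrix` sparse) of counts.
#' @param cell_ids character vector of unique cell identifiers.
#' @param gene_symbols character vector of gene symbols; upper-cased and
#'   required to be unique after normalization.
#' @return a `count_matrix` object (the matrix with validated dimnames).
#' @export
count_matrix <- function(values, cell_ids = rownames(values),
                         gene_symbols = colnames(values)) {
  if (is.null(cell_ids) || is.null(gene_symbols)) {
    lrx_format_error("count matrix needs cell ids and gene symbols")
  }
  cell_ids <- as.character(cell_ids)
  gene_symbols <- normalize_symbols(gene_symbols)
  if (length(cell_ids) != nrow(values)) {
    lrx_format_error(sprintf(
      "cell id list has %d entries but matrix has %d rows",
      length(cell_ids), nrow(values)))
  }
  if (length(gene_symbols) != ncol(values)) {
    lrx_format_error(sprintf(
      "gene symbol list has %d entries but matrix has %d columns",
      length(gene_symbols), ncol(values)))
  }
  if (anyDuplicated(cell_ids)) {
    lrx_format_error(sprintf("duplicate cell id: %s",
                             cell_ids[duplicated(cell_ids)][1L]))
  }
  if (anyDuplicated(gene_symbols)) {
    lrx_format_error(sprintf("duplicate gene symbol: %s",
                             gene_symbols[duplicated(gene_symbols)][1L]))
  }
  if (any(!nzchar(gene_symbols))) lrx_format_error("empty gene symbol")
  # stored dense: desk-scale cohorts only, and S3 semantics stay simple
  vals <- as.matrix(values)
  nz <- as.numeric(vals)
  if (length(nz) && min(nz) < 0) lrx_format_error("negative count entries found")
  if (any(nz %% 1 != 0)) lrx_format_error("non-integer count entries found")
  storage.mode(vals) <- "integer"
  rownames(vals) <- cell_ids
  colnames(vals) <- gene_symbols
  structure(vals, class = c("count_matrix", "matrix", "array"))
}

#' Read a count matrix from a 10x-style MTX triplet or dense TSV
#'
#' A directory is expected to hold `matrix.mtx` (genes x cells, MatrixMarket
#' coordinate format), `barcodes.tsv` and `features.tsv`; the matrix is
#' transposed to cells x genes in memory. A file path is read as a dense TSV
#' with gene symbols in the first column and one column per cell.
#'
#' @param path directory (MTX triplet) or TSV file.
#' @return a validated [count_matrix()].
#' @export
read_counts <- function(path) {
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    bc <- file.path(path, "barcodes.tsv")
    ft <- file.path(path, "features.tsv")
    for (f in c(mtx, bc, ft)) {
      if (!file.exists(f)) lrx_format_error(sprintf("missing file: %s", f))
    }
    m <- Matrix::readMM(mtx)              # genes x cells on disk
    barcodes <- readLines(bc)
    features <- utils::read.delim(ft, header = FALSE,
                                  stringsAsFactors = FALSE)[[1L]]
    if (length(barcodes) != ncol(m)) {
      lrx_format_error(sprintf(
        "barcodes file has %d entries for a %d-column matrix",
        length(barcodes), ncol(m)))
    }
    if (length(features) != nrow(m)) {
      lrx_format_error(sprintf(
        "features file has %d entries for a %d-row matrix",
        length(features), nrow(m)))
    }
    count_matrix(as.matrix(Matrix::t(m)),
                 cell_ids = barcodes, gene_symbols = features)
  } else if (file.exists(path)) {
    tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                             stringsAsFactors = FALSE)
    genes <- tab[[1L]]
    vals <- as.matrix(tab[, -1L, drop = FALSE])
    if (!is.numeric(vals)) lrx_format_error("non-numeric entries in count TSV")
    count_matrix(t(vals), cell_ids = colnames(vals), gene_symbols = genes)
  } else {
    lrx_format_error(sprintf("no such file or directory: %s", path))
  }
}

#' Write a count matrix as a 10x-style MTX triplet
#'
#' @param counts a [count_matrix()].
#' @param dir output directory (created if absent); writes `matrix.mtx`
#'   (genes x cells), `barcodes.tsv`, `features.tsv`.
#' @return `dir`, invisibly.
#' @export
write_counts <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(Matrix::t(Matrix::Matrix(unclass(counts), sparse = TRUE)),
                   "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "barcodes.tsv"))
  writeLines(colnames(counts), file.path(dir, "features.tsv"))
  invisible(dir)
}

#' Read a ligand-receptor pair reference table
#'
#' Expects a TSV with named columns `ligand` and `receptor` (FANTOM5-style
#' two-column catalogue). Symbols are upper-cased and trimmed; duplicate rows
#' are collapsed and self-pairs dropped, each with a logged count.
#'
#' @param path TSV file path.
#' @return data.frame with unique (ligand, receptor) rows, ligand != receptor.
#' @export
read_lr_pairs <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("ligand", "receptor") %in% names(tab))) {
    lrx_format_error("ligand-receptor table must have 'ligand' and 'receptor' columns")
  }
  lr_pair_table(tab$ligand, tab$receptor)
}

#' Construct a validated ligand-receptor pair table
#'
#' @param ligand,receptor character vectors of gene symbols.
#' @return data.frame with columns ligand, receptor.
#' @export
lr_pair_table <- function(ligand, receptor) {
  df <- data.frame(ligand = normalize_symbols(ligand),
                   receptor = normalize_symbols(receptor),
                   stringsAsFactors = FALSE)
  self <- df$ligand == df$receptor
  if (any(self)) {
    lrx_log("info", "dropped %d self-pair(s)", sum(self))
    df <- df[!self, , drop = FALSE]
  }
  dup <- duplicated(df)
  if (any(dup)) {
    lrx_log("info", "collapsed %d duplicate pair row(s)", sum(dup))
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Read a bulk expression matrix (samples x genes, log2 scale)
#'
#' TSV with sample ids in the first column and one named column per gene.
#'
#' @param path TSV file path.
#' @return a `bulk_cohort`: numeric matrix, samples x genes, with unique ids.
#' @export
read_bulk <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  ids <- as.character(tab[[1L]])
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  bulk_cohort(vals, sample_ids = ids, gene_symbols = colnames(vals))
}

#' Construct and validate a bulk cohort matrix
#'
#' @param values samples x genes numeric matrix on the log2 scale.
#' @param sample_ids,gene_symbols unique identifiers.
#' @return a `bulk_cohort` matrix.
#' @export
bulk_cohort <- function(values, sample_ids = rownames(values),
                        gene_symbols = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values) || any(!is.finite(values))) {
    lrx_format_error("bulk matrix must be finite numeric")
  }
  sample_ids <- as.character(sample_ids)
  gene_symbols <- normalize_symbols(gene_symbols)
  if (length(sample_ids) != nrow(values) ||
      length(gene_symbols) != ncol(values)) {
    lrx_format_error("bulk matrix dimensions do not match id lists")
  }
  if (anyDuplicated(sample_ids)) lrx_format_error("duplicate sample ids in bulk")
  if (anyDuplicated(gene_symbols)) {
    lrx_format_error(sprintf("duplicate gene symbol in bulk: %s",
                             gene_symbols[duplicated(gene_symbols)][1L]))
  }
  dimnames(values) <- list(sample_ids, gene_symbols)
  structure(values, class = c("bulk_cohort", "matrix", "array"))
}

#' Write a bulk cohort to TSV
#' @param bulk a `bulk_cohort`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_bulk <- function(bulk, path) {
  df <- data.frame(sample = rownames(bulk), unclass(bulk),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Roman stage labels: sub-stages (IA, IIIB, ...) map to their major stage.
.stage_major <- function(stage) {
  s <- toupper(trimws(as.character(stage)))
  s[s %in% c("", "NA", "UNKNOWN")] <- NA_character_
  out <- rep(NA_character_, length(s))
  for (major in c("IV", "III", "II", "I")) {   # longest prefix first
    hit <- !is.na(s) & is.na(out) & startsWith(s, major)
    out[hit] <- major
  }
  bad <- !is.na(s) & is.na(out)
  if (any(bad)) {
    lrx_format_error(sprintf("unrecognized stage label(s): %s",
                             paste(unique(s[bad]), collapse = ", ")))
  }
  out
}

#' Construct and validate a survival table
#'
#' @param sample sample identifiers.
#' @param time positive follow-up times (months).
#' @param event event indicator, 0 (censored) or 1 (event).
#' @param stage optional stage labels; sub-stages such as "IIIA" are mapped to
#'   their major stage ("III").
#' @return data.frame with columns sample, time, event, stage.
#' @export
survival_table <- function(sample, time, event, stage = NULL) {
  sample <- as.character(sample)
  time <- as.numeric(time)
  event <- as.numeric(event)
  bad_t <- !is.finite(time) | time <= 0
  if (any(bad_t)) {
    lrx_format_error(sprintf("non-positive survival time for sample(s): %s",
                             paste(sample[bad_t], collapse = ", ")))
  }
  if (!all(event %in% c(0, 1))) {
    lrx_format_error("event indicator must be 0 or 1")
  }
  stage <- if (is.null(stage)) rep(NA_character_, length(sample))
           else .stage_major(stage)
  data.frame(sample = sample, time = time, event = as.integer(event),
             stage = stage, stringsAsFactors = FALSE)
}

#' Read a survival table from TSV
#'
#' Requires columns `sample`, `time`, `event`; `stage` optional.
#'
#' @param path TSV file path.
#' @return validated [survival_table()] data.frame.
#' @export
read_survival <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("sample", "time", "event")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    lrx_format_error(sprintf("survival table missing column(s): %s",
                             paste(miss, collapse = ", ")))
  }
  survival_table(tab$sample, tab$time, tab$event,
                 stage = if ("stage" %in% names(tab)) tab$stage else NULL)
}

#' Write a survival table to TSV
#' @param surv a [survival_table()] data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_survival <- function(surv, path) {
  utils::write.table(surv, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cell annotation table from TSV
#'
#' Requires columns `cell`, `sample_id`, `sample_type`; `cluster` and
#' `cell_type` optional.
#'
#' @param path TSV file path.
#' @return validated [cell_annotation()] data.frame.
#' @export
read_annotation <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("cell", "sample_id", "sample_type")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    lrx_format_error(sprintf("annotation missing column(s): %s",
                             paste(miss, collapse = ", ")))
  }
  cell_annotation(tab$cell, tab$sample_id, tab$sample_type,
                  cluster = tab$cluster %||% NA,
                  cell_type = tab$cell_type %||% "unassigned")
}

#' Construct and validate a per-cell annotation table
#'
#' @param cell cell barcodes (unique).
#' @param sample_id originating sample identifier.
#' @param sample_type `"tumor"` or `"normal"` per cell.
#' @param cluster cluster label (integer or string), optional.
#' @param cell_type assigned type label, `"unassigned"` by default.
#' @return data.frame with one row per cell.
#' @export
cell_annotation <- function(cell, sample_id, sample_type,
                            cluster = NA, cell_type = "unassigned") {
  cell <- as.character(cell)
  if (anyDuplicated(cell)) lrx_format_error("duplicate cell ids in annotation")
  sample_type <- as.character(sample_type)
  if (!all(sample_type %in% c("tumor", "normal"))) {
    lrx_format_error("sample_type must be 'tumor' or 'normal'")
  }
  data.frame(cell = cell, sample_id = as.character(sample_id),
             sample_type = sample_type,
             cluster = rep_len(cluster, length(cell)),
             cell_type = rep_len(as.character(cell_type), length(cell)),
             stringsAsFactors = FALSE)
}

#' Write a cell annotation table to TSV
#' @param annotation a [cell_annotation()] data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One tab-separated line per set: name, description, then member symbols.
#'
#' @param path GMT file path.
#' @return named list of upper-cased gene symbol vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L) {
      lrx_format_error("GMT line needs name, description and >= 1 gene")
    }
    unique(normalize_symbols(parts[-(1:2)]))
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1))
  sets
}
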