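# Two-part hurdle differential expression: a binomial likelihood-ratio test
# on detection rates plus a Gaussian likelihood-ratio test on detected
# values, summed as a chi-square statistic with additive degrees of freedom.

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return adjusted values in the input order.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    lrx_config_error("p-values must lie in (0, 1]")
  }
  m <- length(p)
  ord <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(m / (m:1) * p[ord]))
  q[order(ord)]
}

# 0*log(0) = 0 convention for likelihood terms
.xlogy <- function(x, y) ifelse(x == 0, 0, x * log(y))

# Vectorized two-part components for one contrast over many genes.
# kA/kB: detected counts; nA/nB: group sizes; sA1/sA2, sB1/sB2: sums and
# sums of squares of the detected (nonzero) values.
.hurdle_stats <- function(kA, nA, kB, nB, sA1, sA2, sB1, sB2) {
  # discrete part: pooled vs per-group binomial detection
  k <- kA + kB; n <- nA + nB
  p0 <- k / n
  ll0 <- .xlogy(k, p0) + .xlogy(n - k, 1 - p0)
  pA <- kA / nA; pB <- kB / nB
  ll1 <- .xlogy(kA, pA) + .xlogy(nA - kA, 1 - pA) +
         .xlogy(kB, pB) + .xlogy(nB - kB, 1 - pB)
  g_disc <- pmax(0, 2 * (ll1 - ll0))
  df_disc <- as.integer(p0 > 0 & p0 < 1)
  g_disc[df_disc == 0L] <- 0

  # continuous part: equal vs per-group Gaussian means, shared variance,
  # detected cells only; needs >= 2 detected cells in each group
  ok <- kA >= 2 & kB >= 2
  mA <- ifelse(kA > 0, sA1 / kA, 0)
  mB <- ifelse(kB > 0, sB1 / kB, 0)
  rss1 <- pmax(0, (sA2 - kA * mA^2) + (sB2 - kB * mB^2))
  nn <- kA + kB
  m0 <- ifelse(nn > 0, (sA1 + sB1) / nn, 0)
  rss0 <- pmax(0, (sA2 + sB2) - nn * m0^2)
  g_cont <- rep(0, length(kA))
  tiny <- .Machine$double.xmin
  g_cont[ok] <- nn[ok] * log(pmax(rss0[ok], tiny) / pmax(rss1[ok], tiny))
  g_cont <- pmax(0, g_cont)
  df_cont <- as.integer(ok)
  g_cont[!ok] <- 0

  stat <- g_disc + g_cont
  df <- df_disc + df_cont
  p <- ifelse(df == 0L, 1, stats::pchisq(stat, df, lower.tail = FALSE))
  p <- pmax(p, .Machine$double.xmin)
  list(stat = stat, df = df, p = p,
       stat_disc = g_disc, df_disc = df_disc,
       stat_cont = g_cont, df_cont = df_cont)
}

#' Hurdle test for one gene between two cell groups
#'
#' Discrete component: likelihood-ratio G-statistic for equal vs per-group
#' binomial detection rates (df 1; df 0 when detection is 0% or 100% in the
#' pooled groups). Continuous component: on detected cells only, the
#' equal-variance Gaussian likelihood-ratio statistic `N * ln(RSS0/RSS1)` for
#' equal vs per-group means (df 1; df 0 with fewer than 2 detected cells in
#' either group). The reported statistic and degrees of freedom are the sums;
#' `p` is the upper-tail chi-square probability, with `p = 1` at df 0.
#'
#' @param expr an `expr_matrix`.
#' @param cells_A,cells_B disjoint cell id sets, each of size >= 2.
#' @param gene gene symbol.
#' @return one-row data.frame: gene, log2fc (mean log2 expression in A minus
#'   B over all cells), stat, df, p, pct_A, pct_B.
#' @export
hurdle_test <- function(expr, cells_A, cells_B, gene) {
  gene <- normalize_symbols(gene)
  if (!gene %in% colnames(expr)) {
    lrx_config_error(sprintf("gene '%s' absent from matrix", gene))
  }
  .check_groups(expr, cells_A, cells_B)
  xA <- unclass(expr)[cells_A, gene]
  xB <- unclass(expr)[cells_B, gene]
  dA <- xA[xA > 0]; dB <- xB[xB > 0]
  st <- .hurdle_stats(length(dA), length(xA), length(dB), length(xB),
                      sum(dA), sum(dA^2), sum(dB), sum(dB^2))
  data.frame(gene = gene, log2fc = mean(xA) - mean(xB),
             stat = st$stat, df = st$df, p = st$p,
             pct_A = length(dA) / length(xA),
             pct_B = length(dB) / length(xB),
             stringsAsFactors = FALSE)
}

.check_groups <- function(expr, cells_A, cells_B) {
  if (length(cells_A) < 2 || length(cells_B) < 2) {
    lrx_config_error("each group needs at least 2 cells")
  }
  if (length(intersect(cells_A, cells_B))) {
    lrx_config_error("cell groups overlap")
  }
  missing <- setdiff(c(cells_A, cells_B), rownames(expr))
  if (length(missing)) {
    lrx_config_error(sprintf("cell(s) absent from matrix: %s",
                             paste(utils::head(missing, 3), collapse = ", ")))
  }
}

#' Hurdle differential expression over a gene panel
#'
#' Runs [hurdle_test()] for every gene (vectorized), adjusts p-values by
#' Benjamini-Hochberg over the tested panel, and calls a direction: `up` when
#' `q < alpha` and `log2fc > fc_min`, `down` symmetrically, else `ns`.
#'
#' @param expr an `expr_matrix`.
#' @param cells_A,cells_B disjoint cell id sets.
#' @param alpha FDR threshold (default 0.05).
#' @param fc_min minimum |log2 fold change| (default 0.25).
#' @param genes gene panel (default: all genes in the matrix).
#' @return data.frame with one row per gene: gene, log2fc, stat, df, p, q,
#'   pct_A, pct_B, direction.
#' @export
de_table <- function(expr, cells_A, cells_B, alpha = 0.05, fc_min = 0.25,
                     genes = colnames(expr)) {
  genes <- normalize_symbols(genes)
  if (!length(genes)) {
    return(data.frame(gene = character(0), log2fc = numeric(0),
                      stat = numeric(0), df = integer(0), p = numeric(0),
                      q = numeric(0), pct_A = numeric(0), pct_B = numeric(0),
                      direction = character(0), stringsAsFactors = FALSE))
  }
  missing <- setdiff(genes, colnames(expr))
  if (length(missing)) {
    lrx_config_error(sprintf("gene(s) absent from matrix: %s",
                             paste(utils::head(missing, 3), collapse = ", ")))
  }
  .check_groups(expr, cells_A, cells_B)
  xA <- unclass(expr)[cells_A, genes, drop = FALSE]
  xB <- unclass(expr)[cells_B, genes, drop = FALSE]
  kA <- colSums(xA > 0); kB <- colSums(xB > 0)
  st <- .hurdle_stats(kA, nrow(xA), kB, nrow(xB),
                      colSums(xA), colSums(xA^2), colSums(xB), colSums(xB^2))
  log2fc <- colMeans(xA) - colMeans(xB)
  q <- bh_adjust(st$p)
  direction <- rep("ns", length(genes))
  direction[q < alpha & log2fc > fc_min] <- "up"
  direction[q < alpha & log2fc < -fc_min] <- "down"
  data.frame(gene = genes, log2fc = unname(log2fc), stat = unname(st$stat),
             df = unname(st$df), p = unname(st$p), q = unname(q),
             pct_A = unname(kA / nrow(xA)), pct_B = unname(kB / nrow(xB)),
             direction = direction, stringsAsFactors = FALSE)
}
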