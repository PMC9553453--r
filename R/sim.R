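# Synthetic coupled single-cell / bulk / survival cohorts with a ground-truth
# manifest, so every downstream stage is testable by parameter recovery.

#' Simulation configuration
#'
#' Describes a coupled synthetic study: a multi-population single-cell cohort
#' with marker genes and planted differentially expressed ligand-receptor
#' pairs, a bulk cohort with rank-correlated planted pairs, and survival/stage
#' labels driven by planted prognostic genes.
#'
#' Defaults encode the desk-scale world used throughout the test suite:
#' four populations of 200 cells (tumor cells, normal epithelium, tumor- and
#' normal-origin macrophages), marker and DE fold changes of 4, a planted bulk
#' Spearman correlation of 0.5 over 500 samples, and 20 prognostic genes at a
#' log-hazard of 1 per standardized unit.
#'
#' @param n_genes number of genes simulated.
#' @param populations data.frame with columns `name`, `n_cells`,
#'   `sample_type` (`"tumor"` or `"normal"`).
#' @param nb_mean_log_mu,nb_mean_log_sigma log-normal parameters (natural-log
#'   scale) for baseline per-gene negative-binomial means.
#' @param nb_dispersion negative-binomial size (shape) parameter theta;
#'   variance is `mu + mu^2/theta`.
#' @param n_marker_genes_per_type marker genes planted per population.
#' @param marker_fc fold change (> 1) of a marker in its own population.
#' @param n_de_lr_pairs_up,n_de_lr_pairs_down planted concordant
#'   ligand-receptor pairs, up- and downregulated in `de_population`.
#' @param de_fc fold change (> 1) applied to planted DE genes.
#' @param de_population population carrying the planted DE signal; defaults
#'   to the first tumor population.
#' @param n_bulk_samples bulk cohort size.
#' @param planted_rho Spearman correlation planted for each DE pair in bulk,
#'   in (0, 1).
#' @param n_prognostic_genes genes given a survival effect (drawn from the
#'   planted DE ligand/receptor genes first).
#' @param prognostic_beta log-hazard per standardized log-expression unit.
#' @param baseline_hazard exponential baseline hazard per month.
#' @param censor_rate target fraction censored, in [0, 1).
#' @param stage_scale slope of the logistic map from the survival linear
#'   predictor to the probability of stage III-IV.
#' @param seed integer seed; identical configs give identical cohorts.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 1200,
                       populations = data.frame(
                         name = c("tumor_cells", "epithelial",
                                  "macrophage_tumor", "macrophage_normal"),
                         n_cells = 200L,
                         sample_type = c("tumor", "normal", "tumor", "normal"),
                         stringsAsFactors = FALSE),
                       nb_mean_log_mu = -1,
                       nb_mean_log_sigma = 1,
                       nb_dispersion = 2,
                       n_marker_genes_per_type = 25L,
                       marker_fc = 4,
                       n_de_lr_pairs_up = 15L,
                       n_de_lr_pairs_down = 10L,
                       de_fc = 4,
                       de_population = NULL,
                       n_bulk_samples = 500L,
                       planted_rho = 0.5,
                       n_prognostic_genes = 20L,
                       prognostic_beta = 1,
                       baseline_hazard = 0.02,
                       censor_rate = 0.3,
                       stage_scale = 2,
                       seed = 1L) {
  if (!is.data.frame(populations) ||
      !all(c("name", "n_cells", "sample_type") %in% names(populations))) {
    lrx_config_error("populations must have columns name, n_cells, sample_type")
  }
  if (any(populations$n_cells < 1)) {
    lrx_config_error("population cell counts must be strictly positive")
  }
  if (!all(populations$sample_type %in% c("tumor", "normal"))) {
    lrx_config_error("population sample_type must be tumor or normal")
  }
  assert_scalar_number(n_genes, "n_genes", lower = 1)
  assert_scalar_number(nb_dispersion, "nb_dispersion", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(marker_fc, "marker_fc", lower = 1, strict_lower = TRUE)
  assert_scalar_number(de_fc, "de_fc", lower = 1, strict_lower = TRUE)
  assert_scalar_number(planted_rho, "planted_rho", lower = 0, upper = 1,
                       strict_lower = TRUE)
  if (planted_rho >= 1) lrx_config_error("planted_rho must be in (0, 1)")
  assert_scalar_number(censor_rate, "censor_rate", lower = 0, upper = 1 - 1e-9)
  assert_scalar_number(baseline_hazard, "baseline_hazard", lower = 0,
                       strict_lower = TRUE)
  if (is.null(de_population)) {
    tum <- populations$name[populations$sample_type == "tumor"]
    de_population <- if (length(tum)) tum[1L] else populations$name[1L]
  }
  if (!de_population %in% populations$name) {
    lrx_config_error(sprintf("de_population '%s' not among populations",
                             de_population))
  }
  n_planted <- 2L * (n_de_lr_pairs_up + n_de_lr_pairs_down)
  n_markers <- n_marker_genes_per_type * nrow(populations)
  if (n_planted + n_markers > n_genes) {
    lrx_config_error("n_genes too small for the requested marker and DE gene sets")
  }
  structure(list(
    n_genes = as.integer(n_genes), populations = populations,
    nb_mean_log_mu = nb_mean_log_mu, nb_mean_log_sigma = nb_mean_log_sigma,
    nb_dispersion = nb_dispersion,
    n_marker_genes_per_type = as.integer(n_marker_genes_per_type),
    marker_fc = marker_fc,
    n_de_lr_pairs_up = as.integer(n_de_lr_pairs_up),
    n_de_lr_pairs_down = as.integer(n_de_lr_pairs_down),
    de_fc = de_fc, de_population = de_population,
    n_bulk_samples = as.integer(n_bulk_samples), planted_rho = planted_rho,
    n_prognostic_genes = as.integer(n_prognostic_genes),
    prognostic_beta = prognostic_beta, baseline_hazard = baseline_hazard,
    censor_rate = censor_rate, stage_scale = stage_scale,
    seed = as.integer(seed)), class = "sim_config")
}

#' Generate a random ligand-receptor reference table
#'
#' Draws `n_pairs` unique directed (ligand, receptor) rows from a gene pool;
#' a gene may recur across rows and may act as ligand in one pair and
#' receptor in another, but no row repeats and no row is a self-pair.
#'
#' @param n_pairs number of pairs (>= 1).
#' @param gene_pool character vector of candidate gene symbols (>= 2).
#' @param seed integer seed.
#' @return data.frame with columns ligand, receptor.
#' @export
generate_lr_reference <- function(n_pairs, gene_pool, seed = 1L) {
  gene_pool <- unique(normalize_symbols(gene_pool))
  n <- length(gene_pool)
  if (n_pairs < 1) lrx_config_error("n_pairs must be >= 1")
  if (n < 2 || n_pairs > n * (n - 1)) {
    lrx_config_error("gene pool too small for the requested number of pairs")
  }
  set.seed(seed)
  seen <- character(0)
  lig <- rec <- character(0)
  while (length(lig) < n_pairs) {
    k <- n_pairs - length(lig)
    l <- sample(gene_pool, k, replace = TRUE)
    r <- sample(gene_pool, k, replace = TRUE)
    key <- paste(l, r, sep = "\r")
    keep <- l != r & !duplicated(key) & !(key %in% seen)
    lig <- c(lig, l[keep]); rec <- c(rec, r[keep])
    seen <- c(seen, key[keep])
  }
  data.frame(ligand = lig, receptor = rec, stringsAsFactors = FALSE)
}

#' Generate a synthetic single-cell cohort
#'
#' Counts are negative binomial with log-normal gene means. Marker genes are
#' multiplied by `marker_fc` in their own population only. Planted
#' ligand-receptor DE genes are multiplied (up pairs) or divided (down pairs)
#' by `de_fc` in `de_population`, so that population differs from every other
#' population — in particular its normal counterpart — by the planted fold
#' change. The manifest records all planted signals.
#'
#' @param config a [sim_config()].
#' @return list with `counts` ([count_matrix()]), `annotation`
#'   ([cell_annotation()] with an extra ground-truth `population` column),
#'   and `truth` (manifest: `de_genes`, `lr_pairs`, `correlated_pairs`,
#'   `prognostic_genes`, `marker_genes`).
#' @export
generate_sc_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  pops <- config$populations
  genes <- sprintf("G%05d", seq_len(config$n_genes))
  base_mu <- stats::rlnorm(config$n_genes, config$nb_mean_log_mu,
                           config$nb_mean_log_sigma)

  n_mark <- config$n_marker_genes_per_type
  n_up <- config$n_de_lr_pairs_up
  n_dn <- config$n_de_lr_pairs_down
  n_special <- n_mark * nrow(pops) + 2L * (n_up + n_dn)
  # plant markers and DE genes on reasonably expressed genes (upper half of
  # baseline means): real markers are well-detected genes, and fold changes
  # on near-zero means would be unmeasurable at desk scale
  eligible <- which(base_mu >= stats::median(base_mu))
  if (n_special > length(eligible)) {
    lrx_config_error("n_genes too small for the requested marker and DE gene sets")
  }
  special <- sample(eligible, n_special)
  marker_idx <- list()
  off <- 0L
  for (p in pops$name) {
    marker_idx[[p]] <- special[off + seq_len(n_mark)]
    off <- off + n_mark
  }
  de_idx <- special[off + seq_len(2L * (n_up + n_dn))]
  up_idx <- de_idx[seq_len(2L * n_up)]
  dn_idx <- de_idx[2L * n_up + seq_len(2L * n_dn)]
  pair_of <- function(idx) {
    if (!length(idx)) return(data.frame(ligand = character(0),
                                        receptor = character(0)))
    data.frame(ligand = genes[idx[c(TRUE, FALSE)]],
               receptor = genes[idx[c(FALSE, TRUE)]],
               stringsAsFactors = FALSE)
  }
  up_pairs <- pair_of(up_idx)
  dn_pairs <- pair_of(dn_idx)

  counts <- vector("list", nrow(pops))
  cell_ids <- character(0); pop_lab <- character(0)
  for (i in seq_len(nrow(pops))) {
    nm <- pops$name[i]; nc <- pops$n_cells[i]
    mu <- base_mu
    mu[marker_idx[[nm]]] <- mu[marker_idx[[nm]]] * config$marker_fc
    if (nm == config$de_population) {
      mu[up_idx] <- mu[up_idx] * config$de_fc
      mu[dn_idx] <- mu[dn_idx] / config$de_fc
    }
    m <- matrix(stats::rnbinom(nc * config$n_genes,
                               mu = rep(mu, each = nc),
                               size = config$nb_dispersion),
                nrow = nc, ncol = config$n_genes)
    counts[[i]] <- m
    cell_ids <- c(cell_ids, sprintf("%s_c%04d", nm, seq_len(nc)))
    pop_lab <- c(pop_lab, rep(nm, nc))
  }
  values <- do.call(rbind, counts)
  cm <- count_matrix(values, cell_ids = cell_ids, gene_symbols = genes)

  stype <- pops$sample_type[match(pop_lab, pops$name)]
  # three pseudo-donors per population: multi-sample structure without batch effects
  samp <- sprintf("%s_s%d", pop_lab, 1L + (stats::ave(
    seq_along(pop_lab), pop_lab, FUN = seq_along) - 1L) %% 3L)
  ann <- cell_annotation(cell_ids, sample_id = samp, sample_type = stype)
  ann$population <- pop_lab

  de_genes <- rbind(
    if (length(up_idx)) data.frame(
      gene = genes[up_idx],
      contrast = paste0(config$de_population, "_vs_rest"),
      direction = "up", fold_change = config$de_fc,
      stringsAsFactors = FALSE),
    if (length(dn_idx)) data.frame(
      gene = genes[dn_idx],
      contrast = paste0(config$de_population, "_vs_rest"),
      direction = "down", fold_change = config$de_fc,
      stringsAsFactors = FALSE))
  lr_pairs <- rbind(
    if (nrow(up_pairs)) cbind(up_pairs, direction = "up",
                              stringsAsFactors = FALSE),
    if (nrow(dn_pairs)) cbind(dn_pairs, direction = "down",
                              stringsAsFactors = FALSE))
  if (is.null(lr_pairs)) {
    lr_pairs <- data.frame(ligand = character(0), receptor = character(0),
                           direction = character(0), stringsAsFactors = FALSE)
  }
  if (is.null(de_genes)) {
    de_genes <- data.frame(gene = character(0), contrast = character(0),
                           direction = character(0), fold_change = numeric(0),
                           stringsAsFactors = FALSE)
  }
  correlated <- data.frame(ligand = lr_pairs$ligand,
                           receptor = lr_pairs$receptor,
                           planted_rho = rep(config$planted_rho,
                                             nrow(lr_pairs)),
                           stringsAsFactors = FALSE)
  de_pool <- genes[de_idx]
  n_prog <- config$n_prognostic_genes
  prog_genes <- if (n_prog <= length(de_pool)) de_pool[seq_len(n_prog)] else {
    extra <- setdiff(genes, c(de_pool, genes[unlist(marker_idx)]))
    c(de_pool, extra[seq_len(n_prog - length(de_pool))])
  }
  truth <- list(
    de_genes = de_genes,
    lr_pairs = lr_pairs,
    correlated_pairs = correlated,
    prognostic_genes = data.frame(gene = prog_genes,
                                  beta = rep(config$prognostic_beta,
                                             length(prog_genes)),
                                  stringsAsFactors = FALSE),
    marker_genes = lapply(marker_idx, function(ix) genes[ix]))
  list(counts = cm, annotation = ann, truth = truth)
}

#' Generate a coupled bulk cohort with survival and stage labels
#'
#' Bulk log2 expression has Gaussian marginals; each planted pair from the
#' manifest is drawn through a Gaussian copula whose Pearson parameter
#' `2*sin(pi*rho/6)` plants the requested Spearman correlation exactly on the
#' rank scale, leaving marginals untouched. Survival times are exponential
#' with hazard `baseline_hazard * exp(sum beta * z_g)` over the planted
#' prognostic genes (z = standardized log expression), censored by an
#' independent exponential calibrated to `censor_rate`. Stage III-IV is
#' assigned by a logistic function of the same linear predictor, so
#' stage-as-risk-label classification is learnable.
#'
#' @param config a [sim_config()].
#' @param truth manifest from [generate_sc_cohort()] run on the same config.
#' @return list with `bulk` ([bulk_cohort()]) and `survival`
#'   ([survival_table()]).
#' @export
generate_bulk_cohort <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1000L)
  n <- config$n_bulk_samples
  genes <- sprintf("G%05d", seq_len(config$n_genes))
  mu_g <- stats::rnorm(config$n_genes, mean = 6, sd = 1.5)
  sd_g <- stats::runif(config$n_genes, 0.5, 1.5)

  z <- matrix(stats::rnorm(n * config$n_genes), nrow = n)
  colnames(z) <- genes
  pairs <- truth$correlated_pairs
  if (!is.null(pairs) && nrow(pairs)) {
    r <- 2 * sin(pi * pairs$planted_rho / 6)
    for (k in seq_len(nrow(pairs))) {
      li <- match(pairs$ligand[k], genes)
      ri <- match(pairs$receptor[k], genes)
      z[, ri] <- r[k] * z[, li] + sqrt(1 - r[k]^2) * stats::rnorm(n)
    }
  }
  x <- sweep(sweep(z, 2, sd_g, `*`), 2, mu_g, `+`)
  ids <- sprintf("S%04d", seq_len(n))
  bulk <- bulk_cohort(x, sample_ids = ids, gene_symbols = genes)

  prog <- truth$prognostic_genes
  eta <- rep(0, n)
  if (!is.null(prog) && nrow(prog)) {
    zz <- scale(x[, prog$gene, drop = FALSE])
    eta <- drop(zz %*% prog$beta)
  }
  h <- config$baseline_hazard * exp(eta)
  t_event <- stats::rexp(n, rate = h)
  cr <- config$censor_rate
  if (cr > 0) {
    c_rate <- config$baseline_hazard * cr / (1 - cr)
    t_cens <- stats::rexp(n, rate = c_rate)
  } else {
    t_cens <- rep(Inf, n)
  }
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  p_high <- stats::plogis(config$stage_scale * eta)
  high <- stats::runif(n) < p_high
  stage <- ifelse(high, sample(c("III", "IV"), n, replace = TRUE),
                  sample(c("I", "II"), n, replace = TRUE))
  surv <- survival_table(ids, time, event, stage = stage)
  list(bulk = bulk, survival = surv)
}

#' Write a full synthetic study to disk
#'
#' Emits the single-cell counts as a 10x-style MTX triplet, the annotation,
#' bulk and survival tables as TSV, and the truth manifest as a TSV set.
#'
#' @param config a [sim_config()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_sim_study <- function(config, dir) {
  sc <- generate_sc_cohort(config)
  bk <- generate_bulk_cohort(config, sc$truth)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(sc$counts, file.path(dir, "counts"))
  write_annotation(sc$annotation, file.path(dir, "annotation.tsv"))
  write_bulk(bk$bulk, file.path(dir, "bulk.tsv"))
  write_survival(bk$survival, file.path(dir, "survival.tsv"))
  tw <- function(df, f) utils::write.table(df, file.path(dir, f), sep = "\t",
                                           quote = FALSE, row.names = FALSE)
  tw(sc$truth$de_genes, "truth_de_genes.tsv")
  tw(sc$truth$lr_pairs, "truth_lr_pairs.tsv")
  tw(sc$truth$correlated_pairs, "truth_correlated_pairs.tsv")
  tw(sc$truth$prognostic_genes, "truth_prognostic_genes.tsv")
  mk <- sc$truth$marker_genes
  tw(data.frame(cell_type = rep(names(mk), lengths(mk)),
                gene = unlist(mk, use.names = FALSE)), "truth_markers.tsv")
  invisible(dir)
}
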