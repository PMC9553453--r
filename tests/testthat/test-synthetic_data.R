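# Ground-truth generators: reference pairs, single-cell cohort, coupled bulk.

test_that("generate_lr_reference: minimal case, determinism, uniqueness", {
  one <- generate_lr_reference(1, c("A", "B"), seed = 3)
  expect_identical(nrow(one), 1L)
  expect_true(one$ligand != one$receptor)
  expect_true(all(unlist(one) %in% c("A", "B")))

  pool <- sprintf("G%03d", 1:100)
  expect_identical(generate_lr_reference(10, pool, seed = 1),
                   generate_lr_reference(10, pool, seed = 1))

  # brute-force uniqueness: exhaustive pairwise row comparison
  tab <- generate_lr_reference(50, sprintf("G%02d", 1:60), seed = 2)
  expect_identical(nrow(tab), 50L)
  for (i in seq_len(nrow(tab) - 1L)) {
    for (j in seq(i + 1L, nrow(tab))) {
      expect_false(tab$ligand[i] == tab$ligand[j] &&
                   tab$receptor[i] == tab$receptor[j])
    }
  }
  expect_true(all(tab$ligand != tab$receptor))

  expect_error(generate_lr_reference(5, c("A", "B")),
               class = "lrx_config_error")
})

test_that("single-cell generator plants markers and DE at the stated fold change", {
  cfg <- small_sim(seed = 5, n_cells = 250L)
  sc <- generate_sc_cohort(cfg)
  cm <- unclass(sc$counts)
  ann <- sc$annotation

  # marker fold change recovered within 20% at >= 200 cells/population
  for (pop in names(sc$truth$marker_genes)) {
    inp <- ann$population == pop
    for (g in sc$truth$marker_genes[[pop]]) {
      ratio <- mean(cm[inp, g]) / mean(cm[!inp, g])
      expect_gt(ratio, cfg$marker_fc * 0.8)
      expect_lt(ratio, cfg$marker_fc * 1.2)
    }
  }

  # planted up/down DE genes move in the right direction in the DE population
  tum <- ann$population == cfg$de_population
  for (i in seq_len(nrow(sc$truth$de_genes))) {
    g <- sc$truth$de_genes$gene[i]
    ratio <- mean(cm[tum, g]) / mean(cm[!tum, g])
    if (sc$truth$de_genes$direction[i] == "up") expect_gt(ratio, 2)
    else expect_lt(ratio, 1 / 2)
  }

  # conservation: de_genes rows = 2 * (up + down pairs); sets disjoint
  expect_identical(nrow(sc$truth$de_genes),
                   2L * (cfg$n_de_lr_pairs_up + cfg$n_de_lr_pairs_down))
  expect_length(intersect(sc$truth$de_genes$gene,
                          unlist(sc$truth$marker_genes)), 0)
  expect_true(all(sc$truth$de_genes$gene %in% colnames(sc$counts)))
})

test_that("generators are deterministic in the seed", {
  cfg <- small_sim(seed = 11)
  a <- generate_sc_cohort(cfg)
  b <- generate_sc_cohort(small_sim(seed = 11))
  expect_identical(unclass(a$counts), unclass(b$counts))
  expect_identical(a$truth, b$truth)
  ba <- generate_bulk_cohort(cfg, a$truth)
  bb <- generate_bulk_cohort(cfg, b$truth)
  expect_identical(unclass(ba$bulk), unclass(bb$bulk))
  expect_identical(ba$survival, bb$survival)
  c <- generate_sc_cohort(small_sim(seed = 12))
  expect_false(identical(unclass(a$counts), unclass(c$counts)))
})

test_that("bulk copula plants Spearman rho and leaves marginals intact", {
  cfg <- sim_config(seed = 8, n_bulk_samples = 500L, planted_rho = 0.5,
                    n_genes = 600L)
  sc <- generate_sc_cohort(cfg)
  bk <- generate_bulk_cohort(cfg, sc$truth)
  x <- unclass(bk$bulk)

  rhos <- vapply(seq_len(nrow(sc$truth$correlated_pairs)), function(i) {
    spearman_rho(x[, sc$truth$correlated_pairs$ligand[i]],
                 x[, sc$truth$correlated_pairs$receptor[i]])$rho
  }, numeric(1))
  # per-pair sampling sd of Spearman rho at n = 500 is ~0.034, so the
  # +/- 0.08 band is a ~2.4 sigma event per pair: require >= 90% of the 50
  # planted pairs inside it and the mean on target
  expect_gte(mean(abs(rhos - 0.5) < 0.08), 0.9)
  expect_lt(abs(mean(rhos) - 0.5), 0.03)

  # null pairs decorrelated: |rho| < 0.15 for >= 99% of random pairs
  planted <- unique(unlist(sc$truth$correlated_pairs[, 1:2]))
  nullg <- setdiff(colnames(x), planted)
  set.seed(1)
  idx <- matrix(sample(nullg, 400), ncol = 2)
  null_rho <- vapply(seq_len(nrow(idx)), function(i)
    spearman_rho(x[, idx[i, 1]], x[, idx[i, 2]])$rho, numeric(1))
  expect_gte(mean(abs(null_rho) < 0.15), 0.99)

  # copula marginal invariance: changing the planted correlation leaves each
  # gene's marginal mean unchanged up to sampling error
  cfg_lo <- sim_config(seed = 8, n_bulk_samples = 500L, planted_rho = 0.05,
                       n_genes = 600L)
  bk_lo <- generate_bulk_cohort(cfg_lo, generate_sc_cohort(cfg_lo)$truth)
  mu_hi <- colMeans(x[, planted, drop = FALSE])
  mu_lo <- colMeans(unclass(bk_lo$bulk)[, planted, drop = FALSE])
  expect_true(all(abs(mu_hi - mu_lo) < 0.25))
  # and planted-gene sds sit in the generator's stated [0.5, 1.5] range
  sd_hat <- apply(x[, planted, drop = FALSE], 2, sd)
  expect_true(all(sd_hat > 0.35 & sd_hat < 1.75))
})

test_that("survival generator: censoring level and null log-rank behavior", {
  cfg <- sim_config(seed = 13, n_bulk_samples = 400L, prognostic_beta = 0,
                    n_genes = 400L, n_prognostic_genes = 5L,
                    censor_rate = 0.3)
  sc <- generate_sc_cohort(cfg)
  bk <- generate_bulk_cohort(cfg, sc$truth)
  # with beta = 0 the exponential censoring calibration is exact in expectation
  expect_lt(abs(mean(bk$survival$event == 0) - 0.3), 0.08)

  # beta = 0: median-split log-rank p roughly uniform over replicates
  ps <- vapply(1:40, function(r) {
    cfg_r <- sim_config(seed = 100 + r, n_bulk_samples = 150L,
                        prognostic_beta = 0, n_genes = 80L,
                        n_prognostic_genes = 2L,
                        n_de_lr_pairs_up = 2L, n_de_lr_pairs_down = 1L,
                        n_marker_genes_per_type = 2L)
    sc_r <- generate_sc_cohort(cfg_r)
    bk_r <- generate_bulk_cohort(cfg_r, sc_r$truth)
    g <- sc_r$truth$prognostic_genes$gene[1]
    e <- unclass(bk_r$bulk)[, g]
    hi <- e > median(e)
    logrank_test(bk_r$survival$time[hi], bk_r$survival$event[hi],
                 bk_r$survival$time[!hi], bk_r$survival$event[!hi])$p
  }, numeric(1))
  expect_lte(mean(ps < 0.05), 0.15)   # binomial 99% bound around 0.05 at 40 reps
  expect_gt(mean(ps), 0.3)            # not systematically small
})

test_that("a full study writes to disk and reads back", {
  cfg <- small_sim(seed = 2, n_cells = 40L, n_genes = 80L, n_up = 2L,
                   n_dn = 1L)
  dir <- withr::local_tempdir()
  write_sim_study(cfg, dir)
  sc <- generate_sc_cohort(cfg)
  counts <- read_counts(file.path(dir, "counts"))
  expect_equal(as.matrix(unclass(counts)), unclass(sc$counts),
               ignore_attr = TRUE)
  expect_identical(nrow(read_survival(file.path(dir, "survival.tsv"))),
                   cfg$n_bulk_samples)
  truth <- read.delim(file.path(dir, "truth_lr_pairs.tsv"))
  expect_identical(nrow(truth), 3L)
})
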