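# Product-limit curves and log-rank against hand computation and the
# survival package; prognostic screen; risk model training and validation.

test_that("km_curve matches hand computation and survival::survfit", {
  # no events: survival identically 1
  k0 <- km_curve(c(3, 5, 7), c(0, 0, 0))
  expect_true(all(k0$survival == 1))

  # two events at 1 and 2: steps 1 -> 0.5 -> 0
  k2 <- km_curve(c(1, 2), c(1, 1))
  expect_equal(k2$survival, c(0.5, 0))

  # doubling times rescales the x-axis only
  set.seed(4)
  t <- rexp(30, 0.1); e <- rbinom(30, 1, 0.6)
  k1 <- km_curve(t, e); kd <- km_curve(2 * t, e)
  expect_equal(kd$time, 2 * k1$time)
  expect_equal(kd$survival, k1$survival)

  library(survival)
  for (i in 1:10) {
    t <- round(rexp(40, 0.05), 1) + 0.1; e <- rbinom(40, 1, 0.5)
    ours <- km_curve(t, e)
    ref <- summary(survfit(Surv(t, e) ~ 1), times = ours$time)
    expect_equal(ours$survival, ref$surv, tolerance = 1e-12)
    expect_equal(ours$n_risk, ref$n.risk, tolerance = 1e-12)
  }
  expect_error(km_curve(numeric(0), numeric(0)), class = "lrx_config_error")
})

test_that("logrank_test matches the hand-computed example and survdiff", {
  # A: events at 1, 2; B: events at 3, 4 -> chi2 = 2.8824, p = 0.0896
  res <- logrank_test(c(1, 2), c(1, 1), c(3, 4), c(1, 1))
  expect_equal(round(res$chi2, 4), 2.8824)
  expect_lt(abs(res$p - 0.0896), 1e-4)

  # identical groups -> statistic 0, p 1
  same <- logrank_test(c(1, 3, 5), c(1, 0, 1), c(1, 3, 5), c(1, 0, 1))
  expect_equal(same$chi2, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)

  # label-swap symmetry
  set.seed(11)
  tA <- rexp(25, 0.1); eA <- rbinom(25, 1, 0.7)
  tB <- rexp(30, 0.2); eB <- rbinom(30, 1, 0.7)
  r1 <- logrank_test(tA, eA, tB, eB)
  r2 <- logrank_test(tB, eB, tA, eA)
  expect_equal(r1$chi2, r2$chi2, tolerance = 1e-12)

  # no events anywhere -> warning, p 1
  expect_warning(r0 <- logrank_test(c(1, 2), c(0, 0), c(3, 4), c(0, 0)))
  expect_equal(r0$p, 1)

  library(survival)
  for (i in 1:10) {
    tA <- round(rexp(30, 0.05), 1) + 0.1; eA <- rbinom(30, 1, 0.6)
    tB <- round(rexp(35, 0.08), 1) + 0.1; eB <- rbinom(35, 1, 0.6)
    ours <- logrank_test(tA, eA, tB, eB)
    ref <- survdiff(Surv(c(tA, tB), c(eA, eB)) ~
                      rep(c("A", "B"), c(30, 35)))
    expect_equal(ours$chi2, ref$chisq, tolerance = 1e-8)
  }
})

test_that("prognostic_screen flags planted genes, controls nulls, edge cases", {
  cfg <- sim_config(seed = 17, n_bulk_samples = 400L, prognostic_beta = 1,
                    n_prognostic_genes = 10L, n_genes = 400L)
  sc <- generate_sc_cohort(cfg)
  bk <- generate_bulk_cohort(cfg, sc$truth)
  planted <- sc$truth$prognostic_genes$gene
  set.seed(3)
  nulls <- sample(setdiff(colnames(bk$bulk), planted), 60)
  res <- prognostic_screen(bk$bulk, bk$survival, c(planted, nulls))
  expect_gte(mean(res$prognostic[match(planted, res$gene)]), 0.9)
  expect_lte(mean(res$prognostic[match(nulls, res$gene)]), 0.15)

  # alpha = 0 flags nothing
  res0 <- prognostic_screen(bk$bulk, bk$survival, planted, alpha = 0)
  expect_false(any(res0$prognostic))

  # FDR variant is never more liberal than the unadjusted screen
  resf <- prognostic_screen(bk$bulk, bk$survival, c(planted, nulls),
                            fdr = TRUE)
  expect_true(all(resf$prognostic <= res$prognostic))

  # constant gene: degenerate split -> warning, missing p, not prognostic
  bulk_c <- bulk_cohort(cbind(unclass(bk$bulk)[, 1:2],
                              CONSTG = rep(1, nrow(bk$bulk))))
  expect_warning(resc <- prognostic_screen(bulk_c, bk$survival, "CONSTG"),
                 "degenerate")
  expect_true(is.na(resc$logrank_p))
  expect_false(resc$prognostic)
})

test_that("gbt learner separates, predicts probabilities, and is deterministic", {
  set.seed(21)
  x <- matrix(rnorm(400), 200, 2, dimnames = list(NULL, c("f1", "f2")))
  y <- as.integer(x[, 1] + 0.5 * x[, 2] + rnorm(200, sd = 0.3) > 0)
  fit <- gbt_fit(x, y, n_trees = 80)
  p <- predict(fit, x)
  expect_true(all(p > 0 & p < 1))
  expect_gt(mean((p > 0.5) == (y == 1)), 0.93)
  fit2 <- gbt_fit(x, y, n_trees = 80)
  expect_identical(predict(fit2, x), p)
  expect_error(gbt_fit(x, rep(1, 200)), class = "lrx_config_error")
})

test_that("risk model trains with a stratified 2:1 split and validates externally", {
  cfg <- sim_config(seed = 23, n_bulk_samples = 450L, prognostic_beta = 1.5,
                    n_prognostic_genes = 20L, n_genes = 400L)
  sc <- generate_sc_cohort(cfg)
  bk <- generate_bulk_cohort(cfg, sc$truth)
  genes <- sc$truth$prognostic_genes$gene
  mdl <- train_risk_model(bk$bulk, bk$survival, genes, seed = 1,
                          n_trees = 120L)
  expect_lt(abs(mdl$split$realized_ratio - 2), 0.15)
  expect_true(all(unlist(mdl$metrics) >= 0 & unlist(mdl$metrics) <= 1))
  expect_gt(mdl$metrics$precision, 0.6)

  # same seed -> identical split and metrics
  mdl2 <- train_risk_model(bk$bulk, bk$survival, genes, seed = 1,
                           n_trees = 120L)
  expect_identical(mdl$split$train_ids, mdl2$split$train_ids)
  expect_identical(mdl$metrics, mdl2$metrics)

  # save / load round trip preserves predictions exactly
  f <- withr::local_tempfile(fileext = ".json")
  save_risk_model(mdl, f)
  back <- load_risk_model(f)
  expect_equal(predict(back, bk$bulk, type = "prob"),
               predict(mdl, bk$bulk, type = "prob"), tolerance = 1e-12)

  # external validation on an independent cohort with the same planted truth
  cfg2 <- sim_config(seed = 24, n_bulk_samples = 300L, prognostic_beta = 1.5,
                     n_prognostic_genes = 20L, n_genes = 400L)
  bk2 <- generate_bulk_cohort(cfg2, sc$truth)
  val <- validate_risk_model(mdl, bk2$bulk, bk2$survival)
  expect_lt(val$p, 0.05)
  expect_s3_class(val$km$high, "km_curve")

  # missing feature genes are mean-imputed with a warning
  drop1 <- bulk_cohort(unclass(bk2$bulk)[, setdiff(colnames(bk2$bulk),
                                                   genes[1])])
  expect_warning(predict(mdl, drop1, type = "class"), "imputing")

  # chance baseline: with beta = 0 the held-out precision tracks prevalence
  cfg0 <- sim_config(seed = 25, n_bulk_samples = 300L, prognostic_beta = 0,
                     n_prognostic_genes = 10L, n_genes = 300L)
  sc0 <- generate_sc_cohort(cfg0)
  bk0 <- generate_bulk_cohort(cfg0, sc0$truth)
  m0 <- train_risk_model(bk0$bulk, bk0$survival,
                         sc0$truth$prognostic_genes$gene, seed = 1,
                         n_trees = 60L)
  prev <- mean(bk0$survival$stage %in% c("III", "IV"))
  expect_lt(abs(m0$metrics$precision - prev), 0.2)
})
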