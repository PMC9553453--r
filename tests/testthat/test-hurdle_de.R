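# Hurdle test against an independent numerical likelihood-maximization
# oracle, BH adjustment against hand computation and stats::p.adjust,
# calibration and power on generated data.

# --- independent oracle: maximize the stated likelihoods numerically -------

# binomial detection component: 2 * (max ll per-group - max ll pooled)
oracle_disc <- function(xA, xB) {
  kA <- sum(xA > 0); kB <- sum(xB > 0)
  nA <- length(xA); nB <- length(xB)
  ll <- function(k, n, p) {
    if (p <= 0 || p >= 1) return(-Inf)
    k * log(p) + (n - k) * log(1 - p)
  }
  opt1 <- function(k, n) {
    if (k == 0 || k == n) {
      # boundary MLE: limit of the likelihood
      return(ifelse(k == 0, 0, 0))
    }
    stats::optimize(function(p) ll(k, n, p), c(1e-9, 1 - 1e-9),
                    maximum = TRUE)$objective
  }
  llA <- opt1(kA, nA); llB <- opt1(kB, nB)
  k <- kA + kB; n <- nA + nB
  if (k == 0 || k == n) return(list(stat = 0, df = 0L))
  ll0 <- stats::optimize(function(p) ll(kA, nA, p) + ll(kB, nB, p),
                         c(1e-9, 1 - 1e-9), maximum = TRUE)$objective
  list(stat = 2 * (llA + llB - ll0), df = 1L)
}

# Gaussian component on detected values: numeric optimization over means
# and the shared sigma, for both the pooled and per-group models
oracle_cont <- function(xA, xB) {
  dA <- xA[xA > 0]; dB <- xB[xB > 0]
  if (length(dA) < 2 || length(dB) < 2) return(list(stat = 0, df = 0L))
  nll1 <- function(th) -sum(stats::dnorm(dA, th[1], exp(th[3]), log = TRUE)) -
    sum(stats::dnorm(dB, th[2], exp(th[3]), log = TRUE))
  nll0 <- function(th) -sum(stats::dnorm(c(dA, dB), th[1], exp(th[2]),
                                         log = TRUE))
  f1 <- stats::optim(c(mean(dA), mean(dB), log(sd(c(dA, dB)) + 0.1)), nll1,
                     method = "BFGS", control = list(reltol = 1e-14))
  f0 <- stats::optim(c(mean(c(dA, dB)), log(sd(c(dA, dB)) + 0.1)), nll0,
                     method = "BFGS", control = list(reltol = 1e-14))
  list(stat = 2 * (f0$value - f1$value), df = 1L)
}

test_that("hurdle components match the numerical-optimizer oracle", {
  fixtures <- list(
    list(A = c(0, 2, 3), B = c(0, 0, 1)),            # continuous df 0
    list(A = c(0, 2, 3, 4), B = c(0, 1, 1, 2)),      # both components active
    list(A = c(1, 2, 3, 4, 2), B = c(0, 0, 1, 2, 0)),
    list(A = c(0, 0, 5, 6), B = c(3, 4, 0, 0)))
  for (fx in fixtures) {
    e <- raw_expr(cbind(c(fx$A, fx$B)), genes = "GX")
    res <- hurdle_test(e, sprintf("c%d", seq_along(fx$A)),
                       sprintf("c%d", length(fx$A) + seq_along(fx$B)), "GX")
    od <- oracle_disc(fx$A, fx$B)
    oc <- oracle_cont(fx$A, fx$B)
    expect_equal(res$stat, od$stat + oc$stat, tolerance = 1e-6)
    expect_identical(res$df, od$df + oc$df)
    expect_equal(res$p,
                 if (res$df == 0) 1 else
                   pchisq(od$stat + oc$stat, res$df, lower.tail = FALSE),
                 tolerance = 1e-6)
  }
})

test_that("hurdle degenerate conventions and symmetries hold", {
  # identical expression vectors -> stat 0, p 1
  v <- c(0, 1, 2, 0, 3)
  e <- raw_expr(cbind(c(v, v)), genes = "GX")
  a <- sprintf("c%d", 1:5); b <- sprintf("c%d", 6:10)
  res <- hurdle_test(e, a, b, "GX")
  expect_equal(res$stat, 0, tolerance = 1e-12)
  expect_equal(res$p, 1)

  # all-zero gene -> df 0, p = 1
  e0 <- raw_expr(cbind(rep(0, 10)), genes = "GX")
  res0 <- hurdle_test(e0, a, b, "GX")
  expect_identical(res0$df, 0L)
  expect_equal(res0$p, 1)

  # label swap: stat invariant, log2fc flips sign
  set.seed(2)
  ex <- raw_expr(cbind(rpois(12, 2) * runif(12)), genes = "GX")
  a2 <- sprintf("c%d", 1:6); b2 <- sprintf("c%d", 7:12)
  r1 <- hurdle_test(ex, a2, b2, "GX")
  r2 <- hurdle_test(ex, b2, a2, "GX")
  expect_equal(r1$stat, r2$stat, tolerance = 1e-12)
  expect_equal(r1$log2fc, -r2$log2fc, tolerance = 1e-12)

  expect_error(hurdle_test(ex, a2, c(a2[1], b2), "GX"),
               class = "lrx_config_error")
  expect_error(hurdle_test(ex, a2, b2, "NOPE"), class = "lrx_config_error")
})

test_that("bh_adjust matches hand step-up and stats::p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.4, 5)), rep(0.4, 5))
  expect_error(bh_adjust(c(0.5, 0)), class = "lrx_config_error")
  expect_error(bh_adjust(c(0.5, 1.2)), class = "lrx_config_error")
  set.seed(3)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), p.adjust(p, method = "BH"), tolerance = 1e-12)
  }
})

test_that("de_table agrees with per-gene hurdle_test and assigns directions", {
  cfg <- small_sim(seed = 9, n_cells = 80L, n_genes = 120L)
  sc <- generate_sc_cohort(cfg)
  expr <- normalize_log(sc$counts)
  a <- cells_of(sc$annotation, "tumor_cells")
  b <- cells_of(sc$annotation, "epithelial")
  de <- de_table(expr, a, b)
  set.seed(1)
  for (g in sample(de$gene, 15)) {
    row <- hurdle_test(expr, a, b, g)
    i <- match(g, de$gene)
    expect_equal(de$stat[i], row$stat, tolerance = 1e-10)
    expect_identical(de$df[i], row$df)
    expect_equal(de$p[i], row$p, tolerance = 1e-10)
    expect_equal(de$log2fc[i], row$log2fc, tolerance = 1e-10)
  }
  expect_identical(de$direction[de$q < 0.05 & de$log2fc > 0.25][1], "up")
  expect_true(all(de$direction %in% c("up", "down", "ns")))
  # q is the BH transform of p
  expect_equal(de$q, bh_adjust(de$p), tolerance = 1e-12)

  # empty panel -> empty table
  empty <- de_table(expr, a, b, genes = character(0))
  expect_identical(nrow(empty), 0L)
})

test_that("planted fold-change-4 genes are recovered with q < 0.05", {
  hits <- vapply(1:8, function(r) {
    cfg <- small_sim(seed = 200 + r, n_cells = 200L, n_genes = 150L,
                     n_up = 3L, n_dn = 2L)
    sc <- generate_sc_cohort(cfg)
    expr <- normalize_log(sc$counts)
    de <- de_table(expr, cells_of(sc$annotation, "tumor_cells"),
                   cells_of(sc$annotation, "epithelial"))
    planted <- sc$truth$de_genes
    flag <- de$direction[match(planted$gene, de$gene)]
    mean(flag == planted$direction)
  }, numeric(1))
  expect_gte(mean(hits), 0.95)
})
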