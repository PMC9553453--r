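# Kaplan-Meier product-limit estimation, log-rank testing, and per-gene
# prognostic screening by median split.

#' Kaplan-Meier product-limit curve
#'
#' @param times positive follow-up times.
#' @param events event indicators (1 event, 0 censored).
#' @return a `km_curve` data.frame over the distinct observed times: time,
#'   n_risk, n_event, n_censor, survival. Survival starts at 1 and is
#'   non-increasing; censored subjects leave the risk set after their time.
#' @export
km_curve <- function(times, events) {
  if (!length(times)) lrx_config_error("empty input")
  if (any(times <= 0)) lrx_config_error("times must be positive")
  if (!all(events %in% c(0, 1))) lrx_config_error("events must be 0 or 1")
  ut <- sort(unique(times))
  n <- length(times)
  n_risk <- vapply(ut, function(t) sum(times >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(times == t & events == 1), numeric(1))
  n_censor <- vapply(ut, function(t) sum(times == t & events == 0), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                       n_censor = n_censor, survival = surv),
            class = c("km_curve", "data.frame"))
}

#' Two-group log-rank test
#'
#' The classical O - E statistic accumulated over pooled event times with the
#' hypergeometric variance, referred to chi-square with 1 degree of freedom.
#'
#' @param times_A,events_A,times_B,events_B per-group times and indicators.
#' @return list with `chi2` and `p`. With no events in either group the
#'   statistic is 0 and p = 1, with a warning.
#' @export
logrank_test <- function(times_A, events_A, times_B, events_B) {
  if (!length(times_A) || !length(times_B)) {
    lrx_config_error("both groups must be non-empty")
  }
  times <- c(times_A, times_B)
  events <- c(events_A, events_B)
  grp <- rep(c(0L, 1L), c(length(times_A), length(times_B)))
  ev_times <- sort(unique(times[events == 1]))
  if (!length(ev_times)) {
    warning("no events in either group; log-rank undefined")
    return(list(chi2 = 0, p = 1))
  }
  o <- e <- v <- 0
  for (t in ev_times) {
    at <- times >= t
    n <- sum(at); nA <- sum(at & grp == 0L)
    d <- sum(times == t & events == 1)
    dA <- sum(times == t & events == 1 & grp == 0L)
    o <- o + dA
    e <- e + d * nA / n
    if (n > 1) v <- v + d * (n - d) * nA * (n - nA) / (n^2 * (n - 1))
  }
  if (v <= 0) {
    warning("zero log-rank variance")
    return(list(chi2 = 0, p = 1))
  }
  chi2 <- (o - e)^2 / v
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Per-gene prognostic screening by median split
#'
#' For each gene, samples are split at the median of its bulk expression
#' (strictly above the median is the high group; ties go low) and the two
#' groups are compared by log-rank. A gene is called prognostic at
#' `p < alpha` (unadjusted by default; `fdr = TRUE` applies
#' Benjamini-Hochberg and thresholds q instead).
#'
#' @param bulk a [bulk_cohort()].
#' @param surv a [survival_table()]; samples are matched to bulk rows by id,
#'   unmatched ones dropped with a logged count.
#' @param genes gene symbols to screen (must be in the bulk matrix).
#' @param alpha significance level (default 0.05).
#' @param fdr apply BH across the screened genes (default FALSE).
#' @return data.frame: gene, logrank_p, q (if `fdr`), prognostic.
#' @export
prognostic_screen <- function(bulk, surv, genes, alpha = 0.05, fdr = FALSE) {
  genes <- normalize_symbols(genes)
  missing <- setdiff(genes, colnames(bulk))
  if (length(missing)) {
    lrx_config_error(sprintf("gene(s) absent from bulk: %s",
                             paste(utils::head(missing, 3), collapse = ", ")))
  }
  idx <- match(surv$sample, rownames(bulk))
  dropped <- sum(is.na(idx))
  if (dropped) lrx_log("info", "%d survival sample(s) not in bulk; dropped",
                       dropped)
  surv <- surv[!is.na(idx), , drop = FALSE]
  x <- unclass(bulk)[idx[!is.na(idx)], , drop = FALSE]
  p <- vapply(genes, function(g) {
    e <- x[, g]
    high <- e > stats::median(e)
    if (!any(high) || all(high)) {
      warning(sprintf("gene %s: degenerate median split", g))
      return(NA_real_)
    }
    logrank_test(surv$time[high], surv$event[high],
                 surv$time[!high], surv$event[!high])$p
  }, numeric(1))
  out <- data.frame(gene = genes, logrank_p = unname(p),
                    stringsAsFactors = FALSE)
  if (fdr) {
    q <- rep(NA_real_, nrow(out))
    ok <- !is.na(p)
    q[ok] <- bh_adjust(pmax(p[ok], .Machine$double.xmin))
    out$q <- q
    out$prognostic <- !is.na(q) & q < alpha
  } else {
    out$prognostic <- !is.na(p) & p < alpha
  }
  out
}
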