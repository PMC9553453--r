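# Stage-label risk classification: high-risk = stage III-IV, stratified
# train/test split, boosted-tree fit, precision/recall on the held-out part,
# and external validation by Kaplan-Meier / log-rank on predicted groups.

#' Train the stage-based risk classifier
#'
#' Samples are labeled high-risk when their stage is III or IV and low-risk
#' for I-II, split into training and held-out parts at `split_ratio` with
#' stratification by class (per class, `floor(split_ratio * n)` training
#' samples; the realized ratio is recorded), and a gradient-boosted tree
#' classifier ([gbt_fit()]) is trained on the feature genes. Precision and
#' recall of the high-risk class are reported on the held-out part.
#'
#' @param bulk a [bulk_cohort()].
#' @param surv a [survival_table()] with stage present for every matched
#'   sample; samples without stage are dropped with a logged count.
#' @param genes feature gene symbols (typically differentially expressed
#'   ligands/receptors passing [prognostic_screen()]).
#' @param split_ratio training fraction (default 2/3, the "2:1" design).
#' @param seed integer seed for the split.
#' @param n_trees,max_depth,learning_rate boosting hyperparameters
#'   (defaults 300, 3, 0.1).
#' @return a `risk_model` list: `model` ([gbt_fit()] result), `features`,
#'   `feature_means` (training means used to impute genes missing from an
#'   external cohort), `split` (ratio, realized_ratio, seed, train/test ids),
#'   `metrics` (precision, recall), `threshold`.
#' @export
train_risk_model <- function(bulk, surv, genes, split_ratio = 2 / 3,
                             seed = 1L, n_trees = 300L, max_depth = 3L,
                             learning_rate = 0.1) {
  genes <- normalize_symbols(genes)
  if (!length(genes)) lrx_config_error("feature gene list is empty")
  missing <- setdiff(genes, colnames(bulk))
  if (length(missing)) {
    lrx_config_error(sprintf("feature gene(s) absent from bulk: %s",
                             paste(utils::head(missing, 3), collapse = ", ")))
  }
  idx <- match(surv$sample, rownames(bulk))
  keep <- !is.na(idx) & !is.na(surv$stage)
  n_drop <- sum(!keep)
  if (n_drop) lrx_log("info", "%d sample(s) dropped (no bulk row or stage)",
                      n_drop)
  surv <- surv[keep, , drop = FALSE]
  x <- unclass(bulk)[idx[keep], genes, drop = FALSE]
  y <- as.integer(surv$stage %in% c("III", "IV"))
  if (length(unique(y)) < 2L) {
    lrx_config_error("both risk classes must be present")
  }
  set.seed(seed)
  train <- logical(length(y))
  for (cls in c(0L, 1L)) {
    ids <- which(y == cls)
    n_tr <- floor(split_ratio * length(ids))
    if (n_tr < 1L || n_tr >= length(ids)) {
      lrx_config_error("split leaves a class empty in training or test")
    }
    train[sample(ids, n_tr)] <- TRUE
  }
  if (length(unique(y[train])) < 2L) {
    lrx_config_error("a class is absent from the training split")
  }
  fit <- gbt_fit(x[train, , drop = FALSE], y[train], n_trees = n_trees,
                 max_depth = max_depth, learning_rate = learning_rate)
  threshold <- 0.5
  prob <- predict(fit, x[!train, , drop = FALSE])
  pred <- as.integer(prob > threshold)
  truth <- y[!train]
  tp <- sum(pred == 1L & truth == 1L)
  precision <- if (sum(pred == 1L)) tp / sum(pred == 1L) else NA_real_
  if (is.na(precision)) warning("no held-out sample predicted high-risk")
  recall <- tp / sum(truth == 1L)
  structure(list(
    model = fit, features = genes, feature_means = colMeans(x[train, ,
                                                              drop = FALSE]),
    split = list(ratio = split_ratio,
                 realized_ratio = sum(train) / sum(!train),
                 seed = as.integer(seed),
                 train_ids = surv$sample[train],
                 test_ids = surv$sample[!train]),
    metrics = list(precision = precision, recall = recall),
    threshold = threshold), class = "risk_model")
}

#' Predict risk classes for a cohort
#'
#' Feature genes missing from the cohort are imputed with their training
#' means, with a warning.
#'
#' @param object a `risk_model`.
#' @param bulk a [bulk_cohort()].
#' @param type `"class"` (high/low) or `"prob"`.
#' @param ... unused.
#' @return named vector of predictions, one per bulk sample.
#' @export
predict.risk_model <- function(object, bulk, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  missing <- setdiff(object$features, colnames(bulk))
  x <- matrix(NA_real_, nrow(bulk), length(object$features),
              dimnames = list(rownames(bulk), object$features))
  present <- setdiff(object$features, missing)
  x[, present] <- unclass(bulk)[, present]
  if (length(missing)) {
    warning(sprintf("imputing %d feature gene(s) missing from cohort",
                    length(missing)))
    for (g in missing) x[, g] <- object$feature_means[[g]]
  }
  prob <- predict(object$model, x)
  names(prob) <- rownames(bulk)
  if (type == "prob") prob else ifelse(prob > object$threshold, "high", "low")
}

#' Validate a risk model on an external cohort
#'
#' Predicts high/low risk per external sample, draws a Kaplan-Meier curve
#' per predicted group and compares them by log-rank.
#'
#' @param model a `risk_model`.
#' @param bulk_ext external [bulk_cohort()].
#' @param surv_ext external [survival_table()] matched by sample id.
#' @return list: `groups` (named predicted class per sample), `km` (list of
#'   [km_curve()] per group), `chi2`, `p`. When every sample lands in one
#'   class, `p` is NA with a warning.
#' @export
validate_risk_model <- function(model, bulk_ext, surv_ext) {
  idx <- match(surv_ext$sample, rownames(bulk_ext))
  keep <- !is.na(idx)
  if (any(!keep)) lrx_log("info", "%d external sample(s) not in bulk",
                          sum(!keep))
  surv <- surv_ext[keep, , drop = FALSE]
  sub <- unclass(bulk_ext)[idx[keep], , drop = FALSE]
  class(sub) <- c("bulk_cohort", "matrix", "array")
  grp <- predict(model, sub, type = "class")
  if (length(unique(grp)) < 2L) {
    warning("all external samples predicted in one class; log-rank undefined")
    return(list(groups = grp, km = NULL, chi2 = NA_real_, p = NA_real_))
  }
  hi <- grp == "high"
  km <- list(high = km_curve(surv$time[hi], surv$event[hi]),
             low = km_curve(surv$time[!hi], surv$event[!hi]))
  lr <- logrank_test(surv$time[hi], surv$event[hi],
                     surv$time[!hi], surv$event[!hi])
  list(groups = grp, km = km, chi2 = lr$chi2, p = lr$p)
}

#' Persist a risk model with its metadata sidecar
#'
#' Serializes the boosted trees and metadata (features, split, metrics,
#' seed) as a single JSON document; [load_risk_model()] restores it.
#'
#' @param model a `risk_model`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
save_risk_model <- function(model, path) {
  doc <- list(
    features = model$features,
    feature_means = as.list(model$feature_means),
    split = model$split, metrics = model$metrics,
    threshold = model$threshold,
    base = model$model$base, learning_rate = model$model$learning_rate,
    roots = vapply(model$model$trees, attr, integer(1), "root"),
    trees = unname(lapply(model$model$trees, as.data.frame)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a persisted risk model
#' @param path JSON path written by [save_risk_model()].
#' @return a `risk_model`.
#' @export
load_risk_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  trees <- lapply(seq_along(doc$roots), function(i) {
    df <- as.data.frame(doc$trees[[i]])
    # JSON null -> NA of the right type for leaf rows
    for (col in c("feature", "left", "right")) {
      df[[col]] <- suppressWarnings(as.integer(df[[col]]))
    }
    for (col in c("threshold", "value")) {
      df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
    }
    attr(df, "root") <- as.integer(doc$roots[[i]])
    df
  })
  fit <- structure(list(trees = trees, base = doc$base,
                        learning_rate = doc$learning_rate,
                        n_features = length(doc$features),
                        feature_names = doc$features), class = "gbt_model")
  structure(list(model = fit, features = doc$features,
                 feature_means = unlist(doc$feature_means),
                 split = doc$split, metrics = doc$metrics,
                 threshold = doc$threshold), class = "risk_model")
}
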