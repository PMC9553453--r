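# A compact gradient-boosted tree classifier (logistic loss, second-order
# boosting, exact greedy depth-limited regression trees). Implemented here
# because no boosted-tree package is available in the offline toolchain; the
# algorithm follows the standard XGBoost-style formulation: leaf weight
# -G/(H + lambda), split gain from the same regularized objective.

# Fit one regression tree to gradients g and hessians h.
# Returns a data.frame of nodes: feature (NA for leaf), threshold, left,
# right (child row indices), value (leaf weight).
.gbt_tree <- function(x, g, h, max_depth, lambda, min_child_weight,
                      min_gain = 1e-12) {
  nodes <- list()
  new_leaf <- function(idx) {
    nodes[[length(nodes) + 1L]] <<- list(
      feature = NA_integer_, threshold = NA_real_,
      left = NA_integer_, right = NA_integer_,
      value = -sum(g[idx]) / (sum(h[idx]) + lambda))
    length(nodes)
  }
  best_split <- function(idx) {
    G <- sum(g[idx]); H <- sum(h[idx])
    parent <- G^2 / (H + lambda)
    best <- list(gain = min_gain, feature = NA_integer_,
                 threshold = NA_real_)
    for (j in seq_len(ncol(x))) {
      xv <- x[idx, j]
      ord <- order(xv)
      xs <- xv[ord]
      gs <- cumsum(g[idx][ord]); hs <- cumsum(h[idx][ord])
      n <- length(xs)
      if (n < 2L) next
      cut_ok <- which(xs[-n] < xs[-1L])     # only between distinct values
      if (!length(cut_ok)) next
      GL <- gs[cut_ok]; HL <- hs[cut_ok]
      GR <- G - GL; HR <- H - HL
      ok <- HL >= min_child_weight & HR >= min_child_weight
      if (!any(ok)) next
      gain <- 0.5 * (GL^2 / (HL + lambda) + GR^2 / (HR + lambda) - parent)
      gain[!ok] <- -Inf
      k <- which.max(gain)
      if (gain[k] > best$gain) {
        best <- list(gain = gain[k], feature = j,
                     threshold = (xs[cut_ok[k]] + xs[cut_ok[k] + 1L]) / 2)
      }
    }
    best
  }
  grow <- function(idx, depth) {
    if (depth >= max_depth || length(idx) < 2L) return(new_leaf(idx))
    sp <- best_split(idx)
    if (is.na(sp$feature)) return(new_leaf(idx))
    left_idx <- idx[x[idx, sp$feature] <= sp$threshold]
    right_idx <- idx[x[idx, sp$feature] > sp$threshold]
    me <- {
      nodes[[length(nodes) + 1L]] <<- list(
        feature = sp$feature, threshold = sp$threshold,
        left = NA_integer_, right = NA_integer_, value = NA_real_)
      length(nodes)
    }
    l <- grow(left_idx, depth + 1L)
    r <- grow(right_idx, depth + 1L)
    nodes[[me]]$left <<- l
    nodes[[me]]$right <<- r
    me
  }
  root <- grow(seq_len(nrow(x)), 0L)
  df <- do.call(rbind, lapply(nodes, function(nd)
    data.frame(feature = nd$feature, threshold = nd$threshold,
               left = nd$left, right = nd$right, value = nd$value)))
  attr(df, "root") <- root
  df
}

.gbt_tree_predict <- function(tree, x) {
  out <- numeric(nrow(x))
  node_of <- rep(attr(tree, "root"), nrow(x))
  repeat {
    leaf <- is.na(tree$feature[node_of])
    if (all(leaf)) break
    act <- which(!leaf)
    nd <- node_of[act]
    goes_left <- x[cbind(act, tree$feature[nd])] <= tree$threshold[nd]
    node_of[act] <- ifelse(goes_left, tree$left[nd], tree$right[nd])
  }
  tree$value[node_of]
}

#' Fit a gradient-boosted tree classifier
#'
#' Binary classifier trained by second-order gradient boosting of
#' depth-limited regression trees on the logistic loss. Deterministic for
#' fixed inputs (exact greedy splits, no subsampling).
#'
#' @param x numeric feature matrix (samples x features).
#' @param y binary labels (0/1).
#' @param n_trees boosting rounds (default 300).
#' @param max_depth maximum tree depth (default 3).
#' @param learning_rate shrinkage per round (default 0.1).
#' @param lambda L2 regularization on leaf weights (default 0, the classical
#'   gradient-boosting behavior).
#' @param min_child_weight minimum hessian sum per child (default 1).
#' @return a `gbt_model` (list of trees plus the base log-odds).
#' @export
gbt_fit <- function(x, y, n_trees = 300L, max_depth = 3L,
                    learning_rate = 0.1, lambda = 0, min_child_weight = 1) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) lrx_config_error("labels must be 0/1")
  if (length(unique(y)) < 2L) lrx_config_error("both classes required")
  p0 <- mean(y)
  base <- log(p0 / (1 - p0))
  f <- rep(base, nrow(x))
  trees <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    p <- stats::plogis(f)
    g <- p - y
    h <- pmax(p * (1 - p), 1e-12)
    tr <- .gbt_tree(x, g, h, max_depth, lambda, min_child_weight)
    trees[[t]] <- tr
    f <- f + learning_rate * .gbt_tree_predict(tr, x)
  }
  structure(list(trees = trees, base = base, learning_rate = learning_rate,
                 n_features = ncol(x), feature_names = colnames(x)),
            class = "gbt_model")
}

#' Predict from a gradient-boosted tree model
#'
#' @param object a `gbt_model` from [gbt_fit()].
#' @param newdata feature matrix with the training columns.
#' @param type `"prob"` for class-1 probabilities, `"link"` for log-odds.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.gbt_model <- function(object, newdata, type = c("prob", "link"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  if (!is.null(object$feature_names)) {
    x <- x[, object$feature_names, drop = FALSE]
  }
  f <- rep(object$base, nrow(x))
  for (tr in object$trees) {
    f <- f + object$learning_rate * .gbt_tree_predict(tr, x)
  }
  if (type == "link") f else stats::plogis(f)
}
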