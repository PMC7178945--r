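# Gradient boosting machine for the stacking meta-classifier.
#
# Bernoulli deviance, shallow regression trees, Newton leaf estimates
# (sum of residuals / sum of p(1-p)), constant shrinkage, no subsampling --
# fully deterministic. The meta-features are six binary votes, so trees of
# interaction depth 1-3 suffice; split candidates are midpoints of the
# observed feature values and ties go to the first (leftmost) feature.

# Recursive least-squares tree on residuals r with Newton weights w.
fit_gbm_tree <- function(X, r, w, depth, min_obs = 5L) {
  leaf_value <- function(rows) {
    sw <- sum(w[rows])
    if (sw < 1e-12) 0 else sum(r[rows]) / sw
  }
  grow <- function(rows, d) {
    if (d <= 0L || length(rows) < 2L * min_obs) {
      return(list(leaf = TRUE, value = leaf_value(rows)))
    }
    best <- NULL
    base_sse <- {
      mu <- mean(r[rows]); sum((r[rows] - mu)^2)
    }
    for (j in seq_len(ncol(X))) {
      v <- X[rows, j]
      cuts <- sort(unique(v))
      if (length(cuts) < 2L) next
      thresholds <- (cuts[-1] + cuts[-length(cuts)]) / 2
      for (th in thresholds) {
        left <- v < th
        nl <- sum(left)
        if (nl < min_obs || (length(rows) - nl) < min_obs) next
        rl <- r[rows][left]; rr <- r[rows][!left]
        sse <- sum((rl - mean(rl))^2) + sum((rr - mean(rr))^2)
        gain <- base_sse - sse
        if (gain > 1e-12 && (is.null(best) || gain > best$gain + 1e-12)) {
          best <- list(gain = gain, feature = j, threshold = th, left = left)
        }
      }
    }
    if (is.null(best)) return(list(leaf = TRUE, value = leaf_value(rows)))
    list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
         left = grow(rows[best$left], d - 1L),
         right = grow(rows[!best$left], d - 1L))
  }
  grow(seq_len(nrow(X)), depth)
}

predict_gbm_tree <- function(tree, X) {
  out <- numeric(nrow(X))
  walk <- function(node, rows) {
    if (!length(rows)) return()
    if (node$leaf) { out[rows] <<- node$value; return() }
    left <- X[rows, node$feature] < node$threshold
    walk(node$left, rows[left])
    walk(node$right, rows[!left])
  }
  walk(tree, seq_len(nrow(X)))
  out
}

#' Fit a gradient-boosting classifier
#'
#' @param X Numeric feature matrix.
#' @param y01 Binary response (0/1); 1 is the positive (`T`) class.
#' @param n_trees Number of boosting iterations.
#' @param depth Interaction depth of each tree.
#' @param shrinkage Learning rate.
#' @param min_obs Minimum observations per leaf.
#' @return Object of class `gbm_model` supporting staged prediction.
#' @export
gbm_fit <- function(X, y01, n_trees = 100L, depth = 2L, shrinkage = 0.1,
                    min_obs = 5L) {
  stopifnot(is.matrix(X), nrow(X) == length(y01), all(y01 %in% c(0, 1)))
  p0 <- min(max(mean(y01), 1e-6), 1 - 1e-6)
  F0 <- log(p0 / (1 - p0))
  Fx <- rep(F0, nrow(X))
  trees <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    p <- stats::plogis(Fx)
    tree <- fit_gbm_tree(X, r = y01 - p, w = p * (1 - p), depth = depth,
                         min_obs = min_obs)
    trees[[t]] <- tree
    Fx <- Fx + shrinkage * predict_gbm_tree(tree, X)
  }
  structure(list(F0 = F0, trees = trees, shrinkage = shrinkage, depth = depth,
                 n_trees = n_trees, schema = colnames(X)),
            class = "gbm_model")
}

#' Predict with a gradient-boosting classifier
#'
#' @param object A `gbm_model`.
#' @param newdata Feature matrix; columns must match the training schema in
#'   the same order (permuted or renamed columns are rejected).
#' @param n_trees Use only the first `n_trees` trees (staged prediction).
#' @param type `"label"`, `"prob"` or `"link"`.
#' @param ... Unused.
#' @return Labels (`"T"`/`"NT"`), probabilities of `T`, or additive scores.
#' @export
predict.gbm_model <- function(object, newdata, n_trees = NULL,
                              type = c("label", "prob", "link"), ...) {
  type <- match.arg(type)
  stopifnot(is.matrix(newdata))
  if (!is.null(object$schema) && !identical(colnames(newdata), object$schema)) {
    stop("meta-feature columns do not match the trained schema (order matters); ",
         "expected: ", paste(object$schema, collapse = ", "))
  }
  n_trees <- n_trees %||% object$n_trees
  Fx <- rep(object$F0, nrow(newdata))
  for (t in seq_len(n_trees)) {
    Fx <- Fx + object$shrinkage * predict_gbm_tree(object$trees[[t]], newdata)
  }
  switch(type,
    link = Fx,
    prob = stats::plogis(Fx),
    label = ifelse(stats::plogis(Fx) >= 0.5, "T", "NT"))
}

# Inner-CV selection of (n_trees, depth) by accuracy; ties prefer fewer
# trees, then shallower trees. Staged prediction makes the tree-count scan
# nearly free.
gbm_cv_select <- function(X, y01, trees_grid = c(50L, 100L, 150L),
                          depth_grid = 1:3, shrinkage = 0.1, k = 5L, seed = 1L) {
  labels <- ifelse(y01 == 1, "T", "NT")
  k <- min(k, min(table(labels)))
  if (k < 2L) {
    sel <- list(n_trees = max(trees_grid), depth = depth_grid[[1]])
  } else {
    folds <- stratified_folds(labels, k, seed)
    acc <- matrix(0, nrow = length(trees_grid), ncol = length(depth_grid))
    for (fold in seq_len(k)) {
      te <- folds == fold
      for (di in seq_along(depth_grid)) {
        fit <- gbm_fit(X[!te, , drop = FALSE], y01[!te],
                       n_trees = max(trees_grid), depth = depth_grid[di],
                       shrinkage = shrinkage)
        for (ti in seq_along(trees_grid)) {
          pred <- predict(fit, X[te, , drop = FALSE], n_trees = trees_grid[ti])
          acc[ti, di] <- acc[ti, di] + sum(pred == labels[te])
        }
      }
    }
    idx <- which(acc == max(acc), arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1, ]
    sel <- list(n_trees = trees_grid[idx[1]], depth = depth_grid[idx[2]],
                cv_accuracy = max(acc) / length(y01))
  }
  model <- gbm_fit(X, y01, n_trees = sel$n_trees, depth = sel$depth,
                   shrinkage = shrinkage)
  model$selected <- sel
  model
}
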