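# RBF-kernel SVM base classifiers on composition features.
#
# The quadratic dual is solved by a deterministic SMO (src/smo.cpp) on a
# precomputed kernel matrix; grid search reuses one squared-distance matrix
# per fold, so scanning gamma costs one exponential per kernel entry and
# scanning C only re-runs the solver. Composition features already share the
# [0, 1] scale, so no additional feature scaling is applied.

#' Default hyperparameter grids for the RBF-kernel SVM
#'
#' `C` in 2^(-5), 2^(-3), ..., 2^15 and `gamma` in 2^(-15), 2^(-13), ...,
#' 2^3, the customary log2 lattice for RBF grid search.
#'
#' @return List with numeric vectors `C` and `gamma`.
#' @export
default_svm_grid <- function() {
  list(C = 2 ^ seq(-5, 15, by = 2), gamma = 2 ^ seq(-15, 3, by = 2))
}

# Squared Euclidean distances between the rows of X and Y.
sq_dist <- function(X, Y) {
  d2 <- outer(rowSums(X^2), rowSums(Y^2), `+`) - 2 * tcrossprod(X, Y)
  d2[d2 < 0] <- 0
  d2
}

# Fit a C-SVC with RBF kernel at fixed hyperparameters; y is a factor with
# levels NT/T (T is the positive class, mapped to +1).
svm_rbf_fit <- function(x, y, C, gamma) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  y <- factor(as.character(y), levels = c("NT", "T"))
  if (anyNA(y)) stop("labels must be 'T' or 'NT'")
  if (nlevels(droplevels(y)) < 2L) stop("training data must contain both classes")
  yi <- ifelse(y == "T", 1L, -1L)
  K <- exp(-gamma * sq_dist(x, x))
  fit <- smo_train(K, yi, C)
  structure(list(X = x, y = yi, alpha = fit$alpha, b = fit$b,
                 C = C, gamma = gamma, schema = colnames(x),
                 iterations = fit$iterations),
            class = "psi_svm")
}

# Decision values for new rows (positive => T).
svm_decision <- function(object, newx) {
  K <- exp(-object$gamma * sq_dist(newx, object$X))
  as.vector(K %*% (object$alpha * object$y) + object$b)
}

#' Train an RBF-kernel SVM with grid search
#'
#' Selects the `(C, gamma)` pair maximizing mean stratified k-fold
#' cross-validation accuracy (ties broken by smaller `C`, then smaller
#' `gamma`), then refits on all rows.
#'
#' @param x Numeric feature matrix; rows are instances, rownames are ids.
#' @param y Labels (`"T"`/`"NT"`), factor or character.
#' @param grid List with components `C` and `gamma`
#'   (default [default_svm_grid()]).
#' @param k Inner cross-validation folds (default 5).
#' @param seed Seed fixing the fold plan.
#' @return Object of class `psi_svm` carrying the fitted dual coefficients,
#'   the selected hyperparameters, the column schema, the full CV grid
#'   (`$cv`), and the seed.
#' @export
grid_search_train <- function(x, y, grid = default_svm_grid(), k = 5L, seed = 1L) {
  stopifnot(is.matrix(x))
  y <- factor(as.character(y), levels = c("NT", "T"))
  if (anyNA(y)) stop("labels must be 'T' or 'NT'")
  counts <- table(droplevels(y))
  if (length(counts) < 2L) stop("training data must contain both classes")
  if (any(counts < 2L)) stop("need at least 2 examples per class")
  if (!length(grid$C) || !length(grid$gamma)) stop("hyperparameter grid is empty")
  k <- as.integer(k)
  if (k > min(counts)) {
    stop("k = ", k, " exceeds the smallest class count (", min(counts), ")")
  }

  folds <- stratified_folds(y, k, seed)
  yi <- ifelse(y == "T", 1L, -1L)
  grid_df <- expand.grid(C = grid$C, gamma = grid$gamma, KEEP.OUT.ATTRS = FALSE)
  correct <- numeric(nrow(grid_df))

  for (fold in seq_len(k)) {
    te <- folds == fold
    Dtr <- sq_dist(x[!te, , drop = FALSE], x[!te, , drop = FALSE])
    Dte <- sq_dist(x[te, , drop = FALSE], x[!te, , drop = FALSE])
    ytr <- yi[!te]
    for (g in grid$gamma) {
      Ktr <- exp(-g * Dtr)
      Kte <- exp(-g * Dte)
      for (ci in seq_along(grid$C)) {
        fit <- smo_train(Ktr, ytr, grid$C[ci])
        dec <- as.vector(Kte %*% (fit$alpha * ytr) + fit$b)
        row <- which(grid_df$gamma == g)[ci]
        correct[row] <- correct[row] + sum((dec >= 0) == (yi[te] == 1L))
      }
    }
  }
  grid_df$cv_accuracy <- correct / length(y)
  best <- order(-grid_df$cv_accuracy, grid_df$C, grid_df$gamma)[1]

  model <- svm_rbf_fit(x, y, C = grid_df$C[best], gamma = grid_df$gamma[best])
  model$cv <- grid_df
  model$cv_accuracy <- grid_df$cv_accuracy[best]
  model$k <- k
  model$seed <- seed
  model
}

#' Predict labels with a fitted SVM
#'
#' @param object A `psi_svm` from [grid_search_train()].
#' @param newdata Feature matrix whose columns match the training schema
#'   (order-insensitive; mismatches are an error listing missing and extra
#'   columns).
#' @param type `"label"` for `T`/`NT`, `"decision"` for raw decision values.
#' @param ... Unused.
#' @return Character vector of labels (or numeric decision values), named by
#'   rownames of `newdata`.
#' @export
predict.psi_svm <- function(object, newdata, type = c("label", "decision"), ...) {
  type <- match.arg(type)
  stopifnot(is.matrix(newdata))
  if (!is.null(object$schema)) {
    missing_cols <- setdiff(object$schema, colnames(newdata))
    extra_cols <- setdiff(colnames(newdata), object$schema)
    if (length(missing_cols) || length(extra_cols)) {
      stop("feature schema mismatch; missing: [",
           paste(missing_cols, collapse = ", "), "], extra: [",
           paste(extra_cols, collapse = ", "), "]")
    }
    newdata <- newdata[, object$schema, drop = FALSE]
  }
  if (nrow(newdata) == 0L) {
    return(if (type == "label") character(0) else numeric(0))
  }
  dec <- svm_decision(object, newdata)
  names(dec) <- rownames(newdata)
  if (type == "decision") dec else {
    stats::setNames(ifelse(dec >= 0, "T", "NT"), rownames(newdata))
  }
}

#' @export
print.psi_svm <- function(x, ...) {
  cat(sprintf("<psi_svm> C=%g gamma=%g, %d training rows, %d SV, CV accuracy %.4f\n",
              x$C, x$gamma, nrow(x$X), sum(x$alpha > 1e-8),
              x$cv_accuracy %||% NA_real_))
  invisible(x)
}
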