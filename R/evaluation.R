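# Evaluation: confusion matrices, the four headline metrics (sensitivity,
# specificity, accuracy, MCC), repeated stratified cross-validation with
# mean +/- sd reporting, reconstruction of confusion matrices from printed
# rates, and inter-classifier Pearson correlation.

#' Construct a confusion matrix
#'
#' Counts may be non-integer: rate-implied matrices (see
#' [confusion_from_rates()] in `"exact"` mode) are supported.
#'
#' @param TP,FP,FN,TN Non-negative counts; the total must be positive.
#' @return Object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(TP, FP, FN, TN) {
  vals <- c(TP = TP, FP = FP, FN = FN, TN = TN)
  if (any(!is.finite(vals)) || any(vals < 0)) stop("confusion counts must be non-negative")
  if (sum(vals) <= 0) stop("confusion matrix total must be positive")
  structure(as.list(vals), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), nrow = 2,
              dimnames = list(truth = c("T", "NT"), predicted = c("T", "NT")))
  print(m)
  invisible(x)
}

#' Confusion matrix from predicted and true labels
#'
#' @param predicted,truth Vectors of `"T"`/`"NT"` labels; `T` is positive.
#' @return A [confusion_matrix].
#' @export
confusion_from_predictions <- function(predicted, truth) {
  predicted <- as.character(predicted)
  truth <- as.character(truth)
  stopifnot(length(predicted) == length(truth))
  confusion_matrix(TP = sum(predicted == "T" & truth == "T"),
                   FP = sum(predicted == "T" & truth == "NT"),
                   FN = sum(predicted == "NT" & truth == "T"),
                   TN = sum(predicted == "NT" & truth == "NT"))
}

#' Sensitivity, specificity, accuracy and MCC from a confusion matrix
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)` and accuracy
#' `(TP+TN)/total` are reported in percent; the Matthews correlation
#' coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))` is in \[-1, 1\]
#' and defined as 0 when its denominator vanishes (the "no better than
#' random" convention). A rate whose own denominator is zero is `NaN`.
#'
#' @param cm A [confusion_matrix].
#' @return Object of class `metrics_report` with fields `sensitivity`,
#'   `specificity`, `accuracy` (percent), `mcc`, and `cm`.
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  TP <- cm$TP; FP <- cm$FP; FN <- cm$FN; TN <- cm$TN
  rate <- function(num, den) if (den > 0) 100 * num / den else NaN
  denom2 <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (denom2 > 0) (TP * TN - FP * FN) / sqrt(denom2) else 0
  structure(list(sensitivity = rate(TP, TP + FN),
                 specificity = rate(TN, TN + FP),
                 accuracy = rate(TP + TN, TP + FP + FN + TN),
                 mcc = mcc, cm = cm),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("sensitivity %.2f%%  specificity %.2f%%  accuracy %.2f%%  MCC %.4f\n",
              x$sensitivity, x$specificity, x$accuracy, x$mcc))
  invisible(x)
}

#' Reconstruct a confusion matrix from printed rates
#'
#' Inverts the sensitivity/specificity definitions given the class sizes:
#' `TP = sens * n_pos / 100` (rounded to the nearest integer in `"integer"`
#' mode), `FN = n_pos - TP`, and analogously for `TN`/`FP`. Used to recompute
#' accuracy and MCC from published tables.
#'
#' @param sensitivity,specificity Rates in percent, in \[0, 100\].
#' @param n_pos,n_neg Class sizes (positives, negatives).
#' @param rounding `"integer"` (default) or `"exact"`.
#' @return A [confusion_matrix].
#' @export
confusion_from_rates <- function(sensitivity, specificity, n_pos, n_neg,
                                 rounding = c("integer", "exact")) {
  rounding <- match.arg(rounding)
  stopifnot(sensitivity >= 0, sensitivity <= 100,
            specificity >= 0, specificity <= 100, n_pos >= 0, n_neg >= 0)
  TP <- sensitivity * n_pos / 100
  TN <- specificity * n_neg / 100
  if (rounding == "integer") { TP <- round(TP); TN <- round(TN) }
  confusion_matrix(TP = TP, FP = n_neg - TN, FN = n_pos - TP, TN = TN)
}

#' Repeated stratified k-fold cross-validation
#'
#' For each repeat, a fresh stratified partition is drawn; per fold the
#' learner is fitted on the training folds and applied to the held-out fold;
#' the repeat's metrics are computed from the confusion counts pooled across
#' its k folds (pooling is stable for small folds and makes the result
#' invariant to fold order). The report gives mean and standard deviation of
#' each metric over repeats.
#'
#' @param x Feature matrix (rows = instances).
#' @param labels `"T"`/`"NT"` labels per row.
#' @param fit Function `(x, labels) -> model`.
#' @param predict_fun Function `(model, x) -> labels`
#'   (default [predict()]).
#' @param k Folds per repeat (default 10).
#' @param repeats Number of repeated partitions (default 10).
#' @param seed Master seed; each repeat gets a derived sub-seed.
#' @return Object of class `repeated_cv_report`: `mean`, `sd`, `per_repeat`
#'   (list of [compute_metrics()] reports), `k`, `repeats`, `seed`.
#' @export
repeated_cv <- function(x, labels, fit, predict_fun = function(m, d) predict(m, d),
                        k = 10L, repeats = 10L, seed = 1L) {
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels), repeats >= 1L)
  seeds <- derive_seeds(seed, repeats)
  per_repeat <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    folds <- stratified_folds(labels, k, seeds[r])   # errors if class < k
    counts <- c(TP = 0, FP = 0, FN = 0, TN = 0)
    for (fold in seq_len(k)) {
      te <- folds == fold
      model <- fit(x[!te, , drop = FALSE], labels[!te])
      pred <- as.character(predict_fun(model, x[te, , drop = FALSE]))
      counts <- counts + c(TP = sum(pred == "T" & labels[te] == "T"),
                           FP = sum(pred == "T" & labels[te] == "NT"),
                           FN = sum(pred == "NT" & labels[te] == "T"),
                           TN = sum(pred == "NT" & labels[te] == "NT"))
    }
    per_repeat[[r]] <- compute_metrics(confusion_matrix(counts[["TP"]], counts[["FP"]],
                                                        counts[["FN"]], counts[["TN"]]))
  }
  metric_names <- c("sensitivity", "specificity", "accuracy", "mcc")
  values <- sapply(metric_names, function(m) {
    vapply(per_repeat, `[[`, numeric(1), m)
  })
  values <- matrix(values, nrow = repeats,
                   dimnames = list(NULL, metric_names))
  structure(list(mean = colMeans(values),
                 sd = apply(values, 2, stats::sd),
                 per_repeat = per_repeat, k = k, repeats = repeats,
                 seed = seed, seeds = seeds),
            class = "repeated_cv_report")
}

#' @export
print.repeated_cv_report <- function(x, ...) {
  cat(sprintf("%d x %d-fold cross-validation (seed %d)\n", x$repeats, x$k, x$seed))
  for (m in names(x$mean)) {
    unit <- if (m == "mcc") "" else "%"
    cat(sprintf("  %-12s %.2f%s +/- %.2f\n", m, x$mean[[m]], unit,
                if (x$repeats > 1) x$sd[[m]] else 0))
  }
  invisible(x)
}

#' Pearson correlation between base-classifier prediction columns
#'
#' @param meta Meta dataset from [generate_meta_features()] (its `id`/`label`
#'   columns are ignored) or any numeric matrix of 0/1 votes.
#' @return Symmetric correlation matrix with unit diagonal; entries involving
#'   a constant column are `NA` and such columns are listed in the
#'   `constant_columns` attribute (with a warning).
#' @export
prediction_correlation <- function(meta) {
  if (is.data.frame(meta)) {
    meta <- meta[, setdiff(names(meta), c("id", "label")), drop = FALSE]
  }
  X <- as.matrix(meta)
  if (nrow(X) < 2L) stop("need at least 2 rows to correlate predictions")
  storage.mode(X) <- "double"
  const <- apply(X, 2, function(col) stats::sd(col) == 0)
  C <- suppressWarnings(stats::cor(X))
  diag(C) <- 1
  if (any(const)) {
    warning("constant prediction column(s): ",
            paste(colnames(X)[const], collapse = ", "))
  }
  attr(C, "constant_columns") <- colnames(X)[const]
  C
}
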