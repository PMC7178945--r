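toy_dataset <- function(n_T, n_NT, seed = 1L, L = 40L) {
  seqs <- make_sequences(n_T + n_NT, L = L, seed = seed)
  labeled_dataset(seqs, rep(c("T", "NT"), c(n_T, n_NT)))
}

test_that("rule base classifiers yield fold-independent meta columns", {
  data <- toy_dataset(6, 6, seed = 91)
  set.seed(92)
  preds <- stats::setNames(sample(c("T", "NT"), 12, replace = TRUE), data$ids)
  specs <- list(rule1 = transpred:::rule_spec(preds))
  m1 <- generate_meta_features(data, specs, k = 2, seed = 1)
  m2 <- generate_meta_features(data, specs, k = 3, seed = 99)
  expect_identical(m1$rule1, m2$rule1)
  expect_identical(m1$rule1, unname(ifelse(preds[data$ids] == "T", 1L, 0L)))
})

test_that("k = n meta generation is leave-one-out for a majority learner", {
  data <- toy_dataset(5, 4, seed = 93)
  majority <- transpred:::trainable_spec(
    features = matrix(0, 9, 1, dimnames = list(data$ids, "z")),
    fit = function(X, y) if (sum(y == "T") > sum(y == "NT")) "T" else "NT",
    predict_fun = function(model, X) rep(model, nrow(X)))
  meta <- generate_meta_features(data, list(maj = majority), k = 9, seed = 1)
  # removing a T leaves a 4/4 tie -> NT; removing an NT leaves 5/3 -> T
  expect_identical(meta$maj, ifelse(as.character(data$labels) == "T", 0L, 1L))
})

test_that("meta-features are never produced by a model trained on the instance", {
  data <- toy_dataset(10, 10, seed = 94)
  feats <- matrix(runif(20 * 3), 20, 3,
                  dimnames = list(data$ids, paste0("f", 1:3)))
  memorizing <- transpred:::trainable_spec(
    features = feats,
    fit = function(X, y) rownames(X),
    predict_fun = function(model, X) {
      leaked <- intersect(rownames(X), model)
      if (length(leaked)) stop("leakage: ", paste(leaked, collapse = ","))
      rep("T", nrow(X))
    })
  expect_no_error(meta <- generate_meta_features(data, list(mem = memorizing),
                                                 k = 5, seed = 7))
  folds <- attr(meta, "folds")
  expect_identical(sort(unique(folds)), 1:5)
  expect_identical(names(meta), c("id", "mem", "label"))
})

test_that("meta dataset shape and class-count guard match the contract", {
  data <- toy_dataset(6, 6, seed = 95)
  specs <- stats::setNames(
    lapply(1:6, function(i) {
      transpred:::rule_spec(stats::setNames(rep("T", 12), data$ids))
    }),
    transpred:::META_COLUMNS)
  meta <- generate_meta_features(data, specs, k = 3, seed = 1)
  expect_identical(dim(meta), c(12L, 8L))  # id + 6 votes + label
  expect_identical(names(meta), c("id", transpred:::META_COLUMNS, "label"))
  expect_error(generate_meta_features(data, specs, k = 7, seed = 1),
               "smaller than the number of folds")
})

test_that("one perfect base among noise: ensemble tracks the perfect base", {
  n <- 60
  data <- toy_dataset(n / 2, n / 2, seed = 96)
  truth <- as.character(data$labels)
  set.seed(97)
  specs <- c(list(perfect = transpred:::rule_spec(stats::setNames(truth, data$ids))),
             lapply(1:5, function(i) {
               transpred:::rule_spec(stats::setNames(
                 sample(c("T", "NT"), n, replace = TRUE), data$ids))
             }))
  names(specs) <- c("perfect", paste0("noise", 1:5))
  meta <- generate_meta_features(data, specs, k = 10, seed = 5)
  X <- as.matrix(meta[, names(specs)])
  gbm <- transpred:::gbm_cv_select(X, meta$label, seed = 6)

  # held-out instances under the same generating scheme
  set.seed(98)
  truth_new <- sample(c("T", "NT"), 40, replace = TRUE)
  X_new <- cbind(perfect = ifelse(truth_new == "T", 1L, 0L),
                 matrix(rbinom(40 * 5, 1, 0.5), 40, 5,
                        dimnames = list(NULL, paste0("noise", 1:5))))
  acc_ens <- mean(predict(gbm, X_new) == truth_new)
  acc_noise <- apply(X_new[, -1], 2, function(col) {
    mean(ifelse(col == 1, "T", "NT") == truth_new)
  })
  expect_gte(acc_ens, 1.0 - 0.01)        # within 1 point of the perfect base
  expect_gte(acc_ens, max(acc_noise))
})

test_that("a meta-model trained on unanimity follows a unanimous vote", {
  cols <- transpred:::META_COLUMNS
  set.seed(99)
  X <- matrix(rbinom(200 * 6, 1, 0.5), 200, 6, dimnames = list(NULL, cols))
  y <- as.integer(rowSums(X) == 6)       # unanimous T => T
  X <- rbind(X, matrix(1L, 20, 6, dimnames = list(NULL, cols)))
  y <- c(y, rep(1L, 20))
  gbm <- gbm_fit(X, y, n_trees = 60, depth = 3)
  model <- structure(list(gbm = gbm, columns = cols), class = "stacking_model")
  unanimous <- matrix(1L, 1, 6, dimnames = list(NULL, cols))
  expect_identical(unname(predict_meta(model, unanimous)), "T")
  expect_error(predict_meta(model, unanimous[, rev(cols), drop = FALSE]),
               "in that order")
})

test_that("train/predict stacking works end to end on a small fixture", {
  fx_train <- make_pipeline_fixture(20, seed = 4001)
  fx_test <- make_pipeline_fixture(10, seed = 4002)
  model <- train_stacking(fx_train$data, small_stacking_config(fx_train, seed = 11))

  report <- predict_stacking(model, fx_test$data, fx_test$homolog_provider,
                             fx_test$hits_provider)
  expect_identical(names(report), c("id", transpred:::META_COLUMNS, "final"))
  expect_identical(nrow(report), 20L)
  truth <- stats::setNames(as.character(fx_test$data$labels), fx_test$data$ids)
  expect_gte(mean(report$final == truth[report$id]), 0.9)

  # repeated prediction is identical
  report2 <- predict_stacking(model, fx_test$data, fx_test$homolog_provider,
                              fx_test$hits_provider)
  expect_identical(report, report2)
})

test_that("training is deterministic under a fixed master seed", {
  fx <- make_pipeline_fixture(12, seed = 4003)
  m1 <- train_stacking(fx$data, small_stacking_config(fx, seed = 21))
  m2 <- train_stacking(fx$data, small_stacking_config(fx, seed = 21))
  expect_identical(serialize(m1, NULL), serialize(m2, NULL))
})

test_that("model bundles round-trip and queries with no artifacts degrade gracefully", {
  fx <- make_pipeline_fixture(12, seed = 4004)
  model <- train_stacking(fx$data, small_stacking_config(fx, seed = 31))
  path <- tempfile(fileext = ".rds")
  save_stacking_model(model, path)
  back <- load_stacking_model(path)
  expect_identical(serialize(back, NULL), serialize(model, NULL))
  expect_error(load_stacking_model(tempfile()), "not found")

  # zero homologs and zero hits: bases fall back to plain compositions / NT
  lone <- protein_sequence("orphan", random_residues(150, seed = 4005))
  empty_aln <- fx$aln[0, ]
  empty_hits <- fx$hits[0, ]
  report <- predict_stacking(model, lone,
                             homolog_provider_from_table(empty_aln),
                             hits_provider_from_table(empty_hits))
  expect_identical(nrow(report), 1L)
  expect_identical(report$TCDB_med, "NT")
  expect_true(report$final %in% c("T", "NT"))
})
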