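# Stacked generalization: six base classifiers (three psi-composition SVMs,
# three homology-transfer rules) feed hard {0,1} votes to a gradient-boosting
# meta-classifier.  Meta-training rows are generated by stratified k-fold
# cross-validation so that the vote for an instance always comes from a model
# that never saw it; rule classifiers do not train, so their columns are
# fold-independent direct predictions.

#' Canonical base-classifier specification table
#'
#' The six base classifiers of the ensemble in their fixed column order:
#' three SVMs on psi-compositions and three homology-transfer rules.
#'
#' @return Data frame with columns `name` and `family`.
#' @export
base_classifier_specs <- function() {
  data.frame(
    name = c("psiAAC", "psiPAAC", "psiPseAAC",
             "TCDB_exact", "TCDB_high", "TCDB_med"),
    family = c(rep("svm", 3), rep("homology-rule", 3)),
    stringsAsFactors = FALSE)
}

META_COLUMNS <- c("psiAAC", "psiPAAC", "psiPseAAC",
                  "TCDB_exact", "TCDB_high", "TCDB_med")

# A trainable spec for generate_meta_features(): features keyed by row, plus
# fit/predict closures.  Used for the SVM bases and for custom learners in
# property tests.
trainable_spec <- function(features, fit, predict_fun) {
  list(type = "trainable", features = features, fit = fit, predict = predict_fun)
}

# A rule spec: precomputed deterministic predictions keyed by id.
rule_spec <- function(predictions) {
  list(type = "rule", predictions = predictions)
}

#' Generate the meta-classifier training dataset
#'
#' Implements the cross-validated stacking construction: a stratified k-fold
#' partition of the training data; for each trainable spec, the prediction
#' for an instance is made by the model trained on the folds excluding it;
#' rule specs contribute their direct predictions unchanged. Labels are
#' encoded `NT = 0`, `T = 1`.
#'
#' @param data A [labeled_dataset].
#' @param specs Named list of specs. Each is either
#'   `list(type = "trainable", features = <matrix with id rownames>,`
#'   `fit = function(X, y) model, predict = function(model, X) labels)` or
#'   `list(type = "rule", predictions = <named "T"/"NT" vector>)`.
#' @param k Folds (default 10); every class must have at least `k` members.
#' @param seed Seed fixing the fold plan.
#' @return Data frame `id`, one 0/1 column per spec (in `specs` order),
#'   `label` (0/1); attribute `folds` records the fold of each row.
#' @export
generate_meta_features <- function(data, specs, k = 10L, seed = 1L) {
  stopifnot(inherits(data, "labeled_dataset"), length(specs) > 0)
  if (is.null(names(specs)) || any(!nzchar(names(specs)))) {
    stop("specs must be a named list")
  }
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  # k = n is honoured as leave-one-out (stratification is then meaningless);
  # otherwise the partition is stratified and every class needs >= k members.
  folds <- if (k == length(data)) seq_len(k) else stratified_folds(data$labels, k, seed)
  n <- length(data)
  meta <- matrix(NA_integer_, nrow = n, ncol = length(specs),
                 dimnames = list(data$ids, names(specs)))
  y_chr <- as.character(data$labels)

  for (s in seq_along(specs)) {
    spec <- specs[[s]]
    if (identical(spec$type, "rule")) {
      pred <- spec$predictions[data$ids]
      if (anyNA(pred)) stop("rule spec '", names(specs)[s], "' misses some ids")
      meta[, s] <- ifelse(pred == "T", 1L, 0L)
    } else if (identical(spec$type, "trainable")) {
      feats <- spec$features
      if (!all(data$ids %in% rownames(feats))) {
        stop("feature rows missing for spec '", names(specs)[s], "'")
      }
      feats <- feats[data$ids, , drop = FALSE]
      for (fold in seq_len(k)) {
        te <- folds == fold
        model <- spec$fit(feats[!te, , drop = FALSE], y_chr[!te])
        pred <- spec$predict(model, feats[te, , drop = FALSE])
        meta[te, s] <- ifelse(pred == "T", 1L, 0L)
      }
    } else {
      stop("unknown spec type for '", names(specs)[s], "'")
    }
  }
  out <- data.frame(id = data$ids, meta, label = ifelse(y_chr == "T", 1L, 0L),
                    stringsAsFactors = FALSE, check.names = FALSE)
  attr(out, "folds") <- folds
  attr(out, "seed") <- seed
  out
}

#' Stacking training configuration
#'
#' @param homolog_provider Function `(protein_sequence) -> homolog_set`
#'   supplying the psi-composition homologs (live search or fixture-backed;
#'   see [blast_backend_stub()] and [homolog_provider_from_table()]).
#' @param hits_provider Function `(id) -> blast_hits` supplying the
#'   transporter-database hits for the homology rules (see
#'   [hits_provider_from_table()]).
#' @param pseaac [pseaac_params()] used by the PseAAC descriptor.
#' @param svm_grid Hyperparameter grid for the base SVMs.
#' @param svm_cv_k Inner folds for SVM grid search (default 5).
#' @param meta_k Folds for meta-feature generation (default 10).
#' @param gbm_trees,gbm_depth,gbm_shrinkage Meta-learner grid (trees and
#'   interaction depth selected by inner 5-fold CV; fixed learning rate).
#' @param profiles Homology threshold profiles (default
#'   [builtin_profiles()]).
#' @param seed Master seed; every fold plan and learner seed derives from it.
#' @return List with class `stacking_config`.
#' @export
stacking_config <- function(homolog_provider, hits_provider,
                            pseaac = pseaac_params(),
                            svm_grid = default_svm_grid(), svm_cv_k = 5L,
                            meta_k = 10L,
                            gbm_trees = c(50L, 100L, 150L), gbm_depth = 1:3,
                            gbm_shrinkage = 0.1,
                            profiles = builtin_profiles(), seed = 1L) {
  stopifnot(is.function(homolog_provider), is.function(hits_provider))
  structure(list(homolog_provider = homolog_provider,
                 hits_provider = hits_provider, pseaac = pseaac,
                 svm_grid = svm_grid, svm_cv_k = as.integer(svm_cv_k),
                 meta_k = as.integer(meta_k), gbm_trees = gbm_trees,
                 gbm_depth = gbm_depth, gbm_shrinkage = gbm_shrinkage,
                 profiles = profiles, seed = as.integer(seed)),
            class = "stacking_config")
}

# Internal: the three psi feature matrices for a list of sequences.
stacking_features <- function(sequences, homolog_provider, pseaac) {
  hsets <- lapply(sequences, function(s) {
    tryCatch(homolog_provider(s),
             error = function(e) stop("psi-composition homolog retrieval failed for '",
                                      s$id, "': ", conditionMessage(e)))
  })
  list(psiAAC = psi_feature_matrix(hsets, "AAC"),
       psiPAAC = psi_feature_matrix(hsets, "PAAC"),
       psiPseAAC = psi_feature_matrix(hsets, "PseAAC", params = pseaac))
}

# Internal: homology-rule predictions (one named vector per profile).
stacking_rule_predictions <- function(ids, hits_provider, profiles) {
  hit_tables <- lapply(ids, function(id) {
    tryCatch(hits_provider(id),
             error = function(e) stop("homology hit retrieval failed for '", id,
                                      "': ", conditionMessage(e)))
  })
  names(hit_tables) <- ids
  lapply(profiles, function(pr) {
    vapply(ids, function(id) {
      predict_by_homology(hit_tables[[id]], pr, qseqid = id)$label
    }, character(1))
  })
}

#' Train the stacking ensemble
#'
#' Builds the three psi-composition feature matrices, grid-searches the SVM
#' hyperparameters per feature kind, generates meta-features by stratified
#' `meta_k`-fold cross-validation (SVM folds refit at the selected
#' hyperparameters; homology rules predicted directly), fits the
#' gradient-boosting meta-classifier on the meta dataset, and refits the
#' three SVMs on all training rows.
#'
#' @param data A [labeled_dataset] of training sequences.
#' @param config A [stacking_config()].
#' @return Object of class `stacking_model`: fitted base SVMs, threshold
#'   profiles, meta-classifier, meta dataset, column order, and seeds.
#' @export
train_stacking <- function(data, config) {
  stopifnot(inherits(data, "labeled_dataset"), inherits(config, "stacking_config"))
  seeds <- derive_seeds(config$seed, 5L)

  feats <- stacking_features(data$sequences, config$homolog_provider, config$pseaac)
  svms <- lapply(seq_along(feats), function(i) {
    grid_search_train(feats[[i]], data$labels, grid = config$svm_grid,
                      k = config$svm_cv_k, seed = seeds[i])
  })
  names(svms) <- names(feats)

  rules <- stacking_rule_predictions(data$ids, config$hits_provider, config$profiles)
  specs <- c(
    lapply(names(svms), function(nm) {
      model <- svms[[nm]]
      trainable_spec(feats[[nm]],
                     fit = function(X, y) svm_rbf_fit(X, y, C = model$C,
                                                      gamma = model$gamma),
                     predict_fun = function(m, X) predict(m, X))
    }),
    lapply(rules, rule_spec)
  )
  names(specs) <- c(names(svms), names(rules))
  specs <- specs[META_COLUMNS]

  meta <- generate_meta_features(data, specs, k = config$meta_k, seed = seeds[4])
  meta_x <- as.matrix(meta[, META_COLUMNS, drop = FALSE])
  gbm <- gbm_cv_select(meta_x, meta$label, trees_grid = config$gbm_trees,
                       depth_grid = config$gbm_depth,
                       shrinkage = config$gbm_shrinkage, seed = seeds[5])

  structure(list(svms = svms, profiles = config$profiles, gbm = gbm,
                 meta = meta, columns = META_COLUMNS,
                 pseaac = config$pseaac, seed = config$seed,
                 fold_seed = seeds[4], version = "1"),
            class = "stacking_model")
}

#' @export
print.stacking_model <- function(x, ...) {
  cat(sprintf("<stacking_model> %d base classifiers + GBM(trees=%d, depth=%d), seed=%d\n",
              length(x$columns), x$gbm$n_trees, x$gbm$depth, x$seed))
  invisible(x)
}

#' Meta-classifier prediction from base votes
#'
#' Rejects inputs whose columns are missing, renamed or permuted relative to
#' the canonical order the model was trained with.
#'
#' @param model A `stacking_model`.
#' @param meta Data frame or matrix of 0/1 base votes with the model's column
#'   order.
#' @return Character vector of final labels.
#' @export
predict_meta <- function(model, meta) {
  meta_x <- as.matrix(meta[, , drop = FALSE])
  if (!identical(colnames(meta_x), model$columns)) {
    stop("meta input columns must be exactly [",
         paste(model$columns, collapse = ", "), "] in that order")
  }
  predict(model$gbm, meta_x)
}

#' Predict with the stacking ensemble
#'
#' For every query: collect homologs and compute the three psi-composition
#' vectors (three SVM votes), fetch transporter-database hits and apply the
#' three threshold profiles (three rule votes), then feed the six 0/1 votes
#' to the meta-classifier.
#'
#' @param model A `stacking_model`.
#' @param sequences A [protein_sequence], list thereof, or [labeled_dataset].
#' @param homolog_provider,hits_provider As in [stacking_config()].
#' @return Prediction report: data frame `id`, six base label columns, and
#'   `final`.
#' @export
predict_stacking <- function(model, sequences, homolog_provider, hits_provider) {
  stopifnot(inherits(model, "stacking_model"))
  if (inherits(sequences, "protein_sequence")) sequences <- list(sequences)
  if (inherits(sequences, "labeled_dataset")) sequences <- sequences$sequences
  ids <- vapply(sequences, `[[`, character(1), "id")

  feats <- stacking_features(sequences, homolog_provider, model$pseaac)
  svm_votes <- lapply(names(model$svms), function(nm) {
    unname(predict(model$svms[[nm]], feats[[nm]]))
  })
  names(svm_votes) <- names(model$svms)
  rule_votes <- stacking_rule_predictions(ids, hits_provider, model$profiles)

  votes <- c(svm_votes, lapply(rule_votes, unname))[model$columns]
  meta_x <- do.call(cbind, lapply(votes, function(v) ifelse(v == "T", 1L, 0L)))
  colnames(meta_x) <- model$columns
  final <- predict_meta(model, meta_x)

  out <- data.frame(id = ids, stringsAsFactors = FALSE)
  for (nm in model$columns) out[[nm]] <- votes[[nm]]
  out$final <- final
  out
}

#' Save / load a stacking model bundle
#'
#' The bundle is a single serialized archive holding the bases, the
#' meta-classifier, the seeds and the column schema, version-stamped.
#'
#' @param model A `stacking_model`.
#' @param path Bundle path.
#' @return `path` (save) or the restored `stacking_model` (load).
#' @export
save_stacking_model <- function(model, path) {
  stopifnot(inherits(model, "stacking_model"))
  saveRDS(list(format = "transpred_stacking_bundle", format_version = 1L,
               package_version = as.character(utils::packageVersion("transpred")),
               model = model),
          path)
  invisible(path)
}

#' @rdname save_stacking_model
#' @export
load_stacking_model <- function(path) {
  if (!file.exists(path)) stop("model bundle not found: ", path)
  bundle <- readRDS(path)
  if (!identical(bundle$format, "transpred_stacking_bundle")) {
    stop("not a stacking model bundle: ", path)
  }
  bundle$model
}

#' Build a homolog provider from an alignment fixture table
#'
#' @param aln Data frame or file in the `ALN_COLUMNS` dialect.
#' @param config Optional [search_config()] template (cutoff, self-exclusion).
#' @return Function `(protein_sequence) -> homolog_set`.
#' @export
homolog_provider_from_table <- function(aln, config = NULL) {
  backend <- blast_backend_stub(aln)
  base <- config %||% search_config(mode = "psi", backend = backend)
  base$backend <- backend
  function(query) collect_homologs(query, base)
}

#' Build a hits provider from a 12-column hit table
#'
#' @param hits Data frame of hits or a path parsed by
#'   [parse_blast_tabular()].
#' @return Function `(id) -> blast_hits` rows for that query.
#' @export
hits_provider_from_table <- function(hits) {
  if (is.character(hits)) hits <- parse_blast_tabular(hits)
  force(hits)
  function(id) hits[hits$qseqid == id, , drop = FALSE]
}
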