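#' Construct a labeled dataset
#'
#' Subjects-by-features matrix with binary labels.  The package's label
#' coding is `0` = healthy control, `1` = patient.
#'
#' @param X Numeric matrix, subjects in rows.
#' @param y Binary labels of length `nrow(X)`; both classes must be present.
#' @param feature_names Optional character vector of length `ncol(X)`.
#' @param subject_ids Optional character vector of length `nrow(X)`.
#' @return An object of class `labeled_dataset` with `X`, `y`,
#'   `feature_names`, `subject_ids`.
#' @export
labeled_dataset <- function(X, y, feature_names = colnames(X),
                            subject_ids = rownames(X)) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("rows(X) must equal length(y)")
  if (length(unique(y)) != 2L) stop("both classes must be present")
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(ncol(X)))
  if (is.null(subject_ids)) subject_ids <- paste0("s", seq_len(nrow(X)))
  structure(list(X = X, y = y,
                 feature_names = as.character(feature_names),
                 subject_ids = as.character(subject_ids)),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("<labeled_dataset> ", nrow(x$X), " subjects x ", ncol(x$X),
      " features; classes: ",
      paste(names(table(x$y)), table(x$y), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Seeded stratified fold assignment
#'
#' Partitions subjects into `nfolds` folds, stratified by class so each fold
#' holds (as nearly as possible) the overall class proportions.  The same
#' partition is reused for every (learner, feature set) pair within one
#' selection run, making cross-validation scores comparable across pairs.
#'
#' @param y Class labels.
#' @param nfolds Number of folds (default 5).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1:nfolds`, one per subject.
#' @export
make_folds <- function(y, nfolds = 5L, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[sample(idx)] <- rep_len(seq_len(nfolds), length(idx))
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  fold
}

# CV with optionally fold-specific feature sets (fs = list of per-fold
# index vectors, or one shared vector).
.cv_accuracies <- function(spec, X, y, fs, folds) {
  nf <- max(folds)
  acc <- numeric(nf)
  for (f in seq_len(nf)) {
    tr <- folds != f
    fsf <- if (is.list(fs)) fs[[f]] else fs
    if (length(unique(y[tr])) < 2L)
      stop("fold ", f, " training part lacks a class")
    pred <- fit_predict(spec, X[tr, fsf, drop = FALSE], y[tr],
                        X[!tr, fsf, drop = FALSE], seed = f)
    acc[f] <- 100 * mean(pred == y[!tr])
  }
  acc
}

#' Cross-validated accuracy of one learner on one feature set
#'
#' Runs stratified k-fold cross-validation of `spec` on the dataset
#' restricted to the feature indices `features`, returning the per-fold
#' accuracies together with their mean and range (max - min).  The fold
#' partition is seeded, so repeated calls with the same `seed` use identical
#' folds.
#'
#' @param spec A `learner_spec`.
#' @param dataset A [labeled_dataset()] with at least 10 subjects.
#' @param features Integer indices of the columns to use.
#' @param folds Optional precomputed fold vector (from [make_folds()]);
#'   computed from `seed` when omitted.
#' @param nfolds,seed Fold construction parameters when `folds` is `NULL`.
#' @return An object of class `cv_record` with `learner`, `fs_size`,
#'   `fold_accuracies`, `mean`, `range`.
#' @export
cross_validate <- function(spec, dataset, features, folds = NULL,
                           nfolds = 5L, seed = 1L) {
  stopifnot(inherits(dataset, "labeled_dataset"), length(features) >= 1L)
  if (nrow(dataset$X) < 10L) stop("too few subjects for cross-validation")
  if (is.null(folds)) folds <- make_folds(dataset$y, nfolds, seed)
  acc <- .cv_accuracies(spec, dataset$X, dataset$y, features, folds)
  structure(list(learner = spec$name, fs_size = length(features),
                 fold_accuracies = acc, mean = mean(acc),
                 range = max(acc) - min(acc)),
            class = "cv_record")
}

#' Select a base classifier and feature subset by incremental cross-validation
#'
#' For every learner in the bank, features are added one at a time in MRMR
#' order and the learner's 5-fold cross-validation accuracy is recorded at
#' each size `k`.  The incremental loop stops when no learner has improved
#' its best mean accuracy for `patience` consecutive feature additions (a
#' plateau criterion: CV curves are non-monotone, so a one-step test would
#' stop too early), or when `k_max` is reached.  Each learner is then scored
#' by its best mean accuracy over the visited sizes; the five learners with
#' the largest best means are retained, and among those five the learner
#' with the *smallest range* of fold accuracies wins -- the top means are
#' typically very close, so the spread over folds is the deciding stability
#' criterion.  The winner is refit on the full training set restricted to
#' its best feature set.
#'
#' The MRMR ranking is computed once on the full training set (so the CV
#' estimate shares the ranking across folds; the hold-out evaluation remains
#' untouched by any training-time decision).  Setting
#' `per_fold_ranking = TRUE` instead re-ranks features within each fold's
#' training part, removing selection leakage from the CV estimate at extra
#' cost; the final feature set still comes from the full-training ranking.
#'
#' @param dataset A [labeled_dataset()] of training subjects (N >= 10).
#' @param bank List of `learner_spec`s, default [make_learner_bank()].
#' @param nfolds Number of CV folds (default 5).
#' @param seed Seed for the fold partition.
#' @param patience Plateau length: consecutive feature additions without any
#'   learner improving before the loop stops (default 20).
#' @param k_max Cap on the number of features considered
#'   (default `min(d, 1000)`).
#' @param per_fold_ranking Rank features within each training fold instead
#'   of once on the full training set (default `FALSE`).
#' @param n_states Discretization states for MRMR (default 3).
#' @param verbose Print progress per feature count.
#' @return An object of class `selection_result`: `best_learner` (a
#'   `learner_spec`), `best_feature_set` (ordered column indices), `top5`
#'   (list of the retained records), `audit` (data.frame of every (learner,
#'   k) visited: per-fold accuracies, mean, range), `folds`, `ranking`,
#'   and `train` (the training data needed to refit/predict).
#' @export
select_classifier <- function(dataset, bank = make_learner_bank(),
                              nfolds = 5L, seed = 1L, patience = 20L,
                              k_max = NULL, per_fold_ranking = FALSE,
                              n_states = 3L, verbose = FALSE) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  X <- dataset$X; y <- dataset$y
  N <- nrow(X); d <- ncol(X)
  if (N < 10L) stop("too few subjects (need >= 10)")
  if (d < 1L) stop("no features")
  if (is.null(k_max)) k_max <- min(d, 1000L)
  k_max <- min(k_max, d)
  folds <- make_folds(y, nfolds, seed)

  disc <- discretize(X, n_states = n_states)
  st <- .mrmr_state_init(disc, y)
  fold_states <- NULL
  if (per_fold_ranking) {
    fold_states <- lapply(seq_len(max(folds)), function(f) {
      tr <- folds != f
      .mrmr_state_init(discretize(X[tr, , drop = FALSE], n_states = n_states),
                       y[tr])
    })
  }

  nb <- length(bank)
  best_mean <- rep(-Inf, nb)
  best_k <- rep(NA_integer_, nb)
  best_rec <- vector("list", nb)
  audit <- vector("list", 0)
  since_improve <- 0L
  k <- 0L
  repeat {
    k <- k + 1L
    st <- .mrmr_state_extend(st, 1L)
    fs <- st$order[seq_len(k)]
    fs_cv <- fs
    if (per_fold_ranking) {
      fold_states <- lapply(fold_states, .mrmr_state_extend, steps = 1L)
      fs_cv <- lapply(fold_states, function(s) s$order[seq_len(k)])
    }
    improved <- FALSE
    for (li in seq_len(nb)) {
      acc <- .cv_accuracies(bank[[li]], X, y, fs_cv, folds)
      rec <- list(learner = bank[[li]]$name, fs_size = k,
                  fold_accuracies = acc, mean = mean(acc),
                  range = max(acc) - min(acc))
      audit[[length(audit) + 1L]] <- rec
      if (rec$mean > best_mean[li] + 1e-9) {
        best_mean[li] <- rec$mean
        best_k[li] <- k
        best_rec[[li]] <- rec
        improved <- TRUE
      }
    }
    if (verbose)
      message(sprintf("k=%d  best mean so far %.1f%%", k, max(best_mean)))
    since_improve <- if (improved) 0L else since_improve + 1L
    if (since_improve >= patience) break
    if (k >= k_max) {
      if (since_improve < patience && k_max < d)
        warning("stopped at k_max = ", k_max, " before the accuracy plateau")
      break
    }
  }

  # top 5 by best mean; ties at the cut broken by smaller feature set, then
  # bank order
  ord <- order(-best_mean, best_k, seq_len(nb))
  top_idx <- ord[seq_len(min(5L, nb))]
  # winner: smallest fold range among the retained learners; residual ties
  # by larger mean, then bank order
  ranges <- vapply(best_rec[top_idx], `[[`, numeric(1), "range")
  means <- vapply(best_rec[top_idx], `[[`, numeric(1), "mean")
  win <- top_idx[order(ranges, -means, seq_along(top_idx))[1]]

  fs_star <- st$order[seq_len(best_k[win])]
  audit_df <- do.call(rbind, lapply(audit, function(r)
    data.frame(learner = r$learner, k = r$fs_size,
               t(setNames(r$fold_accuracies,
                          paste0("fold", seq_along(r$fold_accuracies)))),
               mean = r$mean, range = r$range)))
  structure(list(best_learner = bank[[win]],
                 best_feature_set = fs_star,
                 top5 = lapply(top_idx, function(i)
                   c(best_rec[[i]], list(features = st$order[seq_len(best_k[i])]))),
                 audit = audit_df,
                 folds = folds,
                 ranking = structure(list(order = st$order, scores = st$scores),
                                     class = "mrmr_ranking"),
                 k_stop = k,
                 train = list(X = X[, fs_star, drop = FALSE], y = y,
                              features = fs_star, seed = seed)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result>\n  winner: ", x$best_learner$name, " with ",
      length(x$best_feature_set), " features\n", sep = "")
  cat("  top learners (best CV mean %, range %):\n")
  for (r in x$top5)
    cat(sprintf("    %-12s k=%-4d mean %.1f  range %.1f\n",
                r$learner, r$fs_size, r$mean, r$range))
  invisible(x)
}

#' Predict labels for new subjects with a selected classifier
#'
#' Refits the winning learner on the full training set restricted to the
#' selected feature set (deterministically, as stored in the result) and
#' predicts the new rows.
#'
#' @param result A [select_classifier()] result.
#' @param X_new Numeric matrix over the *same full feature space* as the
#'   training data (columns are subset internally).
#' @return Predicted labels.
#' @export
predict_selection <- function(result, X_new) {
  stopifnot(inherits(result, "selection_result"))
  X_new <- as.matrix(X_new)
  maxf <- max(result$train$features)
  if (ncol(X_new) < maxf)
    stop("feature-space mismatch: new data has ", ncol(X_new),
         " columns but the selected features need at least ", maxf)
  fit_predict(result$best_learner, result$train$X, result$train$y,
              X_new[, result$train$features, drop = FALSE],
              seed = result$train$seed)
}

#' Evaluate a selected classifier on a hold-out set
#'
#' Applies the winning (learner, feature set) pair to subjects never used in
#' any training-time decision and reports the confusion-matrix metrics.
#'
#' @param result A [select_classifier()] result.
#' @param dataset_test A [labeled_dataset()] over the same feature space as
#'   the training data.
#' @param positive Label treated as positive (default `0`, healthy control).
#' @return An `eval_report`.
#' @export
evaluate_holdout <- function(result, dataset_test, positive = 0) {
  stopifnot(inherits(dataset_test, "labeled_dataset"))
  pred <- predict_selection(result, dataset_test$X)
  evaluate_predictions(pred, dataset_test$y, positive = positive)
}

#' Persist a selection result
#'
#' Writes a JSON manifest (winning learner, hyperparameters, feature
#' indices, top-5 CV table) and the full audit log as TSV.
#'
#' @param result A [select_classifier()] result.
#' @param json_path,audit_path Output paths (`NULL` to skip either).
#' @return Invisibly, the manifest list.
#' @export
write_selection <- function(result, json_path = NULL, audit_path = NULL) {
  stopifnot(inherits(result, "selection_result"))
  manifest <- list(
    learner = result$best_learner$name,
    hyperparams = result$best_learner$params,
    n_features = length(result$best_feature_set),
    feature_indices = result$best_feature_set,
    top5 = lapply(result$top5, function(r)
      list(learner = r$learner, k = r$fs_size, mean = r$mean, range = r$range))
  )
  if (!is.null(json_path))
    jsonlite::write_json(manifest, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(audit_path))
    write.table(result$audit, audit_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(manifest)
}
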