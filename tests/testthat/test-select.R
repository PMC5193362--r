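test_that("stratified folds are balanced and reproducible", {
  y <- rep(0:1, c(60, 40))
  f1 <- make_folds(y, 5, seed = 9)
  f2 <- make_folds(y, 5, seed = 9)
  expect_identical(f1, f2)
  expect_false(identical(f1, make_folds(y, 5, seed = 10)))
  # every fold carries both classes in near-stratified proportion
  for (k in 1:5) {
    expect_equal(sum(f1 == k & y == 0), 12)
    expect_equal(sum(f1 == k & y == 1), 8)
  }
})

test_that("cross-validation of a separating feature is perfect with zero range", {
  ds <- make_toy_dataset(n = 60, delta = 6, sd = 0.2, seed = 40)
  rec <- cross_validate(make_learner_bank()[[1]], ds, features = 1, seed = 1)
  expect_equal(rec$mean, 100)
  expect_equal(rec$range, 0)
  expect_length(rec$fold_accuracies, 5)
  # identical folds across repeated calls with the same seed
  rec2 <- cross_validate(make_learner_bank()[[1]], ds, features = 1, seed = 1)
  expect_identical(rec$fold_accuracies, rec2$fold_accuracies)
  expect_error(cross_validate(make_learner_bank()[[1]],
                              labeled_dataset(matrix(rnorm(8), 4), rep(0:1, 2)),
                              features = 1),
               "too few subjects")
})

test_that("selection recovers a planted separating feature among noise", {
  set.seed(41)
  n <- 60
  y <- rep(0:1, each = n / 2)
  X <- matrix(rnorm(n * 51), n, 51)
  planted <- 17
  X[, planted] <- y * 6 + rnorm(n, 0, 0.2)
  ds <- labeled_dataset(X, y)
  res <- select_classifier(ds, seed = 2, patience = 5)
  expect_true(planted %in% res$best_feature_set)
  ev <- evaluate_holdout(res, ds)
  expect_equal(ev$accuracy, 100)
})

test_that("selection equals exhaustive (learner, k) enumeration on small problems", {
  bank2 <- make_learner_bank()[c(1, 13)]   # SVM-linear and KNN
  for (s in 1:3) {
    ds <- make_toy_dataset(n = 60, n_signal = 2, n_noise = 3, delta = 1.5,
                           sd = 1, seed = 50 + s)
    d <- ncol(ds$X)
    got <- suppressWarnings(
      select_classifier(ds, bank = bank2, seed = s, patience = d, k_max = d))
    want <- exhaustive_select(ds, bank2, seed = s, top_n = 5)
    expect_equal(got$best_learner$name, want$learner)
    expect_equal(length(got$best_feature_set), want$k)
    expect_equal(got$best_feature_set, want$fs)
    expect_equal(sort(vapply(got$top5, `[[`, numeric(1), "mean")),
                 sort(want$top_means))
  }
})

test_that("the audit log and top-5 satisfy the selection invariants", {
  ds <- make_toy_dataset(n = 60, n_signal = 1, n_noise = 5, delta = 1, sd = 1,
                         seed = 60)
  res <- suppressWarnings(select_classifier(ds, seed = 3, patience = 3, k_max = 6))
  audit <- res$audit
  # one record per (learner, k) visited
  expect_equal(nrow(audit), 13 * res$k_stop)
  expect_equal(audit$range, apply(audit[, paste0("fold", 1:5)], 1, max) -
                 apply(audit[, paste0("fold", 1:5)], 1, min), tolerance = 1e-9)
  expect_equal(audit$mean, rowMeans(audit[, paste0("fold", 1:5)]),
               tolerance = 1e-9)
  # per-learner best mean is >= the mean at k = 1
  by_l <- split(audit, audit$learner)
  for (bl in by_l)
    expect_gte(max(bl$mean), bl$mean[bl$k == 1])
  # top5 carries the 5 largest per-learner best means
  best_means <- sort(vapply(by_l, function(bl) max(bl$mean), numeric(1)),
                     decreasing = TRUE)
  top_means <- vapply(res$top5, `[[`, numeric(1), "mean")
  expect_equal(sort(top_means, decreasing = TRUE), best_means[1:5],
               ignore_attr = TRUE)
  # winner's range is minimal among the top 5
  ranges <- vapply(res$top5, `[[`, numeric(1), "range")
  win <- which(vapply(res$top5, `[[`, character(1), "learner") ==
                 res$best_learner$name)[1]
  expect_equal(ranges[win], min(ranges))
})

test_that("selection is deterministic end-to-end for a fixed seed", {
  ds <- make_toy_dataset(n = 60, n_signal = 1, n_noise = 4, delta = 2, sd = 1,
                         seed = 70)
  r1 <- select_classifier(ds, seed = 5, patience = 3)
  r2 <- select_classifier(ds, seed = 5, patience = 3)
  expect_identical(r1$best_learner$name, r2$best_learner$name)
  expect_identical(r1$best_feature_set, r2$best_feature_set)
  expect_identical(r1$audit, r2$audit)
})

test_that("hold-out evaluation rejects a mismatched feature space", {
  ds <- make_toy_dataset(seed = 80)
  res <- select_classifier(ds, seed = 1, patience = 2)
  small <- labeled_dataset(ds$X[, 1, drop = FALSE], ds$y)
  maxf <- max(res$best_feature_set)
  if (maxf > 1)
    expect_error(evaluate_holdout(res, small), "mismatch")
  else succeed("selected set fits inside the reduced space")
})

test_that("per-fold ranking mode runs and selects from the full-train ranking", {
  ds <- make_toy_dataset(n = 60, n_signal = 2, n_noise = 4, delta = 2, sd = 0.5,
                         seed = 90)
  res <- select_classifier(ds, seed = 4, patience = 2, per_fold_ranking = TRUE)
  expect_true(all(res$best_feature_set %in% seq_len(ncol(ds$X))))
  expect_equal(res$best_feature_set,
               res$ranking$order[seq_along(res$best_feature_set)])
})

test_that("a selection result serializes to a manifest and audit table", {
  ds <- make_toy_dataset(seed = 95)
  res <- select_classifier(ds, seed = 1, patience = 2)
  fj <- withr::local_tempfile(fileext = ".json")
  ft <- withr::local_tempfile(fileext = ".tsv")
  write_selection(res, fj, ft)
  j <- jsonlite::read_json(fj)
  expect_equal(j$learner, res$best_learner$name)
  expect_equal(j$n_features, length(res$best_feature_set))
  at <- read.delim(ft)
  expect_equal(nrow(at), nrow(res$audit))
})
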