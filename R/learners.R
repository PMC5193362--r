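#' The fixed bank of base classifiers
#'
#' Thirteen base learners, in a fixed, deterministic order: a linear-kernel
#' SVM; nine Gaussian-kernel SVMs `SVM-RBF-1` ... `SVM-RBF-9`, where
#' `SVM-RBF-i` uses the radial basis kernel
#' `K(u, v) = exp(-||u - v||^2 / (2 sigma^2))` with `sigma = i`; Gaussian
#' naive Bayes; a CART decision tree; and k-nearest-neighbours with `k = 5`.
#' SVM misclassification cost is 1.  Hyperparameters not pinned down by the
#' method (KNN's k, the tree depth, the RBF convention) use these documented
#' defaults and are stored on each spec.
#'
#' @return A list of 13 objects of class `learner_spec`, each with elements
#'   `name`, `type` and `params`.
#' @export
make_learner_bank <- function() {
  specs <- list(list(name = "SVM-linear", type = "svm_linear",
                     params = list(cost = 1)))
  for (i in 1:9)
    specs[[length(specs) + 1L]] <-
      list(name = paste0("SVM-RBF-", i), type = "svm_rbf",
           params = list(sigma = i, cost = 1))
  specs[[length(specs) + 1L]] <-
    list(name = "NaiveBayes", type = "naive_bayes", params = list())
  specs[[length(specs) + 1L]] <-
    list(name = "DecisionTree", type = "decision_tree", params = list())
  specs[[length(specs) + 1L]] <-
    list(name = "KNN", type = "knn", params = list(k = 5))
  lapply(specs, function(s) structure(s, class = "learner_spec"))
}

# Column standardization with training-set statistics (zero-variance
# columns left centered only).
.standardize_pair <- function(X_train, X_test) {
  mu <- colMeans(X_train)
  sdev <- apply(X_train, 2, sd)
  sdev[!is.finite(sdev) | sdev == 0] <- 1
  list(train = sweep(sweep(X_train, 2, mu), 2, sdev, "/"),
       test = sweep(sweep(X_test, 2, mu), 2, sdev, "/"))
}

#' Fit a base learner and predict test labels
#'
#' Fits the learner described by `spec` on the training data and returns one
#' predicted label per test row.  Distance-based learners (SVMs, KNN) see
#' features standardized to zero mean / unit variance using training-set
#' statistics, so no feature dominates on raw scale.  Any stochastic
#' internals (KNN distance-tie resolution) are seeded, so predictions are
#' deterministic given `seed`.
#'
#' @param spec A `learner_spec` from [make_learner_bank()].
#' @param X_train,X_test Numeric matrices with identical column counts.
#' @param y_train Binary labels (two distinct values, both present).
#' @param seed Integer seed for stochastic learner internals.
#' @return Predicted labels, same type/coding as `y_train`.
#' @export
fit_predict <- function(spec, X_train, y_train, X_test, seed = 0L) {
  stopifnot(inherits(spec, "learner_spec"))
  X_train <- as.matrix(X_train); X_test <- as.matrix(X_test)
  if (ncol(X_train) != ncol(X_test)) stop("train/test feature count mismatch")
  lev <- sort(unique(y_train))
  if (length(lev) != 2L)
    stop("degenerate input: training data must contain exactly two classes")
  yf <- factor(y_train, levels = lev)
  colnames(X_train) <- colnames(X_test) <- paste0("V", seq_len(ncol(X_train)))
  pred <- switch(spec$type,
    svm_linear = {
      z <- .standardize_pair(X_train, X_test)
      m <- e1071::svm(x = z$train, y = yf, kernel = "linear",
                      cost = spec$params$cost, scale = FALSE)
      predict(m, z$test)
    },
    svm_rbf = {
      z <- .standardize_pair(X_train, X_test)
      m <- e1071::svm(x = z$train, y = yf, kernel = "radial",
                      gamma = 1 / (2 * spec$params$sigma^2),
                      cost = spec$params$cost, scale = FALSE)
      predict(m, z$test)
    },
    naive_bayes = {
      m <- e1071::naiveBayes(x = as.data.frame(X_train), y = yf)
      # floor within-class SDs so a feature constant in one class does not
      # produce NaN densities
      m$tables <- lapply(m$tables, function(tb) {
        if (is.matrix(tb) && ncol(tb) == 2L) tb[, 2] <- pmax(tb[, 2], 1e-9)
        tb
      })
      predict(m, as.data.frame(X_test))
    },
    decision_tree = {
      df <- data.frame(.y = yf, X_train, check.names = FALSE)
      m <- rpart::rpart(.y ~ ., data = df, method = "class")
      predict(m, data.frame(X_test, check.names = FALSE), type = "class")
    },
    knn = {
      z <- .standardize_pair(X_train, X_test)
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      set.seed(seed)
      p <- class::knn(z$train, z$test, yf, k = spec$params$k)
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
      p
    },
    stop("unknown learner type: ", spec$type)
  )
  out <- lev[match(as.character(pred), as.character(lev))]
  out
}

#' Confusion-matrix evaluation of predictions
#'
#' Computes accuracy, sensitivity and specificity (as percentages) and the
#' underlying confusion counts.  `sensitivity = TP / (TP + FN)` is the rate
#' among true positives, `specificity = TN / (TN + FP)` among true
#' negatives.  The default positive class is the label `0` (healthy
#' control in this package's coding).
#'
#' @param pred,truth Equal-length label vectors.
#' @param positive The label counted as positive (default `0`).
#' @return An object of class `eval_report`: `accuracy`, `sensitivity`,
#'   `specificity` (percentages), and `counts` (`tp`, `fn`, `tn`, `fp`).
#' @export
evaluate_predictions <- function(pred, truth, positive = 0) {
  if (length(pred) != length(truth)) stop("'pred'/'truth' length mismatch")
  is_pos <- truth == positive
  tp <- sum(pred == positive & is_pos)
  fn <- sum(pred != positive & is_pos)
  tn <- sum(pred != positive & !is_pos)
  fp <- sum(pred == positive & !is_pos)
  structure(list(
    accuracy = 100 * (tp + tn) / length(truth),
    sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
    counts = c(tp = tp, fn = fn, tn = tn, fp = fp),
    positive = positive
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Accuracy %.1f%%  Sensitivity %.1f%%  Specificity %.1f%%\n",
              x$accuracy, x$sensitivity, x$specificity))
  cat("counts:", paste(names(x$counts), x$counts, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Serialize an evaluation report
#'
#' Writes the report as JSON, or as a one-row TSV with columns
#' accuracy / sensitivity / specificity.
#'
#' @param report An [evaluate_predictions()] result.
#' @param path Output path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "eval_report"))
  if (format == "json") {
    jsonlite::write_json(list(accuracy = report$accuracy,
                              sensitivity = report$sensitivity,
                              specificity = report$specificity,
                              counts = as.list(report$counts)),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    df <- data.frame(accuracy = round(report$accuracy, 1),
                     sensitivity = round(report$sensitivity, 1),
                     specificity = round(report$specificity, 1))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
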