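#' Label-balanced train/test split
#'
#' Randomly partitions a dataset into training and hold-out subsets,
#' stratified by class so the training set holds `fraction` of each class
#' (to rounding); the split is disjoint and exhaustive.
#'
#' @param dataset A [labeled_dataset()].
#' @param fraction Training fraction in (0, 1).
#' @param seed Integer seed.
#' @return A list with `train` and `test`, both `labeled_dataset`s.
#' @export
split_train_test <- function(dataset, fraction = 0.8, seed = 1L) {
  stopifnot(inherits(dataset, "labeled_dataset"), fraction > 0, fraction < 1)
  y <- dataset$y
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  tr <- logical(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    n_tr <- round(fraction * length(idx))
    if (n_tr < 1L || n_tr >= length(idx))
      stop("class ", cl, " too small for a balanced split at fraction ",
           fraction)
    tr[sample(idx, n_tr)] <- TRUE
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  subset_ds <- function(sel)
    labeled_dataset(dataset$X[sel, , drop = FALSE], y[sel],
                    feature_names = dataset$feature_names,
                    subject_ids = dataset$subject_ids[sel])
  list(train = subset_ds(tr), test = subset_ds(!tr))
}

#' Assemble a pipeline configuration
#'
#' @param volumes_dir Directory holding NIfTI volumes and a `labels.tsv`
#'   table (columns `subject_id`, `label`, `file`), e.g. written by
#'   [generate_cohort()].
#' @param personal_csv Optional CSV of personal characteristics with a
#'   `subject_id` column.
#' @param hog A [hog_params()].
#' @param seed Single seed funnelling all randomness (split and CV folds).
#' @param holdout_fraction Fraction of subjects held out (default 0.2).
#' @param split_file Optional TSV with columns `subject_id`, `set`
#'   (`train`/`test`) overriding the random split.
#' @param patience,k_max,per_fold_ranking Passed to [select_classifier()].
#' @param positive Positive class for the hold-out report (default 0).
#' @param out_dir Optional output directory for manifest and artifacts.
#' @return A list of class `run_config`.
#' @export
run_config <- function(volumes_dir, personal_csv = NULL, hog = hog_params(),
                       seed = 1L, holdout_fraction = 0.2, split_file = NULL,
                       patience = 20L, k_max = NULL,
                       per_fold_ranking = FALSE, positive = 0,
                       out_dir = NULL) {
  structure(list(volumes_dir = volumes_dir, personal_csv = personal_csv,
                 hog = hog, seed = as.integer(seed),
                 holdout_fraction = holdout_fraction,
                 split_file = split_file, patience = as.integer(patience),
                 k_max = k_max, per_fold_ranking = per_fold_ranking,
                 positive = positive, out_dir = out_dir),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; `hog` may be a mapping with
#' `cell_size`, `block_cells`, `block_stride`, `epsilon`.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  hp <- do.call(hog_params, y$hog %||% list())
  y$hog <- NULL
  do.call(run_config, c(y, list(hog = hp)))
}

# read volumes listed in labels.tsv, preprocess, extract HOG features
.extract_cohort_features <- function(volumes_dir, hog) {
  lab_path <- file.path(volumes_dir, "labels.tsv")
  if (!file.exists(lab_path)) stop("no labels.tsv in ", volumes_dir)
  tab <- read.delim(lab_path, stringsAsFactors = FALSE)
  stopifnot(all(c("subject_id", "label", "file") %in% names(tab)))
  feats <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    vol <- tryCatch({
      v <- read_volume(file.path(volumes_dir, tab$file[i]))
      v <- znormalize(v)
      if (inherits(v, "scan4d")) v <- time_average(v)
      v
    }, error = function(e)
      stop("stage preprocess failed for subject ", tab$subject_id[i], ": ",
           conditionMessage(e), call. = FALSE))
    feats[[i]] <- tryCatch(extract_hog(vol, hog)$features,
                           error = function(e)
                             stop("stage extract failed for subject ",
                                  tab$subject_id[i], ": ",
                                  conditionMessage(e), call. = FALSE))
  }
  X <- do.call(rbind, feats)
  rownames(X) <- tab$subject_id
  list(X = X, labels = tab$label, ids = tab$subject_id)
}

#' Run the full learning pipeline
#'
#' Executes the stages in order: read each volume, z-normalize, average over
#' time if 4D, extract the 3D HOG descriptor; optionally clean, impute,
#' encode and concatenate personal-characteristic features; split into
#' training and hold-out subsets (label-balanced, or from an explicit split
#' file); select the base learner and feature subset by incremental
#' cross-validation; and evaluate once on the hold-out subjects.  All
#' randomness flows from `config$seed`.  When `config$out_dir` is set, a
#' JSON manifest (config echo, stage log, selection summary, hold-out
#' metrics), the CV audit TSV and the selection manifest are written there.
#'
#' @param config A [run_config()].
#' @return A list with `selection` (a `selection_result`), `eval` (an
#'   `eval_report`), `split`, and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stages <- character(0)
  tick <- function(s) stages <<- c(stages, s)

  co <- .extract_cohort_features(config$volumes_dir, config$hog)
  tick("preprocess+extract")

  if (!is.null(config$personal_csv)) {
    per <- read.csv(config$personal_csv, stringsAsFactors = FALSE)
    per <- filter_missing_features(per)$table
    per <- impute_mean(per)
    ds <- concat_features(co$X, per, labels = co$labels)
    tick("personal")
  } else {
    ds <- labeled_dataset(co$X, co$labels, subject_ids = co$ids)
  }

  if (!is.null(config$split_file)) {
    sp <- read.delim(config$split_file, stringsAsFactors = FALSE)
    stopifnot(all(c("subject_id", "set") %in% names(sp)))
    tr_ids <- sp$subject_id[sp$set == "train"]
    sel <- ds$subject_ids %in% tr_ids
    split <- list(
      train = labeled_dataset(ds$X[sel, , drop = FALSE], ds$y[sel],
                              subject_ids = ds$subject_ids[sel]),
      test = labeled_dataset(ds$X[!sel, , drop = FALSE], ds$y[!sel],
                             subject_ids = ds$subject_ids[!sel]))
  } else {
    split <- split_train_test(ds, 1 - config$holdout_fraction, config$seed)
  }
  tick("split")

  sel_res <- select_classifier(split$train, seed = config$seed,
                               patience = config$patience,
                               k_max = config$k_max,
                               per_fold_ranking = config$per_fold_ranking)
  tick("select")
  report <- evaluate_holdout(sel_res, split$test, positive = config$positive)
  tick("evaluate")

  manifest <- list(
    seed = config$seed,
    stages = stages,
    n_train = nrow(split$train$X), n_test = nrow(split$test$X),
    n_features = ncol(ds$X),
    learner = sel_res$best_learner$name,
    n_selected = length(sel_res$best_feature_set),
    holdout = list(accuracy = report$accuracy,
                   sensitivity = report$sensitivity,
                   specificity = report$specificity)
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    write_selection(sel_res,
                    json_path = file.path(config$out_dir, "selection.json"),
                    audit_path = file.path(config$out_dir, "audit.tsv"))
    write_eval_report(report, file.path(config$out_dir, "holdout.json"))
  }
  list(selection = sel_res, eval = report, split = split, manifest = manifest)
}
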