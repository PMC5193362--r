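#' Recode handedness scores to a binary category
#'
#' Signed continuous handedness scores are collapsed to a categorical code:
#' positive scores become 1 (right-handed), negative scores 0 (left-handed).
#' Values already categorical in \{0, 1\} are passed through unchanged.  A
#' score of exactly 0 (numerically ambidextrous) is not covered by the
#' sign rule; it is mapped to `ambiguous` (default 1) with a warning.
#' `NA` stays `NA`.
#'
#' @param score Numeric vector of handedness scores or 0/1 categories.
#' @param ambiguous Value assigned to scores of exactly 0.
#' @return Integer vector of 0/1 codes.
#' @export
recode_handedness <- function(score, ambiguous = 1L) {
  score <- as.numeric(score)
  obs <- score[!is.na(score)]
  if (length(obs) && all(obs %in% c(0, 1)))
    return(as.integer(score))
  if (any(!is.na(score) & score == 0))
    warning("handedness score exactly 0: coded as ", ambiguous)
  out <- ifelse(score > 0, 1L, ifelse(score < 0, 0L, as.integer(ambiguous)))
  as.integer(out)
}

# missingness indicator covering NA, empty strings and "NaN" tokens
.is_missing <- function(x) {
  if (is.character(x)) is.na(x) | x == "" | x == "NaN" else is.na(x)
}

#' Drop columns with too many missing values
#'
#' Removes every column whose fraction of missing entries is greater than or
#' equal to `threshold` (default 0.30 -- "30% or more" is dropped, 29% is
#' retained).  Identifier and label columns are never dropped.
#'
#' @param table A data.frame of subject records.
#' @param threshold Missing-fraction cutoff in (0, 1].
#' @param keep Column names never dropped (default `subject_id`, `label`).
#' @return A list with `table` (the reduced data.frame) and `dropped`
#'   (character vector of removed column names).
#' @export
filter_missing_features <- function(table, threshold = 0.30,
                                    keep = c("subject_id", "label")) {
  stopifnot(is.data.frame(table), threshold > 0, threshold <= 1)
  frac <- vapply(table, function(x) mean(.is_missing(x)), numeric(1))
  drop <- names(frac)[frac >= threshold & !names(frac) %in% keep]
  list(table = table[, setdiff(names(table), drop), drop = FALSE],
       dropped = drop)
}

#' Impute missing values by the column mean (mode for categoricals)
#'
#' Each missing numeric entry is replaced by the mean of the observed values
#' of its column, so the column mean is unchanged by imputation.  For
#' non-numeric (categorical) columns -- where a mean is undefined -- the most
#' frequent observed level is used instead (ties broken toward the first
#' level in sort order).
#'
#' @param table A data.frame; every retained column must have at least one
#'   observed value.
#' @return The data.frame with no missing values.
#' @export
impute_mean <- function(table) {
  stopifnot(is.data.frame(table))
  for (j in names(table)) {
    x <- table[[j]]
    miss <- .is_missing(x)
    if (!any(miss)) next
    if (all(miss))
      stop("column '", j, "' is entirely missing; drop it before imputing")
    if (is.numeric(x)) {
      x[miss] <- mean(x[!miss])
    } else {
      tab <- sort(table(x[!miss]), decreasing = TRUE)
      mode_lvl <- names(tab)[tab == max(tab)][1]
      x[miss] <- mode_lvl
    }
    table[[j]] <- x
  }
  table
}

#' Encode a personal-characteristics table as a numeric feature matrix
#'
#' Applies the cleaning conventions for subject tables: handedness is
#' recoded to 0/1 with [recode_handedness()]; two-level categoricals (sex,
#' eyestat) become 0/1 by sorted level order; the imaging site becomes a
#' single integer code (or one-hot indicator columns with
#' `one_hot_site = TRUE`); numeric columns pass through.  Columns named in
#' `blocklist` (e.g. symptom scores or medication status, which leak the
#' diagnosis) are removed, as are `subject_id` and `label`.
#'
#' @param table A cleaned data.frame (no missing values; see
#'   [filter_missing_features()] and [impute_mean()]).
#' @param one_hot_site Encode site as one-hot indicators instead of one
#'   integer code.
#' @param blocklist Character vector of columns to exclude.
#' @return Numeric matrix with one row per subject; rownames are subject
#'   ids when available.
#' @export
encode_personal <- function(table, one_hot_site = FALSE,
                            blocklist = character()) {
  stopifnot(is.data.frame(table))
  ids <- if ("subject_id" %in% names(table)) as.character(table$subject_id) else NULL
  cols <- setdiff(names(table), c("subject_id", "label", blocklist))
  out <- list()
  for (j in cols) {
    x <- table[[j]]
    if (j == "handedness") {
      out[[j]] <- as.numeric(recode_handedness(x))
    } else if (is.numeric(x)) {
      out[[j]] <- as.numeric(x)
    } else if (j == "site" && one_hot_site) {
      lv <- sort(unique(as.character(x)))
      for (l in lv) out[[paste0("site_", l)]] <- as.numeric(x == l)
    } else {
      lv <- sort(unique(as.character(x)))
      if (length(lv) > 2 && j != "site")
        warning("multi-level categorical '", j, "' integer-coded")
      out[[j]] <- as.numeric(match(as.character(x), lv) - 1L)
    }
  }
  m <- if (length(out)) do.call(cbind, out)
       else matrix(numeric(0), nrow = nrow(table), ncol = 0)
  rownames(m) <- ids
  m
}

#' Concatenate image features with personal-characteristic features
#'
#' Joins a subjects-by-features image matrix with an encoded personal table
#' by subject id, producing a [labeled_dataset()] whose columns are the
#' image features followed by the personal features (e.g. 116,480 + 6 =
#' 116,486 columns).  Column provenance is recorded in the attribute
#' `"provenance"` (`"image"` / `"personal"` per column).
#'
#' @param image_features Numeric matrix with subject ids as rownames.
#' @param personal A data.frame with a `subject_id` column (and optionally
#'   `label`), or an already-encoded numeric matrix with id rownames.  May
#'   have zero feature columns, in which case the image matrix is used
#'   unchanged.
#' @param labels Optional label vector (in image row order); defaults to the
#'   `label` column of `personal`.
#' @param ... Passed to [encode_personal()] when `personal` is a data.frame.
#' @return A `labeled_dataset`.
#' @export
concat_features <- function(image_features, personal, labels = NULL, ...) {
  image_features <- as.matrix(image_features)
  ids <- rownames(image_features)
  if (is.null(ids)) stop("'image_features' must have subject ids as rownames")
  if (is.data.frame(personal)) {
    if (!"subject_id" %in% names(personal))
      stop("'personal' needs a subject_id column")
    pid <- as.character(personal$subject_id)
    if (is.null(labels) && "label" %in% names(personal))
      labels <- personal$label[match(ids, pid)]
    pmat <- encode_personal(personal, ...)
    rownames(pmat) <- pid
  } else {
    pmat <- as.matrix(personal)
    pid <- rownames(pmat)
  }
  missing_ids <- setdiff(ids, pid)
  extra_ids <- setdiff(pid, ids)
  if (length(missing_ids) || length(extra_ids))
    stop("subject id mismatch; missing from personal table: ",
         paste(head(missing_ids, 5), collapse = ", "),
         if (length(extra_ids)) paste0("; extra: ",
                                       paste(head(extra_ids, 5), collapse = ", ")))
  pmat <- pmat[match(ids, pid), , drop = FALSE]
  X <- cbind(image_features, pmat)
  if (is.null(labels)) stop("no labels available")
  if (is.null(colnames(image_features)))
    colnames(X)[seq_len(ncol(image_features))] <-
      paste0("img", seq_len(ncol(image_features)))
  ds <- labeled_dataset(X, labels, subject_ids = ids)
  attr(ds, "provenance") <- c(rep("image", ncol(image_features)),
                              rep("personal", ncol(pmat)))
  ds
}
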