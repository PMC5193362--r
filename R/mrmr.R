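#' Mutual information of two discrete vectors
#'
#' Plug-in estimate from the empirical joint distribution, in bits (log base
#' 2).  Symmetric and non-negative; bounded above by the smaller marginal
#' entropy.
#'
#' @param x,y Vectors of equal length interpretable as discrete codes
#'   (integer, factor or character).
#' @return Non-negative numeric scalar, bits.
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 1L) stop("empty input")
  tab <- table(x, y)
  n <- sum(tab)
  px <- rowSums(tab) / n
  py <- colSums(tab) / n
  p <- tab / n
  terms <- p * log2(p / outer(px, py))
  sum(terms[p > 0])
}

#' Discretize a feature matrix for mutual-information estimation
#'
#' Default scheme (`"mean_sd"`): each column is coded into 3 states using
#' thresholds at mean - SD and mean + SD (codes 0 / 1 / 2; boundary values
#' fall in the outer states).  Columns that are already discrete -- all
#' values integers with at most `n_states` distinct values -- are passed
#' through recoded to 0-based codes.  A constant column collapses to the
#' single state 0 (its mutual information with anything is then 0).  The
#' `"quantile"` scheme uses equal-probability bins instead.
#'
#' @param X Numeric matrix (subjects x features), all values finite.
#' @param n_states Number of states per feature (3 for `"mean_sd"`).
#' @param scheme `"mean_sd"` or `"quantile"`.
#' @return An object of class `discretized_matrix` with elements `values`
#'   (integer matrix of 0-based codes), `n_states_per_feature`, `scheme`.
#' @export
discretize <- function(X, n_states = 3L, scheme = c("mean_sd", "quantile")) {
  scheme <- match.arg(scheme)
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("'X' must be finite")
  if (scheme == "mean_sd" && n_states != 3L)
    stop("the mean_sd scheme defines exactly 3 states")
  d <- ncol(X)
  V <- matrix(0L, nrow(X), d)
  ns <- integer(d)
  for (j in seq_len(d)) {
    x <- X[, j]
    u <- unique(x)
    if (length(u) == 1L) {                 # constant feature
      ns[j] <- 1L
      next
    }
    if (all(x == round(x)) && length(u) <= n_states) {
      codes <- match(x, sort(u)) - 1L      # already discrete: pass through
      V[, j] <- codes
      ns[j] <- length(u)
      next
    }
    if (scheme == "mean_sd") {
      m <- mean(x); s <- sd(x)
      codes <- ifelse(x <= m - s, 0L, ifelse(x >= m + s, 2L, 1L))
    } else {
      br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_states + 1)))
      codes <- as.integer(cut(x, breaks = br, include.lowest = TRUE)) - 1L
    }
    codes <- match(codes, sort(unique(codes))) - 1L  # compact empty states
    V[, j] <- codes
    ns[j] <- max(codes) + 1L
  }
  structure(list(values = V, n_states_per_feature = ns, scheme = scheme),
            class = "discretized_matrix")
}

# MI (bits) of one discrete vector s against every column of the 0-based
# integer code matrix V.  Vectorized over columns.
.mi_columns <- function(s, V) {
  n <- length(s)
  s_states <- sort(unique(s))
  max_code <- max(V)
  d <- ncol(V)
  marg_b <- matrix(0, max_code + 1L, d)
  for (b in 0:max_code) marg_b[b + 1L, ] <- colSums(V == b)
  mi <- numeric(d)
  for (a in s_states) {
    rows <- s == a
    na <- sum(rows)
    if (na == 0L) next
    for (b in 0:max_code) {
      nab <- colSums(V[rows, , drop = FALSE] == b)
      nb <- marg_b[b + 1L, ]
      pos <- nab > 0
      mi[pos] <- mi[pos] +
        (nab[pos] / n) * log2((nab[pos] * n) / (na * nb[pos]))
    }
  }
  mi
}

# Incremental greedy state: relevance vector, cumulative redundancy sums,
# selected order.  Extending by one step costs one .mi_columns pass.
.mrmr_state_init <- function(disc, y) {
  y <- as.integer(as.factor(y)) - 1L
  relevance <- .mi_columns(y, disc$values)
  list(disc = disc, y = y, relevance = relevance,
       redsum = numeric(ncol(disc$values)),
       order = integer(0), scores = numeric(0))
}

.mrmr_state_extend <- function(state, steps = 1L) {
  V <- state$disc$values
  d <- ncol(V)
  for (s in seq_len(steps)) {
    k <- length(state$order)
    if (k >= d) break
    cand <- setdiff(seq_len(d), state$order)
    score <- if (k == 0L) state$relevance[cand]
             else state$relevance[cand] - state$redsum[cand] / k
    pick <- cand[which.max(score)]        # which.max -> lowest index on ties
    state$order <- c(state$order, pick)
    state$scores <- c(state$scores, max(score))
    if (length(state$order) < d)
      state$redsum <- state$redsum + .mi_columns(V[, pick], V)
  }
  state
}

#' Greedy minimum-redundancy-maximum-relevance feature ranking
#'
#' Sequentially selects features that are most relevant to the class label
#' (high mutual information) while penalizing redundancy with the features
#' already selected.  The first pick maximizes `MI(f, y)`; each subsequent
#' pick maximizes, over unselected features `f`,
#' `MI(f, y) - (1/|S|) * sum_{s in S} MI(f, s)` (the difference-form MID
#' criterion).  Ties are broken toward the lowest feature index, so the
#' ranking is deterministic, and rankings satisfy the prefix property:
#' `mrmr_select(X, y, k)` equals the first `k` entries of
#' `mrmr_select(X, y, k + 1)`.
#'
#' @param X A [discretize()]d matrix, or a numeric matrix which is
#'   discretized with the default scheme.
#' @param y Class labels (vector of length `nrow(X)`).
#' @param k Number of features to rank, `1 <= k <= ncol(X)`.
#' @return An object of class `mrmr_ranking` with `order` (distinct feature
#'   indices) and `scores` (the selection score at each step).
#' @export
mrmr_select <- function(X, y, k) {
  disc <- if (inherits(X, "discretized_matrix")) X else discretize(as.matrix(X))
  d <- ncol(disc$values)
  if (length(y) != nrow(disc$values)) stop("label length mismatch")
  if (!(k >= 1 && k <= d)) stop("'k' must be in [1, ", d, "]")
  st <- .mrmr_state_init(disc, y)
  st <- .mrmr_state_extend(st, as.integer(k))
  structure(list(order = st$order, scores = st$scores), class = "mrmr_ranking")
}

#' @export
print.mrmr_ranking <- function(x, ...) {
  cat("<mrmr_ranking> top", length(x$order), "features:",
      paste(head(x$order, 10), collapse = ", "),
      if (length(x$order) > 10) "...\n" else "\n")
  invisible(x)
}

#' Write an MRMR ranking as TSV
#'
#' Columns: rank, feature index, selection score.
#'
#' @param ranking A [mrmr_select()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  stopifnot(inherits(ranking, "mrmr_ranking"))
  df <- data.frame(rank = seq_along(ranking$order),
                   feature = ranking$order, score = ranking$scores)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
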