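# Independent reference implementations used as oracles.  These are written
# as explicit per-voxel / per-pair loops, deliberately sharing no code with
# the package internals.

naive_direction_set <- function(D) {
  rows <- list()
  if (D == 2) {
    for (dy in -1:1) for (dx in -1:1)
      if (dx != 0 || dy != 0) rows[[length(rows) + 1]] <- c(dx, dy)
  } else {
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1)
      if (dx != 0 || dy != 0 || dz != 0)
        rows[[length(rows) + 1]] <- c(dx, dy, dz)
  }
  do.call(rbind, rows)
}

# full 3D HOG by explicit loops: central differences, cosine argmax with
# lowest-index ties, cell accumulation, overlapping blocks, normalization
naive_hog <- function(a, cell = 8L, bc = 2L, stride = 1L, eps = 1e-5) {
  dims <- dim(a)
  B <- naive_direction_set(3)
  Bu <- B / sqrt(rowSums(B^2))
  nbins <- nrow(B)
  nc <- dims %/% cell
  bins <- array(0, c(nc, nbins))
  for (z in 2:(dims[3] - 1)) for (y in 2:(dims[2] - 1)) for (x in 2:(dims[1] - 1)) {
    cx <- (x - 1) %/% cell + 1; cy <- (y - 1) %/% cell + 1; cz <- (z - 1) %/% cell + 1
    if (cx > nc[1] || cy > nc[2] || cz > nc[3]) next
    g <- c(a[x + 1, y, z] - a[x - 1, y, z],
           a[x, y + 1, z] - a[x, y - 1, z],
           a[x, y, z + 1] - a[x, y, z - 1]) / 2
    m <- sqrt(sum(g^2))
    if (m == 0) next
    gu <- g / m
    best <- -Inf; bi <- 0L
    for (j in 1:nbins) {
      al <- sum(gu * Bu[j, ])
      if (al > best + 1e-9) { best <- al; bi <- j }
    }
    bins[cx, cy, cz, bi] <- bins[cx, cy, cz, bi] + m
  }
  nb <- (nc - bc) %/% stride + 1L
  feats <- numeric(0)
  for (bz in 0:(nb[3] - 1)) for (by in 0:(nb[2] - 1)) for (bx in 0:(nb[1] - 1)) {
    v <- numeric(0)
    for (oz in 0:(bc - 1)) for (oy in 0:(bc - 1)) for (ox in 0:(bc - 1))
      v <- c(v, bins[bx * stride + ox + 1, by * stride + oy + 1,
                     bz * stride + oz + 1, ])
    feats <- c(feats, v / sqrt(sum(v^2) + eps^2))
  }
  feats
}

# count blocks by explicit enumeration of fitting block origins
naive_block_count <- function(n_cells, bc, stride) {
  cnt <- 0L
  for (o in seq(0L, max(n_cells - bc, 0L), by = stride))
    if (o + bc <= n_cells) cnt <- cnt + 1L
  cnt
}

brute_mi <- function(x, y) {
  n <- length(x); s <- 0
  for (a in unique(x)) for (b in unique(y)) {
    pab <- sum(x == a & y == b) / n
    if (pab > 0)
      s <- s + pab * log2(pab / ((sum(x == a) / n) * (sum(y == b) / n)))
  }
  s
}

# greedy MRMR by direct re-evaluation of every candidate at every step
brute_mrmr <- function(V, y, k) {
  sel <- integer(0)
  for (step in seq_len(k)) {
    cand <- setdiff(seq_len(ncol(V)), sel)
    sc <- vapply(cand, function(j) {
      rel <- brute_mi(V[, j], y)
      red <- if (length(sel))
        mean(vapply(sel, function(s2) brute_mi(V[, j], V[, s2]), numeric(1)))
      else 0
      rel - red
    }, numeric(1))
    sel <- c(sel, cand[which.max(sc)])
  }
  sel
}

# exhaustive (learner, k) enumeration implementing the selection rule
# directly: per-learner best CV mean (ties -> smaller k), top-5 learners by
# best mean, winner = smallest fold range among them
exhaustive_select <- function(ds, bank, seed, top_n = 5) {
  folds <- make_folds(ds$y, 5, seed)
  d <- ncol(ds$X)
  rank_full <- mrmr_select(ds$X, ds$y, d)$order
  best <- vector("list", length(bank))
  for (li in seq_along(bank)) {
    recs <- lapply(seq_len(d), function(k)
      cross_validate(bank[[li]], ds, rank_full[seq_len(k)], folds = folds))
    means <- vapply(recs, `[[`, numeric(1), "mean")
    # smallest k within numerical tolerance of the maximum (documented tie rule)
    kbest <- which(means >= max(means) - 1e-9)[1]
    best[[li]] <- list(k = kbest, mean = means[kbest],
                       range = recs[[kbest]]$range)
  }
  bm <- vapply(best, `[[`, numeric(1), "mean")
  bk <- vapply(best, `[[`, numeric(1), "k")
  ord <- order(-bm, bk, seq_along(bank))
  top <- ord[seq_len(min(top_n, length(bank)))]
  rg <- vapply(best[top], `[[`, numeric(1), "range")
  mm <- vapply(best[top], `[[`, numeric(1), "mean")
  win <- top[order(rg, -mm, seq_along(top))[1]]
  list(learner = bank[[win]]$name, k = best[[win]]$k,
       fs = rank_full[seq_len(best[[win]]$k)],
       top_means = bm[top])
}

# rotate a 3D array 90 degrees about the z axis: voxel (p, q, r) maps to
# (n2 + 1 - q, p, r)
rot90_z <- function(a) {
  b <- aperm(a, c(2, 1, 3))
  b[dim(b)[1]:1, , , drop = FALSE]
}

# small labeled dataset with `n_signal` informative features and noise
make_toy_dataset <- function(n = 60, n_signal = 1, n_noise = 4, delta = 2,
                             sd = 0.5, seed = 1) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  X <- cbind(
    matrix(rep(y * delta, n_signal), n, n_signal) +
      matrix(rnorm(n * n_signal, 0, sd), n, n_signal),
    matrix(rnorm(n * n_noise), n, n_noise)
  )
  labeled_dataset(X, y)
}
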