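#' HOG extraction parameters
#'
#' Geometry of the histogram-of-oriented-gradients descriptor.  With the
#' defaults (8-voxel cells, 2x2x2-cell blocks at stride one cell) each block
#' spans 16 voxels per axis and contributes `8 * 26 = 208` values in 3D;
#' overlapping blocks re-normalize each cell in several contexts.
#'
#' @param cell_size Positive integer, cell edge length in voxels (per axis).
#' @param block_cells Positive integer, cells per axis in a block.
#' @param block_stride Positive integer, block stride in cells.
#' @param epsilon Small positive constant guarding the block normalization
#'   `v -> v / sqrt(||v||^2 + epsilon^2)` when all magnitudes in a block are
#'   zero.
#' @return An object of class `hog_params`.
#' @export
hog_params <- function(cell_size = 8L, block_cells = 2L, block_stride = 1L,
                       epsilon = 1e-5) {
  stopifnot(cell_size >= 1, block_cells >= 1, block_stride >= 1, epsilon > 0)
  structure(list(cell_size = as.integer(cell_size),
                 block_cells = as.integer(block_cells),
                 block_stride = as.integer(block_stride),
                 epsilon = as.numeric(epsilon)),
            class = "hog_params")
}

#' Orientation bin direction set
#'
#' The `3^D - 1` nonzero integer offset vectors with components in
#' \{-1, 0, 1\}: the 26 neighbor directions in 3D, 8 in 2D.  Each vector is
#' one orientation bin.  The order is fixed and documented: lexicographic by
#' components with the first (x) component varying fastest.
#'
#' @param D Dimension, 2 or 3.
#' @return An object of class `direction_set` with elements `vectors`
#'   (a `count x D` integer matrix, one direction per row), `unit` (the
#'   row-normalized directions) and `count`.
#' @export
make_direction_set <- function(D) {
  if (!(is.numeric(D) && length(D) == 1L && D %in% c(2, 3)))
    stop("'D' must be 2 or 3")
  D <- as.integer(D)
  g <- as.matrix(do.call(expand.grid, rep(list(-1:1), D)))
  dimnames(g) <- NULL
  g <- g[rowSums(g != 0) > 0, , drop = FALSE]
  structure(list(vectors = g,
                 unit = g / sqrt(rowSums(g^2)),
                 count = nrow(g)),
            class = "direction_set")
}

#' Central-difference gradient field of an image
#'
#' Computes per-voxel partial derivatives by central differences in voxel
#' index units, e.g. `f_x = (f(x+1,y,z) - f(x-1,y,z)) / 2`, together with the
#' Euclidean gradient magnitude.  Boundary voxels, where a central difference
#' does not exist, are marked invalid and contribute nothing downstream.
#'
#' @param vol A [volume3d()], a 3-axis array, or a 2-axis matrix (2D image).
#' @return An object of class `gradient_field` with elements `components`
#'   (list of D arrays), `magnitude`, `valid` (logical array), `dims`, `D`.
#' @export
gradient_field <- function(vol) {
  x <- if (inherits(vol, "volume3d")) vol$intensities else as.array(vol)
  dims <- dim(x)
  D <- length(dims)
  if (!D %in% c(2L, 3L)) stop("image must be 2- or 3-dimensional")
  if (any(dims < 3L))
    stop("degenerate input: every axis extent must be >= 3")
  comps <- vector("list", D)
  for (a in seq_len(D)) {
    g <- array(0, dims)
    n <- dims[a]
    idx_hi <- lapply(seq_len(D), function(b) if (b == a) 3:n else seq_len(dims[b]))
    idx_lo <- lapply(seq_len(D), function(b) if (b == a) 1:(n - 2) else seq_len(dims[b]))
    idx_mid <- lapply(seq_len(D), function(b) if (b == a) 2:(n - 1) else seq_len(dims[b]))
    di <- (do.call(`[`, c(list(x), idx_hi)) - do.call(`[`, c(list(x), idx_lo))) / 2
    g <- do.call(`[<-`, c(list(g), idx_mid, list(di)))
    comps[[a]] <- g
  }
  mag <- sqrt(Reduce(`+`, lapply(comps, function(g) g^2)))
  valid <- array(TRUE, dims)
  for (a in seq_len(D)) {
    sel <- lapply(seq_len(D), function(b)
      if (b == a) c(1L, dims[a]) else seq_len(dims[b]))
    valid <- do.call(`[<-`, c(list(valid), sel, list(FALSE)))
  }
  structure(list(components = comps, magnitude = mag, valid = valid,
                 dims = dims, D = D),
            class = "gradient_field")
}

# Vectorized orientation binning: rows of G are gradient vectors; returns the
# index of the direction with maximal cosine similarity, NA for zero rows.
# Ties (within 1e-9 on the cosine) keep the lowest index in the fixed order.
.bin_directions <- function(G, dirs) {
  mag <- sqrt(rowSums(G^2))
  ok <- mag > 0
  out <- rep(NA_integer_, nrow(G))
  if (!any(ok)) return(out)
  Gu <- G[ok, , drop = FALSE] / mag[ok]
  best <- rep(-Inf, nrow(Gu))
  pick <- integer(nrow(Gu))
  for (j in seq_len(dirs$count)) {
    a <- as.vector(Gu %*% dirs$unit[j, ])
    upd <- a > best + 1e-9
    pick[upd] <- j
    best[upd] <- a[upd]
  }
  out[ok] <- pick
  out
}

#' Assign a gradient vector to its orientation bin
#'
#' Returns the index (into the fixed order of [make_direction_set()]) of the
#' direction `b` maximizing the overlap `alpha(g, b) = (g . b) / (|g| |b|)`.
#' Exact ties are broken toward the lowest index.  A zero-magnitude gradient
#' has no defined orientation and returns `NA` ("no bin"); callers skip such
#' voxels.
#'
#' @param g Numeric gradient vector of length `D`.
#' @param dirs A [make_direction_set()] of matching dimension.
#' @return Integer bin index, or `NA` for a zero gradient.
#' @export
bin_direction <- function(g, dirs) {
  stopifnot(inherits(dirs, "direction_set"),
            length(g) == ncol(dirs$vectors))
  .bin_directions(matrix(as.numeric(g), nrow = 1), dirs)[1]
}

#' Accumulate per-cell orientation histograms
#'
#' Partitions the image into non-overlapping cells of `cell_size` voxels per
#' axis (trailing partial cells are discarded).  Every valid interior voxel
#' with a nonzero gradient adds its gradient magnitude to the orientation bin
#' of its cell: `bin[dir(x,y,z)] += |grad f(x,y,z)|`.
#'
#' @param grad A [gradient_field()].
#' @param params A [hog_params()].
#' @param dirs Optionally a precomputed [make_direction_set()].
#' @return An object of class `cell_histograms`: `bins` is an array of
#'   dimension `c(cell_grid, n_bins)`; `cell_grid` the number of cells per
#'   axis.
#' @export
cell_histograms <- function(grad, params = hog_params(), dirs = NULL) {
  stopifnot(inherits(grad, "gradient_field"), inherits(params, "hog_params"))
  D <- grad$D
  cs <- params$cell_size
  nc <- grad$dims %/% cs
  if (any(nc < 1L))
    stop("degenerate input: image smaller than one cell per axis")
  if (is.null(dirs)) dirs <- make_direction_set(D)
  n <- prod(grad$dims)
  # 1-based voxel coordinates along each axis, flattened column-major
  coord <- arrayInd(seq_len(n), grad$dims)
  inb <- rep(TRUE, n)
  for (a in seq_len(D)) inb <- inb & coord[, a] <= nc[a] * cs
  keep <- inb & as.vector(grad$valid) & as.vector(grad$magnitude) > 0
  bins <- array(0, c(nc, dirs$count))
  if (any(keep)) {
    G <- do.call(cbind, lapply(grad$components, function(g) as.vector(g)[keep]))
    b <- .bin_directions(G, dirs)
    cellc <- (coord[keep, , drop = FALSE] - 1L) %/% cs   # 0-based cell coords
    cell_lin <- cellc[, 1]
    mult <- nc[1]
    if (D >= 2) for (a in 2:D) { cell_lin <- cell_lin + cellc[, a] * mult; mult <- mult * nc[a] }
    grp <- cell_lin + (b - 1L) * prod(nc)                # 0-based bin slot
    acc <- rowsum(as.vector(grad$magnitude)[keep], grp)
    bins[as.integer(rownames(acc)) + 1L] <- acc[, 1]
  }
  structure(list(bins = bins, cell_grid = nc, n_bins = dirs$count,
                 D = D, params = params),
            class = "cell_histograms")
}

#' Gather overlapping blocks of cell histograms
#'
#' Collects blocks of `block_cells` cells per axis at `block_stride`, in
#' x-fastest grid order.  Each block vector is the concatenation of its
#' cells' histograms (cells in x-fastest order within the block, bins
#' innermost), of length `block_cells^D * n_bins` -- 208 at the 3D defaults.
#' The number of blocks per axis is
#' `floor((cells - block_cells) / stride) + 1`.
#'
#' @param cells A [cell_histograms()].
#' @param params A [hog_params()].
#' @return A list with `vectors` (an `n_blocks x block_length` matrix, one
#'   unnormalized block vector per row) and `block_grid`.
#' @export
assemble_blocks <- function(cells, params = cells$params) {
  stopifnot(inherits(cells, "cell_histograms"))
  D <- cells$D
  bc <- params$block_cells
  st <- params$block_stride
  nc <- cells$cell_grid
  if (any(nc < bc))
    stop("degenerate input: fewer cells than one block per axis")
  nb <- (nc - bc) %/% st + 1L
  nbins <- cells$n_bins
  ncell_tot <- prod(nc)
  # flat bins matrix: rows = cells (x-fastest), cols = bins
  binmat <- matrix(cells$bins, nrow = ncell_tot, ncol = nbins)
  # cell offsets within a block, x-fastest
  off <- as.matrix(do.call(expand.grid, rep(list(0:(bc - 1L)), D)))
  blk_origin <- as.matrix(do.call(expand.grid,
                                  lapply(seq_len(D), function(a) seq(0L, by = st, length.out = nb[a]))))
  n_blocks <- nrow(blk_origin)
  blen <- bc^D * nbins
  V <- matrix(0, n_blocks, blen)
  mult <- cumprod(c(1, nc[-D]))
  for (ci in seq_len(nrow(off))) {
    cell_lin <- as.vector((blk_origin + matrix(off[ci, ], n_blocks, D,
                                               byrow = TRUE)) %*% mult) + 1L
    V[, ((ci - 1L) * nbins + 1L):(ci * nbins)] <- binmat[cell_lin, , drop = FALSE]
  }
  list(vectors = V, block_grid = nb)
}

#' Normalize a block vector
#'
#' Applies `v -> v / sqrt(||v||_2^2 + epsilon^2)`.  The constant `epsilon`
#' keeps the map defined when every gradient magnitude in the block is zero
#' (the zero vector maps to the zero vector); the output norm is strictly
#' below 1.
#'
#' @param v Numeric vector (or matrix of row vectors).
#' @param epsilon Small positive constant.
#' @return Normalized vector (or matrix) of the same shape.
#' @export
normalize_block <- function(v, epsilon = 1e-5) {
  stopifnot(epsilon > 0)
  if (is.matrix(v)) v / sqrt(rowSums(v^2) + epsilon^2)
  else v / sqrt(sum(v^2) + epsilon^2)
}

#' Extract the HOG descriptor of a volume (or 2D image)
#'
#' Full pipeline: central-difference gradients, max-overlap orientation
#' binning over the `3^D - 1` neighbor directions, per-cell magnitude
#' accumulation, overlapping-block gathering, and block normalization.  The
#' feature vector concatenates the normalized block vectors in x-fastest
#' block-grid order; within a block, cells in x-fastest order with bins
#' innermost.  On the canonical 79 x 95 x 68 grid with default parameters
#' this yields a 9 x 11 x 8 cell grid, 8 x 10 x 7 = 560 blocks and
#' 560 * 208 = 116,480 features.
#'
#' @param vol A [volume3d()], 3-axis array, or 2-axis matrix.
#' @param params A [hog_params()].
#' @return An object of class `hog_descriptor` with elements `features`
#'   (numeric vector, each entry in `[0, 1)`), `params`, `dims`, `cell_grid`,
#'   `block_grid`, `n_bins`, `D`.
#' @export
extract_hog <- function(vol, params = hog_params()) {
  grad <- gradient_field(vol)
  dirs <- make_direction_set(grad$D)
  cells <- cell_histograms(grad, params, dirs)
  blocks <- assemble_blocks(cells, params)
  Vn <- normalize_block(blocks$vectors, params$epsilon)
  structure(list(features = as.vector(t(Vn)),
                 params = params,
                 dims = grad$dims,
                 cell_grid = cells$cell_grid,
                 block_grid = blocks$block_grid,
                 n_bins = dirs$count,
                 D = grad$D),
            class = "hog_descriptor")
}

#' Map a feature index back to image space
#'
#' Decodes a (1-based) feature index into its block, cell-within-block and
#' orientation bin, and returns the geometric center of the block both in
#' 0-based voxel coordinates and in anatomical mm via the grid affine.  This
#' supports reporting which image regions a selected feature describes.
#'
#' @param idx 1-based feature index.
#' @param desc A [extract_hog()] descriptor.
#' @param grid A [grid_geometry()]; defaults to the descriptor's own
#'   dimensions on a 2 mm grid with origin at the canonical bounding-box
#'   corner when the descriptor matches the canonical 79 x 95 x 68 grid,
#'   otherwise origin 0.
#' @return List with `block` (1-based block grid index), `cell` (1-based
#'   cell-within-block index), `bin` (1-based orientation bin),
#'   `center_voxel` (0-based, possibly fractional), `center_mm`.
#' @export
map_feature_to_space <- function(idx, desc, grid = NULL) {
  stopifnot(inherits(desc, "hog_descriptor"))
  if (idx < 1 || idx > length(desc$features))
    stop("feature index out of range: ", idx)
  if (desc$D != 3L && !is.null(grid))
    stop("mm mapping requires a 3D descriptor")
  p <- desc$params
  nbins <- desc$n_bins
  cells_per_block <- p$block_cells^desc$D
  i0 <- as.integer(idx) - 1L
  bin <- i0 %% nbins
  cell <- (i0 %/% nbins) %% cells_per_block
  blk <- i0 %/% (nbins * cells_per_block)
  blk_coord <- integer(desc$D)
  r <- blk
  for (a in seq_len(desc$D)) {
    blk_coord[a] <- r %% desc$block_grid[a]
    r <- r %/% desc$block_grid[a]
  }
  cell_coord <- integer(desc$D)
  r <- cell
  for (a in seq_len(desc$D)) {
    cell_coord[a] <- r %% p$block_cells
    r <- r %/% p$block_cells
  }
  span <- p$block_cells * p$cell_size
  origin_voxel <- blk_coord * p$block_stride * p$cell_size
  center_voxel <- origin_voxel + (span - 1) / 2
  out <- list(block = blk_coord + 1L, cell = cell_coord + 1L, bin = bin + 1L,
              center_voxel = center_voxel)
  if (desc$D == 3L) {
    if (is.null(grid)) {
      grid <- if (all(desc$dims == c(79L, 95L, 68L))) grid_geometry()
              else grid_geometry(desc$dims, origin_mm = c(0, 0, 0))
    }
    out$center_mm <- voxel_to_mm(grid, center_voxel)
  }
  out
}

#' @export
print.hog_descriptor <- function(x, ...) {
  cat("<hog_descriptor> ", length(x$features), " features: ",
      paste(x$block_grid, collapse = " x "), " blocks x ",
      x$params$block_cells^x$D, " cells x ", x$n_bins, " bins\n", sep = "")
  invisible(x)
}
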