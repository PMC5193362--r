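test_that("direction sets have 3^D - 1 members in a fixed symmetric order", {
  d3 <- make_direction_set(3)
  d2 <- make_direction_set(2)
  expect_equal(d3$count, 26L)
  expect_equal(d2$count, 8L)
  # order matches an independently constructed lexicographic enumeration
  expect_equal(d3$vectors, naive_direction_set(3), ignore_attr = TRUE)
  expect_equal(d2$vectors, naive_direction_set(2), ignore_attr = TRUE)
  # every vector's negation is in the set
  for (j in seq_len(d3$count))
    expect_true(any(colSums(t(d3$vectors) == -d3$vectors[j, ]) == 3))
  expect_error(make_direction_set(4), "must be 2 or 3")
})

test_that("central differences match hand computation on the 2D worked pixel", {
  # center pixel with x-neighbors 94/56 and y-neighbors 93/54
  img <- matrix(0, 3, 3)
  img[3, 2] <- 94; img[1, 2] <- 56; img[2, 3] <- 93; img[2, 1] <- 54
  g <- gradient_field(img)
  expect_equal(g$components[[1]][2, 2], (94 - 56) / 2)   # 19
  expect_equal(g$components[[2]][2, 2], (93 - 54) / 2)   # 19.5
  expect_equal(g$magnitude[2, 2], sqrt(19^2 + 19.5^2))
  b <- bin_direction(c(g$components[[1]][2, 2], g$components[[2]][2, 2]),
                     make_direction_set(2))
  expect_equal(make_direction_set(2)$vectors[b, ], c(1, 1), ignore_attr = TRUE)
})

test_that("gradient of a constant volume is zero and of a linear ramp is its slope", {
  g0 <- gradient_field(volume3d(array(4, c(5, 5, 5))))
  expect_true(all(g0$magnitude == 0))

  ramp <- array(0, c(6, 5, 5))
  for (x in 1:6) ramp[x, , ] <- 2 * x
  gr <- gradient_field(volume3d(ramp))
  inner <- gr$valid
  expect_true(all(gr$components[[1]][inner] == 2))
  expect_true(all(gr$components[[2]][inner] == 0))
  expect_true(all(gr$components[[3]][inner] == 0))
  # boundary voxels carry no central difference
  expect_false(any(gr$valid[1, , ]) || any(gr$valid[6, , ]))
  expect_error(gradient_field(volume3d(array(0, c(2, 5, 5)))), "extent")
})

test_that("orientation binning picks the maximum-overlap direction", {
  d3 <- make_direction_set(3)
  b <- bin_direction(c(0, 0, 5), d3)
  expect_equal(d3$vectors[b, ], c(0, 0, 1), ignore_attr = TRUE)
  expect_true(is.na(bin_direction(c(0, 0, 0), d3)))

  # exact tie at 22.5 degrees between (1,0) and (1,1): lowest index wins
  d2 <- make_direction_set(2)
  s <- 1 / sqrt(2)
  g <- c(1 + s, s)           # bisector of (1,0) and (1,1)/sqrt(2)
  i10 <- which(d2$vectors[, 1] == 1 & d2$vectors[, 2] == 0)
  i11 <- which(d2$vectors[, 1] == 1 & d2$vectors[, 2] == 1)
  expect_equal(bin_direction(g, d2), min(i10, i11))
})

test_that("cell accumulation adds each voxel's magnitude to its direction bin", {
  # constant image: all bins zero
  ch0 <- cell_histograms(gradient_field(volume3d(array(1, c(16, 16, 16)))),
                         hog_params())
  expect_true(all(ch0$bins == 0))

  # a synthetic gradient field with a single nonzero voxel: exactly one bin
  dims <- c(16, 16, 16)
  comp <- lapply(1:3, function(a) array(0, dims))
  comp[[3]][5, 5, 5] <- 5
  gf <- structure(list(components = comp,
                       magnitude = sqrt(Reduce(`+`, lapply(comp, `^`, 2))),
                       valid = array(TRUE, dims), dims = dims, D = 3L),
                  class = "gradient_field")
  ch <- cell_histograms(gf, hog_params())
  expect_equal(sum(ch$bins != 0), 1L)
  expect_equal(sum(ch$bins), 5)
  d3 <- make_direction_set(3)
  hit <- which(ch$bins != 0, arr.ind = TRUE)
  expect_equal(hit[1, 1:3], c(1, 1, 1), ignore_attr = TRUE)  # voxel 5 in cell 1
  expect_equal(d3$vectors[hit[1, 4], ], c(0, 0, 1), ignore_attr = TRUE)
})

test_that("block geometry follows the counting formula", {
  set.seed(7)
  # one full block: 2x2x2 cells -> 208 values
  ch <- cell_histograms(gradient_field(volume3d(array(rnorm(16^3), c(16, 16, 16)))),
                        hog_params())
  expect_equal(ch$cell_grid, c(2L, 2L, 2L))
  bl <- assemble_blocks(ch)
  expect_equal(dim(bl$vectors), c(1L, 208L))

  # synthetic 9 x 11 x 8 cell grid at defaults -> 8 x 10 x 7 = 560 blocks
  ch2 <- structure(list(bins = array(abs(rnorm(9 * 11 * 8 * 26)), c(9, 11, 8, 26)),
                        cell_grid = c(9L, 11L, 8L), n_bins = 26L, D = 3L,
                        params = hog_params()),
                   class = "cell_histograms")
  bl2 <- assemble_blocks(ch2)
  expect_equal(bl2$block_grid, c(8L, 10L, 7L))
  expect_equal(nrow(bl2$vectors), 560L)
  expect_equal(560L * 208L, 116480L)

  # non-overlapping tiling: stride = block size, 4^3 cells, 2-cell blocks
  ch3 <- structure(list(bins = array(1, c(4, 4, 4, 26)),
                        cell_grid = c(4L, 4L, 4L), n_bins = 26L, D = 3L,
                        params = hog_params(block_stride = 2L)),
                   class = "cell_histograms")
  expect_equal(nrow(assemble_blocks(ch3)$vectors), 8L)

  expect_error(assemble_blocks(structure(list(
    bins = array(0, c(1, 1, 1, 26)), cell_grid = c(1L, 1L, 1L), n_bins = 26L,
    D = 3L, params = hog_params()), class = "cell_histograms")), "fewer cells")
})

test_that("block normalization is bounded and exact", {
  expect_equal(normalize_block(rep(0, 208)), rep(0, 208))
  expect_equal(normalize_block(c(3, 4), epsilon = 1e-12), c(0.6, 0.8),
               tolerance = 1e-9)
  set.seed(8)
  v <- rnorm(208)
  w <- normalize_block(v, 1e-5)
  expect_equal(sum(w^2), sum(v^2) / (sum(v^2) + 1e-10), tolerance = 1e-12)
  expect_lt(sqrt(sum(w^2)), 1)
})

test_that("descriptor length follows block counting on varied shapes", {
  expect_equal(length(extract_hog(volume3d(array(rnorm(16^3), c(16, 16, 16))))$features),
               208L)
  expect_equal(length(extract_hog(volume3d(array(rnorm(24^3), c(24, 24, 24))))$features),
               (3 - 1)^3 * 208L)
  set.seed(9)
  for (i in 1:6) {
    dims <- sample(10:28, 3, replace = TRUE)
    cs <- sample(3:6, 1)
    st <- sample(1:2, 1)
    p <- hog_params(cell_size = cs, block_cells = 2, block_stride = st)
    nc <- dims %/% cs
    if (any(nc < 2)) next
    nb <- vapply(nc, naive_block_count, integer(1), bc = 2L, stride = st)
    h <- extract_hog(volume3d(array(rnorm(prod(dims)), dims)), p)
    expect_equal(length(h$features), prod(nb) * 8L * 26L)
    expect_equal(h$block_grid, as.integer(nb))
  }
})

test_that("a constant volume yields the zero descriptor", {
  h <- extract_hog(volume3d(array(3, c(16, 16, 16))))
  expect_true(all(h$features == 0))
})

test_that("the full pipeline matches a naive per-voxel reference", {
  set.seed(10)
  a <- array(rnorm(16 * 24 * 16), c(16, 24, 16))
  expect_equal(extract_hog(volume3d(a))$features, naive_hog(a),
               tolerance = 1e-10)
  b <- array(rnorm(20^3), c(20, 20, 20))
  p <- hog_params(cell_size = 5, block_cells = 2, block_stride = 1)
  expect_equal(extract_hog(volume3d(b), p)$features,
               naive_hog(b, cell = 5L), tolerance = 1e-10)
})

test_that("90-degree rotation permutes cell histogram bins accordingly", {
  set.seed(11)
  a <- array(rnorm(16^3), c(16, 16, 16))
  d3 <- make_direction_set(3)
  bins_o <- cell_histograms(gradient_field(volume3d(a)))$bins
  bins_r <- cell_histograms(gradient_field(volume3d(rot90_z(a))))$bins
  # direction (dx,dy,dz) maps to (-dy,dx,dz) under the rotation
  perm <- apply(d3$vectors, 1, function(v)
    which(d3$vectors[, 1] == -v[2] & d3$vectors[, 2] == v[1] &
            d3$vectors[, 3] == v[3]))
  nc <- dim(bins_o)[1:3]
  for (cx in seq_len(nc[1])) for (cy in seq_len(nc[2])) for (cz in seq_len(nc[3]))
    expect_equal(bins_r[nc[2] + 1 - cy, cx, cz, perm],
                 bins_o[cx, cy, cz, ], tolerance = 1e-10,
                 ignore_attr = TRUE)
})

test_that("intensity rescaling leaves the normalized descriptor invariant in the small-epsilon limit", {
  set.seed(12)
  a <- array(rnorm(16^3), c(16, 16, 16))
  p <- hog_params(epsilon = 1e-12)
  h1 <- extract_hog(volume3d(a), p)$features
  h2 <- extract_hog(volume3d(5 * a), p)$features
  expect_equal(h1, h2, tolerance = 1e-8)
})

test_that("feature indices decode to block centers in voxel and mm space", {
  set.seed(13)
  h <- extract_hog(volume3d(array(rnorm(16^3), c(16, 16, 16))))
  m1 <- map_feature_to_space(1, h)
  expect_equal(m1$center_voxel, c(7.5, 7.5, 7.5))   # the volume center
  # same block, different cell/bin 26 features later
  m2 <- map_feature_to_space(27, h)
  expect_equal(m2$block, m1$block)
  expect_equal(m2$center_voxel, m1$center_voxel)
  expect_equal(m2$bin, 1L)                          # bins are innermost
  expect_equal(m2$cell, c(2L, 1L, 1L))              # next cell within block
  # mm coordinate through a custom affine: origin + 2 * voxel index
  g <- grid_geometry(c(16, 16, 16), c(2, 2, 2), c(-78, -112, -50))
  m3 <- map_feature_to_space(1, h, g)
  expect_equal(m3$center_mm, c(-78, -112, -50) + 2 * c(7.5, 7.5, 7.5))
  expect_error(map_feature_to_space(209, h), "out of range")
})
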