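#' Specification of a synthetic two-class cohort
#'
#' Parameters of the phantom generator used to validate the full pipeline
#' without any real imaging data.  Volumes are Gaussian noise; class-1
#' subjects additionally carry a sinusoidal grating of amplitude `effect`,
#' with a fixed orientation, confined to the central sub-block of the
#' volume -- an oriented-gradient signature that a HOG descriptor is, by
#' construction, sensitive to.  `effect = 0` gives a null cohort (both
#' classes identically distributed).  One global `seed` fans out to
#' per-subject streams, so a cohort can be extended without regenerating
#' earlier subjects.
#'
#' @param n_per_class Subjects per class (>= 5); default 100.
#' @param dims Volume shape; default `c(32, 32, 32)` (use the canonical
#'   79 x 95 x 68 grid for scale checks).
#' @param effect Amplitude of the class-1 grating, in the same intensity
#'   units as the noise; default 3 (i.e. three noise SDs at the default
#'   `noise_sd`).
#' @param noise_sd SD of the Gaussian background noise; default 1.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_class = 100L, dims = c(32L, 32L, 32L),
                        effect = 3, noise_sd = 1, seed = 1L) {
  stopifnot(n_per_class >= 5L, length(dims) == 3L, all(dims >= 3L),
            effect >= 0, noise_sd >= 0)
  structure(list(n_per_class = as.integer(n_per_class),
                 dims = as.integer(dims),
                 effect = as.numeric(effect),
                 noise_sd = as.numeric(noise_sd),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# grating region: central half of the volume along each axis
.grating_region <- function(dims) {
  lapply(dims, function(n) {
    w <- n %/% 2
    lo <- n %/% 4 + 1L
    lo:(lo + w - 1L)
  })
}

# orientation (unit vector) and wavelength (voxels) of the planted grating
.grating_orientation <- c(1, 1, 0) / sqrt(2)
.grating_wavelength <- 8

#' Generate one synthetic volume
#'
#' Deterministic for a given `(spec$seed, subject)` pair.
#'
#' @param class_label 0 (noise only) or 1 (noise plus oriented grating).
#' @param spec A [cohort_spec()].
#' @param subject Subject index within the cohort (drives the per-subject
#'   random stream).
#' @return A [volume3d()] on a 2 mm grid.
#' @export
generate_volume <- function(class_label, spec, subject = 1L) {
  stopifnot(inherits(spec, "cohort_spec"), class_label %in% c(0, 1))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed((spec$seed * 100003L + as.integer(subject)) %% .Machine$integer.max)
  dims <- spec$dims
  v <- array(if (spec$noise_sd > 0) rnorm(prod(dims), 0, spec$noise_sd) else 0,
             dims)
  if (class_label == 1 && spec$effect > 0) {
    reg <- .grating_region(dims)
    u <- .grating_orientation
    phase <- outer(outer(reg[[1]] * u[1], reg[[2]] * u[2], `+`),
                   reg[[3]] * u[3], `+`)
    v[reg[[1]], reg[[2]], reg[[3]]] <-
      v[reg[[1]], reg[[2]], reg[[3]]] +
      spec$effect * sin(2 * pi * phase / .grating_wavelength)
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  volume3d(v, voxel_size_mm = c(2, 2, 2), origin_mm = c(0, 0, 0))
}

#' Generate and write a synthetic cohort
#'
#' Writes `2 * n_per_class` NIfTI volumes (class 0 subjects first) plus a
#' tab-separated label table with columns `subject_id`, `label`, `file`.
#'
#' @param spec A [cohort_spec()].
#' @param dir Output directory (created if needed).
#' @return The label table (data.frame), invisibly; also written to
#'   `labels.tsv` in `dir`.
#' @export
generate_cohort <- function(spec, dir) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  n <- spec$n_per_class
  labels <- rep(c(0L, 1L), each = n)
  ids <- sprintf("sub%04d", seq_len(2L * n))
  files <- file.path(dir, paste0(ids, ".nii.gz"))
  for (i in seq_len(2L * n)) {
    vol <- generate_volume(labels[i], spec, subject = i)
    write_volume(vol, files[i])
  }
  tab <- data.frame(subject_id = ids, label = labels,
                    file = basename(files), stringsAsFactors = FALSE)
  write.table(tab, file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(tab)
}

#' Generate a synthetic cohort as an in-memory feature dataset
#'
#' Convenience wrapper used by tests and simulations: generates every
#' subject volume, z-normalizes it, extracts its HOG descriptor, and stacks
#' the descriptors into a [labeled_dataset()] -- skipping the NIfTI round
#' trip.
#'
#' @param spec A [cohort_spec()].
#' @param params A [hog_params()].
#' @return A `labeled_dataset` of HOG features.
#' @export
generate_feature_dataset <- function(spec, params = hog_params()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_per_class
  labels <- rep(c(0L, 1L), each = n)
  feats <- lapply(seq_len(2L * n), function(i) {
    vol <- generate_volume(labels[i], spec, subject = i)
    if (spec$noise_sd > 0 || (labels[i] == 1 && spec$effect > 0))
      vol <- znormalize(vol)
    extract_hog(vol, params)$features
  })
  X <- do.call(rbind, feats)
  rownames(X) <- sprintf("sub%04d", seq_len(2L * n))
  labeled_dataset(X, labels)
}

#' Generate a synthetic personal-characteristics table
#'
#' Emulates the structure of multi-site phenotypic tables: age, sex,
#' signed handedness score, IQ (with missing values at `missing_rate`,
#' placed deterministically given the seed), imaging site (4 levels) and
#' eye status.  Subject ids follow the cohort convention (`sub0001`, ...).
#'
#' @param n Number of subjects.
#' @param missing_rate Fraction of IQ entries set missing, in `[0, 1)`;
#'   the realized count is `round(n * missing_rate)`.
#' @param seed Integer seed.
#' @return A data.frame with columns `subject_id`, `age`, `sex`,
#'   `handedness`, `iq`, `site`, `eyestat`.
#' @export
generate_personal_table <- function(n, missing_rate = 0.1, seed = 1L) {
  stopifnot(n >= 1, missing_rate >= 0, missing_rate < 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  tab <- data.frame(
    subject_id = sprintf("sub%04d", seq_len(n)),
    age = round(rnorm(n, 12, 3), 1),
    sex = sample(c("F", "M"), n, replace = TRUE),
    handedness = round(runif(n, -1, 1), 2),
    iq = round(rnorm(n, 110, 13)),
    site = sample(paste0("site", 1:4), n, replace = TRUE),
    eyestat = sample(0:1, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  n_miss <- round(n * missing_rate)
  if (n_miss > 0) tab$iq[sample(n, n_miss)] <- NA
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  tab
}
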