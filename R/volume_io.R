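#' Construct a 3D intensity volume
#'
#' A `volume3d` holds a 3-axis real array of voxel intensities indexed
#' `(x, y, z)` together with its grid geometry: the physical voxel size and
#' the anatomical (mm) coordinate of voxel `(0, 0, 0)`.  The anatomical
#' coordinate of 0-based voxel index `(i, j, k)` is
#' `origin_mm + voxel_size_mm * (i, j, k)`; arrays are never reoriented.
#'
#' @param intensities 3-axis numeric array, all values finite.
#' @param voxel_size_mm length-3 positive numeric, voxel edge lengths in mm.
#' @param origin_mm length-3 numeric, mm coordinate of voxel `(0, 0, 0)`.
#' @return An object of class `volume3d` with elements `intensities`,
#'   `dims`, `voxel_size_mm`, `origin_mm`.
#' @seealso [scan4d()], [read_volume()], [extract_hog()]
#' @export
volume3d <- function(intensities, voxel_size_mm = c(2, 2, 2),
                     origin_mm = c(0, 0, 0)) {
  intensities <- as.array(intensities)
  if (length(dim(intensities)) != 3L)
    stop("'intensities' must be a 3-axis array")
  if (!all(is.finite(intensities)))
    stop("volume contains non-finite intensities")
  stopifnot(length(voxel_size_mm) == 3L, all(voxel_size_mm > 0),
            length(origin_mm) == 3L)
  structure(list(intensities = intensities, dims = dim(intensities),
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 origin_mm = as.numeric(origin_mm)),
            class = "volume3d")
}

#' Construct a 4D scan (time series of 3D volumes)
#'
#' A `scan4d` holds voxel intensities indexed `(x, y, z, t)`, e.g. a
#' resting-state fMRI acquisition with `k` time points.
#'
#' @param intensities 4-axis numeric array, all values finite; the fourth
#'   axis is time and must have extent >= 1.
#' @inheritParams volume3d
#' @return An object of class `scan4d`.
#' @seealso [time_average()], [znormalize()]
#' @export
scan4d <- function(intensities, voxel_size_mm = c(2, 2, 2),
                   origin_mm = c(0, 0, 0)) {
  intensities <- as.array(intensities)
  if (length(dim(intensities)) != 4L)
    stop("'intensities' must be a 4-axis array")
  if (dim(intensities)[4] < 1L) stop("time extent must be >= 1")
  if (!all(is.finite(intensities)))
    stop("scan contains non-finite intensities")
  stopifnot(length(voxel_size_mm) == 3L, all(voxel_size_mm > 0),
            length(origin_mm) == 3L)
  structure(list(intensities = intensities, dims = dim(intensities),
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 origin_mm = as.numeric(origin_mm)),
            class = "scan4d")
}

#' Grid geometry of a volumetric image
#'
#' Records image dimensions, voxel size, and origin.  The default is the
#' canonical 2 mm grid of 79 x 95 x 68 voxels spanning the bounding box
#' from (-78, -112, -50) mm, the grid on which spatially normalized brain
#' volumes are commonly resampled.
#'
#' @param dims length-3 positive integers.
#' @param voxel_size_mm length-3 positive numeric (mm).
#' @param origin_mm length-3 numeric; mm coordinate of voxel `(0, 0, 0)`.
#' @return An object of class `grid_geometry`.
#' @export
grid_geometry <- function(dims = c(79L, 95L, 68L), voxel_size_mm = c(2, 2, 2),
                          origin_mm = c(-78, -112, -50)) {
  stopifnot(length(dims) == 3L, all(dims >= 1),
            length(voxel_size_mm) == 3L, all(voxel_size_mm > 0),
            length(origin_mm) == 3L)
  structure(list(dims = as.integer(dims),
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 origin_mm = as.numeric(origin_mm)),
            class = "grid_geometry")
}

#' Convert 0-based voxel indices to anatomical mm coordinates
#'
#' @param grid A [grid_geometry()].
#' @param voxel Numeric length-3 vector (0-based voxel index; may be
#'   fractional, e.g. a block center).
#' @return Length-3 numeric mm coordinate.
#' @export
voxel_to_mm <- function(grid, voxel) {
  stopifnot(inherits(grid, "grid_geometry"), length(voxel) == 3L)
  grid$origin_mm + grid$voxel_size_mm * as.numeric(voxel)
}

#' Read a NIfTI-1 volume or 4D scan
#'
#' Reads a `.nii` or `.nii.gz` file.  A file with three dimensions yields a
#' [volume3d()], four dimensions a [scan4d()].  Voxel size is taken from the
#' file's pixdim and the origin from the translation part of its affine; the
#' array is kept in the file's own `(x, y, z[, t])` axis order without
#' reorientation.
#'
#' @param path Path to a readable NIfTI-1 file.
#' @return A `volume3d` or `scan4d`.
#' @seealso [write_volume()]
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop("cannot read NIfTI file '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  arr <- as.array(img)
  nd <- length(dim(arr))
  if (!nd %in% c(3L, 4L))
    stop("file '", path, "' has ", nd, " dimensions; expected 3 or 4")
  if (!all(is.finite(arr)))
    stop("file '", path, "' contains non-finite voxel values")
  vs <- abs(RNifti::pixdim(img))[1:3]
  xf <- try(RNifti::xform(img), silent = TRUE)
  origin <- if (inherits(xf, "try-error")) c(0, 0, 0) else as.numeric(xf[1:3, 4])
  if (nd == 3L) volume3d(arr, vs, origin) else scan4d(arr, vs, origin)
}

#' Write a volume or scan to a NIfTI-1 file
#'
#' @param vol A [volume3d()] or [scan4d()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume3d") || inherits(vol, "scan4d"))
  img <- RNifti::asNifti(vol$intensities)
  nd <- length(vol$dims)
  pd <- if (nd == 4L) c(vol$voxel_size_mm, 1) else vol$voxel_size_mm
  img <- RNifti::`pixdim<-`(img, pd)
  aff <- rbind(cbind(diag(vol$voxel_size_mm), vol$origin_mm), c(0, 0, 0, 1))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Average a 4D scan across time
#'
#' Collapses a functional time series to a single 3D volume by the per-voxel
#' arithmetic mean `f(x,y,z) = (1/k) * sum_t f(x,y,z,t)` over the `k` time
#' points.  Geometry is preserved.
#'
#' @param scan A [scan4d()].
#' @return A [volume3d()] of the per-voxel temporal means.
#' @export
time_average <- function(scan) {
  stopifnot(inherits(scan, "scan4d"))
  k <- scan$dims[4]
  m <- rowMeans(array(scan$intensities, c(prod(scan$dims[1:3]), k)))
  volume3d(array(m, scan$dims[1:3]), scan$voxel_size_mm, scan$origin_mm)
}

#' Subject-level z-score normalization
#'
#' Standardizes image intensities to zero mean and unit standard deviation
#' using one global mean and SD computed over every entry of the image (all
#' voxels, and all time points for a 4D scan) -- not per voxel.  This places
#' images scanned at different sites on a common intensity scale.  The SD is
#' the population standard deviation (divisor `n`).
#'
#' For 4D data, z-score first and average afterwards with [time_average()].
#'
#' @param vol A [volume3d()] or [scan4d()].
#' @return Object of the same class with standardized intensities.
#' @section Degenerate input: A constant image (zero variance) is rejected
#'   with an error rather than silently mapped to zeros, since a zero volume
#'   would propagate meaningless downstream texture features.
#' @export
znormalize <- function(vol) {
  stopifnot(inherits(vol, "volume3d") || inherits(vol, "scan4d"))
  x <- vol$intensities
  mu <- mean(x)
  sdev <- sqrt(mean((x - mu)^2))
  if (sdev <= 0)
    stop("degenerate input: image has zero intensity variance")
  vol$intensities <- (x - mu) / sdev
  vol
}

#' @export
print.volume3d <- function(x, ...) {
  cat("<volume3d> ", paste(x$dims, collapse = " x "),
      " voxels, voxel size ", paste(x$voxel_size_mm, collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' @export
print.scan4d <- function(x, ...) {
  cat("<scan4d> ", paste(x$dims[1:3], collapse = " x "), " voxels x ",
      x$dims[4], " time points\n", sep = "")
  invisible(x)
}
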