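#' Construct a label volume
#'
#' A 3D integer grid with a voxel-index-to-mm affine. Labels form a hard
#' segmentation: each voxel carries exactly one label. Voxel indices are
#' 0-based and map through the affine to voxel centres (NIfTI convention).
#'
#' @param grid 3D array of integer labels.
#' @param affine 4x4 voxel-to-world matrix (invertible).
#' @param label_names Optional named character vector mapping label integers
#'   (names) to region names.
#' @return Object of class `label_volume`.
#' @export
label_volume <- function(grid, affine, label_names = NULL) {
  if (length(dim(grid)) != 3L)
    stop("grid must be a 3D array", call. = FALSE)
  if (!is.numeric(grid) || any(grid != round(grid)))
    stop("label volumes must hold integer-valued data", call. = FALSE)
  storage.mode(grid) <- "integer"
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || !is.finite(det(affine)) ||
      abs(det(affine)) < .Machine$double.eps)
    stop("affine must be an invertible 4x4 matrix", call. = FALSE)
  if (abs(det(affine[1:3, 1:3])) <= 0)
    stop("affine spatial block must have nonzero determinant", call. = FALSE)
  structure(list(grid = grid, affine = affine, label_names = label_names),
            class = "label_volume")
}

#' Voxel volume of a label volume, in mm^3
#' @param v A [label_volume()].
#' @return Scalar mm^3.
#' @export
voxel_volume <- function(v) {
  stopifnot(inherits(v, "label_volume"))
  abs(det(v$affine[1:3, 1:3]))
}

#' @export
print.label_volume <- function(x, ...) {
  labs <- sort(unique(as.vector(x$grid)))
  cat(sprintf("label_volume: %s grid, %.3g mm^3 voxels, labels {%s}\n",
              paste(dim(x$grid), collapse = "x"), voxel_volume(x),
              paste(labs, collapse = ",")))
  invisible(x)
}

#' Read a NIfTI label volume
#'
#' @param path NIfTI-1 file with integer-valued data.
#' @param label_names Optional label-name map to attach.
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path, label_names = NULL) {
  img <- RNifti::readNifti(path)
  raw <- as.array(img)
  grid <- array(as.vector(raw), dim = dim(raw)[1:3])  # strip RNifti attributes
  if (any(grid != round(grid)))
    stop(sprintf("'%s' holds non-integer data; not a label volume", path),
         call. = FALSE)
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = c(4L, 4L))
  label_volume(grid, affine, label_names)
}

#' Write a label volume as NIfTI-1
#'
#' @param v A [label_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(v, path) {
  stopifnot(inherits(v, "label_volume"))
  img <- RNifti::asNifti(v$grid)
  # sform only: the qform route stores a quaternion + pixdim and does not
  # round-trip anisotropic or sheared affines exactly
  img <- RNifti::`sform<-`(img, value = structure(v$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "int32")
  invisible(path)
}

#' Read a 4x4 affine from a whitespace-delimited text file
#' @param path Text file containing 16 numbers, row-major.
#' @return 4x4 matrix.
#' @export
read_affine <- function(path) {
  v <- scan(path, what = double(), quiet = TRUE)
  if (length(v) != 16L)
    stop(sprintf("affine file '%s' must contain exactly 16 numbers", path),
         call. = FALSE)
  matrix(v, 4L, 4L, byrow = TRUE)
}

#' Map world-space points (mm) to 0-based voxel indices
#'
#' Continuous voxel coordinates via the inverse affine; no rounding.
#'
#' @param points n x 3 matrix of mm coordinates.
#' @param affine 4x4 voxel-to-world matrix.
#' @return n x 3 matrix of continuous 0-based voxel coordinates.
#' @export
world_to_voxel <- function(points, affine) {
  points <- as.matrix(points)
  inv <- solve(affine)
  h <- cbind(points, 1) %*% t(inv)
  h[, 1:3, drop = FALSE]
}

# round-half-away-from-zero, the fixed tie rule for voxel membership
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
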