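#' Construct a spatial transform
#'
#' An affine map optionally followed by a dense displacement field (applied
#' after the affine). The field stores, for each of its voxels, a 3-vector
#' displacement in mm; values are looked up by trilinear interpolation at the
#' affine-mapped point.
#'
#' @param affine 4x4 invertible matrix (default identity).
#' @param displacement Optional list with elements `field` (4D array
#'   X x Y x Z x 3 of mm displacements) and `affine` (4x4 voxel-to-world map
#'   of the field grid).
#' @return Object of class `spatial_transform`.
#' @export
spatial_transform <- function(affine = diag(4), displacement = NULL) {
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < .Machine$double.eps)
    stop("affine must be an invertible 4x4 matrix", call. = FALSE)
  if (!is.null(displacement)) {
    stopifnot(is.list(displacement), !is.null(displacement$field),
              !is.null(displacement$affine))
    fd <- dim(displacement$field)
    if (length(fd) != 4L || fd[4] != 3L)
      stop("displacement field must be an X x Y x Z x 3 array", call. = FALSE)
    if (!all(is.finite(displacement$field)))
      stop("displacement field values must be finite", call. = FALSE)
    displacement$affine <- as.matrix(displacement$affine)
  }
  structure(list(affine = affine, displacement = displacement),
            class = "spatial_transform")
}

#' Read a displacement field from a vector-valued NIfTI file
#'
#' Accepts fields stored as X x Y x Z x 3 or X x Y x Z x 1 x 3.
#'
#' @param path NIfTI path.
#' @return List with `field` (4D array) and `affine`, suitable for
#'   [spatial_transform()].
#' @export
read_displacement_field <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  d <- dim(arr)
  if (length(d) == 5L && d[4] == 1L) arr <- array(arr, d[c(1:3, 5)])
  if (length(dim(arr)) != 4L || dim(arr)[4] != 3L)
    stop(sprintf("'%s' is not a 3-component displacement field", path),
         call. = FALSE)
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = c(4L, 4L))
  list(field = arr, affine = affine)
}

# Trilinear interpolation of the displacement field at world points (n x 3).
# Points whose continuous field-voxel coordinates fall outside [0, dim-1]
# are out of domain -> NA rows.
interp_displacement <- function(displacement, points) {
  vox <- world_to_voxel(points, displacement$affine)
  fd <- dim(displacement$field)[1:3]
  out <- matrix(NA_real_, nrow(vox), 3L)
  ok <- vox[, 1] >= 0 & vox[, 1] <= fd[1] - 1 &
        vox[, 2] >= 0 & vox[, 2] <= fd[2] - 1 &
        vox[, 3] >= 0 & vox[, 3] <= fd[3] - 1
  if (!any(ok)) return(out)
  v <- vox[ok, , drop = FALSE]
  f0 <- pmin(floor(v), matrix(rep(fd - 2, each = nrow(v)), ncol = 3))
  f0 <- pmax(f0, 0)
  w <- v - f0
  acc <- matrix(0, nrow(v), 3L)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wt <- (if (dx) w[, 1] else 1 - w[, 1]) *
          (if (dy) w[, 2] else 1 - w[, 2]) *
          (if (dz) w[, 3] else 1 - w[, 3])
    idx <- cbind(f0[, 1] + dx, f0[, 2] + dy, f0[, 3] + dz) + 1L
    for (comp in 1:3) {
      acc[, comp] <- acc[, comp] +
        wt * displacement$field[cbind(idx, comp)]
    }
  }
  out[ok, ] <- acc
  out
}

#' Apply a spatial transform to a tractogram
#'
#' Every point is mapped through the affine first, then (if present) offset by
#' the trilinearly interpolated displacement field. Streamline and point
#' counts are unchanged.
#'
#' @param t A [tractogram()].
#' @param xf A [spatial_transform()].
#' @param space_id Spatial tag of the output (default appends `"+warped"`).
#' @return A transformed [tractogram()].
#' @export
transform_tractogram <- function(t, xf, space_id = NULL) {
  stopifnot(inherits(t, "tractogram"), inherits(xf, "spatial_transform"))
  if (is.null(space_id)) space_id <- paste0(t$space_id, "+warped")
  out <- vector("list", length(t))
  for (i in seq_along(out)) {
    p <- cbind(unclass(t$streamlines[[i]]), 1) %*% t(xf$affine)
    p <- p[, 1:3, drop = FALSE]
    if (!is.null(xf$displacement)) {
      disp <- interp_displacement(xf$displacement, p)
      if (anyNA(disp))
        stop(sprintf("streamline %d has points outside the displacement-field domain", i),
             call. = FALSE)
      p <- p + disp
    }
    out[[i]] <- p
  }
  tractogram(out, space_id = space_id)
}
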