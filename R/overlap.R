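#' Percentage of bundle streamlines transected by a binary mask
#'
#' Each streamline is resampled at an arc-length step no larger than `step`
#' and counted as transected if any sample point falls in a nonzero voxel of
#' the mask (nearest-voxel membership, round-half-away-from-zero per index;
#' points outside the grid are ignored). 100% means complete transection of
#' the bundle.
#'
#' @param t A [tractogram()], non-empty.
#' @param mask Binary [label_volume()] (labels 0/1).
#' @param step Sampling step in mm; default half the smallest voxel edge.
#' @param bundle_name Name recorded in the result.
#' @param check_space If `TRUE` (default), require `t$space_id` to match the
#'   mask's `space_id` attribute when both are set.
#' @return A `streamline_overlap` result: list with `bundle_name`,
#'   `n_streamlines`, `n_transected`, `percent`.
#' @export
streamline_mask_overlap <- function(t, mask, step = NULL,
                                    bundle_name = "bundle",
                                    check_space = TRUE) {
  stopifnot(inherits(t, "tractogram"), inherits(mask, "label_volume"))
  if (length(t) == 0L)
    stop("cannot score an empty tractogram", call. = FALSE)
  labs <- unique(as.vector(mask$grid))
  if (!all(labs %in% c(0L, 1L)))
    stop("mask must be binary (labels 0/1)", call. = FALSE)
  mask_space <- attr(mask, "space_id")
  if (check_space && !is.null(mask_space) && !identical(mask_space, t$space_id))
    stop(sprintf("space mismatch: tractogram '%s' vs mask '%s'",
                 t$space_id, mask_space), call. = FALSE)
  if (is.null(step)) {
    edges <- sqrt(colSums(mask$affine[1:3, 1:3]^2))
    step <- min(edges) / 2
  }
  stopifnot(step > 0)
  dims <- dim(mask$grid)
  transected <- logical(length(t))
  for (i in seq_along(transected)) {
    s <- t$streamlines[[i]]
    len <- sum(sqrt(rowSums(diff(unclass(s))^2)))
    npts <- max(2L, as.integer(ceiling(len / step)) + 1L)
    p <- resample_streamline(s, npts)
    vox <- round_half_away(world_to_voxel(p, mask$affine))
    inside <- vox[, 1] >= 0 & vox[, 1] < dims[1] &
              vox[, 2] >= 0 & vox[, 2] < dims[2] &
              vox[, 3] >= 0 & vox[, 3] < dims[3]
    if (!any(inside)) next
    idx <- vox[inside, , drop = FALSE] + 1
    transected[i] <- any(mask$grid[idx] != 0L)
  }
  structure(list(bundle_name = bundle_name,
                 n_streamlines = length(transected),
                 n_transected = sum(transected),
                 percent = 100 * sum(transected) / length(transected)),
            class = "streamline_overlap")
}

#' @export
print.streamline_overlap <- function(x, ...) {
  cat(sprintf("%s: %d/%d streamlines transected (%.1f%%)\n",
              x$bundle_name, x$n_transected, x$n_streamlines, x$percent))
  invisible(x)
}

#' Overlap volume between an ablation mask and each segmentation label
#'
#' For every label of the hard segmentation, the overlap volume is the count
#' of voxels carrying that label inside the ablation mask times the voxel
#' volume. Background (label 0) is reported alongside the named labels so the
#' per-label volumes sum exactly to the ablation volume.
#'
#' @param seg [label_volume()] hard segmentation.
#' @param ablation Binary [label_volume()] on the same grid (shape and affine
#'   must agree within `tol`).
#' @param tol Elementwise affine agreement tolerance (default 1e-4).
#' @return Data frame with columns `label`, `name`, `overlap_mm3`, one row
#'   per distinct label of `seg`.
#' @export
label_overlap_volumes <- function(seg, ablation, tol = 1e-4) {
  stopifnot(inherits(seg, "label_volume"), inherits(ablation, "label_volume"))
  if (!identical(dim(seg$grid), dim(ablation$grid)))
    stop("segmentation and ablation grids differ in shape", call. = FALSE)
  if (max(abs(seg$affine - ablation$affine)) > tol)
    stop(sprintf("segmentation and ablation affines differ by more than %g", tol),
         call. = FALSE)
  labs <- unique(as.vector(ablation$grid))
  if (!all(labs %in% c(0L, 1L)))
    stop("ablation mask must be binary (labels 0/1)", call. = FALSE)
  vv <- voxel_volume(seg)
  all_labels <- sort(unique(as.vector(seg$grid)))
  inside <- seg$grid[ablation$grid == 1L]
  counts <- vapply(all_labels, function(L) sum(inside == L), integer(1))
  name <- as.character(all_labels)
  if (!is.null(seg$label_names)) {
    hit <- match(name, names(seg$label_names))
    name[!is.na(hit)] <- seg$label_names[hit[!is.na(hit)]]
  }
  name[all_labels == 0L & name == "0"] <- "background"
  data.frame(label = all_labels, name = name,
             overlap_mm3 = counts * vv,
             stringsAsFactors = FALSE)
}
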