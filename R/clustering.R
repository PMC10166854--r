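#' Single-pass incremental MDF clustering of streamlines
#'
#' Streamlines are processed in stored order. Each streamline (resampled to
#' `k` points) is compared by minimum average direct-flip (MDF) distance to
#' the running centroid of every existing cluster; it joins the nearest
#' cluster if that distance is strictly below `threshold`, otherwise it founds
#' a new cluster. On joining, the streamline is flip-aligned to the centroid
#' and the centroid is updated as the running mean of flip-aligned members.
#' The result is order-dependent by construction; callers that need exact
#' reproducibility must fix input order.
#'
#' @param t A [tractogram()], non-empty.
#' @param threshold Merge threshold in mm, > 0.
#' @param k Resampling point count (default 12).
#' @return A `cluster_decomposition`: list with `clusters` (each with
#'   `centroid`, a k-point streamline, and `member_ids`), `labels`
#'   (per-streamline cluster index), `threshold_mm`, `k` and `amp_roles`
#'   (`NULL` here; set by [select_amp_clusters()]).
#' @export
quickbundles <- function(t, threshold, k = 12L) {
  stopifnot(inherits(t, "tractogram"))
  if (length(t) == 0L) stop("cannot cluster an empty tractogram", call. = FALSE)
  if (!is.numeric(threshold) || threshold <= 0)
    stop("threshold must be > 0 mm", call. = FALSE)
  A <- resample_tractogram_array(t, k)
  n <- dim(A)[1]
  sums <- list()     # per-cluster k x 3 running sums of flip-aligned members
  counts <- integer(0)
  members <- list()
  labels <- integer(n)
  for (i in seq_len(n)) {
    P <- matrix(A[i, , ], ncol = 3)
    if (length(counts) > 0L) {
      dd <- numeric(length(counts)); ff <- numeric(length(counts))
      for (c in seq_along(counts)) {
        C <- sums[[c]] / counts[c]
        dd[c] <- mean(sqrt(rowSums((P - C)^2)))
        ff[c] <- mean(sqrt(rowSums((P[k:1, , drop = FALSE] - C)^2)))
      }
      d <- pmin(dd, ff)
      best <- which.min(d)
      if (d[best] < threshold) {
        aligned <- if (ff[best] < dd[best]) P[k:1, , drop = FALSE] else P
        sums[[best]] <- sums[[best]] + aligned
        counts[best] <- counts[best] + 1L
        members[[best]] <- c(members[[best]], i)
        labels[i] <- best
        next
      }
    }
    sums[[length(sums) + 1L]] <- P
    counts <- c(counts, 1L)
    members[[length(members) + 1L]] <- i
    labels[i] <- length(counts)
  }
  clusters <- lapply(seq_along(counts), function(c)
    list(centroid = streamline(sums[[c]] / counts[c]), member_ids = members[[c]]))
  structure(list(clusters = clusters, labels = labels,
                 threshold_mm = threshold, k = k, amp_roles = NULL),
            class = "cluster_decomposition")
}

#' @export
print.cluster_decomposition <- function(x, ...) {
  sizes <- vapply(x$clusters, function(c) length(c$member_ids), integer(1))
  cat(sprintf("cluster_decomposition: %d clusters at threshold %.2f mm (sizes: %s)\n",
              length(sizes), x$threshold_mm, paste(sizes, collapse = ", ")))
  if (!is.null(x$amp_roles))
    cat("  roles:", paste(sprintf("%s=cluster %d", names(x$amp_roles), x$amp_roles),
                          collapse = ", "), "\n")
  invisible(x)
}

# mean coordinate along the anterior axis of the mid-tract slab of a centroid.
# axis: "x+","x-","y+","y-","z+","z-"; sign flips the ranking direction so
# "y+" means larger y = more anterior (RAS convention).
centroid_anterior_coord <- function(centroid, axis = "y+", slab = c(1 / 3, 2 / 3)) {
  ax <- match(substr(axis, 1, 1), c("x", "y", "z"))
  if (is.na(ax)) stop("axis must start with one of x, y, z", call. = FALSE)
  sgn <- if (substr(axis, 2, 2) == "-") -1 else 1
  k <- nrow(centroid)
  idx <- max(1L, floor(k * slab[1]) + 1L):min(k, ceiling(k * slab[2]))
  sgn * mean(centroid[idx, ax])
}

#' Adaptive-threshold selection of anterior/middle/posterior clusters
#'
#' Runs [quickbundles()] at `start_threshold`, `start_threshold + step`, ...
#' until a decomposition contains at least three clusters each holding at
#' least `min_fraction` of the streamlines. The three largest such clusters
#' are role-labelled anterior/middle/posterior by the rank of the mean
#' anterior-axis coordinate of their centroid points within a mid-tract slab
#' (by default the middle third of centroid points, avoiding the convergent
#' endpoint regions).
#'
#' @param t A [tractogram()].
#' @param start_threshold,step,max_threshold Threshold search grid in mm
#'   (defaults 2, 1, 30).
#' @param axis Anterior axis spec, e.g. `"y+"` (default): larger y is more
#'   anterior.
#' @param min_fraction Minimum cluster size as a fraction of streamlines for
#'   a cluster to qualify for a role (default 0.05).
#' @param slab Fractional range of centroid point indices used for the
#'   anterior-coordinate ranking (default middle third).
#' @param k Resampling point count.
#' @return A `cluster_decomposition` with `amp_roles` set (named integer
#'   vector over `anterior`, `middle`, `posterior`) and `threshold_mm` the
#'   first qualifying threshold; the searched thresholds and their cluster
#'   counts are attached as attribute `trajectory`.
#' @export
select_amp_clusters <- function(t, start_threshold = 2, step = 1,
                                max_threshold = 30, axis = "y+",
                                min_fraction = 0.05, slab = c(1 / 3, 2 / 3),
                                k = 12L) {
  stopifnot(start_threshold > 0, start_threshold < max_threshold, step > 0)
  n <- length(t)
  thresholds <- seq(start_threshold, max_threshold, by = step)
  trajectory <- data.frame(threshold_mm = thresholds,
                           n_clusters = NA_integer_,
                           n_qualifying = NA_integer_)
  for (row in seq_along(thresholds)) {
    dec <- quickbundles(t, thresholds[row], k = k)
    sizes <- vapply(dec$clusters, function(c) length(c$member_ids), integer(1))
    qualifying <- which(sizes >= min_fraction * n)
    trajectory$n_clusters[row] <- length(sizes)
    trajectory$n_qualifying[row] <- length(qualifying)
    if (length(qualifying) >= 3L) {
      top3 <- qualifying[order(-sizes[qualifying])][1:3]
      coord <- vapply(top3, function(c)
        centroid_anterior_coord(dec$clusters[[c]]$centroid, axis, slab),
        numeric(1))
      ord <- top3[order(coord)]  # smallest anterior coordinate first
      dec$amp_roles <- c(posterior = ord[1], middle = ord[2], anterior = ord[3])
      attr(dec, "trajectory") <- trajectory[seq_len(row), ]
      return(dec)
    }
  }
  stop(paste0("no threshold up to ", max_threshold,
              " mm produced 3 qualifying clusters; cluster counts were: ",
              paste(sprintf("%g mm -> %d (%d qualifying)",
                            trajectory$threshold_mm, trajectory$n_clusters,
                            trajectory$n_qualifying), collapse = "; ")),
       call. = FALSE)
}

#' Assign every streamline to the nearest of three role centroids
#'
#' Forced-choice assignment by MDF distance: each streamline receives the
#' role of the nearest centroid, so the three roles partition the tractogram.
#'
#' @param t A [tractogram()], non-empty.
#' @param centroids Named list of exactly 3 streamlines; names are the roles
#'   (`anterior`, `middle`, `posterior`).
#' @param k Resampling point count.
#' @return Character vector of roles, one per streamline.
#' @export
assign_to_centroids <- function(t, centroids, k = 12L) {
  stopifnot(inherits(t, "tractogram"))
  if (length(t) == 0L) stop("cannot assign an empty tractogram", call. = FALSE)
  if (length(centroids) != 3L || is.null(names(centroids)))
    stop("centroids must be a named list of exactly 3 streamlines", call. = FALSE)
  A <- resample_tractogram_array(t, k)
  C <- array(0, c(3L, k, 3L))
  for (j in 1:3) C[j, , ] <- resample_streamline(centroids[[j]], k)
  D <- mdf_matrix_arrays(A, C)
  names(centroids)[apply(D, 1L, which.min)]
}

#' Extract the role-named centroid list from a decomposition
#' @param dec A `cluster_decomposition` with `amp_roles` set.
#' @return Named list of 3 centroid streamlines.
#' @export
amp_centroids <- function(dec) {
  stopifnot(inherits(dec, "cluster_decomposition"), !is.null(dec$amp_roles))
  stats::setNames(lapply(dec$amp_roles, function(i) dec$clusters[[i]]$centroid),
                  names(dec$amp_roles))
}

#' Streamline coherence scores
#'
#' The coherence score of a streamline is its mean MDF distance to all other
#' streamlines of the tractogram (exact O(N^2) computation); smaller is more
#' coherent.
#'
#' @param t A [tractogram()] with at least 2 streamlines.
#' @param k Resampling point count.
#' @return Numeric vector of scores, one per streamline.
#' @export
coherence_scores <- function(t, k = 12L) {
  n <- length(t)
  if (n < 2L) return(rep(0, n))
  D <- mdf_distance_matrix(t, k)
  rowSums(D) / (n - 1)
}

#' Keep the most coherent streamlines of a tractogram
#'
#' Retains the `n_keep` streamlines with the smallest mean MDF distance to
#' all others, ties broken by original index; the streamlines themselves are
#' returned unmodified (original point counts).
#'
#' @param t A [tractogram()].
#' @param n_keep Number of streamlines to keep (>= 1); if `n_keep >=
#'   length(t)` the tractogram is returned unchanged.
#' @param k Resampling point count used for the distance.
#' @return A filtered [tractogram()]; kept original indices are attached as
#'   attribute `kept`.
#' @export
coherence_filter <- function(t, n_keep, k = 12L) {
  stopifnot(inherits(t, "tractogram"))
  if (!is.numeric(n_keep) || n_keep < 1L)
    stop("n_keep must be >= 1", call. = FALSE)
  n <- length(t)
  if (n_keep >= n) {
    attr(t, "kept") <- seq_len(n)
    return(t)
  }
  score <- coherence_scores(t, k)
  keep <- sort(order(score, seq_len(n))[seq_len(n_keep)])
  out <- tractogram(t$streamlines[keep], space_id = t$space_id)
  attr(out, "kept") <- keep
  out
}

#' Build a cross-subject template bundle
#'
#' Concatenates per-subject streamline sets (all in one template space) and
#' keeps the `n_keep` most coherent streamlines of the pooled set. Output
#' streamlines are members of the input union, not averages.
#'
#' @param per_subject List of [tractogram()]s sharing one `space_id`.
#' @param n_keep Retention count (default 1000).
#' @param k Resampling point count.
#' @return A [tractogram()] in the shared space.
#' @export
build_template_bundle <- function(per_subject, n_keep = 1000L, k = 12L) {
  stopifnot(is.list(per_subject), length(per_subject) >= 1L)
  spaces <- unique(vapply(per_subject, function(t) t$space_id, character(1)))
  if (length(spaces) != 1L)
    stop(sprintf("all subject tractograms must share one space; got: %s",
                 paste(spaces, collapse = ", ")), call. = FALSE)
  pooled <- tractogram(unlist(lapply(per_subject, function(t) t$streamlines),
                              recursive = FALSE),
                       space_id = spaces)
  coherence_filter(pooled, n_keep, k = k)
}
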