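#' Construct a streamline
#'
#' A streamline is an ordered polyline of 3D points in scanner (RAS) mm.
#'
#' @param points Numeric matrix with one row per point and 3 columns (x, y, z
#'   in mm). At least 2 rows; all values finite.
#' @return A numeric matrix of class `streamline`.
#' @export
streamline <- function(points) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 3L)
    stop("a streamline needs an n x 3 numeric matrix of points", call. = FALSE)
  if (nrow(points) < 2L)
    stop("a streamline needs at least 2 points", call. = FALSE)
  if (!all(is.finite(points)))
    stop("streamline coordinates must all be finite", call. = FALSE)
  storage.mode(points) <- "double"
  dimnames(points) <- NULL
  class(points) <- c("streamline", "matrix", "array")
  points
}

#' Construct a tractogram
#'
#' @param streamlines List of streamlines (n x 3 matrices).
#' @param space_id Free-text spatial reference tag shared by all streamlines,
#'   e.g. `"native-dwi"` or `"template"`.
#' @return An object of class `tractogram` with elements `streamlines` and
#'   `space_id`.
#' @export
tractogram <- function(streamlines = list(), space_id = "unknown") {
  stopifnot(is.list(streamlines), is.character(space_id), length(space_id) == 1L)
  streamlines <- lapply(streamlines, streamline)
  structure(list(streamlines = streamlines, space_id = space_id),
            class = "tractogram")
}

#' @export
length.tractogram <- function(x) length(x$streamlines)

#' @export
print.tractogram <- function(x, ...) {
  np <- vapply(x$streamlines, nrow, integer(1))
  cat(sprintf("tractogram: %d streamlines in space '%s'", length(np), x$space_id))
  if (length(np) > 0)
    cat(sprintf(" (%d-%d points per streamline)", min(np), max(np)))
  cat("\n")
  invisible(x)
}

# one pass of equal-arc-length piecewise-linear interpolation
arc_resample_once <- function(p, k) {
  seg <- diff(p)
  cum <- c(0, cumsum(sqrt(rowSums(seg^2))))
  total <- cum[length(cum)]
  if (total == 0) return(p[rep(1L, k), , drop = FALSE])
  target <- seq(0, total, length.out = k)
  out <- matrix(0, k, 3)
  for (d in 1:3)
    out[, d] <- stats::approx(cum, p[, d], xout = target, ties = "ordered")$y
  out[1L, ] <- p[1L, ]
  out[k, ] <- p[nrow(p), ]
  out
}

#' Resample a streamline to a fixed number of points
#'
#' Piecewise-linear interpolation at equal arc-length spacing along the
#' polyline, iterated to a fixed point so that consecutive segment lengths of
#' the output are equal (a single pass leaves residual inequality wherever
#' the polyline bends, because chord lengths of the resampled polyline differ
#' from arc-length spacing on the original). Endpoints are preserved exactly
#' and the operation is idempotent at fixed `k`.
#'
#' @param s A streamline (n x 3 matrix).
#' @param k Number of output points, at least 2.
#' @return A `streamline` with `k` rows.
#' @export
resample_streamline <- function(s, k) {
  s <- streamline(s)
  if (!is.numeric(k) || length(k) != 1L || k < 2)
    stop("k must be a single integer >= 2", call. = FALSE)
  k <- as.integer(k)
  out <- arc_resample_once(unclass(s), k)
  for (iter in seq_len(200L)) {
    nxt <- arc_resample_once(out, k)
    if (max(abs(nxt - out)) < 1e-9) { out <- nxt; break }
    out <- nxt
  }
  streamline(out)
}

#' Minimum average direct-flip (MDF) distance between two streamlines
#'
#' Both streamlines are resampled to `k` points; the distance is the smaller
#' of the mean point-wise Euclidean distance taken directly and with one
#' streamline reversed. Symmetric, non-negative and flip-invariant.
#'
#' @param a,b Streamlines.
#' @param k Resampling point count (default 12).
#' @return Distance in mm.
#' @export
mdf_distance <- function(a, b, k = 12L) {
  pa <- resample_streamline(a, k)
  pb <- resample_streamline(b, k)
  direct <- mean(sqrt(rowSums((pa - pb)^2)))
  flip <- mean(sqrt(rowSums((pa - pb[nrow(pb):1, , drop = FALSE])^2)))
  min(direct, flip)
}

#' Resample every streamline of a tractogram into a point array
#'
#' @param t Tractogram.
#' @param k Point count.
#' @return Array of dim `c(n_streamlines, k, 3)`.
#' @keywords internal
resample_tractogram_array <- function(t, k = 12L) {
  n <- length(t)
  arr <- array(0, c(n, k, 3))
  for (i in seq_len(n))
    arr[i, , ] <- resample_streamline(t$streamlines[[i]], k)
  arr
}

# Pairwise MDF between two resampled point arrays (nA x k x 3, nB x k x 3).
# Vectorised: one nA x nB distance accumulation per resampled point index,
# direct and flipped, then the elementwise minimum.
mdf_matrix_arrays <- function(A, B) {
  k <- dim(A)[2]
  nA <- dim(A)[1]; nB <- dim(B)[1]
  direct <- matrix(0, nA, nB)
  flip <- matrix(0, nA, nB)
  for (j in seq_len(k)) {
    P <- A[, j, , drop = TRUE]; if (is.null(dim(P))) P <- matrix(P, 1)
    Qd <- B[, j, , drop = TRUE]; if (is.null(dim(Qd))) Qd <- matrix(Qd, 1)
    Qf <- B[, k + 1L - j, , drop = TRUE]; if (is.null(dim(Qf))) Qf <- matrix(Qf, 1)
    p2 <- rowSums(P^2)
    d2 <- outer(p2, rowSums(Qd^2), "+") - 2 * tcrossprod(P, Qd)
    f2 <- outer(p2, rowSums(Qf^2), "+") - 2 * tcrossprod(P, Qf)
    direct <- direct + sqrt(pmax(d2, 0))
    flip <- flip + sqrt(pmax(f2, 0))
  }
  pmin(direct, flip) / k
}

#' Pairwise MDF distance matrix for a tractogram
#'
#' @param t Tractogram.
#' @param k Resampling point count.
#' @return Symmetric `n x n` matrix of MDF distances in mm.
#' @export
mdf_distance_matrix <- function(t, k = 12L) {
  A <- resample_tractogram_array(t, k)
  D <- mdf_matrix_arrays(A, A)
  diag(D) <- 0
  (D + t(D)) / 2
}
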