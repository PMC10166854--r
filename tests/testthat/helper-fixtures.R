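# shared fixtures and independent oracles, built in code at test time

straight_streamline <- function(from = c(0, 0, 0), to = c(0, 0, 10),
                                n = 2L) {
  streamline(mapply(function(a, b) seq(a, b, length.out = n), from, to))
}

# noisy helix: the standard awkward polyline for arc-length checks
helix_streamline <- function(n = 100L, noise_sd = 0.1, seed = 42L) {
  set.seed(seed)
  t <- seq(0, 4 * pi, length.out = n)
  p <- cbind(10 * cos(t), 10 * sin(t), 2 * t)
  streamline(p + matrix(rnorm(3 * n, sd = noise_sd), n, 3))
}

# oracle: cumulative arc length of a polyline by direct segment summation
polyline_arclength <- function(p) {
  c(0, cumsum(sqrt(rowSums(diff(unclass(p))^2))))
}

# oracle: brute-force MDF via the exported scalar distance, pair by pair
brute_mdf_matrix <- function(t, k = 12L) {
  n <- length(t)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- mdf_distance(t$streamlines[[i]], t$streamlines[[j]], k)
  D
}

# oracle: naive triple-loop per-label overlap volume count
brute_label_overlap <- function(seg, ablation) {
  dims <- dim(seg$grid)
  counts <- integer(0)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (kk in seq_len(dims[3])) {
      if (ablation$grid[i, j, kk] == 1L) {
        L <- as.character(seg$grid[i, j, kk])
        counts[L] <- (if (is.na(counts[L])) 0L else counts[L]) + 1L
      }
    }
  counts
}

# a rigid transform (rotation about z plus translation)
rigid_transform <- function(theta = 0.7, shift = c(5, -3, 2)) {
  R <- diag(4)
  R[1:2, 1:2] <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  R[1:3, 4] <- shift
  spatial_transform(R)
}

expect_tractograms_equal <- function(a, b, tol = 1e-6) {
  expect_equal(length(a), length(b))
  for (i in seq_along(a$streamlines))
    expect_equal(unclass(a$streamlines[[i]]), unclass(b$streamlines[[i]]),
                 tolerance = tol)
}
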