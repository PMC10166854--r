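make_box_mask <- function(dim, affine, lo, hi) {
  idx <- as.matrix(expand.grid(i = seq_len(dim[1]) - 1L,
                               j = seq_len(dim[2]) - 1L,
                               k = seq_len(dim[3]) - 1L))
  world <- cbind(idx, 1) %*% t(affine)
  inside <- world[, 1] >= lo[1] & world[, 1] <= hi[1] &
            world[, 2] >= lo[2] & world[, 2] <= hi[2] &
            world[, 3] >= lo[3] & world[, 3] <= hi[3]
  label_volume(array(as.integer(inside), dim), affine)
}

grid_affine <- function(origin) { a <- diag(4); a[1:3, 4] <- origin; a }

test_that("transection percentage spans the 0/25/100 contract", {
  # 4 parallel straight streamlines 10 mm apart along x
  sl <- lapply(c(0, 10, 20, 30), function(x)
    straight_streamline(c(x, 5, 0), c(x, 5, 10), 5))
  t <- tractogram(sl, "native")
  aff <- grid_affine(c(-5, -5, -5))
  dims <- c(45L, 20L, 25L)
  # box enclosing exactly the first streamline -> 25%
  box <- make_box_mask(dims, aff, c(-2, 3, 2), c(2, 7, 8))
  res <- streamline_mask_overlap(t, box, bundle_name = "quartet")
  expect_equal(res$n_transected, 1L)
  expect_equal(res$percent, 25)
  # all-zero mask -> 0%
  zero <- label_volume(array(0L, dims), aff)
  expect_equal(streamline_mask_overlap(t, zero)$percent, 0)
  # full-coverage mask -> 100%
  full <- label_volume(array(1L, dims), aff)
  expect_equal(streamline_mask_overlap(t, full)$percent, 100)
})

test_that("transection validates its inputs", {
  t <- tractogram(list(straight_streamline()), "native")
  aff <- grid_affine(c(-5, -5, -5))
  expect_error(streamline_mask_overlap(tractogram(list(), "native"),
                                       label_volume(array(0L, c(5, 5, 5)), aff)),
               "empty")
  tri <- label_volume(array(sample(0:2, 125, TRUE), c(5, 5, 5)), aff)
  expect_error(streamline_mask_overlap(t, tri), "binary")
  m <- label_volume(array(1L, c(5, 5, 5)), aff)
  attr(m, "space_id") <- "template"
  expect_error(streamline_mask_overlap(t, m), "space mismatch")
})

test_that("transection is monotone in mask inclusion and sampling step", {
  gb <- gen_bundle(n_streamlines = 60, seed = 20)
  aff <- grid_affine(c(-16, -60, -40))
  dims <- c(64L, 64L, 64L)
  small <- gen_ablation_mask(c(13, -18, 3), 2.5, dims, aff)
  big <- gen_ablation_mask(c(13, -18, 3), 6, dims, aff)
  expect_true(all(big$grid >= small$grid))
  n_small <- streamline_mask_overlap(gb$tractogram, small,
                                     check_space = FALSE)$n_transected
  n_big <- streamline_mask_overlap(gb$tractogram, big,
                                   check_space = FALSE)$n_transected
  expect_gte(n_big, n_small)
  # halving the step can only find more transections
  coarse <- streamline_mask_overlap(gb$tractogram, small, step = 2,
                                    check_space = FALSE)$n_transected
  fine <- streamline_mask_overlap(gb$tractogram, small, step = 1,
                                  check_space = FALSE)$n_transected
  finer <- streamline_mask_overlap(gb$tractogram, small, step = 0.5,
                                   check_space = FALSE)$n_transected
  expect_gte(fine, coarse)
  expect_gte(finer, fine)
})

test_that("transection is stable under a common rigid transform", {
  gb <- gen_bundle(n_streamlines = 50, seed = 21)
  aff <- grid_affine(c(-16, -60, -40))
  mask <- gen_ablation_mask(c(13, -18, 3), 4, c(64L, 64L, 64L), aff)
  base <- streamline_mask_overlap(gb$tractogram, mask, check_space = FALSE)
  xf <- rigid_transform(theta = 0.4, shift = c(8, -6, 3))
  t2 <- transform_tractogram(gb$tractogram, xf)
  mask2 <- label_volume(mask$grid, xf$affine %*% mask$affine)
  moved <- streamline_mask_overlap(t2, mask2, check_space = FALSE)
  # re-gridding tolerance: at most 2% of streamlines may flip
  expect_lte(abs(moved$n_transected - base$n_transected), ceiling(0.02 * 50))
})

test_that("label overlap volumes match the naive voxel loop", {
  set.seed(22)
  aff <- grid_affine(c(0, 0, 0)); aff[2, 2] <- 1.5
  seg <- gen_nuclei_segmentation(c(12L, 12L, 12L), aff, n_labels = 4L,
                                 seed = 23)
  abl <- label_volume(array(rbinom(12^3, 1, 0.3), c(12, 12, 12)), aff)
  res <- label_overlap_volumes(seg, abl)
  brute <- brute_label_overlap(seg, abl)
  vv <- voxel_volume(seg)
  for (i in seq_len(nrow(res))) {
    lab <- as.character(res$label[i])
    expected <- if (is.na(brute[lab])) 0 else brute[[lab]] * vv
    expect_equal(res$overlap_mm3[i], expected)
  }
  # hard segmentation: per-label volumes sum exactly to the ablation volume
  expect_equal(sum(res$overlap_mm3), sum(abl$grid) * vv)
})

test_that("label overlap handles containment, disjointness and mismatches", {
  aff <- grid_affine(c(0, 0, 0))
  seg_grid <- array(5L, c(10, 10, 10)); seg_grid[1:5, , ] <- 2L
  seg <- label_volume(seg_grid, aff, label_names = c("5" = "VLp", "2" = "VLa"))
  abl_grid <- array(0L, c(10, 10, 10)); abl_grid[7:9, 4:6, 4:6] <- 1L
  abl <- label_volume(abl_grid, aff)
  res <- label_overlap_volumes(seg, abl)
  expect_equal(res$overlap_mm3[res$name == "VLp"], 27)  # fully inside label 5
  expect_equal(res$overlap_mm3[res$name == "VLa"], 0)
  # disjoint ablation
  none <- label_volume(array(0L, c(10, 10, 10)), aff)
  expect_true(all(label_overlap_volumes(seg, none)$overlap_mm3 == 0))
  # affine mismatch beyond tolerance
  aff2 <- aff; aff2[1, 4] <- 0.01
  expect_error(label_overlap_volumes(seg, label_volume(abl_grid, aff2)),
               "affines differ")
  expect_error(label_overlap_volumes(seg, label_volume(array(0L, c(9, 10, 10)),
                                                       aff)),
               "shape")
})

test_that("label overlap is monotone in mask inclusion", {
  aff <- grid_affine(c(0, 0, 0))
  seg <- gen_nuclei_segmentation(c(10L, 10L, 10L), aff, n_labels = 3L,
                                 seed = 24)
  inner <- gen_ablation_mask(c(5, 5, 5), 2, c(10L, 10L, 10L), aff)
  outer <- gen_ablation_mask(c(5, 5, 5), 4, c(10L, 10L, 10L), aff)
  vi <- label_overlap_volumes(seg, inner)$overlap_mm3
  vo <- label_overlap_volumes(seg, outer)$overlap_mm3
  expect_true(all(vo >= vi))
})
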