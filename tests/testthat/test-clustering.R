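test_that("threshold extremes give all singletons or one cluster", {
  set.seed(10)
  # 5 mutually distant parallel segments, >= 20 mm apart
  sl <- lapply(seq(0, 80, by = 20), function(x)
    straight_streamline(c(x, 0, 0), c(x, 0, 30), 5))
  t <- tractogram(sl)
  dec <- quickbundles(t, threshold = 1)
  expect_equal(length(dec$clusters), 5L)
  expect_equal(sort(dec$labels), 1:5)
  dec <- quickbundles(t, threshold = 1e4)
  expect_equal(length(dec$clusters), 1L)
  expect_equal(dec$labels, rep(1L, 5))
  expect_error(quickbundles(tractogram(list()), 5), "empty")
  expect_error(quickbundles(t, 0), "> 0")
})

test_that("two separated sub-bundles are recovered exactly", {
  gb <- gen_bundle(n_streamlines = 120, offsets = c(0, 20), jitter_sd = 0.5,
                   seed = 11)
  dec <- quickbundles(gb$tractogram, threshold = 5)
  expect_equal(length(dec$clusters), 2L)
  # cluster labels must partition identically to the generative sub-bundles
  expect_equal(length(unique(paste(dec$labels, gb$sub_bundle))), 2L)
})

test_that("quickbundles partitions and centroids stay in member bounds", {
  gb <- gen_bundle(n_streamlines = 90, seed = 12)
  dec <- quickbundles(gb$tractogram, threshold = 4)
  sizes <- vapply(dec$clusters, function(c) length(c$member_ids), integer(1))
  expect_equal(sum(sizes), length(gb$tractogram))
  expect_equal(sort(unlist(lapply(dec$clusters, `[[`, "member_ids"))),
               seq_len(length(gb$tractogram)))
  # per resampled index, each centroid lies inside the bounding box of its
  # flip-aligned members (a running mean cannot leave their convex hull)
  k <- dec$k
  for (cl in dec$clusters) {
    members <- lapply(gb$tractogram$streamlines[cl$member_ids],
                      resample_streamline, k)
    aligned <- lapply(members, function(m) {
      if (mean(sqrt(rowSums((m - cl$centroid)^2))) <=
          mean(sqrt(rowSums((m[k:1, ] - cl$centroid)^2)))) m else m[k:1, ]
    })
    for (j in seq_len(k)) {
      pts <- t(vapply(aligned, function(m) m[j, ], numeric(3)))
      for (d in 1:3) {
        expect_gte(cl$centroid[j, d], min(pts[, d]) - 1e-9)
        expect_lte(cl$centroid[j, d], max(pts[, d]) + 1e-9)
      }
    }
  }
})

test_that("adaptive threshold search labels anterior/middle/posterior by offset", {
  gb <- gen_bundle(n_streamlines = 300, offsets = c(-6, 0, 6), seed = 13)
  dec <- select_amp_clusters(gb$tractogram)
  expect_named(dec$amp_roles)
  expect_setequal(names(dec$amp_roles), c("anterior", "middle", "posterior"))
  expect_equal(length(unique(dec$amp_roles)), 3L)
  # the posterior-labelled cluster must have the smallest mean y
  ymean <- vapply(dec$amp_roles, function(i)
    mean(dec$clusters[[i]]$centroid[, 2]), numeric(1))
  expect_lt(ymean[["posterior"]], ymean[["middle"]])
  expect_lt(ymean[["middle"]], ymean[["anterior"]])
  # role assignment agrees with the generative sub-bundle offsets
  for (role in names(dec$amp_roles)) {
    ids <- dec$clusters[[dec$amp_roles[[role]]]]$member_ids
    expect_equal(unique(gb$labels[ids]), role)
  }
  # recorded threshold is on the search grid and matches the trajectory
  traj <- attr(dec, "trajectory")
  expect_equal(dec$threshold_mm, traj$threshold_mm[nrow(traj)])
  expect_true(all(traj$n_qualifying[-nrow(traj)] < 3))
})

test_that("a single tight bundle fails the role search with a trajectory", {
  gb <- gen_bundle(n_streamlines = 60, offsets = 0, jitter_sd = 0.2, seed = 14)
  expect_error(select_amp_clusters(gb$tractogram, start_threshold = 2,
                                   step = 2, max_threshold = 10),
               "cluster counts were")
})

test_that("centroid assignment is forced-choice, flip-invariant and exhaustive", {
  gb <- gen_bundle(n_streamlines = 300, seed = 15)
  dec <- select_amp_clusters(gb$tractogram)
  cents <- amp_centroids(dec)
  roles <- assign_to_centroids(gb$tractogram, cents)
  expect_equal(length(roles), length(gb$tractogram))
  expect_true(all(roles %in% c("anterior", "middle", "posterior")))
  # a centroid itself, and its reversal, map to their own role
  probe <- tractogram(list(cents$posterior,
                           cents$posterior[nrow(cents$posterior):1, ]))
  expect_equal(assign_to_centroids(probe, cents), rep("posterior", 2))
  expect_error(assign_to_centroids(tractogram(list()), cents), "empty")
  expect_error(assign_to_centroids(gb$tractogram, cents[1:2]), "exactly 3")
})

test_that("assignment reproduces clustering labels for well-separated bundles", {
  gb <- gen_bundle(n_streamlines = 150, offsets = c(-15, 0, 15),
                   jitter_sd = 0.5, seed = 16)
  dec <- select_amp_clusters(gb$tractogram)
  roles <- assign_to_centroids(gb$tractogram, amp_centroids(dec))
  by_cluster <- character(length(roles))
  for (role in names(dec$amp_roles))
    by_cluster[dec$clusters[[dec$amp_roles[[role]]]]$member_ids] <- role
  expect_equal(roles, by_cluster)
})

test_that("coherence filter keeps the brute-force most coherent streamlines", {
  gb <- gen_bundle(n_streamlines = 30, offsets = 0, seed = 17)
  t <- gb$tractogram
  t$streamlines[[30]] <- t$streamlines[[30]] + 50  # gross outlier
  D <- brute_mdf_matrix(t)
  brute_score <- rowSums(D) / (length(t) - 1)
  expect_equal(coherence_scores(t), brute_score, tolerance = 1e-9)
  expect_equal(which.max(brute_score), 30L)
  kept <- attr(coherence_filter(t, 29), "kept")
  expect_false(30L %in% kept)
  # n_keep >= count returns the tractogram unchanged
  same <- coherence_filter(t, 1000)
  expect_tractograms_equal(same, t)
  expect_error(coherence_filter(t, 0), "n_keep")
})

test_that("coherence filter is order-invariant up to the tie rule", {
  gb <- gen_bundle(n_streamlines = 40, seed = 18)
  t <- gb$tractogram
  perm <- sample(40)
  tp <- tractogram(t$streamlines[perm], t$space_id)
  kept_orig <- attr(coherence_filter(t, 10), "kept")
  kept_perm <- attr(coherence_filter(tp, 10), "kept")
  expect_setequal(perm[kept_perm], kept_orig)
})

test_that("template bundles are coherent selections from the pooled set", {
  subs <- lapply(1:4, function(i)
    gen_bundle(n_streamlines = 50, seed = 100 + i,
               space_id = "template")$tractogram)
  tb <- build_template_bundle(subs, n_keep = 80)
  expect_equal(length(tb), 80L)
  expect_equal(tb$space_id, "template")
  # every output streamline is point-identical to some input streamline
  pool <- unlist(lapply(subs, function(s) s$streamlines), recursive = FALSE)
  keyed <- vapply(pool, function(m) paste(signif(m, 12), collapse = ","),
                  character(1))
  for (s in tb$streamlines)
    expect_true(paste(signif(s, 12), collapse = ",") %in% keyed)
  # single-subject input reduces to coherence_filter
  one <- build_template_bundle(subs[1], n_keep = 20)
  expect_tractograms_equal(one, coherence_filter(subs[[1]], 20))
  bad <- subs; bad[[2]]$space_id <- "native"
  expect_error(build_template_bundle(bad, 10), "share one space")
})

test_that("pooled clustering plus per-subject assignment recovers roles", {
  subs <- lapply(1:6, function(i)
    gen_bundle(n_streamlines = 120, seed = 200 + i))
  pooled <- tractogram(unlist(lapply(subs, function(s)
    s$tractogram$streamlines), recursive = FALSE))
  dec <- select_amp_clusters(pooled)
  cents <- amp_centroids(dec)
  agree <- vapply(subs, function(s)
    mean(assign_to_centroids(s$tractogram, cents) == s$labels), numeric(1))
  expect_gte(min(agree), 0.95)
})
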