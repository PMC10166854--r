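#' Write a complete synthetic study dataset to disk
#'
#' Emulates, per subject, everything the overlap and cohort pipelines read:
#' a native tractogram with three-sub-bundle structure (TCK), the three
#' template sub-bundles (TCK, with an identity affine text file standing in
#' for the template-to-subject warp, which in real use is estimated
#' upstream), a spherical ablation mask and a hard nuclei segmentation
#' (NIfTI), pre/post clinical records (CSV) and per-element treatment
#' parameters (long CSV). All randomness derives from `seed`, with a
#' documented per-subject/per-stage offset.
#'
#' @param dir Output directory (created).
#' @param n_subjects Number of subjects (default 3).
#' @param seed Base integer seed; subject `i`, stage `s` uses
#'   `seed + i * 1000 + s` (kept additive so derived seeds stay within
#'   32-bit integer range).
#' @param n_streamlines Streamlines per native tractogram (default 300).
#' @param mask_radius Ablation radius in mm (default 3).
#' @return The overlap-pipeline config list (subjects, paths, `out_dir`
#'   unset), with `clinical_csv` and `treatment_csv` paths attached.
#' @export
gen_study_dataset <- function(dir, n_subjects = 3L, seed = 1L,
                              n_streamlines = 300L, mask_radius = 3) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grid_dim <- c(64L, 64L, 64L)
  affine <- diag(4)
  affine[1:3, 4] <- c(-16, -60, -40)  # 1 mm grid covering the tract's lower arc
  subjects <- list()
  clin_rows <- list(); treat_rows <- list()
  for (i in seq_len(n_subjects)) {
    id <- sprintf("S%02d", i)
    sdir <- file.path(dir, id)
    dir.create(sdir, showWarnings = FALSE)
    s0 <- as.integer(seed) + i * 1000L
    gb <- gen_bundle(n_streamlines = n_streamlines, seed = s0 + 1L,
                     space_id = "native")
    write_tractogram(gb$tractogram, file.path(sdir, "native.tck"))
    bundles <- list()
    for (role in c("anterior", "middle", "posterior")) {
      sel <- which(gb$labels == role)
      tb <- tractogram(gb$tractogram$streamlines[sel], space_id = "template")
      p <- file.path(sdir, paste0(role, ".tck"))
      write_tractogram(tb, p)
      bundles[[role]] <- p
    }
    xf_path <- file.path(sdir, "transform.txt")
    writeLines(apply(diag(4), 1, paste, collapse = " "), xf_path)
    set.seed(s0 + 2L)
    center <- c(13, -18, 3) + stats::rnorm(3, sd = 1.5)
    mask <- gen_ablation_mask(center, mask_radius, grid_dim, affine)
    write_label_volume(mask, file.path(sdir, "mask.nii.gz"))
    seg <- gen_nuclei_segmentation(grid_dim, affine, n_labels = 6L,
                                   seed = s0 + 3L)
    write_label_volume(seg, file.path(sdir, "seg.nii.gz"))
    subjects[[i]] <- list(id = id,
                          native_tck = file.path(sdir, "native.tck"),
                          bundles = bundles,
                          transform = xf_path,
                          mask = file.path(sdir, "mask.nii.gz"),
                          seg = file.path(sdir, "seg.nii.gz"))
    set.seed(s0 + 4L)
    pre_items_d <- stats::setNames(sample(1:4, 8, replace = TRUE),
                                   HTS_ITEMS_DOMINANT)
    pre_items_nd <- stats::setNames(sample(1:4, 7, replace = TRUE),
                                    HTS_ITEMS_NONDOMINANT)
    improve <- stats::runif(1, 0.3, 0.7)
    post_items_d <- pre_items_d
    post_items_d[] <- pmax(0, round(pre_items_d * (1 - improve)))
    post_items_nd <- pre_items_nd
    post_items_nd[] <- pmax(0, round(pre_items_nd * (1 - improve)))
    pre_parts <- round(stats::runif(3, 10, 30))
    post_parts <- pmax(1, round(pre_parts * (1 - improve)))
    row <- function(tp, parts, d, nd, date) {
      out <- data.frame(subject_id = id, date = date, timepoint = tp,
                        crst_a = parts[1], crst_b = parts[2], crst_c = parts[3],
                        stringsAsFactors = FALSE)
      for (it in HTS_ITEMS_DOMINANT) out[[paste0("hts_d_", it)]] <- d[[it]]
      for (it in HTS_ITEMS_NONDOMINANT) out[[paste0("hts_nd_", it)]] <- nd[[it]]
      out
    }
    clin_rows[[2 * i - 1L]] <- row("pre", pre_parts, pre_items_d,
                                   pre_items_nd, "2020-01-01")
    clin_rows[[2 * i]] <- row("post", post_parts, post_items_d,
                              post_items_nd, "2021-01-01")
    tp <- gen_treatment_params(seed = s0 + 5L)
    treat_rows[[i]] <- do.call(rbind, lapply(
      c("sdr", "skull_thickness", "angle_inner", "angle_outer"),
      function(p) data.frame(subject_id = id, parameter = p,
                             element_index = 0:1023, value = tp[[p]],
                             stringsAsFactors = FALSE)))
  }
  clinical_csv <- file.path(dir, "clinical.csv")
  treatment_csv <- file.path(dir, "treatment.csv")
  utils::write.csv(do.call(rbind, clin_rows), clinical_csv, row.names = FALSE)
  utils::write.csv(do.call(rbind, treat_rows), treatment_csv, row.names = FALSE)
  list(subjects = subjects, space = "native",
       clinical_csv = clinical_csv, treatment_csv = treatment_csv)
}
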