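#' @name pipeline
#' @title End-to-end orchestration of the tract-lesion analysis
#'
#' @description
#' [run_overlap_pipeline()] scores, per subject, the transection of the
#' native tract and the three warped template sub-bundles by the ablation
#' mask, and the overlap volume of the mask with every segmented nucleus.
#' [run_cohort_analysis()] assembles the cohort table (latest follow-up per
#' subject, signed percent score changes, skull-parameter summaries,
#' overlaps) and runs the two-stage forward-selection regression for each
#' tremor response. Both take a config (a list, or a YAML path), write
#' deterministic CSV/JSON outputs, and record per-stage log lines without
#' timestamps so reruns with identical config are byte-identical.
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

read_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  config
}

write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(path)
}

#' Run the per-subject overlap pipeline
#'
#' For each subject in the config: read the native tractogram and the three
#' template sub-bundles, optionally apply the subject's affine transform to
#' the template bundles (warping them into subject space), then score
#' streamline transection against the ablation mask and per-nucleus overlap
#' volumes. Per-subject failures are recorded and do not stop the run.
#'
#' @param config List or YAML path with elements: `subjects` (each with `id`,
#'   `native_tck`, `bundles` = named paths for `anterior`/`middle`/
#'   `posterior`, `mask`, `seg`, optional `transform` affine text file),
#'   `out_dir`, optional `step` (mm) and `space` tag.
#' @return Invisible report list with `overlaps`, `label_overlaps`,
#'   `failures` and `n_failed`; files `overlap_streamlines.csv`,
#'   `overlap_labels.csv`, `overlap_summary.csv`, `overlap_report.json` and
#'   `log.txt` are written under `out_dir`.
#' @export
run_overlap_pipeline <- function(config) {
  config <- read_config(config)
  stopifnot(!is.null(config$subjects), !is.null(config$out_dir))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  space <- config$space %||% "native"
  step <- config$step
  log <- c("stage: run_overlap_pipeline",
           sprintf("param: step=%s space=%s",
                   if (is.null(step)) "auto" else format(step), space))
  sl_rows <- list(); lab_rows <- list(); failures <- character(0)
  for (subj in config$subjects) {
    id <- subj$id
    res <- tryCatch({
      mask <- read_label_volume(subj$mask)
      attr(mask, "space_id") <- space
      seg <- read_label_volume(subj$seg)
      bundles <- list(native = read_tractogram(subj$native_tck, space_id = space))
      for (role in names(subj$bundles)) {
        b <- read_tractogram(subj$bundles[[role]], space_id = "template")
        if (!is.null(subj$transform)) {
          xf <- spatial_transform(read_affine(subj$transform))
          b <- transform_tractogram(b, xf, space_id = space)
        } else {
          b$space_id <- space
        }
        bundles[[role]] <- b
      }
      sl <- lapply(names(bundles), function(nm)
        streamline_mask_overlap(bundles[[nm]], mask, step = step,
                                bundle_name = nm))
      lab <- label_overlap_volumes(seg, mask)
      list(sl = sl, lab = lab,
           ablation_mm3 = sum(mask$grid) * voxel_volume(mask))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s: %s", id, conditionMessage(res)))
      log <- c(log, sprintf("subject %s: FAILED (%s)", id, conditionMessage(res)))
      next
    }
    sl_rows[[id]] <- do.call(rbind, lapply(res$sl, function(r)
      data.frame(subject_id = id, bundle = r$bundle_name,
                 n_streamlines = r$n_streamlines,
                 n_transected = r$n_transected, percent = r$percent,
                 stringsAsFactors = FALSE)))
    lab <- res$lab
    lab$subject_id <- id
    lab$ablation_mm3 <- res$ablation_mm3
    lab_rows[[id]] <- lab[, c("subject_id", "label", "name", "overlap_mm3",
                              "ablation_mm3")]
    log <- c(log, sprintf("subject %s: ok (%d bundles, %d labels, ablation %.1f mm3)",
                          id, length(res$sl), nrow(lab), res$ablation_mm3))
  }
  overlaps <- do.call(rbind, sl_rows)
  label_overlaps <- do.call(rbind, lab_rows)
  summary_wide <- NULL
  if (!is.null(overlaps)) {
    summary_wide <- stats::reshape(
      overlaps[, c("subject_id", "bundle", "percent")],
      idvar = "subject_id", timevar = "bundle", direction = "wide")
    names(summary_wide) <- sub("^percent\\.(.*)$", "\\1_overlap",
                               names(summary_wide))
    abl <- unique(label_overlaps[, c("subject_id", "ablation_mm3")])
    summary_wide <- merge(summary_wide, abl, by = "subject_id", sort = TRUE)
    names(summary_wide)[names(summary_wide) == "ablation_mm3"] <-
      "ablation_volume"
  }
  if (!is.null(overlaps))
    write_table_csv(overlaps, file.path(config$out_dir, "overlap_streamlines.csv"))
  if (!is.null(label_overlaps))
    write_table_csv(label_overlaps, file.path(config$out_dir, "overlap_labels.csv"))
  if (!is.null(summary_wide))
    write_table_csv(summary_wide, file.path(config$out_dir, "overlap_summary.csv"))
  report <- list(n_subjects = length(config$subjects),
                 n_failed = length(failures), failures = failures)
  write_report_json(report, file.path(config$out_dir, "overlap_report.json"))
  writeLines(log, file.path(config$out_dir, "log.txt"))
  invisible(list(overlaps = overlaps, label_overlaps = label_overlaps,
                 summary = summary_wide, failures = failures,
                 n_failed = length(failures)))
}

#' Read per-element treatment parameters from long-format CSV
#'
#' Expected columns: `subject_id`, `parameter` (one of `sdr`,
#' `skull_thickness`, `angle_inner`, `angle_outer`), `element_index`
#' (0-1023), `value`.
#'
#' @param path CSV path.
#' @return Named list of [treatment_params()] per subject.
#' @export
read_treatment_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- list()
  for (id in unique(df$subject_id)) {
    sub <- df[df$subject_id == id, ]
    arrays <- lapply(c("sdr", "skull_thickness", "angle_inner", "angle_outer"),
                     function(p) {
                       rows <- sub[sub$parameter == p, ]
                       rows$value[order(rows$element_index)]
                     })
    names(arrays) <- c("sdr", "skull_thickness", "angle_inner", "angle_outer")
    out[[as.character(id)]] <- do.call(treatment_params, arrays)
  }
  out
}

#' Assemble the cohort table from clinical, treatment and overlap inputs
#'
#' Joins the per-subject score changes (latest follow-up), skull-parameter
#' summaries (per-parameter mean and SD over the 1,024 elements) and the
#' wide overlap summary from [run_overlap_pipeline()].
#'
#' @param records List of [clinical_record()]s.
#' @param treatments Named list of [treatment_params()] per subject.
#' @param overlap_summary Data frame from `overlap_summary.csv`.
#' @param secondary_ids Optional subject ids carrying secondary lesions.
#' @return Cohort data frame, one row per subject.
#' @export
build_cohort_table <- function(records, treatments, overlap_summary,
                               secondary_ids = character(0)) {
  changes <- score_changes(records)
  trows <- lapply(names(treatments), function(id) {
    ts <- treatment_summary(treatments[[id]])
    df <- data.frame(subject_id = id, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(ts))) {
      df[[paste0(ts$parameter[i], "_mean")]] <- ts$mean[i]
      df[[paste0(ts$parameter[i], "_sd")]] <- ts$sd[i]
    }
    df
  })
  tab <- merge(changes, do.call(rbind, trows), by = "subject_id", sort = TRUE)
  tab <- merge(tab, overlap_summary, by = "subject_id", sort = TRUE)
  tab$secondary_lesion <- tab$subject_id %in% secondary_ids
  tab
}

DEFAULT_RESPONSES <- c("crst_a_change", "crst_b_change", "crst_c_change",
                       "crst_t_change", "hts_d_change", "hts_nd_change")

#' Run the cohort regression analysis
#'
#' Builds (or reads) the cohort table and runs [two_stage_select()] for each
#' tremor response, writing one JSON model report per response. With
#' `exclude_secondary`, the analysis is repeated on the subjects without
#' secondary lesions and reported alongside.
#'
#' @param config List or YAML path with either `cohort_csv` (a prebuilt
#'   cohort table) or `clinical_csv` + `treatment_csv` + `overlap_summary_csv`
#'   (assembled via [build_cohort_table()]); plus `patient_pool`,
#'   `treatment_pool`, optional `responses` (default the six tremor changes),
#'   `alpha` (default 0.05), `exclude_secondary` (default FALSE),
#'   `secondary_ids`, and `out_dir`.
#' @return Invisible named list of per-response results (each with
#'   `baseline`, `extended`, `comparison`); files `model_<response>.json`
#'   and `cohort_table.csv` are written under `out_dir`.
#' @export
run_cohort_analysis <- function(config) {
  config <- read_config(config)
  stopifnot(!is.null(config$out_dir))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(config$cohort_csv)) {
    tab <- utils::read.csv(config$cohort_csv, stringsAsFactors = FALSE)
    if (is.null(tab$secondary_lesion)) tab$secondary_lesion <- FALSE
  } else {
    records <- read_clinical_csv(config$clinical_csv)
    treatments <- read_treatment_csv(config$treatment_csv)
    overlap_summary <- utils::read.csv(config$overlap_summary_csv,
                                       stringsAsFactors = FALSE)
    tab <- build_cohort_table(records, treatments, overlap_summary,
                              secondary_ids = config$secondary_ids %||%
                                character(0))
  }
  responses <- config$responses %||% DEFAULT_RESPONSES
  alpha <- config$alpha %||% 0.05
  patient_pool <- unlist(config$patient_pool)
  treatment_pool <- unlist(config$treatment_pool)
  min_n <- max(6L, length(c(patient_pool, treatment_pool)) %/% 4L)
  if (nrow(tab) < min_n)
    stop(sprintf("cohort has %d subjects; at least %d are needed to fit the selection models",
                 nrow(tab), min_n), call. = FALSE)
  write_table_csv(tab, file.path(config$out_dir, "cohort_table.csv"))
  model_json <- function(fit) list(
    predictors = as.list(fit$predictors),
    beta_std = as.list(fit$beta_std),
    beta_raw = as.list(fit$beta_raw),
    p_values = as.list(fit$p_values),
    r_squared = fit$r_squared, rss = fit$rss, n = fit$n)
  results <- list()
  for (resp in responses) {
    use <- tab[stats::complete.cases(tab[c(resp, patient_pool, treatment_pool)]), ]
    res <- two_stage_select(use, resp, patient_pool, treatment_pool, alpha)
    rep <- list(response = resp,
                n = nrow(use),
                alpha = alpha,
                baseline = model_json(res$baseline),
                extended = model_json(res$extended),
                comparison = res$comparison[c("identical_models", "f", "p", "df")])
    if (isTRUE(config$exclude_secondary)) {
      keep <- use[!use$secondary_lesion, ]
      res2 <- two_stage_select(keep, resp, patient_pool, treatment_pool, alpha)
      rep$excluding_secondary <- list(
        n = nrow(keep),
        baseline = model_json(res2$baseline),
        extended = model_json(res2$extended),
        comparison = res2$comparison[c("identical_models", "f", "p", "df")])
    }
    write_report_json(rep, file.path(config$out_dir,
                                     paste0("model_", resp, ".json")))
    results[[resp]] <- res
  }
  invisible(results)
}
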