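#' @name synthetic
#' @title Seeded synthetic inputs for the tract-lesion pipeline
#'
#' @description
#' Generators for every input the pipeline consumes: streamline bundles with
#' anterior/middle/posterior sub-bundle structure, ellipsoidal ablation
#' masks, hard nuclei segmentations, per-element skull-parameter arrays and
#' outcome cohorts driven by a known linear model. All generators are pure
#' functions of their arguments and seed, so every stage of the analysis is
#' testable without patient data.
NULL

# default centerline: an arc sweeping from a cerebellar (dentate) position
# through the midbrain (red nucleus level) up to the thalamus and towards
# motor cortex, in RAS mm. Anatomical realism is not the goal; a smooth,
# geometrically separable tract is.
DEFAULT_CENTERLINE <- matrix(c(
  14, -56, -34,
   8, -40, -22,
   5, -21,  -8,
  13, -18,   3,
  22, -20,  28,
  30, -22,  55), ncol = 3, byrow = TRUE)

#' Generate a synthetic streamline bundle with sub-bundle structure
#'
#' Streamlines follow a smooth centerline (cubic spline through the control
#' points), offset per sub-bundle along the anterior (y) axis, with
#' independent per-point Gaussian jitter. The generative sub-bundle labels
#' are returned for oracle tests.
#'
#' @param n_streamlines Total streamline count (split by `weights`).
#' @param offsets Sub-bundle offsets along the anterior axis in mm
#'   (default `c(-6, 0, 6)`: posterior, middle, anterior).
#' @param weights Sub-bundle mixing weights (default equal); must sum to 1.
#' @param jitter_sd Per-point Gaussian jitter SD in mm (default 0.5).
#' @param control_points Centerline control points (matrix, >= 2 rows).
#' @param n_points Points per generated streamline (default 30).
#' @param seed Integer seed.
#' @param space_id Spatial tag of the output tractogram.
#' @return List with `tractogram`, `labels` (per-streamline generative role:
#'   `posterior`/`middle`/`anterior` by offset rank, or `sub1`... when the
#'   number of sub-bundles is not 3), `offsets`, `sub_bundle` (index).
#' @export
gen_bundle <- function(n_streamlines = 900L, offsets = c(-6, 0, 6),
                       weights = NULL, jitter_sd = 0.5,
                       control_points = DEFAULT_CENTERLINE,
                       n_points = 30L, seed = 1L,
                       space_id = "synthetic") {
  if (is.null(weights)) weights <- rep(1 / length(offsets), length(offsets))
  if (length(weights) != length(offsets) || abs(sum(weights) - 1) > 1e-8)
    stop("weights must match offsets and sum to 1", call. = FALSE)
  if (jitter_sd < 0) stop("jitter_sd must be >= 0", call. = FALSE)
  control_points <- as.matrix(control_points)
  if (nrow(control_points) < 2L)
    stop("need at least 2 centerline control points", call. = FALSE)
  set.seed(seed)
  u <- seq(0, 1, length.out = nrow(control_points))
  uu <- seq(0, 1, length.out = n_points)
  center <- sapply(1:3, function(d)
    stats::spline(u, control_points[, d], xout = uu)$y)
  counts <- diff(round(cumsum(c(0, weights)) * n_streamlines))
  counts[length(counts)] <- n_streamlines - sum(counts[-length(counts)])
  sub <- rep(seq_along(offsets), counts)
  sl <- vector("list", n_streamlines)
  for (i in seq_len(n_streamlines)) {
    p <- center
    p[, 2] <- p[, 2] + offsets[sub[i]]
    p <- p + matrix(stats::rnorm(3 * n_points, sd = jitter_sd), n_points, 3)
    sl[[i]] <- p
  }
  role_names <- if (length(offsets) == 3L) {
    c("posterior", "middle", "anterior")[rank(offsets, ties.method = "first")]
  } else {
    paste0("sub", seq_along(offsets))
  }
  list(tractogram = tractogram(sl, space_id = space_id),
       labels = role_names[sub],
       offsets = offsets,
       sub_bundle = sub)
}

#' Generate a spherical ablation mask
#'
#' Binary mask of all voxels whose centres lie within `radius` mm of
#' `center`.
#'
#' @param center World-space centre (mm, length 3); must map inside the grid.
#' @param radius Radius in mm, >= 0.
#' @param dim Grid dimensions (length 3).
#' @param affine 4x4 voxel-to-world matrix.
#' @param space_id Optional spatial tag attached as attribute.
#' @return A binary [label_volume()].
#' @export
gen_ablation_mask <- function(center, radius, dim = c(40L, 40L, 40L),
                              affine = diag(4), space_id = NULL) {
  stopifnot(length(center) == 3L, radius >= 0, length(dim) == 3L)
  cvox <- world_to_voxel(matrix(center, 1L), affine)
  if (any(cvox < -0.5) || any(cvox > dim - 0.5))
    stop("ablation centre lies outside the grid field of view", call. = FALSE)
  idx <- as.matrix(expand.grid(i = seq_len(dim[1]) - 1L,
                               j = seq_len(dim[2]) - 1L,
                               k = seq_len(dim[3]) - 1L))
  world <- cbind(idx, 1) %*% t(affine)
  d2 <- (world[, 1] - center[1])^2 + (world[, 2] - center[2])^2 +
        (world[, 3] - center[3])^2
  grid <- array(as.integer(d2 <= radius^2), dim)
  v <- label_volume(grid, affine, label_names = c("1" = "ablation"))
  if (!is.null(space_id)) attr(v, "space_id") <- space_id
  v
}

#' Generate a hard nuclei segmentation (Voronoi regions)
#'
#' Labels every voxel with the nearest of `n_labels` randomly placed sites
#' (Euclidean distance in mm), so each voxel carries exactly one label and
#' the label volumes sum to the grid volume.
#'
#' @param dim Grid dimensions.
#' @param affine 4x4 voxel-to-world matrix.
#' @param n_labels Number of regions, >= 2.
#' @param seed Integer seed.
#' @param space_id Optional spatial tag attached as attribute.
#' @return A [label_volume()] with labels 1..`n_labels`.
#' @export
gen_nuclei_segmentation <- function(dim = c(40L, 40L, 40L), affine = diag(4),
                                    n_labels = 6L, seed = 1L,
                                    space_id = NULL) {
  if (n_labels < 2L) stop("n_labels must be >= 2", call. = FALSE)
  set.seed(seed)
  sites_vox <- cbind(stats::runif(n_labels, 0, dim[1] - 1),
                     stats::runif(n_labels, 0, dim[2] - 1),
                     stats::runif(n_labels, 0, dim[3] - 1))
  sites <- cbind(sites_vox, 1) %*% t(affine)
  idx <- as.matrix(expand.grid(i = seq_len(dim[1]) - 1L,
                               j = seq_len(dim[2]) - 1L,
                               k = seq_len(dim[3]) - 1L))
  world <- cbind(idx, 1) %*% t(affine)
  best <- rep(1L, nrow(world)); bestd <- rep(Inf, nrow(world))
  for (L in seq_len(n_labels)) {
    d2 <- (world[, 1] - sites[L, 1])^2 + (world[, 2] - sites[L, 2])^2 +
          (world[, 3] - sites[L, 3])^2
    hit <- d2 < bestd
    best[hit] <- L; bestd[hit] <- d2[hit]
  }
  v <- label_volume(array(best, dim), affine,
                    label_names = stats::setNames(paste0("nucleus_", seq_len(n_labels)),
                                                  seq_len(n_labels)))
  if (!is.null(space_id)) attr(v, "space_id") <- space_id
  v
}

#' Generate per-treatment skull and sonication parameters
#'
#' Draws the four per-element skull parameter arrays (1,024 elements each,
#' Gaussian) and the per-treatment sonication scalars. Default distribution
#' parameters give SDR ~ 0.45 +/- 0.1, skull thickness ~ 7 +/- 1.5 mm and
#' skull angles ~ 12 +/- 4 / 15 +/- 5 degrees.
#'
#' @param seed Integer seed.
#' @param sdr_mean,sdr_sd,thickness_mean,thickness_sd,angle_inner_mean,
#'   angle_inner_sd,angle_outer_mean,angle_outer_sd Element-array
#'   distribution parameters.
#' @return A [treatment_params()].
#' @export
gen_treatment_params <- function(seed = 1L, sdr_mean = 0.45, sdr_sd = 0.1,
                                 thickness_mean = 7, thickness_sd = 1.5,
                                 angle_inner_mean = 12, angle_inner_sd = 4,
                                 angle_outer_mean = 15, angle_outer_sd = 5) {
  set.seed(seed)
  n <- N_TRANSDUCER_ELEMENTS
  treatment_params(
    sdr = stats::rnorm(n, sdr_mean, sdr_sd),
    skull_thickness = stats::rnorm(n, thickness_mean, thickness_sd),
    angle_inner = stats::rnorm(n, angle_inner_mean, angle_inner_sd),
    angle_outer = stats::rnorm(n, angle_outer_mean, angle_outer_sd),
    max_temperature_c = round(stats::runif(1, 54, 62), 1),
    active_elements = as.integer(round(stats::runif(1, 800, 1024))),
    n_sonications = as.integer(round(stats::runif(1, 6, 14))),
    summed_temperature_c = round(stats::runif(1, 350, 600), 1))
}

# cohort predictor distributions: age and overlap/volume summaries follow
# the cohort characteristics of the study population this pipeline targets
COHORT_PREDICTORS <- list(
  age = c(75.72, 7.20),
  pdrtt_overlap = c(25.28, 12.14),
  mdrtt_overlap = c(28.35, 11.66),
  adrtt_overlap = c(21.79, 10.56),
  native_overlap = c(20.86, 11.33),
  sdr_mean = c(0.45, 0.08),
  sdr_sd = c(0.09, 0.025),
  skull_thickness_mean = c(7.0, 1.0),
  ablation_volume = c(11.61, 4.82),
  brain_volume = c(1.45e6, 1.2e5),
  pre_crst_t = c(60.0, 17.3))

#' Generate a synthetic outcome cohort with known effects
#'
#' Draws independent per-subject predictors and forms a standardized
#' response as a linear combination of the z-scored posterior-bundle
#' overlap, age and SDR standard deviation, plus Gaussian noise whose
#' variance is set so the population R-squared equals `target_r2`. The
#' response is then rescaled to a percent-change scale (mean
#' `response_mean`, SD `response_sd`) and clipped to [-100, 100].
#'
#' @param n_subjects Number of subjects (>= 5; default 31).
#' @param betas Named standardized effects; default
#'   `c(pdrtt_overlap = 0.53, age = -0.38, sdr_sd = -0.32)`.
#' @param target_r2 Population R-squared in (0, 1] (default 0.55); 1 means a
#'   noiseless response.
#' @param response_mean,response_sd Percent-change scale of the response
#'   (default 44.8 and 16.6).
#' @param seed Integer seed.
#' @param n_secondary Number of subjects flagged as having secondary lesions
#'   (default 9; used by the exclusion re-analysis flag).
#' @return List with `table` (data frame; response column `crst_t_change`,
#'   logical `secondary_lesion`, and all predictors), `betas` (generative
#'   standardized effects), `sigma` (noise SD on the standardized scale),
#'   `patient_pool` and `treatment_pool` (predictor name vectors).
#' @export
gen_cohort <- function(n_subjects = 31L,
                       betas = c(pdrtt_overlap = 0.53, age = -0.38,
                                 sdr_sd = -0.32),
                       target_r2 = 0.55,
                       response_mean = 44.8, response_sd = 16.6,
                       seed = 1L, n_secondary = 9L) {
  if (n_subjects < 5L) stop("n_subjects must be >= 5", call. = FALSE)
  if (target_r2 <= 0 || target_r2 > 1)
    stop("target_r2 must be in (0, 1]", call. = FALSE)
  if (sum(betas^2) == 0)
    stop("infeasible target_r2: all generative effects are zero", call. = FALSE)
  if (!all(names(betas) %in% names(COHORT_PREDICTORS)))
    stop("betas must be named after known predictors", call. = FALSE)
  set.seed(seed)
  tab <- data.frame(subject_id = sprintf("S%02d", seq_len(n_subjects)))
  z <- list()
  for (nm in names(COHORT_PREDICTORS)) {
    zi <- stats::rnorm(n_subjects)
    par <- COHORT_PREDICTORS[[nm]]
    tab[[nm]] <- par[1] + par[2] * zi
    z[[nm]] <- zi
  }
  tab$sex <- stats::rbinom(n_subjects, 1L, 0.74)
  tab$pdrtt_overlap <- pmin(pmax(tab$pdrtt_overlap, 0), 100)
  tab$mdrtt_overlap <- pmin(pmax(tab$mdrtt_overlap, 0), 100)
  tab$adrtt_overlap <- pmin(pmax(tab$adrtt_overlap, 0), 100)
  tab$native_overlap <- pmin(pmax(tab$native_overlap, 0), 100)
  # the response is driven by the stored (post-clipping) predictor columns,
  # population-scaled, so a noiseless cohort is exactly linear in the table
  for (nm in names(betas)) {
    par <- COHORT_PREDICTORS[[nm]]
    z[[nm]] <- (tab[[nm]] - par[1]) / par[2]
  }
  # population R^2 = sum(beta^2) / (sum(beta^2) + sigma^2)
  sigma <- sqrt(sum(betas^2) * (1 - target_r2) / target_r2)
  signal <- Reduce(`+`, Map(function(b, nm) b * z[[nm]],
                            betas, names(betas)))
  y_std <- signal + stats::rnorm(n_subjects, sd = sigma)
  sd_y <- sqrt(sum(betas^2) + sigma^2)
  tab$crst_t_change <- pmin(pmax(
    response_mean + response_sd * y_std / sd_y, -100), 100)
  tab$secondary_lesion <- c(rep(TRUE, min(n_secondary, n_subjects)),
                            rep(FALSE, max(0L, n_subjects - n_secondary)))
  list(table = tab,
       betas = betas,
       sigma = sigma,
       patient_pool = c("age", "sex", "sdr_mean", "sdr_sd",
                        "skull_thickness_mean", "brain_volume", "pre_crst_t"),
       treatment_pool = c("pdrtt_overlap", "mdrtt_overlap", "adrtt_overlap",
                          "native_overlap", "ablation_volume"))
}
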