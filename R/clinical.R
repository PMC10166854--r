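#' @name clinical
#' @title Tremor rating scores and treatment parameters
#'
#' @description
#' The Clinical Rating Scale for Tremor (CRST) has three parts: A (tremor by
#' body region), B (task performance), C (disability); the combined score
#' CRST_T = A + B + C has maximum 160. The Hand Tremor Score (HTS) is a
#' CRST-derived upper-limb subscore over the items rest, postural and action
#' tremor, pouring, handwriting, large and small constrained spirals, and
#' constrained straight lines, each scored 0-4. Handwriting is only tested in
#' the dominant hand, so the dominant-hand HTS is out of 32 and the
#' non-dominant out of 28.
NULL

HTS_ITEMS_DOMINANT <- c("rest", "postural", "action", "pouring", "handwriting",
                        "spiral_large", "spiral_small", "straight_lines")
HTS_ITEMS_NONDOMINANT <- setdiff(HTS_ITEMS_DOMINANT, "handwriting")

#' Construct a clinical record
#'
#' @param subject_id Subject identifier.
#' @param timepoint `"pre"` or `"post"`.
#' @param crst_a,crst_b,crst_c CRST part scores (points, >= 0).
#' @param hts_dominant Named numeric vector of the 8 dominant-hand items
#'   (`rest`, `postural`, `action`, `pouring`, `handwriting`, `spiral_large`,
#'   `spiral_small`, `straight_lines`), each 0-4.
#' @param hts_nondominant Named numeric vector of the 7 non-dominant items
#'   (dominant list minus `handwriting`), each 0-4.
#' @param date Optional assessment date (`Date` or coercible).
#' @return Object of class `clinical_record`.
#' @export
clinical_record <- function(subject_id, timepoint = c("pre", "post"),
                            crst_a, crst_b, crst_c,
                            hts_dominant, hts_nondominant, date = NULL) {
  timepoint <- match.arg(timepoint)
  parts <- c(a = crst_a, b = crst_b, c = crst_c)
  if (any(!is.finite(parts)) || any(parts < 0))
    stop("CRST part scores must be finite and >= 0", call. = FALSE)
  check_items <- function(items, expected, hand) {
    missing <- setdiff(expected, names(items))
    if (length(missing) > 0)
      stop(sprintf("missing %s-hand HTS item(s): %s", hand,
                   paste(missing, collapse = ", ")), call. = FALSE)
    items <- items[expected]
    bad <- expected[!(items %in% 0:4)]
    if (length(bad) > 0)
      stop(sprintf("%s-hand HTS item(s) outside the 0-4 scale: %s", hand,
                   paste(bad, collapse = ", ")), call. = FALSE)
    items
  }
  hts_dominant <- check_items(hts_dominant, HTS_ITEMS_DOMINANT, "dominant")
  hts_nondominant <- check_items(hts_nondominant, HTS_ITEMS_NONDOMINANT,
                                 "non-dominant")
  rec <- list(subject_id = subject_id, timepoint = timepoint,
              crst_a = crst_a, crst_b = crst_b, crst_c = crst_c,
              hts_dominant = hts_dominant, hts_nondominant = hts_nondominant,
              date = if (is.null(date)) NULL else as.Date(date))
  class(rec) <- "clinical_record"
  crst_total(rec)  # enforce the combined-score ceiling at construction
  rec
}

#' Hand Tremor Score
#'
#' Sum of the upper-limb item scores for one hand: maximum 32 for the
#' dominant hand (8 items including handwriting), 28 for the non-dominant
#' hand (7 items).
#'
#' @param record A [clinical_record()].
#' @param hand `"dominant"` or `"nondominant"`.
#' @return Score in points.
#' @export
hts_score <- function(record, hand = c("dominant", "nondominant")) {
  stopifnot(inherits(record, "clinical_record"))
  hand <- match.arg(hand)
  items <- if (hand == "dominant") record$hts_dominant else record$hts_nondominant
  sum(items)
}

#' Combined CRST score
#'
#' CRST_T = part A + part B + part C; the combined maximum is 160.
#'
#' @param record A [clinical_record()], or `crst_a` may be given as three
#'   numeric part scores via `crst_a`, `crst_b`, `crst_c`.
#' @return Combined score in points.
#' @export
crst_total <- function(record) {
  stopifnot(inherits(record, "clinical_record"))
  total <- record$crst_a + record$crst_b + record$crst_c
  if (any(c(record$crst_a, record$crst_b, record$crst_c) < 0))
    stop("CRST part scores must be >= 0", call. = FALSE)
  if (total > 160)
    stop(sprintf("combined CRST %g exceeds the scale maximum of 160", total),
         call. = FALSE)
  total
}

#' Signed percent change of a tremor score
#'
#' `100 * (pre - post) / pre`: positive values indicate a reduction in
#' tremor score (improvement).
#'
#' @param pre Pre-treatment score, > 0.
#' @param post Post-treatment score.
#' @return Percent change.
#' @export
percent_change <- function(pre, post) {
  if (any(pre == 0))
    stop("percent change is undefined for a pre-treatment score of 0",
         call. = FALSE)
  100 * (pre - post) / pre
}

N_TRANSDUCER_ELEMENTS <- 1024L

#' Construct per-treatment transducer and sonication parameters
#'
#' Skull parameters are measured along the beam of each of the 1,024
#' transducer elements; the per-element arrays are stored in full so that
#' both the mean (the value used clinically) and the across-skull standard
#' deviation can be derived.
#'
#' @param sdr Skull density ratio per element (unitless), length 1024.
#' @param skull_thickness Skull thickness per element (mm), length 1024.
#' @param angle_inner,angle_outer Inner/outer skull angle per element (deg),
#'   length 1024.
#' @param max_temperature_c Peak sonication temperature (deg C).
#' @param active_elements Active element count of the first sonication.
#' @param n_sonications Total sonication count.
#' @param summed_temperature_c Sum of temperatures across sonications (deg C).
#' @return Object of class `treatment_params`.
#' @export
treatment_params <- function(sdr, skull_thickness, angle_inner, angle_outer,
                             max_temperature_c = NA_real_,
                             active_elements = NA_integer_,
                             n_sonications = NA_integer_,
                             summed_temperature_c = NA_real_) {
  arrays <- list(sdr = sdr, skull_thickness = skull_thickness,
                 angle_inner = angle_inner, angle_outer = angle_outer)
  for (nm in names(arrays)) {
    if (length(arrays[[nm]]) != N_TRANSDUCER_ELEMENTS)
      stop(sprintf("'%s' must have exactly %d elements (got %d)",
                   nm, N_TRANSDUCER_ELEMENTS, length(arrays[[nm]])),
           call. = FALSE)
    if (!all(is.finite(arrays[[nm]])))
      stop(sprintf("'%s' must be finite", nm), call. = FALSE)
  }
  structure(c(arrays,
              list(max_temperature_c = max_temperature_c,
                   active_elements = active_elements,
                   n_sonications = n_sonications,
                   summed_temperature_c = summed_temperature_c)),
            class = "treatment_params")
}

#' Per-parameter mean and standard deviation of skull parameters
#'
#' Arithmetic mean and sample SD (denominator n - 1) over the 1,024
#' transducer elements, for each of SDR, skull thickness and the inner and
#' outer skull angles.
#'
#' @param params A [treatment_params()].
#' @return Data frame with columns `parameter`, `mean`, `sd`.
#' @export
treatment_summary <- function(params) {
  stopifnot(inherits(params, "treatment_params"))
  nms <- c("sdr", "skull_thickness", "angle_inner", "angle_outer")
  data.frame(parameter = nms,
             mean = vapply(nms, function(nm) mean(params[[nm]]), numeric(1)),
             sd = vapply(nms, function(nm) stats::sd(params[[nm]]), numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read clinical records from CSV
#'
#' Expected columns: `subject_id`, `date`, `timepoint` (pre/post),
#' `crst_a`, `crst_b`, `crst_c`, and per-item HTS columns `hts_d_<item>`
#' (8 dominant items) and `hts_nd_<item>` (7 non-dominant items).
#'
#' @param path CSV path.
#' @return List of [clinical_record()]s.
#' @export
read_clinical_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    dom <- as.numeric(row[paste0("hts_d_", HTS_ITEMS_DOMINANT)])
    names(dom) <- HTS_ITEMS_DOMINANT
    nd <- as.numeric(row[paste0("hts_nd_", HTS_ITEMS_NONDOMINANT)])
    names(nd) <- HTS_ITEMS_NONDOMINANT
    clinical_record(row$subject_id, row$timepoint,
                    row$crst_a, row$crst_b, row$crst_c,
                    hts_dominant = dom, hts_nondominant = nd,
                    date = row$date)
  })
}

#' Latest-available follow-up per subject
#'
#' Keeps, for each subject, the post-treatment record with the latest date
#' (ties broken deterministically by row order: the later row wins).
#'
#' @param records List of [clinical_record()]s.
#' @return Named list of post records, one per subject.
#' @export
latest_followup <- function(records) {
  post <- Filter(function(r) r$timepoint == "post", records)
  out <- list()
  for (r in post) {
    id <- as.character(r$subject_id)
    cur <- out[[id]]
    if (is.null(cur) || is.null(cur$date) || is.null(r$date) ||
        r$date >= cur$date)
      out[[id]] <- r
  }
  out
}

#' Per-subject tremor score changes from pre/post records
#'
#' Pairs each subject's pre record with the latest available follow-up and
#' computes signed percent changes for CRST parts A/B/C, CRST_T and both
#' hands' HTS. Subjects with a zero pre-treatment score on any scale are
#' flagged (`NA` change for that scale).
#'
#' @param records List of [clinical_record()]s.
#' @return Data frame with one row per subject: pre/post scores and
#'   `*_change` columns (percent).
#' @export
score_changes <- function(records) {
  pre <- Filter(function(r) r$timepoint == "pre", records)
  pre_by_id <- stats::setNames(pre, vapply(pre, function(r)
    as.character(r$subject_id), character(1)))
  post_by_id <- latest_followup(records)
  ids <- intersect(names(pre_by_id), names(post_by_id))
  pc <- function(a, b) if (a == 0) NA_real_ else percent_change(a, b)
  rows <- lapply(ids, function(id) {
    p <- pre_by_id[[id]]; q <- post_by_id[[id]]
    data.frame(subject_id = id,
               crst_a_pre = p$crst_a, crst_b_pre = p$crst_b,
               crst_c_pre = p$crst_c, crst_t_pre = crst_total(p),
               hts_d_pre = hts_score(p, "dominant"),
               hts_nd_pre = hts_score(p, "nondominant"),
               crst_a_change = pc(p$crst_a, q$crst_a),
               crst_b_change = pc(p$crst_b, q$crst_b),
               crst_c_change = pc(p$crst_c, q$crst_c),
               crst_t_change = pc(crst_total(p), crst_total(q)),
               hts_d_change = pc(hts_score(p, "dominant"),
                                 hts_score(q, "dominant")),
               hts_nd_change = pc(hts_score(p, "nondominant"),
                                  hts_score(q, "nondominant")),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
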