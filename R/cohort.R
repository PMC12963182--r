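#' @keywords internal
mtici_levels <- function() c("0", "1", "2a", "2b", "2c", "3")

eligibility_stages <- data.frame(
  stage = 1:7,
  id = c("mri_pair", "reperfusion", "sequence", "quality",
         "lesion_volume", "reocclusion", "time_to_recan"),
  reason = c(
    "no pre-EVT MRI or no follow-up MRI 12-36 h after EVT",
    "mTICI below 2c",
    "different scanner or DWI sequence pre vs post",
    "insufficient image quality",
    "pre-EVT DWI lesion <= 1 mL",
    "re-occlusion of a treated vessel",
    "recanalization more than 120 min after MRI"
  ),
  stringsAsFactors = FALSE
)

required_eligibility_fields <- c(
  "patient_id", "has_pre_mri", "has_post_mri_12_36h", "mtici",
  "same_scanner_sequence", "image_quality_ok", "pre_lesion_ml",
  "reocclusion", "time_mri_to_recan_min")

check_patient_record <- function(p) {
  missing <- setdiff(required_eligibility_fields, names(p))
  if (length(missing))
    stop("patient record is missing eligibility field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  bad <- required_eligibility_fields[vapply(p[required_eligibility_fields],
                                            function(x) length(x) != 1L || is.na(x),
                                            logical(1))]
  if (length(bad))
    stop("patient record has NA/empty eligibility field(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (!as.character(p$mtici) %in% mtici_levels())
    stop("invalid mTICI grade: ", p$mtici, call. = FALSE)
  invisible(TRUE)
}

#' Evaluate study eligibility for one patient record
#'
#' Applies the cohort's eligibility chain in a fixed stage order:
#' (1) paired MRI — baseline scan plus follow-up 12-36 h after treatment;
#' (2) successful reperfusion, mTICI 2c or 3;
#' (3) identical scanner and DWI sequence pre/post;
#' (4) sufficient image quality for segmentation and co-registration;
#' (5) baseline DWI lesion strictly greater than 1 mL;
#' (6) no re-occlusion of a treated vessel;
#' (7) recanalization within 120 min of the baseline MRI.
#' The first failing stage is reported; later stages are not evaluated.
#'
#' @param p a one-row data.frame or named list with at least the fields
#'   `patient_id`, `has_pre_mri`, `has_post_mri_12_36h`, `mtici` (one of
#'   `"0","1","2a","2b","2c","3"`), `same_scanner_sequence`,
#'   `image_quality_ok`, `pre_lesion_ml`, `reocclusion`,
#'   `time_mri_to_recan_min`. Additional clinical metadata is carried along
#'   untouched.
#' @return list with `included` (logical), `failed_stage` (integer or `NA`),
#'   `reason` (string, `"included"` when eligible).
#' @examples
#' rec <- list(patient_id = "p1", has_pre_mri = TRUE, has_post_mri_12_36h = TRUE,
#'             mtici = "3", same_scanner_sequence = TRUE, image_quality_ok = TRUE,
#'             pre_lesion_ml = 12, reocclusion = FALSE, time_mri_to_recan_min = 80)
#' apply_eligibility(rec)$included
#' @export
apply_eligibility <- function(p) {
  check_patient_record(p)
  fails <- c(
    !(isTRUE(as.logical(p$has_pre_mri)) && isTRUE(as.logical(p$has_post_mri_12_36h))),
    !(as.character(p$mtici) %in% c("2c", "3")),
    !isTRUE(as.logical(p$same_scanner_sequence)),
    !isTRUE(as.logical(p$image_quality_ok)),
    !(p$pre_lesion_ml > 1),
    isTRUE(as.logical(p$reocclusion)),
    !(p$time_mri_to_recan_min <= 120)
  )
  if (any(fails)) {
    s <- which(fails)[1L]
    list(included = FALSE, failed_stage = s, reason = eligibility_stages$reason[s])
  } else {
    list(included = TRUE, failed_stage = NA_integer_, reason = "included")
  }
}

#' Inclusion flow summary for a cohort
#'
#' Runs [apply_eligibility()] over a cohort and reports, for each stage of the
#' chain, how many patients survive it — the numbers of a study-inclusion flow
#' diagram. Counts are non-increasing; the last count equals the number of
#' included patients.
#'
#' @param cohort data.frame of patient records (one row each).
#' @return list with `n_total`, `surviving` (named integer vector, one entry
#'   per stage in order), `n_included`, and `decisions` (data.frame of
#'   patient_id / included / failed_stage / reason).
#' @export
flow_summary <- function(cohort) {
  stages <- eligibility_stages
  if (is.null(cohort) || nrow(as.data.frame(cohort)) == 0L) {
    surv <- setNames(integer(length(stages$id)), stages$id)
    return(list(n_total = 0L, surviving = surv, n_included = 0L,
                decisions = data.frame(patient_id = character(),
                                       included = logical(),
                                       failed_stage = integer(),
                                       reason = character())))
  }
  cohort <- as.data.frame(cohort)
  dec <- lapply(seq_len(nrow(cohort)), function(i) apply_eligibility(cohort[i, ]))
  failed <- vapply(dec, function(d) ifelse(is.na(d$failed_stage), Inf,
                                           d$failed_stage), numeric(1))
  surv <- vapply(stages$stage, function(s) sum(failed > s), integer(1))
  surv <- setNames(surv, stages$id)
  list(
    n_total = nrow(cohort),
    surviving = surv,
    n_included = as.integer(sum(is.infinite(failed))),
    decisions = data.frame(
      patient_id = as.character(cohort$patient_id),
      included = vapply(dec, `[[`, logical(1), "included"),
      failed_stage = vapply(dec, `[[`, integer(1), "failed_stage"),
      reason = vapply(dec, `[[`, character(1), "reason"),
      stringsAsFactors = FALSE)
  )
}

#' Read a cohort metadata table
#'
#' Thin wrapper over [utils::read.delim()] for the tab-separated metadata
#' table written by [generate_cohort()] (or assembled by hand with the same
#' header). Logical columns are parsed from TRUE/FALSE; `mtici` is kept as
#' character.
#'
#' @param path TSV file path.
#' @return data.frame of patient records.
#' @export
read_cohort_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path, call. = FALSE)
  md <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(patient_id = "character"))
  md$mtici <- as.character(md$mtici)
  md
}
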