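#' Run the full lesion-reversal analysis on a cohort directory
#'
#' One-command end-to-end analysis. The input directory must contain a
#' `metadata.tsv` patient table (see [read_cohort_metadata()]) and, per
#' patient, `<id>_adc.nii(.gz)`, `<id>_pre.nii(.gz)`, `<id>_post.nii(.gz)`
#' and optionally `<id>_haem.nii(.gz)` — the layout written by
#' [generate_cohort()]. The pipeline:
#' applies the eligibility chain ([flow_summary()]); loads each eligible
#' patient's volumes, verifies grid identity, classifies voxel fates
#' ([classify_voxels()]) and applies the minimum-lesion gate; pools all
#' surviving voxels and fits the threshold model ([reversal_fit()]); repeats
#' the ROC on the canonical subgroup (anterior occlusion, mTICI 3,
#' recanalization within 90 min); and writes every report to `output_dir`.
#'
#' Patients failing grid checks are recorded in the QC report and skipped
#' with a warning, not a crash. An empty eligible cohort is an error.
#'
#' @param input_dir cohort directory.
#' @param output_dir report directory (created if needed).
#' @param thresholds sweep thresholds (default [reference_thresholds()]).
#' @param adc_window ADC inclusion window (default `c(200, 760)`).
#' @param band_halfwidth band halfwidth (default 10).
#' @param min_lesion_ml minimum baseline lesion volume (default 1).
#' @param subgroup_predicate function(metadata) -> logical; default
#'   [subgroup_anterior_fast()]. `NULL` skips the subgroup analysis.
#' @param boot_reps patient-bootstrap replicates for the AUC CI (default 0).
#' @param seed seed recorded in provenance and used for the bootstrap.
#' @return invisibly, list: `fit` ([reversal_fit]), `flow`, `qc`,
#'   `subgroup_fit` (or `NULL`), `files` (paths of the written reports).
#' @section Reports written:
#' `flow.json` (inclusion flow), `qc.tsv` (per-patient QC), `sweep.tsv`
#' (threshold sweep), `roc.json` (AUC, optimal threshold, curve), `bands.tsv`
#' (band-probability curve), `subgroup_roc.json`, `provenance.json`
#' (parameters, versions, seed).
#' @export
run_pipeline <- function(input_dir, output_dir,
                         thresholds = reference_thresholds(),
                         adc_window = c(200, 760), band_halfwidth = 10,
                         min_lesion_ml = 1.0,
                         subgroup_predicate = subgroup_anterior_fast,
                         boot_reps = 0, seed = 1) {
  md_path <- file.path(input_dir, "metadata.tsv")
  if (!file.exists(md_path))
    stop("no metadata.tsv in input directory: ", input_dir, call. = FALSE)
  if (!dir.exists(output_dir) && !dir.create(output_dir, recursive = TRUE))
    stop("cannot create output directory: ", output_dir, call. = FALSE)
  md <- read_cohort_metadata(md_path)

  flow <- flow_summary(md)
  eligible <- flow$decisions$patient_id[flow$decisions$included]
  if (length(eligible) == 0L)
    stop("no eligible patients after the inclusion chain", call. = FALSE)

  find_vol <- function(pid, suffix) {
    for (ext in c(".nii.gz", ".nii")) {
      p <- file.path(input_dir, paste0(pid, "_", suffix, ext))
      if (file.exists(p)) return(p)
    }
    NULL
  }
  qc <- data.frame(patient_id = eligible, status = "ok",
                   pre_lesion_ml = NA_real_, included_voxels = NA_integer_,
                   reversal_fraction = NA_real_, stringsAsFactors = FALSE)
  tables <- list()
  for (i in seq_along(eligible)) {
    pid <- eligible[i]
    res <- tryCatch({
      paths <- lapply(c("adc", "pre", "post"), function(s) {
        p <- find_vol(pid, s)
        if (is.null(p)) stop("missing ", s, " volume for patient ", pid,
                             call. = FALSE)
        p
      })
      adc <- read_volume(paths[[1]], "adc")
      pre <- read_volume(paths[[2]], "mask")
      post <- read_volume(paths[[3]], "mask")
      hp <- find_vol(pid, "haem")
      haem <- if (is.null(hp)) NULL else read_volume(hp, "mask")
      tab <- classify_voxels(adc, pre, post, haem, patient_id = pid,
                             adc_window = adc_window)
      qc$pre_lesion_ml[i] <- nrow(tab) * prod(pre$spacing) / 1000
      qc$included_voxels[i] <- sum(tab$included)
      if (!qc_min_lesion(tab, min_lesion_ml)) {
        qc$status[i] <- sprintf("lesion <= %g mL", min_lesion_ml)
        NULL
      } else {
        qc$reversal_fraction[i] <- reversal_fraction(tab)
        tab
      }
    }, error = function(e) {
      qc$status[i] <<- conditionMessage(e)
      warning("skipping patient ", pid, ": ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (!is.null(res)) tables[[pid]] <- res
  }
  if (length(tables) == 0L)
    stop("no analysable patients after QC", call. = FALSE)

  pooled <- pool_voxel_tables(tables)
  fit <- reversal_fit(pooled, thresholds = thresholds, adc_range = adc_window,
                      band_halfwidth = band_halfwidth,
                      boot_reps = boot_reps, boot_seed = seed)

  subgroup_fit <- NULL
  if (!is.null(subgroup_predicate)) {
    md_a <- md[md$patient_id %in% names(tables), , drop = FALSE]
    sub <- subgroup_voxels(pooled, md_a, subgroup_predicate)
    if (nrow(sub) > 0 && any(sub$included & sub$fate == "reversed") &&
        any(sub$included & sub$fate == "unchanged"))
      subgroup_fit <- reversal_fit(sub, thresholds = thresholds,
                                   adc_range = adc_window,
                                   band_halfwidth = band_halfwidth)
  }

  files <- c(flow = file.path(output_dir, "flow.json"),
             qc = file.path(output_dir, "qc.tsv"),
             sweep = file.path(output_dir, "sweep.tsv"),
             roc = file.path(output_dir, "roc.json"),
             bands = file.path(output_dir, "bands.tsv"),
             subgroup = file.path(output_dir, "subgroup_roc.json"),
             provenance = file.path(output_dir, "provenance.json"))
  jsonlite::write_json(list(n_total = flow$n_total,
                            surviving = as.list(flow$surviving),
                            n_included = flow$n_included),
                       files["flow"], auto_unbox = TRUE, digits = NA)
  utils::write.table(qc, files["qc"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fit$sweep, files["sweep"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  roc_report <- function(f) list(
    auc = f$auc, auc_ci = f$auc_ci,
    optimal_threshold = f$optimal_threshold,
    sensitivity = f$sensitivity, specificity = f$specificity,
    n_voxels = f$n_voxels, n_patients = f$n_patients,
    reversal_fraction = f$reversal_fraction,
    points = f$roc$points[, c("fpr", "tpr")])
  jsonlite::write_json(roc_report(fit), files["roc"], auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  utils::write.table(fit$bands, files["bands"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(subgroup_fit))
    jsonlite::write_json(roc_report(subgroup_fit), files["subgroup"],
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  else files <- files[names(files) != "subgroup"]
  jsonlite::write_json(list(
    package = "adcrev",
    version = as.character(utils::packageVersion("adcrev")),
    r_version = as.character(getRversion()),
    parameters = list(thresholds = thresholds, adc_window = adc_window,
                      band_halfwidth = band_halfwidth,
                      min_lesion_ml = min_lesion_ml, boot_reps = boot_reps,
                      seed = seed),
    n_analysed = length(tables),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    files["provenance"], auto_unbox = TRUE, digits = NA)

  invisible(list(fit = fit, flow = flow, qc = qc, subgroup_fit = subgroup_fit,
                 files = files))
}
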