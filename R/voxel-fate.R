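#' Classify baseline lesion voxels as reversed or persistent
#'
#' The unit of analysis is the baseline (pre-treatment) lesion voxel. Each
#' voxel of the pre-treatment mask is labelled by its fate on follow-up:
#' `"reversed"` if it is absent from the union of the post-treatment mask and
#' the optional haemorrhage mask, `"unchanged"` otherwise. Haemorrhagic
#' transformation obscures follow-up signal, so haemorrhage voxels are
#' conservatively counted as persistent infarction. Voxels present only in the
#' post mask (lesion growth) are not scored — the question is the fate of
#' baseline lesion tissue.
#'
#' Baseline ADC gates statistical inclusion: voxels with ADC above 760 are
#' excluded (likely partial volume / non-core tissue), voxels below 200 are
#' treated as segmentation artifacts; the window is closed, `200 <= adc <=
#' 760`. No ADC filter applies to post-mask membership, which avoids
#' overestimating reversal. Excluded voxels stay in the table with their
#' exclusion reason so every denominator is auditable.
#'
#' @param adc baseline ADC map ([adc_volume], kind `"adc"`, units 1e-6 mm^2/s).
#' @param pre,post binary lesion masks on the same grid as `adc`.
#' @param haemorrhage optional binary mask of haemorrhagic transformation.
#' @param patient_id identifier stored with every record.
#' @param adc_window inclusion window, default `c(200, 760)`.
#' @return a `voxel_table`: data.frame with columns `patient_id`, `i`, `j`,
#'   `k` (0-based indices), `adc`, `fate` (`"reversed"`/`"unchanged"`),
#'   `included` (logical), `exclusion_reason` (`"none"`, `"adc_below_min"`,
#'   `"adc_above_max"`); attributes `spacing` and `n_patients`.
#' @examples
#' adc <- adc_volume(array(500, c(3, 1, 1)), c(1, 1, 1), "adc")
#' pre <- adc_volume(array(1L, c(3, 1, 1)), c(1, 1, 1), "mask")
#' post <- adc_volume(array(0L, c(3, 1, 1)), c(1, 1, 1), "mask")
#' classify_voxels(adc, pre, post, patient_id = "p1")
#' @export
classify_voxels <- function(adc, pre, post, haemorrhage = NULL,
                            patient_id = "patient", adc_window = c(200, 760)) {
  stopifnot(inherits(adc, "adc_volume"), inherits(pre, "adc_volume"),
            inherits(post, "adc_volume"))
  assert_same_grid(adc, pre)
  assert_same_grid(adc, post)
  if (!is.null(haemorrhage)) assert_same_grid(adc, haemorrhage)

  idx <- which(pre$data > 0)
  if (length(idx) == 0L)
    stop(errorCondition("pre-treatment lesion mask is empty",
                        class = c("adcrev_empty_lesion_error", "error")))
  persistent <- post$data[idx] > 0
  if (!is.null(haemorrhage)) persistent <- persistent | (haemorrhage$data[idx] > 0)

  d <- dim(pre$data)
  ai <- arrayInd(idx, d)
  adc_vals <- as.numeric(adc$data[idx])
  reason <- rep("none", length(idx))
  reason[adc_vals < adc_window[1]] <- "adc_below_min"
  reason[adc_vals > adc_window[2]] <- "adc_above_max"

  tab <- data.frame(
    patient_id = rep(as.character(patient_id), length(idx)),
    i = ai[, 1] - 1L, j = ai[, 2] - 1L, k = ai[, 3] - 1L,
    adc = adc_vals,
    fate = ifelse(persistent, "unchanged", "reversed"),
    included = reason == "none",
    exclusion_reason = reason,
    stringsAsFactors = FALSE)
  as_voxel_table(tab, spacing = pre$spacing)
}

#' @keywords internal
as_voxel_table <- function(df, spacing, n_patients = NULL) {
  attr(df, "spacing") <- as.numeric(spacing)
  attr(df, "n_patients") <- if (is.null(n_patients))
    length(unique(df$patient_id)) else as.integer(n_patients)
  class(df) <- c("voxel_table", "data.frame")
  df
}

#' Pool per-patient voxel tables
#'
#' Row-binds voxel tables from several patients into one pooled table; every
#' voxel keeps equal weight. All tables must share the voxel spacing (grids
#' may differ in shape).
#'
#' @param ... `voxel_table` objects, or a single list of them.
#' @return a pooled `voxel_table`.
#' @export
pool_voxel_tables <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && !inherits(tabs[[1L]], "voxel_table")) tabs <- tabs[[1L]]
  stopifnot(length(tabs) >= 1L, all(vapply(tabs, inherits, logical(1), "voxel_table")))
  sp <- attr(tabs[[1L]], "spacing")
  for (t in tabs[-1L])
    if (max(abs(attr(t, "spacing") - sp) / sp) > 1e-6)
      stop("cannot pool voxel tables with different voxel spacing", call. = FALSE)
  pooled <- do.call(rbind, lapply(tabs, as.data.frame))
  as_voxel_table(pooled, spacing = sp)
}

voxel_ml <- function(table) prod(attr(table, "spacing")) / 1000

#' Reversal volume of a voxel table, in mL
#'
#' Volume of included reversed voxels. For pooled tables the result is the
#' cohort total; divide by `attr(table, "n_patients")` for the per-patient
#' mean.
#'
#' @param table a `voxel_table`.
#' @param per_patient if `TRUE`, return the mean per patient.
#' @return volume in mL.
#' @export
reversal_volume_ml <- function(table, per_patient = FALSE) {
  n <- sum(table$included & table$fate == "reversed")
  v <- n * voxel_ml(table)
  if (per_patient) v / attr(table, "n_patients") else v
}

#' Fraction of included lesion voxels that reversed
#'
#' @param table a `voxel_table` with at least one included voxel.
#' @return fraction in `[0, 1]`.
#' @export
reversal_fraction <- function(table) {
  n_inc <- sum(table$included)
  if (n_inc == 0L)
    stop(errorCondition("no included voxels: cannot compute reversal fraction",
                        class = c("adcrev_degenerate_error", "error")))
  sum(table$included & table$fate == "reversed") / n_inc
}

#' Minimum-lesion quality gate
#'
#' Small lesions are disproportionately affected by segmentation and
#' co-registration error, so patients with a baseline lesion at or below
#' `min_ml` are rejected. The gate uses the raw pre-mask volume — all
#' baseline lesion voxels, before any ADC windowing.
#'
#' @param table a `voxel_table` for one patient.
#' @param min_ml threshold in mL (default 1).
#' @return `TRUE` (pass) iff pre-mask volume is strictly greater than `min_ml`.
#' @export
qc_min_lesion <- function(table, min_ml = 1.0) {
  nrow(table) * voxel_ml(table) > min_ml
}

#' Write / read a voxel table as TSV
#'
#' Flat serialisation (one voxel per row) for downstream statistics or
#' debugging outside R. Spacing is carried in a `# spacing_mm:` header line.
#'
#' @param table a `voxel_table`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_voxel_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# spacing_mm: %s",
                     paste(attr(table, "spacing"), collapse = " ")), con)
  utils::write.table(as.data.frame(table), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_voxel_table
#' @export
read_voxel_table <- function(path) {
  hdr <- readLines(path, n = 1L)
  spacing <- as.numeric(strsplit(sub("^# spacing_mm: *", "", hdr), " ")[[1]])
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = c(patient_id = "character"))
  as_voxel_table(df, spacing = spacing)
}
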