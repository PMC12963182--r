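included_voxels <- function(voxels) {
  stopifnot(inherits(voxels, "voxel_table"))
  voxels[voxels$included, , drop = FALSE]
}

check_both_classes <- function(v) {
  if (!any(v$fate == "reversed") || !any(v$fate == "unchanged"))
    stop(errorCondition(
      "need at least one included reversed and one included unchanged voxel",
      class = c("adcrev_degenerate_error", "error")))
}

#' Voxel-level sensitivity and specificity of an ADC threshold
#'
#' The positive class is reversal; the test calls a voxel positive when its
#' baseline ADC is at or above the threshold (higher ADC, better salvage
#' prospects). Sensitivity is the percentage of reversed voxels with
#' `adc >= t`; specificity the percentage of unchanged voxels with `adc < t`.
#' Only included voxels (ADC window) enter.
#'
#' @param voxels a `voxel_table` (single patient or pooled).
#' @param t threshold in 1e-6 mm^2/s.
#' @return named numeric: `sensitivity`, `specificity` (percent).
#' @export
sensitivity_specificity <- function(voxels, t) {
  v <- included_voxels(voxels)
  check_both_classes(v)
  r <- v$adc[v$fate == "reversed"]
  u <- v$adc[v$fate == "unchanged"]
  c(sensitivity = 100 * sum(r >= t) / length(r),
    specificity = 100 * sum(u < t) / length(u))
}

#' Threshold sweep over a pooled voxel table
#'
#' For each threshold `t` the sweep reports, over included voxels: the lesion
#' volume strictly below `t` (as a per-patient mean, in mL, and as a
#' percentage of the total lesion), the reversed volume below `t` (mL and
#' percentage of all reversed volume), the proportion of below-threshold
#' voxels that reversed, sensitivity/specificity (test-positive `adc >= t`),
#' Youden's J on the percentage scale, and the reversal probability for
#' voxels within `band_halfwidth` of `t` (see [band_probability()]).
#'
#' "Below" is strict (`adc < t`) throughout, which makes
#' `sensitivity + reversed_pct_below = 100` an exact identity on pooled data.
#' When no voxel lies below a threshold the proportion column is `NA` —
#' undefined, not zero.
#'
#' @param voxels pooled `voxel_table`.
#' @param thresholds vector of thresholds inside the ADC window; default the
#'   reference grid [reference_thresholds()].
#' @param band_halfwidth halfwidth of the per-threshold probability band
#'   (default 10).
#' @return data.frame with one row per threshold and the columns of
#'   [reference_sweep()] plus `youden_j`.
#' @export
sweep_thresholds <- function(voxels, thresholds = reference_thresholds(),
                             band_halfwidth = 10) {
  v <- included_voxels(voxels)
  if (nrow(v) == 0L)
    stop(errorCondition("no included voxels to sweep",
                        class = c("adcrev_degenerate_error", "error")))
  thresholds <- sort(as.numeric(thresholds))
  n_pat <- attr(voxels, "n_patients")
  vml <- voxel_ml(voxels)
  rev <- v$fate == "reversed"
  n_inc <- nrow(v); n_rev <- sum(rev); n_unc <- n_inc - n_rev
  div <- function(num, den) if (den == 0L) NA_real_ else num / den
  rows <- lapply(thresholds, function(t) {
    below <- v$adc < t
    nb <- sum(below); nrb <- sum(below & rev)
    data.frame(
      threshold = t,
      lesion_ml_below = nb * vml / n_pat,
      lesion_pct_below = 100 * nb / n_inc,
      reversed_ml_below = nrb * vml / n_pat,
      reversed_pct_below = 100 * div(nrb, n_rev),
      proportion_r_below = 100 * div(nrb, nb),
      sensitivity = 100 * div(sum(!below & rev), n_rev),
      specificity = 100 * div(sum(below & !rev), n_unc),
      band_probability = band_probability(voxels, t, halfwidth = band_halfwidth))
  })
  out <- do.call(rbind, rows)
  out$youden_j <- out$sensitivity + out$specificity - 100
  out
}

#' Trapezoid-rule area under an ROC curve
#'
#' @param points data.frame or matrix with columns `fpr`, `tpr`, sorted by
#'   `fpr` (ties allowed), including the `(0,0)` and `(1,1)` endpoints.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc_trapezoid(data.frame(fpr = c(0, 1), tpr = c(0, 1))) # 0.5
#' @export
auc_trapezoid <- function(points) {
  points <- as.data.frame(points)
  stopifnot(all(c("fpr", "tpr") %in% names(points)))
  fpr <- points$fpr; tpr <- points$tpr
  if (is.unsorted(fpr)) stop("ROC points must be sorted by fpr", call. = FALSE)
  if (abs(fpr[1]) > 1e-12 || abs(fpr[length(fpr)] - 1) > 1e-12)
    stop("ROC points must span fpr = 0 to fpr = 1", call. = FALSE)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Empirical ROC analysis of ADC as a predictor of voxel reversal
#'
#' Evaluates sensitivity/specificity at every threshold on an integer grid
#' across the ADC window, assembles the ROC polygon, integrates it by the
#' trapezoid rule, and picks the threshold maximising Youden's J (ties broken
#' toward the lower threshold). ADC values are rounded half-up to integers
#' first — scanner ADC maps are integer-valued at this scale.
#'
#' @param voxels pooled `voxel_table`.
#' @param adc_min,adc_max window bounds (default 200, 760).
#' @param step threshold grid step (default 1).
#' @return list of class `adc_roc`: `points` (data.frame `threshold`, `fpr`,
#'   `tpr`, fpr-sorted with endpoints), `auc`, `optimal_threshold`,
#'   `optimal_j` (percentage points), `sensitivity` and `specificity` at the
#'   optimum, `n_reversed`, `n_unchanged`.
#' @export
adc_roc <- function(voxels, adc_min = 200, adc_max = 760, step = 1) {
  v <- included_voxels(voxels)
  check_both_classes(v)
  adc <- floor(v$adc + 0.5)
  rev <- v$fate == "reversed"
  grid <- seq(adc_min, adc_max, by = step)
  n_r <- sum(rev); n_u <- sum(!rev)
  # #(adc >= t) = n - #(adc <= t - 0.5) for integer-valued adc, via findInterval
  sr <- sort(adc[rev]); su <- sort(adc[!rev])
  tpr <- (n_r - findInterval(grid - 0.5, sr)) / n_r  # P(adc >= t | reversed)
  fpr <- (n_u - findInterval(grid - 0.5, su)) / n_u  # P(adc >= t | unchanged)
  j <- tpr - fpr
  best <- which.max(j)       # which.max takes the first (lowest threshold) tie
  ord <- order(fpr, tpr)
  pts <- data.frame(threshold = c(Inf, grid[ord], -Inf),
                    fpr = c(0, fpr[ord], 1), tpr = c(0, tpr[ord], 1))
  structure(list(points = pts,
                 auc = auc_trapezoid(pts),
                 optimal_threshold = grid[best],
                 optimal_j = 100 * j[best],
                 sensitivity = 100 * tpr[best],
                 specificity = 100 * (1 - fpr[best]),
                 n_reversed = n_r, n_unchanged = n_u),
            class = "adc_roc")
}

#' @export
print.adc_roc <- function(x, ...) {
  cat(sprintf(paste0("Voxel-level ROC: AUC = %.3f  (%d reversed / %d unchanged ",
                     "voxels)\noptimal threshold %g (Youden J = %.1f; ",
                     "sensitivity %.1f%%, specificity %.1f%%)\n"),
              x$auc, x$n_reversed, x$n_unchanged, x$optimal_threshold,
              x$optimal_j, x$sensitivity, x$specificity))
  invisible(x)
}

#' Youden-optimal threshold from a sweep table
#'
#' Maximises `sensitivity + specificity - 100` over the rows of a sweep;
#' ties are broken toward the lower threshold.
#'
#' @param rows data.frame with columns `threshold`, `sensitivity`,
#'   `specificity` (percent), e.g. [sweep_thresholds()] output or
#'   [reference_sweep()].
#' @return the optimal threshold (1e-6 mm^2/s).
#' @examples
#' youden_optimal(reference_sweep()) # 555
#' @export
youden_optimal <- function(rows) {
  rows <- as.data.frame(rows)
  if (nrow(rows) == 0L) stop("empty sweep: no thresholds to choose from",
                             call. = FALSE)
  stopifnot(all(c("threshold", "sensitivity", "specificity") %in% names(rows)))
  j <- rows$sensitivity + rows$specificity - 100
  ord <- order(rows$threshold)
  j <- j[ord]; thr <- rows$threshold[ord]
  thr[which.max(j)]
}

#' Reversal probability within an ADC band
#'
#' The proportion of reversed voxels among included voxels whose ADC lies in
#' the closed band `[center - halfwidth, center + halfwidth]`. Two modes:
#' `"pooled"` computes a single ratio over all voxels (each voxel equal
#' weight); `"per_patient_mean"` computes the ratio within each patient that
#' has voxels in the band and averages across those patients — the
#' patient-averaged probability curve.
#'
#' @param voxels pooled `voxel_table`.
#' @param center band center (1e-6 mm^2/s).
#' @param halfwidth band halfwidth (default 10).
#' @param mode `"pooled"` or `"per_patient_mean"`.
#' @return probability in percent; `NA` if no voxel falls in the band.
#' @export
band_probability <- function(voxels, center, halfwidth = 10,
                             mode = c("pooled", "per_patient_mean")) {
  mode <- match.arg(mode)
  v <- included_voxels(voxels)
  inband <- v$adc >= center - halfwidth & v$adc <= center + halfwidth
  if (!any(inband)) return(NA_real_)
  b <- v[inband, , drop = FALSE]
  if (mode == "pooled") {
    100 * sum(b$fate == "reversed") / nrow(b)
  } else {
    per <- tapply(b$fate == "reversed", b$patient_id, mean)
    100 * mean(per)
  }
}

#' Band-probability curve over a grid of centers
#'
#' @param voxels pooled `voxel_table`.
#' @param centers band centers (default every 10 from 350 to 750).
#' @param halfwidth band halfwidth (default 10).
#' @return data.frame `center`, `pooled_pct`, `per_patient_mean_pct`,
#'   `n_voxels`.
#' @export
band_curve <- function(voxels, centers = seq(350, 750, by = 10), halfwidth = 10) {
  v <- included_voxels(voxels)
  data.frame(
    center = centers,
    pooled_pct = vapply(centers, function(c0)
      band_probability(voxels, c0, halfwidth, "pooled"), numeric(1)),
    per_patient_mean_pct = vapply(centers, function(c0)
      band_probability(voxels, c0, halfwidth, "per_patient_mean"), numeric(1)),
    n_voxels = vapply(centers, function(c0)
      sum(v$adc >= c0 - halfwidth & v$adc <= c0 + halfwidth), numeric(1)))
}

#' Restrict a pooled voxel table to a patient subgroup
#'
#' Filters the pooled table to patients whose metadata satisfies `predicate`;
#' downstream statistics are unchanged. A canonical subgroup of interest is
#' anterior-circulation occlusion with complete (mTICI 3) recanalization
#' within 90 min of MRI — see [subgroup_anterior_fast()].
#'
#' @param voxels pooled `voxel_table`.
#' @param metadata data.frame with a `patient_id` column covering every
#'   patient in `voxels`.
#' @param predicate function taking the metadata data.frame and returning a
#'   logical vector (one entry per row).
#' @return a `voxel_table` restricted to the selected patients (possibly with
#'   zero rows).
#' @export
subgroup_voxels <- function(voxels, metadata, predicate) {
  stopifnot(inherits(voxels, "voxel_table"), is.function(predicate))
  metadata <- as.data.frame(metadata)
  unknown <- setdiff(unique(voxels$patient_id), as.character(metadata$patient_id))
  if (length(unknown))
    stop("voxel table contains patient_id(s) missing from metadata: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  keep <- predicate(metadata)
  if (!is.logical(keep) || length(keep) != nrow(metadata))
    stop("predicate must return one logical per metadata row", call. = FALSE)
  ids <- as.character(metadata$patient_id)[keep %in% TRUE]
  out <- voxels[voxels$patient_id %in% ids, , drop = FALSE]
  as_voxel_table(out, spacing = attr(voxels, "spacing"),
                 n_patients = length(intersect(ids, unique(voxels$patient_id))))
}

#' @rdname subgroup_voxels
#' @param max_time_min recanalization-delay cutoff in minutes (default 90).
#' @export
subgroup_anterior_fast <- function(metadata, max_time_min = 90) {
  as.character(metadata$mtici) == "3" &
    metadata$occlusion_type %in% c("LVO", "MeVO") &
    metadata$time_mri_to_recan_min <= max_time_min
}
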