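#' Published voxel-level threshold sweep used for calibration
#'
#' A 14-row reference table from a published 71-patient voxel-level DWI
#' lesion-reversal study (successful endovascular recanalization within
#' 120 min of baseline MRI). For each ADC threshold it gives the mean DWI
#' lesion volume below the threshold, the mean reversed (DWI-R) volume below
#' it, the proportion of below-threshold voxels that reversed, voxel-level
#' sensitivity/specificity for detecting reversal (test-positive: ADC >=
#' threshold), and the reversal probability for voxels within +-10 of the
#' threshold value.
#'
#' The table plays two roles in the package: it is the default calibration of
#' the synthetic cohort generator (cumulative lesion-ADC fractions and the
#' conditional reversal curve, see [synth_config()]), and it is a worked input
#' for the threshold statistics ([youden_optimal()], [auc_trapezoid()]).
#'
#' @return data.frame with columns `threshold`, `lesion_ml_below`,
#'   `lesion_pct_below`, `reversed_ml_below`, `reversed_pct_below`,
#'   `proportion_r_below`, `sensitivity`, `specificity`, `band_probability`;
#'   one row per threshold (1e-6 mm^2/s), ascending. Percentages are on the
#'   0-100 scale.
#' @export
reference_sweep <- function() {
  data.frame(
    threshold          = c(250, 300, 350, 400, 450, 500, 520, 550, 555,
                           600, 620, 650, 700, 750),
    lesion_ml_below    = c(0.06, 0.23, 0.68, 1.61, 3.24, 5.54, 6.59, 8.21,
                           8.50, 11.02, 12.12, 13.68, 16.03, 17.85),
    lesion_pct_below   = c(0.3, 1.3, 3.7, 8.9, 17.9, 30.6, 36.3, 45.3,
                           46.9, 60.8, 66.9, 75.5, 88.4, 98.5),
    reversed_ml_below  = c(0.00, 0.02, 0.06, 0.16, 0.40, 0.88, 1.17, 1.70,
                           1.80, 2.86, 3.39, 4.20, 5.53, 6.61),
    reversed_pct_below = c(0.1, 0.3, 0.9, 2.4, 5.9, 13.0, 17.2, 25.0,
                           26.5, 42.2, 50.0, 62.0, 81.6, 97.6),
    proportion_r_below = c(8.14, 8.05, 8.68, 9.93, 12.29, 15.92, 17.72,
                           20.65, 21.17, 25.96, 27.96, 30.68, 34.47, 37.03),
    sensitivity        = c(99.94, 99.73, 99.15, 97.68, 94.22, 87.17, 83.01,
                           75.26, 73.78, 58.16, 50.38, 38.43, 18.81, 2.68),
    specificity        = c(0.43, 1.82, 5.32, 12.57, 24.72, 40.66, 47.35,
                           57.07, 58.64, 71.59, 76.63, 83.33, 92.38, 98.94),
    band_probability   = c(7.36, 7.38, 9.88, 11.30, 17.39, 25.43, 29.03,
                           35.82, 36.95, 46.54, 49.30, 53.14, 58.89, 59.44)
  )
}

#' Headline summary statistics of the reference cohort
#'
#' Cohort-level reference values accompanying [reference_sweep()]: mean
#' baseline lesion and reversed volumes, and the mean baseline ADC in reversed
#' vs persistent lesion segments (1e-6 mm^2/s). Used by the worked examples
#' and the calibration checks.
#'
#' @return named list: `n_patients`, `lesion_ml_mean`, `reversed_ml_mean`,
#'   `adc_mean_reversed`, `adc_mean_unchanged`.
#' @export
reference_summary <- function() {
  list(n_patients = 71L,
       lesion_ml_mean = 18.13,
       reversed_ml_mean = 6.77,
       adc_mean_reversed = 597.6,
       adc_mean_unchanged = 536.7)
}

#' Default threshold grid of the reference sweep
#'
#' @return the 14 ADC thresholds (1e-6 mm^2/s) of [reference_sweep()].
#' @export
reference_thresholds <- function() reference_sweep()$threshold
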