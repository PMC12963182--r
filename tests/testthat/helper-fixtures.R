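# Builders for small in-code fixtures shared across test files.

mk_mask <- function(values, dim3 = c(length(values), 1, 1), spacing = c(1, 1, 1)) {
  adc_volume(array(as.integer(values), dim3), spacing, kind = "mask")
}

mk_adc <- function(values, dim3 = c(length(values), 1, 1), spacing = c(1, 1, 1)) {
  adc_volume(array(as.numeric(values), dim3), spacing, kind = "adc")
}

# voxel table straight from adc/fate vectors (one patient unless given)
mk_voxels <- function(adc, fate, patient_id = "p1", spacing = c(1, 1, 1),
                      included = NULL) {
  n <- length(adc)
  reason <- rep("none", n)
  reason[adc < 200] <- "adc_below_min"
  reason[adc > 760] <- "adc_above_max"
  df <- data.frame(patient_id = rep_len(patient_id, n),
                   i = seq_len(n) - 1L, j = 0L, k = 0L,
                   adc = as.numeric(adc), fate = fate,
                   included = if (is.null(included)) reason == "none" else included,
                   exclusion_reason = reason, stringsAsFactors = FALSE)
  adcrev:::as_voxel_table(df, spacing = spacing)
}

random_mask_array <- function(dim3, p = 0.3) {
  array(as.integer(stats::runif(prod(dim3)) < p), dim3)
}

# small, fast generator configuration for property tests; radii keep every
# lesion above the 1 mL gate (min 8*8*2 semi-axes = 1.25 mL at 0.6x0.6x6.5 mm)
small_config <- function(seed = 1, ...) {
  synth_config(grid_shape = c(32, 32, 8), lesion_radius_range = c(8, 13),
               lesion_z_radius_range = c(2, 3), seed = seed, ...)
}

# brute-force Mann-Whitney pair statistic: P(reversed > unchanged) + 0.5 ties
mw_pair_statistic <- function(adc_reversed, adc_unchanged) {
  gt <- sum(outer(adc_reversed, adc_unchanged, `>`))
  eq <- sum(outer(adc_reversed, adc_unchanged, `==`))
  (gt + 0.5 * eq) / (length(adc_reversed) * length(adc_unchanged))
}

# an eligible patient record with every field passing
eligible_record <- function(...) {
  rec <- list(patient_id = "p1", has_pre_mri = TRUE, has_post_mri_12_36h = TRUE,
              mtici = "3", same_scanner_sequence = TRUE, image_quality_ok = TRUE,
              pre_lesion_ml = 12, reocclusion = FALSE,
              time_mri_to_recan_min = 80)
  utils::modifyList(rec, list(...))
}
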