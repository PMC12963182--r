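test_that("patient generation is deterministic given the seeds", {
  cfg <- small_config(seed = 51)
  a <- generate_patient(cfg, 3)
  b <- generate_patient(cfg, 3)
  expect_identical(a$adc$data, b$adc$data)
  expect_identical(a$pre$data, b$pre$data)
  expect_identical(a$post$data, b$post$data)
  expect_identical(as.data.frame(a$truth), as.data.frame(b$truth))
  c1 <- generate_patient(cfg, 4)
  expect_false(identical(a$adc$data, c1$adc$data))
})

test_that("degenerate reversal curves give all-persistent or all-reversed lesions", {
  ref <- reference_sweep()
  flat0 <- data.frame(threshold = ref$threshold, prob_pct = 0)
  cfg0 <- small_config(seed = 52, reversal_knots = flat0,
                       haemorrhage_probability = 0)
  b0 <- generate_patient(cfg0, 1)
  expect_identical(b0$post$data, b0$pre$data)
  expect_equal(reversal_volume_ml(b0$truth), 0)

  flat100 <- data.frame(threshold = ref$threshold, prob_pct = 100)
  cfg100 <- small_config(seed = 52, reversal_knots = flat100,
                         haemorrhage_probability = 0)
  b100 <- generate_patient(cfg100, 1)
  expect_equal(sum(b100$post$data), 0)
  expect_true(all(b100$truth$fate == "reversed"))
})

test_that("generated lesion ADC matches the configured cumulative knots", {
  cfg <- synth_config(seed = 53, haemorrhage_probability = 0)
  tabs <- lapply(1:12, function(i) generate_patient(cfg, i)$truth)
  pooled <- pool_voxel_tables(tabs)
  adc <- pooled$adc[pooled$included]
  g <- adcrev:::config_adc_mass(cfg)
  for (t in cfg$lesion_adc_knots$threshold) {
    expected <- sum(g$mass[g$adc < t])
    observed <- mean(adc < t)
    se <- sqrt(expected * (1 - expected) / length(adc))
    expect_lt(abs(observed - expected), 3 * se + 1e-9)
  }
})

test_that("the configured class-conditional ADC means sit near the reference values", {
  g <- adcrev:::config_observed_curve(synth_config())
  P <- sum(g$mass * g$p)
  mean_rev <- sum(g$adc * g$mass * g$p) / P
  mean_unc <- sum(g$adc * g$mass * (1 - g$p)) / (1 - P)
  ref <- reference_summary()
  expect_lt(abs(mean_rev - ref$adc_mean_reversed), 15)
  expect_lt(abs(mean_unc - ref$adc_mean_unchanged), 15)
})

test_that("analytic AUC handles flat, step and degenerate curves", {
  ref <- reference_sweep()
  flat <- small_config(reversal_knots = data.frame(threshold = ref$threshold,
                                                   prob_pct = 50),
                       haemorrhage_probability = 0)
  expect_equal(analytic_auc(flat), 0.5, tolerance = 1e-12)

  step <- small_config(reversal_knots = data.frame(threshold = c(250, 554, 555, 750),
                                                   prob_pct = c(0, 0, 100, 100)),
                       haemorrhage_probability = 0)
  expect_equal(analytic_auc(step), 1, tolerance = 1e-12)

  zero <- small_config(reversal_knots = data.frame(threshold = ref$threshold,
                                                   prob_pct = 0),
                       haemorrhage_probability = 0)
  expect_error(analytic_auc(zero), "degenerate")

  # default calibrated configuration implies an AUC near 0.71
  expect_lt(abs(analytic_auc(synth_config()) - 0.708), 0.01)
})

test_that("config validation and lesion geometry errors fire", {
  ref <- reference_sweep()
  expect_error(synth_config(lesion_adc_knots = data.frame(
    threshold = c(300, 400), cum_pct = c(50, 40))), "strictly increasing")
  expect_error(synth_config(reversal_knots = data.frame(
    threshold = c(300, 400), prob_pct = c(-5, 50))), "\\[0, 100\\]")
  tiny_grid <- synth_config(grid_shape = c(10, 10, 4),
                            lesion_radius_range = c(20, 20))
  expect_error(generate_patient(tiny_grid, 1), "does not fit")
})

test_that("cohort generation writes a complete, reproducible bundle", {
  cfg <- small_config(seed = 55)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_cohort(cfg, 2, d1)
  generate_cohort(cfg, 2, d2)
  expect_true(file.exists(file.path(d1, "metadata.tsv")))
  expect_true(file.exists(file.path(d1, "ground_truth.tsv")))
  expect_true(file.exists(file.path(d1, "config.json")))
  expect_true(file.exists(file.path(d1, "p001_adc.nii.gz")))
  expect_identical(readLines(file.path(d1, "metadata.tsv")),
                   readLines(file.path(d2, "metadata.tsv")))
  expect_identical(readLines(file.path(d1, "ground_truth.tsv")),
                   readLines(file.path(d2, "ground_truth.tsv")))
  v1 <- read_volume(file.path(d1, "p001_adc.nii.gz"), "adc")
  v2 <- read_volume(file.path(d2, "p001_adc.nii.gz"), "adc")
  expect_identical(v1$data, v2$data)
  # ground truth agrees with classifying the written volumes
  pre <- read_volume(file.path(d1, "p001_pre.nii.gz"), "mask")
  post <- read_volume(file.path(d1, "p001_post.nii.gz"), "mask")
  hp <- file.path(d1, "p001_haem.nii.gz")
  haem <- if (file.exists(hp)) read_volume(hp, "mask") else NULL
  tab <- classify_voxels(v1, pre, post, haem, patient_id = "p001")
  truth <- read_voxel_table(file.path(d1, "ground_truth.tsv"))
  truth1 <- truth[truth$patient_id == "p001", ]
  expect_equal(tab$fate, truth1$fate)
  expect_equal(tab$adc, truth1$adc)
})

test_that("planted eligibility violations reproduce the documented flow", {
  cfg <- small_config(seed = 56)
  d <- withr::local_tempdir()
  out <- generate_cohort(cfg, 24, d, with_exclusions = TRUE)
  plan <- exclusion_plan(24)
  fl <- flow_summary(out$metadata)
  expect_identical(unname(fl$surviving), plan$surviving)
  expect_equal(fl$n_included, sum(plan$fail_stage == 0L))
  # stage-5 violators have genuinely sub-1-mL lesions on the image
  small_ids <- out$metadata$patient_id[plan$fail_stage == 5L]
  expect_true(all(out$metadata$pre_lesion_ml[
    out$metadata$patient_id %in% small_ids] < 1))
})
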