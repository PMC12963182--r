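two_class_voxels <- function(adc_rev, adc_unc, patient_id_rev = "p1",
                             patient_id_unc = "p1") {
  mk_voxels(c(adc_rev, adc_unc),
            c(rep("reversed", length(adc_rev)), rep("unchanged", length(adc_unc))),
            patient_id = c(rep_len(patient_id_rev, length(adc_rev)),
                           rep_len(patient_id_unc, length(adc_unc))))
}

test_that("sensitivity/specificity orientation: test-positive is adc >= t", {
  v <- two_class_voxels(c(600, 700), c(400, 500))
  expect_equal(unname(sensitivity_specificity(v, 200)), c(100, 0))
  expect_equal(unname(sensitivity_specificity(v, 761)), c(0, 100))
  expect_equal(unname(sensitivity_specificity(v, 555)), c(100, 100))
  one_class <- mk_voxels(c(500, 600), c("reversed", "reversed"))
  expect_error(sensitivity_specificity(one_class, 500),
               class = "adcrev_degenerate_error")
})

test_that("sweep columns are exact on a fully reversed single-value table", {
  v <- mk_voxels(rep(500, 10), rep("reversed", 10))
  row <- sweep_thresholds(v, thresholds = 750)
  expect_equal(row$lesion_pct_below, 100)
  expect_equal(row$reversed_pct_below, 100)
  expect_equal(row$proportion_r_below, 100)
  # nothing below 250: proportion undefined, not zero
  row0 <- sweep_thresholds(v, thresholds = 250)
  expect_true(is.na(row0$proportion_r_below))
})

test_that("sweep invariants hold on random pooled tables", {
  set.seed(21)
  for (r in 1:4) {
    n <- 400
    adc <- round(runif(n, 200, 760))
    fate <- ifelse(runif(n) < plogis((adc - 550) / 80), "reversed", "unchanged")
    if (length(unique(fate)) < 2) next
    v <- mk_voxels(adc, fate)
    sw <- sweep_thresholds(v)
    expect_true(all(diff(sw$lesion_ml_below) >= 0))
    expect_true(all(diff(sw$sensitivity) <= 1e-12))
    expect_true(all(diff(sw$specificity) >= -1e-12))
    # strict-below convention makes this identity exact on pooled data
    expect_equal(sw$sensitivity + sw$reversed_pct_below, rep(100, nrow(sw)))
    expect_equal(sw$youden_j, sw$sensitivity + sw$specificity - 100)
  }
})

test_that("proportion of reversal below threshold reproduces printed volume ratios", {
  ref <- reference_sweep()
  r750 <- ref[ref$threshold == 750, ]
  expect_equal(100 * r750$reversed_ml_below / r750$lesion_ml_below,
               37.03, tolerance = 0.02 / 37.03)
  r620 <- ref[ref$threshold == 620, ]
  expect_lt(abs(100 * r620$reversed_ml_below / r620$lesion_ml_below - 27.96),
            0.02)
})

test_that("auc_trapezoid integrates canonical curves and validates input", {
  expect_equal(auc_trapezoid(data.frame(fpr = c(0, 1), tpr = c(0, 1))), 0.5)
  expect_equal(auc_trapezoid(data.frame(fpr = c(0, 0, 1), tpr = c(0, 1, 1))), 1)
  expect_error(auc_trapezoid(data.frame(fpr = c(0, 0.7, 0.3, 1),
                                        tpr = c(0, 1, 0.5, 1))), "sorted")
  expect_error(auc_trapezoid(data.frame(fpr = c(0.2, 1), tpr = c(0, 1))), "span")
})

test_that("empirical ROC AUC equals the brute-force Mann-Whitney pair statistic", {
  set.seed(22)
  for (r in 1:6) {
    n_r <- sample(5:250, 1); n_u <- sample(5:250, 1)
    adc_r <- round(runif(n_r, 200, 760))
    adc_u <- round(runif(n_u, 200, 760))
    v <- two_class_voxels(adc_r, adc_u)
    roc <- adc_roc(v)
    expect_equal(roc$auc, mw_pair_statistic(adc_r, adc_u), tolerance = 1e-12)
  }
})

test_that("AUC is ~0.5 for identical class distributions and 1 for separated ones", {
  set.seed(23)
  adc_all <- round(runif(4000, 250, 700))
  v_null <- two_class_voxels(adc_all[1:2000], adc_all[2001:4000])
  expect_lt(abs(adc_roc(v_null)$auc - 0.5), 0.03)
  v_sep <- two_class_voxels(round(runif(200, 600, 760)),
                            round(runif(200, 200, 500)))
  expect_equal(adc_roc(v_sep)$auc, 1)
})

test_that("ROC output matches an established ROC implementation", {
  library(pROC)
  set.seed(24)
  adc_r <- round(runif(300, 350, 760)); adc_u <- round(runif(400, 200, 650))
  v <- two_class_voxels(adc_r, adc_u)
  ours <- adc_roc(v)
  ref <- pROC::roc(response = c(rep(1, 300), rep(0, 400)),
                   predictor = c(adc_r, adc_u), quiet = TRUE,
                   direction = "<")
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-9)
})

test_that("youden_optimal maximises J and breaks ties toward the lower threshold", {
  one <- data.frame(threshold = 500, sensitivity = 70, specificity = 60)
  expect_equal(youden_optimal(one), 500)
  expect_equal(youden_optimal(reference_sweep()), 555)
  tie <- data.frame(threshold = c(600, 500),
                    sensitivity = c(60, 70), specificity = c(70, 60))
  expect_equal(youden_optimal(tie), 500)
  expect_error(youden_optimal(data.frame()), "empty")
})

test_that("band probability counts reversed voxels inside a closed band", {
  only_rev <- mk_voxels(rep(520, 5), rep("reversed", 5))
  expect_equal(band_probability(only_rev, 520), 100)
  v <- mk_voxels(c(rep(500, 3), rep(505, 7)),
                 c(rep("reversed", 3), rep("unchanged", 7)))
  expect_equal(band_probability(v, 500), 30)
  expect_equal(band_probability(v, 500, mode = "per_patient_mean"), 30)
  # closed interval: voxel at exactly center + halfwidth is in
  edge <- mk_voxels(c(510, 530), c("reversed", "unchanged"))
  expect_equal(band_probability(edge, 520, halfwidth = 10), 50)
  expect_true(is.na(band_probability(v, 700)))
})

test_that("per-patient mean skips patients with no voxels in the band", {
  v <- mk_voxels(c(500, 500, 700), c("reversed", "unchanged", "unchanged"),
                 patient_id = c("a", "a", "b"))
  expect_equal(band_probability(v, 500, mode = "per_patient_mean"), 50)
  expect_equal(band_probability(v, 700, mode = "per_patient_mean"), 0)
})

test_that("a flat configured reversal curve is recovered at every band", {
  ref <- reference_sweep()
  cfg <- small_config(seed = 31,
                      reversal_knots = data.frame(threshold = ref$threshold,
                                                  prob_pct = 40),
                      haemorrhage_probability = 0)
  tabs <- lapply(1:6, function(i) generate_patient(cfg, i)$truth)
  pooled <- pool_voxel_tables(tabs)
  bc <- band_curve(pooled, centers = seq(400, 700, by = 100))
  for (i in seq_len(nrow(bc))) {
    se <- sqrt(0.4 * 0.6 / bc$n_voxels[i])
    expect_lt(abs(bc$pooled_pct[i] - 40), 100 * 3 * se + 1e-9)
  }
})

test_that("subgroup filtering is identity/empty at the predicate extremes", {
  v <- mk_voxels(c(500, 600, 550), c("reversed", "unchanged", "reversed"),
                 patient_id = c("a", "a", "b"))
  md <- data.frame(patient_id = c("a", "b"), mtici = c("3", "2c"),
                   occlusion_type = c("LVO", "LVO"),
                   time_mri_to_recan_min = c(80, 80))
  all_in <- subgroup_voxels(v, md, function(m) rep(TRUE, nrow(m)))
  expect_equal(as.data.frame(all_in), as.data.frame(v))
  none <- subgroup_voxels(v, md, function(m) rep(FALSE, nrow(m)))
  expect_equal(nrow(none), 0L)
  expect_error(sweep_thresholds(none), class = "adcrev_degenerate_error")
  expect_error(subgroup_voxels(v, md[1, ], function(m) rep(TRUE, nrow(m))),
               "missing from metadata")
  fast <- subgroup_voxels(v, md, subgroup_anterior_fast)
  expect_setequal(unique(fast$patient_id), "a")
})

test_that("the canonical subgroup selects 20 of 71 synthetic patients", {
  md <- synthetic_metadata(71, seed = 5)
  expect_equal(sum(subgroup_anterior_fast(md)), 20)
  expect_equal(sum(md$mtici == "3"), 34)
  expect_equal(sum(md$occlusion_type == "posterior"), 5)
})
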