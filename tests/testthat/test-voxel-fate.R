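test_that("identical pre and post masks give zero reversal", {
  adc <- mk_adc(c(300, 400, 500, 600))
  pre <- mk_mask(c(1, 1, 1, 1))
  tab <- classify_voxels(adc, pre, pre)
  expect_true(all(tab$fate == "unchanged"))
  expect_equal(reversal_volume_ml(tab), 0)
})

test_that("an empty post mask reverses every in-window voxel", {
  adc <- mk_adc(c(300, 400, 500, 600))
  pre <- mk_mask(c(1, 1, 1, 1))
  post <- mk_mask(c(0, 0, 0, 0))
  tab <- classify_voxels(adc, pre, post)
  expect_true(all(tab$fate == "reversed"))
  expect_true(all(tab$included))
  expect_equal(reversal_fraction(tab), 1)
})

test_that("the three-voxel worked example classifies and windows as specified", {
  adc <- mk_adc(c(150, 500, 800))
  pre <- mk_mask(c(1, 1, 1))
  post <- mk_mask(c(0, 1, 0))
  tab <- classify_voxels(adc, pre, post)
  expect_identical(tab$fate, c("reversed", "unchanged", "reversed"))
  expect_identical(tab$included, c(FALSE, TRUE, FALSE))
  expect_identical(tab$exclusion_reason,
                   c("adc_below_min", "none", "adc_above_max"))
  # the only included voxel is unchanged
  expect_equal(reversal_fraction(tab), 0)
})

test_that("the ADC window is closed at both ends", {
  adc <- mk_adc(c(199, 200, 760, 761))
  pre <- mk_mask(rep(1, 4))
  post <- mk_mask(rep(0, 4))
  tab <- classify_voxels(adc, pre, post)
  expect_identical(tab$included, c(FALSE, TRUE, TRUE, FALSE))
})

test_that("growth voxels (post only) are not scored and empty pre is an error", {
  adc <- mk_adc(c(500, 500, 500))
  pre <- mk_mask(c(1, 1, 0))
  post <- mk_mask(c(1, 1, 1))
  tab <- classify_voxels(adc, pre, post)
  expect_equal(nrow(tab), 2L)
  expect_error(classify_voxels(adc, mk_mask(c(0, 0, 0)), post),
               class = "adcrev_empty_lesion_error")
  expect_error(classify_voxels(adc, pre, mk_mask(c(0, 0))),
               class = "adcrev_grid_error")
})

test_that("haemorrhage voxels count as persistent: classify(pre, post, h) == classify(pre, post | h)", {
  set.seed(11)
  for (r in 1:5) {
    d <- c(6, 5, 3)
    adc <- adc_volume(array(round(runif(prod(d), 100, 900)), d), c(1, 1, 1), "adc")
    pre_arr <- random_mask_array(d, 0.6)
    if (!any(pre_arr > 0)) pre_arr[1] <- 1L
    pre <- adc_volume(pre_arr, c(1, 1, 1), "mask")
    post <- adc_volume(random_mask_array(d, 0.3), c(1, 1, 1), "mask")
    h <- adc_volume(random_mask_array(d, 0.2), c(1, 1, 1), "mask")
    union <- adc_volume(array(as.integer(post$data | h$data), d), c(1, 1, 1), "mask")
    expect_identical(as.data.frame(classify_voxels(adc, pre, post, h)),
                     as.data.frame(classify_voxels(adc, pre, union)))
  }
})

test_that("every pre voxel is scored exactly once and classes partition", {
  set.seed(12)
  for (r in 1:5) {
    d <- c(7, 6, 4)
    adc <- adc_volume(array(round(runif(prod(d), 100, 900)), d), c(1, 1, 1), "adc")
    pre_arr <- random_mask_array(d, 0.5)
    if (!any(pre_arr > 0)) pre_arr[1] <- 1L
    pre <- adc_volume(pre_arr, c(1, 1, 1), "mask")
    post <- adc_volume(random_mask_array(d, 0.4), c(1, 1, 1), "mask")
    tab <- classify_voxels(adc, pre, post)
    expect_equal(nrow(tab), sum(pre$data))
    expect_false(any(duplicated(tab[, c("i", "j", "k")])))
    expect_equal(sum(tab$included) + sum(!tab$included), nrow(tab))
    expect_identical(tab$included, tab$exclusion_reason == "none")
    expect_equal(sum(tab$fate == "reversed") + sum(tab$fate == "unchanged"),
                 nrow(tab))
  }
})

test_that("enlarging the post mask never increases reversal volume", {
  set.seed(13)
  d <- c(8, 8, 3)
  adc <- adc_volume(array(round(runif(prod(d), 200, 760)), d), c(1, 1, 1), "adc")
  pre <- adc_volume(array(1L, d), c(1, 1, 1), "mask")
  post_small <- random_mask_array(d, 0.3)
  grow <- post_small | random_mask_array(d, 0.3)
  v_small <- reversal_volume_ml(classify_voxels(adc, pre,
    adc_volume(post_small, c(1, 1, 1), "mask")))
  v_big <- reversal_volume_ml(classify_voxels(adc, pre,
    adc_volume(array(as.integer(grow), d), c(1, 1, 1), "mask")))
  expect_lte(v_big, v_small)
})

test_that("the 1 mL lesion gate sits exactly at the voxel arithmetic boundary", {
  sp <- c(0.6, 0.6, 6.5)
  mk <- function(n) mk_voxels(rep(500, n), rep("unchanged", n), spacing = sp)
  expect_false(qc_min_lesion(mk(427)))  # 0.99918 mL
  expect_true(qc_min_lesion(mk(428)))   # 1.00152 mL
  empty <- mk(1)[0, ]
  empty <- adcrev:::as_voxel_table(empty, spacing = sp)
  expect_false(qc_min_lesion(empty))
  # the gate uses the raw pre-mask, before ADC exclusion
  out_of_window <- mk_voxels(rep(900, 428), rep("unchanged", 428), spacing = sp)
  expect_true(qc_min_lesion(out_of_window))
})

test_that("voxel tables survive a TSV round trip", {
  tmp <- withr::local_tempdir()
  tab <- mk_voxels(c(150, 500, 800), c("reversed", "unchanged", "reversed"),
                   spacing = c(0.6, 0.6, 6.5))
  p <- file.path(tmp, "voxels.tsv")
  write_voxel_table(tab, p)
  back <- read_voxel_table(p)
  expect_equal(as.data.frame(back), as.data.frame(tab))
  expect_equal(attr(back, "spacing"), attr(tab, "spacing"))
})

test_that("reversal volumes and fractions use included voxels only", {
  tab <- mk_voxels(c(150, 500, 600, 800),
                   c("reversed", "reversed", "unchanged", "reversed"))
  expect_equal(reversal_fraction(tab), 0.5)
  expect_equal(reversal_volume_ml(tab), 1 / 1000)  # one included reversed voxel
  none <- mk_voxels(c(100, 900), c("reversed", "reversed"))
  expect_error(reversal_fraction(none), class = "adcrev_degenerate_error")
})
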