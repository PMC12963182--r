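#' Configuration of the synthetic stroke-cohort generator
#'
#' The generator emulates the statistical structure that the voxel-fate
#' analysis assumes, so the whole pipeline is testable without patient data:
#' a two-compartment GM/WM background (grey matter higher ADC than white), an
#' ellipsoidal baseline lesion whose included-voxel ADC marginal follows a
#' tabulated cumulative distribution, voxel-wise reversal drawn independently
#' with a probability that rises with ADC along a tabulated curve, optional
#' haemorrhagic-transformation blobs forced into the post-treatment mask, and
#' optional in-plane registration jitter.
#'
#' Defaults are calibrated to the published reference cohort
#' ([reference_sweep()]): the lesion ADC marginal interpolates the cumulative
#' lesion-volume fractions at the 14 reference thresholds, and the reversal
#' curve interpolates the reference per-band reversal probabilities (constant
#' beyond the first/last knot, clamped to \[0, 1\]). Under these defaults the
#' implied pooled reversal fraction is about 0.37 and the implied AUC of ADC
#' for reversal about 0.71.
#'
#' @param grid_shape integer 3-vector, voxels per axis.
#' @param spacing voxel size in mm (default the reference acquisition,
#'   0.6 x 0.6 x 6.5).
#' @param gm_adc_mean,wm_adc_mean normal-tissue ADC means (1e-6 mm^2/s).
#' @param noise_sd Gaussian noise SD applied to background tissue before
#'   integer rounding. Lesion voxels are drawn directly from the tabulated
#'   marginal (which already describes the observed, noisy distribution), so
#'   the calibration knots stay exact.
#' @param lesion_radius_range in-plane ellipsoid semi-axis range (voxels).
#' @param lesion_z_radius_range through-plane semi-axis range (voxels); kept
#'   separate because slice spacing is ~11x the in-plane spacing.
#' @param lesion_adc_knots data.frame `threshold`, `cum_pct`: cumulative
#'   percentage of included lesion voxels with ADC strictly below each
#'   threshold; strictly increasing.
#' @param reversal_knots data.frame `threshold`, `prob_pct`: reversal
#'   probability (percent) for voxels at each ADC knot.
#' @param frac_below_window,frac_above_window fractions of lesion voxels
#'   given ADC below 200 (segmentation artifacts) / above 760 (partial
#'   volume), exercising the exclusion rules.
#' @param haemorrhage_probability per-patient probability of a
#'   haemorrhagic-transformation blob.
#' @param haemorrhage_radius_frac haemorrhage ellipsoid semi-axes as a
#'   fraction of the lesion's (blob kept fully inside the lesion, so its
#'   expected volume fraction is this value cubed).
#' @param registration_jitter_voxels integer in-plane translation applied to
#'   the post mask (default 0 = perfect co-registration).
#' @param seed base RNG seed; each patient derives a sub-seed from it.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(grid_shape = c(96, 96, 16),
                         spacing = c(0.6, 0.6, 6.5),
                         gm_adc_mean = 800, wm_adc_mean = 700, noise_sd = 30,
                         lesion_radius_range = c(8, 32),
                         lesion_z_radius_range = c(2, 6),
                         lesion_adc_knots = NULL, reversal_knots = NULL,
                         frac_below_window = 0.01, frac_above_window = 0.03,
                         haemorrhage_probability = 0.56,
                         haemorrhage_radius_frac = 0.3,
                         registration_jitter_voxels = 0L,
                         seed = 1L) {
  ref <- reference_sweep()
  if (is.null(lesion_adc_knots))
    lesion_adc_knots <- data.frame(threshold = ref$threshold,
                                   cum_pct = ref$lesion_pct_below)
  if (is.null(reversal_knots))
    reversal_knots <- data.frame(threshold = ref$threshold,
                                 prob_pct = ref$band_probability)
  if (any(diff(lesion_adc_knots$cum_pct) <= 0) ||
      any(lesion_adc_knots$cum_pct <= 0) || any(lesion_adc_knots$cum_pct >= 100))
    stop("lesion ADC cumulative fractions must be strictly increasing within (0, 100)",
         call. = FALSE)
  if (any(reversal_knots$prob_pct < 0) || any(reversal_knots$prob_pct > 100))
    stop("reversal curve values must lie in [0, 100] percent", call. = FALSE)
  cfg <- list(grid_shape = as.integer(grid_shape), spacing = as.numeric(spacing),
              gm_adc_mean = gm_adc_mean, wm_adc_mean = wm_adc_mean,
              noise_sd = noise_sd,
              lesion_radius_range = lesion_radius_range,
              lesion_z_radius_range = lesion_z_radius_range,
              lesion_adc_knots = lesion_adc_knots,
              reversal_knots = reversal_knots,
              frac_below_window = frac_below_window,
              frac_above_window = frac_above_window,
              haemorrhage_probability = haemorrhage_probability,
              haemorrhage_radius_frac = haemorrhage_radius_frac,
              registration_jitter_voxels = as.integer(registration_jitter_voxels),
              adc_window = c(200, 760),
              seed = as.integer(seed))
  class(cfg) <- "synth_config"
  cfg
}

# piecewise-linear CDF of the included-lesion ADC marginal, on [200, 760]
lesion_cdf_knots <- function(config) {
  w <- config$adc_window
  list(x = c(w[1], config$lesion_adc_knots$threshold, w[2]),
       y = c(0, config$lesion_adc_knots$cum_pct / 100, 1))
}

sample_lesion_adc <- function(config, n) {
  k <- lesion_cdf_knots(config)
  u <- stats::runif(n)
  floor(stats::approx(k$y, k$x, xout = u, ties = "ordered")$y + 0.5)
}

#' Conditional reversal probability of the configured model
#'
#' Evaluates the generator's reversal curve p(reversal | ADC): linear
#' interpolation between the configured knots, constant beyond the ends,
#' clamped to \[0, 1\].
#'
#' @param config a [synth_config()].
#' @param adc ADC values (1e-6 mm^2/s).
#' @return probabilities in `[0, 1]`.
#' @export
reversal_probability <- function(config, adc) {
  p <- stats::approx(config$reversal_knots$threshold,
                     config$reversal_knots$prob_pct / 100,
                     xout = adc, rule = 2)$y
  pmin(pmax(p, 0), 1)
}

ellipsoid_mask <- function(shape, center, radii) {
  i <- seq_len(shape[1]); j <- seq_len(shape[2]); k <- seq_len(shape[3])
  di <- ((i - center[1]) / radii[1])^2
  dj <- ((j - center[2]) / radii[2])^2
  dk <- ((k - center[3]) / radii[3])^2
  arr <- outer(outer(di, dj, `+`), dk, `+`)
  array(as.integer(arr <= 1), shape)
}

patient_subseed <- function(config, patient_seed) {
  as.integer((as.numeric(config$seed) * 100003 + as.numeric(patient_seed) * 7919) %%
               2147483647)
}

#' Generate one synthetic patient
#'
#' Builds the full per-patient imaging bundle: GM/WM background ADC map with
#' an embedded ellipsoidal lesion whose ADC follows the configured marginal,
#' a pre-treatment lesion mask, voxel-wise true fates drawn from the
#' configured reversal curve, an optional haemorrhage blob (its voxels forced
#' to persist), the resulting post-treatment mask, and the ground-truth voxel
#' table. Fully reproducible from `(config$seed, patient_seed)`.
#'
#' @param config a [synth_config()].
#' @param patient_seed integer sub-seed (e.g. the patient index).
#' @param patient_id identifier; defaults to `sprintf("p%03d", patient_seed)`.
#' @param tiny_lesion if `TRUE`, generate a sub-1-mL lesion (used to exercise
#'   the minimum-lesion quality gate).
#' @return list: `adc`, `pre`, `post`, `haemorrhage` ([adc_volume] or `NULL`),
#'   `truth` (a `voxel_table` of true fates), `pre_lesion_ml`.
#' @export
generate_patient <- function(config, patient_seed,
                             patient_id = sprintf("p%03d", patient_seed),
                             tiny_lesion = FALSE) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(patient_subseed(config, patient_seed))
  shape <- config$grid_shape
  n_vox <- prod(shape)

  # background: central white-matter ellipsoid inside grey matter
  wm <- ellipsoid_mask(shape, center = shape / 2, radii = shape * 0.6)
  bg_mean <- ifelse(wm > 0, config$wm_adc_mean, config$gm_adc_mean)
  adc_arr <- floor(bg_mean + stats::rnorm(n_vox, 0, config$noise_sd) + 0.5)
  adc_arr[adc_arr < 0] <- 0
  adc_arr <- array(adc_arr, shape)

  # lesion geometry
  rr <- if (tiny_lesion) c(2, 4) else config$lesion_radius_range
  zr <- if (tiny_lesion) c(1, 1) else config$lesion_z_radius_range
  radii <- c(stats::runif(2, rr[1], rr[2]), stats::runif(1, zr[1], zr[2]))
  if (any(2 * radii + 2 > shape))
    stop("lesion does not fit inside the grid: radii (",
         paste(round(radii, 1), collapse = ", "), ") vs shape (",
         paste(shape, collapse = ", "), ")", call. = FALSE)
  center <- vapply(1:3, function(d)
    stats::runif(1, radii[d] + 1, shape[d] - radii[d]), numeric(1))
  pre_arr <- ellipsoid_mask(shape, center, radii)
  idx <- which(pre_arr > 0)
  n_les <- length(idx)

  # lesion ADC: calibrated marginal inside the window, plus artifact tails
  les_adc <- sample_lesion_adc(config, n_les)
  u_tail <- stats::runif(n_les)
  low <- u_tail < config$frac_below_window
  high <- u_tail > 1 - config$frac_above_window
  les_adc[low] <- floor(stats::runif(sum(low), 120, 200))
  les_adc[high] <- floor(stats::runif(sum(high), 761, 1100))
  adc_arr[idx] <- les_adc

  # voxel-wise true fate
  reversed <- stats::runif(n_les) < reversal_probability(config, les_adc)

  # haemorrhagic transformation: blob kept fully inside the lesion
  haem_arr <- NULL
  if (stats::runif(1) < config$haemorrhage_probability) {
    hf <- config$haemorrhage_radius_frac
    # offset within (1 - hf) of the lesion radii keeps the blob inside
    repeat {
      off <- stats::runif(3, -1, 1)
      if (sum(off^2) <= 1) break
    }
    hc <- center + off * (1 - hf) * radii
    haem_arr <- ellipsoid_mask(shape, hc, hf * radii) & pre_arr
    haem_arr <- array(as.integer(haem_arr), shape)
  }

  post_arr <- array(0L, shape)
  post_arr[idx[!reversed]] <- 1L
  if (!is.null(haem_arr)) post_arr[haem_arr > 0] <- 1L

  jit <- config$registration_jitter_voxels
  if (jit > 0) {
    sh <- sample(seq(-jit, jit), 2, replace = TRUE)
    post_arr <- shift_xy(post_arr, sh[1], sh[2])
  }

  ai <- arrayInd(idx, shape)
  persist <- post_arr[idx] > 0
  w <- config$adc_window
  reason <- rep("none", n_les)
  reason[les_adc < w[1]] <- "adc_below_min"
  reason[les_adc > w[2]] <- "adc_above_max"
  truth <- as_voxel_table(data.frame(
    patient_id = rep(patient_id, n_les),
    i = ai[, 1] - 1L, j = ai[, 2] - 1L, k = ai[, 3] - 1L,
    adc = as.numeric(les_adc),
    fate = ifelse(persist, "unchanged", "reversed"),
    included = reason == "none",
    exclusion_reason = reason,
    stringsAsFactors = FALSE), spacing = config$spacing)

  sp <- config$spacing
  list(adc = adc_volume(adc_arr, sp, "adc"),
       pre = adc_volume(pre_arr, sp, "mask"),
       post = adc_volume(post_arr, sp, "mask"),
       haemorrhage = if (is.null(haem_arr)) NULL else adc_volume(haem_arr, sp, "mask"),
       truth = truth,
       pre_lesion_ml = voxels_to_ml(n_les, sp))
}

shift_xy <- function(arr, dx, dy) {
  out <- array(0L, dim(arr))
  d <- dim(arr)
  xs <- seq_len(d[1]); ys <- seq_len(d[2])
  xt <- xs + dx; yt <- ys + dy
  okx <- xt >= 1 & xt <= d[1]; oky <- yt >= 1 & yt <= d[2]
  out[xt[okx], yt[oky], ] <- arr[xs[okx], ys[oky], ]
  out
}

#' Synthetic clinical metadata for a cohort
#'
#' Draws per-patient clinical attributes with the reference cohort's mix:
#' about 48/71 LVO, 18/71 anterior MeVO and 5/71 posterior occlusions, 34/71
#' complete (mTICI 3) recanalization, and recanalization delays with median
#' near 84 min. Allocation is stratified so that for `n = 71` exactly 20
#' patients fall in the canonical subgroup (anterior occlusion, mTICI 3,
#' recanalization within 90 min); other `n` scale proportionally. All
#' eligibility fields default to passing.
#'
#' @param n number of patients.
#' @param seed RNG seed.
#' @param ids patient identifiers (default `p001`, `p002`, ...).
#' @return data.frame of patient records (without `pre_lesion_ml`, which
#'   comes from the generated images).
#' @export
synthetic_metadata <- function(n, seed = 1, ids = sprintf("p%03d", seq_len(n))) {
  set.seed(seed)
  n_post <- round(5 / 71 * n)     # posterior circulation
  n_m3 <- round(34 / 71 * n)      # mTICI 3
  n_sub <- min(round(20 / 71 * n), n_m3)  # canonical subgroup members
  perm <- sample.int(n)
  posterior <- rep(FALSE, n); posterior[perm[seq_len(n_post)]] <- TRUE
  anterior_ids <- perm[!perm %in% perm[seq_len(n_post)]]
  sub <- rep(FALSE, n); sub[anterior_ids[seq_len(n_sub)]] <- TRUE
  m3 <- sub
  pool <- setdiff(perm, which(sub))
  extra_m3 <- utils::head(pool, max(0, n_m3 - n_sub))
  m3[extra_m3] <- TRUE
  occl <- ifelse(posterior, "posterior",
                 ifelse(stats::runif(n) < 48 / 66, "LVO", "MeVO"))
  time_min <- round(pmin(pmax(stats::rnorm(n, 84, 17), 30), 119))
  time_min[sub] <- round(stats::runif(sum(sub), 55, 90))
  # anterior mTICI-3 patients outside the subgroup must exceed the 90-min cut
  slow <- m3 & !posterior & !sub
  time_min[slow] <- round(stats::runif(sum(slow), 91, 119))
  data.frame(
    patient_id = ids,
    has_pre_mri = TRUE, has_post_mri_12_36h = TRUE,
    mtici = ifelse(m3, "3", "2c"),
    same_scanner_sequence = TRUE, image_quality_ok = TRUE,
    reocclusion = FALSE,
    time_mri_to_recan_min = time_min,
    occlusion_type = occl,
    age = round(pmin(pmax(stats::rnorm(n, 71, 12), 25), 95)),
    sex = ifelse(stats::runif(n) < 0.437, "M", "F"),
    nihss = round(pmin(pmax(stats::rlnorm(n, log(12), 0.5), 1), 38)),
    thrombolysis = stats::runif(n) < 0.69,
    stringsAsFactors = FALSE)
}

#' Failure-stage plan of the `with_exclusions` fixture
#'
#' With exclusions enabled, [generate_cohort()] assigns eligibility failures
#' deterministically by patient index: index `i` fails eligibility stage
#' `i %% 8` (stages 1-7), and indices with `i %% 8 == 0` are fully eligible.
#' This helper returns the implied flow-diagram counts for `n` patients, used
#' as the constructed truth in tests.
#'
#' @param n cohort size.
#' @return list: `fail_stage` (integer vector, 0 = eligible) and `surviving`
#'   (counts after each of the 7 stages).
#' @export
exclusion_plan <- function(n) {
  fail <- seq_len(n) %% 8L
  surv <- vapply(1:7, function(s) sum(fail == 0L | fail > s), integer(1))
  list(fail_stage = fail, surviving = surv)
}

#' Generate and write a synthetic cohort
#'
#' Generates `n_patients` independent synthetic patients (see
#' [generate_patient()]) and writes them to `dir` as NIfTI volumes
#' (`<id>_adc`, `<id>_pre`, `<id>_post`, and `<id>_haem` when present), a
#' `metadata.tsv` eligibility/clinical table, a pooled `ground_truth.tsv`
#' voxel table, and a `config.json` echo of every generator parameter.
#'
#' With `with_exclusions = TRUE` a documented subset of records violates each
#' eligibility rule (see [exclusion_plan()]); stage-5 violators get genuinely
#' sub-1-mL lesions so the image-level quality gate agrees with the metadata.
#'
#' @param config a [synth_config()].
#' @param n_patients cohort size.
#' @param dir output directory (created if needed).
#' @param seed metadata RNG seed; defaults to `config$seed`.
#' @param with_exclusions plant eligibility-rule violations.
#' @return invisibly, list: `dir`, `metadata`, `config`.
#' @export
generate_cohort <- function(config, n_patients, dir, seed = config$seed,
                            with_exclusions = FALSE) {
  stopifnot(inherits(config, "synth_config"), n_patients >= 1)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir, call. = FALSE)
  md <- synthetic_metadata(n_patients, seed = seed)
  plan <- if (with_exclusions) exclusion_plan(n_patients)$fail_stage
          else integer(n_patients)
  md$has_post_mri_12_36h[plan == 1L] <- FALSE
  md$mtici[plan == 2L] <- "2b"
  md$same_scanner_sequence[plan == 3L] <- FALSE
  md$image_quality_ok[plan == 4L] <- FALSE
  md$reocclusion[plan == 6L] <- TRUE
  md$time_mri_to_recan_min[plan == 7L] <- 150

  md$pre_lesion_ml <- NA_real_
  truth_path <- file.path(dir, "ground_truth.tsv")
  if (file.exists(truth_path)) file.remove(truth_path)
  truths <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    pid <- md$patient_id[i]
    b <- generate_patient(config, patient_seed = i, patient_id = pid,
                          tiny_lesion = plan[i] == 5L)
    md$pre_lesion_ml[i] <- b$pre_lesion_ml
    write_volume(b$adc, file.path(dir, paste0(pid, "_adc.nii.gz")))
    write_volume(b$pre, file.path(dir, paste0(pid, "_pre.nii.gz")))
    write_volume(b$post, file.path(dir, paste0(pid, "_post.nii.gz")))
    if (!is.null(b$haemorrhage))
      write_volume(b$haemorrhage, file.path(dir, paste0(pid, "_haem.nii.gz")))
    truths[[i]] <- b$truth
  }
  write_voxel_table(pool_voxel_tables(truths), truth_path)
  utils::write.table(md, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg_out <- config
  class(cfg_out) <- NULL
  jsonlite::write_json(cfg_out, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(list(dir = dir, metadata = md, config = config))
}

#' Eligibility-flow fixture cohort
#'
#' Constructs a deterministic cohort of records whose eligibility-failure
#' pattern reproduces the reference study's inclusion flow: 565 screened,
#' then 204, 146, 92, 77, 73 and finally 71 included after the successive
#' stages. Useful as a known-truth input for [flow_summary()].
#'
#' @param seed RNG seed for the shuffle of record order.
#' @return data.frame of patient records.
#' @export
synthetic_flow_cohort <- function(seed = 1) {
  counts_fail <- c(361, 58, 54, 15, 4, 2, 0)  # failures at stages 1..7
  n_inc <- 71
  fail_stage <- c(rep(1:7, counts_fail), rep(0L, n_inc))
  set.seed(seed)
  fail_stage <- sample(fail_stage)
  n <- length(fail_stage)
  md <- data.frame(
    patient_id = sprintf("f%03d", seq_len(n)),
    has_pre_mri = TRUE,
    has_post_mri_12_36h = fail_stage != 1L,
    mtici = ifelse(fail_stage == 2L, "2b", "2c"),
    same_scanner_sequence = fail_stage != 3L,
    image_quality_ok = fail_stage != 4L,
    pre_lesion_ml = ifelse(fail_stage == 5L, 0.6, 15),
    reocclusion = fail_stage == 6L,
    time_mri_to_recan_min = ifelse(fail_stage == 7L, 150, 84),
    occlusion_type = "LVO",
    stringsAsFactors = FALSE)
  md
}

# --- analytic oracles of the configured model -------------------------------

# probability mass of integer ADC values on the window, after rounding
config_adc_mass <- function(config) {
  k <- lesion_cdf_knots(config)
  w <- config$adc_window
  a <- seq(w[1], w[2])
  Fi <- stats::approxfun(k$x, k$y, rule = 2)
  m <- Fi(pmin(a + 0.5, w[2])) - Fi(pmax(a - 0.5, w[1]))
  list(adc = a, mass = m / sum(m))
}

# expected fraction of lesion voxels masked persistent by haemorrhage
haemorrhage_fraction <- function(config) {
  config$haemorrhage_probability * config$haemorrhage_radius_frac^3
}

# observed (haemorrhage-attenuated) reversal probability at integer ADC
config_observed_curve <- function(config) {
  g <- config_adc_mass(config)
  p <- reversal_probability(config, g$adc) * (1 - haemorrhage_fraction(config))
  list(adc = g$adc, mass = g$mass, p = p)
}

#' Analytic AUC implied by a generator configuration
#'
#' The AUC of baseline ADC as a classifier of voxel reversal that the
#' configured model implies: `P(ADC_reversed > ADC_unchanged) + 0.5 *
#' P(equal)`, computed by exact summation over the integer ADC grid using the
#' configured marginal and reversal curve (attenuated by the expected
#' haemorrhage fraction, which masks reversal independently of ADC). Serves
#' as the independent oracle for end-to-end parameter-recovery tests.
#'
#' @param config a [synth_config()].
#' @return AUC in `[0, 1]`.
#' @export
analytic_auc <- function(config) {
  g <- config_observed_curve(config)
  P <- sum(g$mass * g$p)
  if (P <= 0 || P >= 1)
    stop("degenerate reversal curve: AUC undefined", call. = FALSE)
  w1 <- g$mass * g$p / P
  w0 <- g$mass * (1 - g$p) / (1 - P)
  c0 <- cumsum(w0)
  sum(w1 * (c0 - w0 / 2))
}

#' @rdname analytic_auc
#' @export
analytic_reversal_fraction <- function(config) {
  g <- config_observed_curve(config)
  sum(g$mass * g$p)
}

#' Analytic band reversal probability of a configuration
#'
#' Expected value of the pooled [band_probability()] statistic under the
#' configured model: the mass-weighted mean of the observed reversal curve
#' over the closed ADC band.
#'
#' @param config a [synth_config()].
#' @param center band center(s).
#' @param halfwidth band halfwidth (default 10).
#' @return expected probabilities in percent.
#' @export
analytic_band_probability <- function(config, center, halfwidth = 10) {
  g <- config_observed_curve(config)
  vapply(center, function(c0) {
    inb <- g$adc >= c0 - halfwidth & g$adc <= c0 + halfwidth
    100 * sum(g$mass[inb] * g$p[inb]) / sum(g$mass[inb])
  }, numeric(1))
}

#' Analytic Youden-optimal threshold of a configuration
#'
#' Maximises the model-implied Youden J over a threshold grid (ties toward
#' the lower threshold).
#'
#' @param config a [synth_config()].
#' @param thresholds candidate thresholds (default the configured knots).
#' @return list: `threshold`, `j` (percentage points).
#' @export
analytic_youden <- function(config, thresholds = config$reversal_knots$threshold) {
  g <- config_observed_curve(config)
  P <- sum(g$mass * g$p)
  w1 <- g$mass * g$p / P
  w0 <- g$mass * (1 - g$p) / (1 - P)
  thresholds <- sort(thresholds)
  j <- vapply(thresholds, function(t)
    sum(w1[g$adc >= t]) + sum(w0[g$adc < t]) - 1, numeric(1))
  list(threshold = thresholds[which.max(j)], j = 100 * max(j))
}
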