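#' Fit the ADC threshold model for voxel reversal
#'
#' The package's central estimator. Given a pooled voxel table (baseline-lesion
#' voxels with their baseline ADC and observed fate), it quantifies how well a
#' single ADC cutoff predicts reversal: the full empirical ROC over the ADC
#' window with trapezoidal AUC, the Youden-optimal threshold, a Table-style
#' threshold sweep, the per-band reversal-probability curve (pooled and
#' patient-averaged), and class-conditional ADC summaries.
#'
#' The headline AUC and optimal threshold pool all voxels from all patients
#' with equal weight; the patient-averaged band curve is also reported. An
#' optional patient-level bootstrap gives a confidence interval for the AUC
#' (resampling patients, with replacement, keeping all their voxels).
#'
#' @param voxels a `voxel_table` (see [classify_voxels()], [pool_voxel_tables()]).
#' @param thresholds sweep thresholds (default [reference_thresholds()]).
#' @param adc_range ADC window, default `c(200, 760)`.
#' @param band_halfwidth band halfwidth for probability curves (default 10).
#' @param band_centers centers of the band curve (default 350-750 by 10).
#' @param boot_reps patient-bootstrap replicates for the AUC CI (0 = skip;
#'   default 0 — use a few hundred or more for a stable interval).
#' @param boot_seed RNG seed for the bootstrap.
#' @return object of class `reversal_fit`: list with `roc` ([adc_roc()]
#'   result), `sweep`, `bands`, `optimal_threshold`, `auc`, `auc_ci` (or
#'   `NULL`), `reversal_fraction`, `adc_mean_reversed`, `adc_mean_unchanged`,
#'   `n_voxels`, `n_patients`, `call`, plus the training voxels.
#' @seealso [predict.reversal_fit()], [plot.reversal_fit()]
#' @examples
#' cfg <- synth_config(grid_shape = c(32, 32, 8), seed = 7)
#' tabs <- lapply(1:3, function(i) generate_patient(cfg, i)$truth)
#' fit <- reversal_fit(pool_voxel_tables(tabs))
#' coef(fit)
#' @export
reversal_fit <- function(voxels, thresholds = reference_thresholds(),
                         adc_range = c(200, 760), band_halfwidth = 10,
                         band_centers = seq(350, 750, by = 10),
                         boot_reps = 0, boot_seed = 1) {
  v <- included_voxels(voxels)
  check_both_classes(v)
  roc <- adc_roc(voxels, adc_min = adc_range[1], adc_max = adc_range[2])
  sw <- sweep_thresholds(voxels, thresholds, band_halfwidth)
  bands <- band_curve(voxels, band_centers, band_halfwidth)
  auc_ci <- NULL
  if (boot_reps > 0) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    set.seed(boot_seed)
    ids <- unique(v$patient_id)
    by_id <- split(seq_len(nrow(v)), v$patient_id)
    aucs <- vapply(seq_len(boot_reps), function(r) {
      take <- sample(ids, length(ids), replace = TRUE)
      vb <- v[unlist(by_id[take], use.names = FALSE), , drop = FALSE]
      vb <- as_voxel_table(vb, attr(voxels, "spacing"))
      if (!any(vb$fate == "reversed") || !any(vb$fate == "unchanged")) return(NA_real_)
      adc_roc(vb, adc_range[1], adc_range[2])$auc
    }, numeric(1))
    auc_ci <- stats::quantile(aucs, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  }
  structure(list(
    roc = roc, sweep = sw, bands = bands,
    optimal_threshold = roc$optimal_threshold,
    auc = roc$auc, auc_ci = auc_ci,
    sensitivity = roc$sensitivity, specificity = roc$specificity,
    reversal_fraction = reversal_fraction(voxels),
    adc_mean_reversed = mean(v$adc[v$fate == "reversed"]),
    adc_mean_unchanged = mean(v$adc[v$fate == "unchanged"]),
    n_voxels = nrow(v), n_patients = attr(voxels, "n_patients"),
    band_halfwidth = band_halfwidth,
    voxels = voxels, call = match.call()),
    class = "reversal_fit")
}

#' @export
print.reversal_fit <- function(x, ...) {
  cat("ADC threshold model for DWI lesion reversal\n")
  cat(sprintf("  %d voxels from %d patient(s); %.1f%% reversed\n",
              x$n_voxels, x$n_patients, 100 * x$reversal_fraction))
  cat(sprintf("  AUC = %.3f%s\n", x$auc,
              if (!is.null(x$auc_ci))
                sprintf(" (95%% CI %.3f-%.3f, patient bootstrap)",
                        x$auc_ci[1], x$auc_ci[2]) else ""))
  cat(sprintf("  optimal threshold %g (sensitivity %.1f%%, specificity %.1f%%)\n",
              x$optimal_threshold, x$sensitivity, x$specificity))
  invisible(x)
}

#' @export
summary.reversal_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  mean ADC: reversed %.1f, unchanged %.1f (difference %.1f)\n",
              object$adc_mean_reversed, object$adc_mean_unchanged,
              object$adc_mean_reversed - object$adc_mean_unchanged))
  cat("\nThreshold sweep:\n")
  print(object$sweep, digits = 4, row.names = FALSE)
  invisible(object)
}

#' @export
coef.reversal_fit <- function(object, ...) {
  c(optimal_threshold = object$optimal_threshold,
    auc = object$auc,
    sensitivity = object$sensitivity,
    specificity = object$specificity,
    youden_j = object$roc$optimal_j)
}

band_prob_fun <- function(object) {
  b <- object$bands[!is.na(object$bands$pooled_pct), , drop = FALSE]
  function(adc) {
    p <- stats::approx(b$center, b$pooled_pct / 100, xout = adc, rule = 2)$y
    pmin(pmax(p, 0), 1)
  }
}

#' Predict voxel fate from baseline ADC
#'
#' `type = "class"` applies the fitted Youden-optimal threshold (ADC at or
#' above the threshold predicts reversal); `type = "prob"` interpolates the
#' fitted pooled band-probability curve, i.e. the estimated probability of
#' reversal at that ADC.
#'
#' @param object a [reversal_fit()].
#' @param newdata numeric ADC values, or a data.frame with an `adc` column;
#'   defaults to the training voxels.
#' @param type `"class"` or `"prob"`.
#' @param ... unused.
#' @return factor (`reversed`/`unchanged`) or numeric probabilities.
#' @export
predict.reversal_fit <- function(object, newdata = NULL,
                                 type = c("class", "prob"), ...) {
  type <- match.arg(type)
  adc <- if (is.null(newdata)) included_voxels(object$voxels)$adc
         else if (is.data.frame(newdata)) newdata$adc else as.numeric(newdata)
  if (type == "class")
    factor(ifelse(adc >= object$optimal_threshold, "reversed", "unchanged"),
           levels = c("reversed", "unchanged"))
  else band_prob_fun(object)(adc)
}

#' @export
residuals.reversal_fit <- function(object, ...) {
  v <- included_voxels(object$voxels)
  as.numeric(v$fate == "reversed") - band_prob_fun(object)(v$adc)
}

#' Simulate voxel fates from the fitted reversal curve
#'
#' Draws Bernoulli fates for the training voxels with probabilities from the
#' fitted pooled band-probability curve — a parametric-bootstrap primitive.
#'
#' @param object a [reversal_fit()].
#' @param nsim number of simulated fate vectors.
#' @param seed RNG seed.
#' @param ... unused.
#' @return data.frame with `nsim` columns of simulated fates
#'   (`"reversed"`/`"unchanged"`), one row per included training voxel.
#' @export
simulate.reversal_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  v <- included_voxels(object$voxels)
  p <- band_prob_fun(object)(v$adc)
  out <- as.data.frame(lapply(seq_len(nsim), function(s)
    ifelse(stats::runif(length(p)) < p, "reversed", "unchanged")),
    col.names = paste0("sim_", seq_len(nsim)))
  out
}

#' Plot a fitted reversal model
#'
#' Two base-graphics panels: the empirical ROC curve with the Youden-optimal
#' operating point, and the reversal-probability band curve (pooled and
#' patient-averaged) with the optimal threshold marked.
#'
#' @param x a [reversal_fit()].
#' @param which subset of panels, any of `1` (ROC) and `2` (band curve).
#' @param ... passed to [graphics::plot()].
#' @export
plot.reversal_fit <- function(x, which = 1:2, ...) {
  if (length(which) > 1L) {
    op <- graphics::par(mfrow = c(1, length(which)))
    on.exit(graphics::par(op))
  }
  if (1 %in% which) {
    graphics::plot(x$roc$points$fpr, x$roc$points$tpr, type = "l",
                   xlab = "1 - specificity", ylab = "sensitivity",
                   main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
    graphics::abline(0, 1, lty = 3)
    graphics::points(1 - x$specificity / 100, x$sensitivity / 100, pch = 19)
  }
  if (2 %in% which) {
    b <- x$bands
    graphics::plot(b$center, b$pooled_pct, type = "l",
                   xlab = "ADC (1e-6 mm²/s)", ylab = "P(reversal) %",
                   main = "Reversal probability by ADC band",
                   ylim = range(c(b$pooled_pct, b$per_patient_mean_pct), na.rm = TRUE),
                   ...)
    graphics::lines(b$center, b$per_patient_mean_pct, lty = 2)
    graphics::abline(v = x$optimal_threshold, col = "red", lty = 3)
    graphics::legend("topleft", bty = "n", lty = c(1, 2),
                     legend = c("pooled", "patient mean"))
  }
  invisible(x)
}
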