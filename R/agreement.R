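#' Dice overlap between two segmentation masks
#'
#' Dice coefficient `2|A∩B| / (|A|+|B|)` between two binary masks on the same
#' grid, with a consensus gate: agreement below 0.7 flags the pair for
#' consensus re-segmentation (`needs_consensus`). The gate is strict — a Dice
#' of exactly 0.7 does not trigger consensus.
#'
#' @param a,b binary masks ([adc_volume], kind `"mask"`) on the same grid; at
#'   least one non-empty.
#' @param consensus_gate Dice value below which consensus review is flagged
#'   (default 0.7).
#' @return list: `dice` in `[0, 1]`, `needs_consensus` logical.
#' @export
dice <- function(a, b, consensus_gate = 0.7) {
  stopifnot(inherits(a, "adc_volume"), inherits(b, "adc_volume"))
  assert_same_grid(a, b)
  na <- sum(a$data > 0); nb <- sum(b$data > 0)
  if (na + nb == 0L)
    stop(errorCondition("both masks are empty: Dice agreement is undefined",
                        class = c("adcrev_degenerate_error", "error")))
  d <- 2 * sum(a$data > 0 & b$data > 0) / (na + nb)
  list(dice = d, needs_consensus = d < consensus_gate)
}

#' Two-group comparison with a normality gate
#'
#' Compares two numeric samples the way the field's clinical tables do: a
#' Shapiro–Wilk normality check on each group (alpha = 0.05); if both pass, a
#' two-sample t-test (Welch by default, classic pooled-variance on request),
#' otherwise the Mann–Whitney U (Wilcoxon rank-sum) test. Shapiro–Wilk is
#' limited to 5000 observations, so larger groups are gated on a
#' deterministic evenly-spaced-rank subsample of 5000.
#'
#' @param x,y numeric vectors, each with at least 3 values.
#' @param alpha normality-test level (default 0.05).
#' @param welch use Welch's unequal-variance t-test (default `TRUE`).
#' @return list: `test` (`"t-test"` or `"mann-whitney"`), `statistic`,
#'   `p_value`, `normal_x`, `normal_y`.
#' @export
compare_groups <- function(x, y, alpha = 0.05, welch = TRUE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 3L || length(y) < 3L)
    stop("each group needs at least 3 observations", call. = FALSE)
  is_normal <- function(v) {
    if (stats::sd(v) == 0) return(FALSE)  # constant: Shapiro undefined
    if (length(v) > 5000L)
      v <- sort(v)[round(seq(1L, length(v), length.out = 5000L))]
    stats::shapiro.test(v)$p.value >= alpha
  }
  nx <- is_normal(x); ny <- is_normal(y)
  if (nx && ny) {
    ht <- stats::t.test(x, y, var.equal = !welch)
    list(test = "t-test", statistic = unname(ht$statistic),
         p_value = ht$p.value, normal_x = nx, normal_y = ny)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    list(test = "mann-whitney", statistic = unname(ht$statistic),
         p_value = ht$p.value, normal_x = nx, normal_y = ny)
  }
}

#' Mean with a bootstrap percentile confidence interval
#'
#' Nonparametric percentile bootstrap of the sample mean with a fixed seed
#' for reproducibility.
#'
#' @param x numeric vector, `n >= 2`.
#' @param level confidence level (default 0.95).
#' @param reps bootstrap resamples (default 10000).
#' @param seed RNG seed (default 1).
#' @return named numeric: `mean`, `lower`, `upper`.
#' @export
mean_ci <- function(x, level = 0.95, reps = 10000, seed = 1) {
  x <- as.numeric(x)
  if (length(x) < 2L) stop("need at least 2 observations", call. = FALSE)
  n <- length(x)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  boot <- vapply(seq_len(reps),
                 function(i) mean(x[sample.int(n, n, replace = TRUE)]),
                 numeric(1))
  q <- stats::quantile(boot, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  c(mean = mean(x), lower = q[1], upper = q[2])
}
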