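---
title: "Methods: voxel-level ADC threshold analysis of DWI lesion reversal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxel-level ADC threshold analysis of DWI lesion reversal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adcrev)
```

## The analysis model

The unit of analysis is the baseline-lesion voxel. Given a baseline ADC map
(units 10⁻⁶ mm²/s throughout — the number 555, never 5.55e-4) and binary
pre-/post-treatment lesion masks already co-registered to the same grid,
every voxel of the pre-treatment mask receives a fate:

* **reversed** if it is absent from the union of the post-treatment and
  (optional) haemorrhage masks;
* **unchanged** otherwise.

Three conventions do most of the scientific work, and all are deliberate:

1. **Haemorrhage counts as persistent.** Haemorrhagic transformation
   obscures the follow-up DWI signal, so a haemorrhage voxel cannot be
   claimed as salvage; classifying it as persistent is the conservative
   choice. Internally `classify_voxels(pre, post, h)` is identical to
   `classify_voxels(pre, post | h)` — a property the tests assert.
2. **Growth is not scored.** Voxels present only on the post mask are new
   lesion, not baseline tissue whose fate is in question.
3. **ADC windows statistical inclusion only.** Baseline voxels outside
   200 ≤ ADC ≤ 760 stay in the table flagged `adc_below_min` /
   `adc_above_max` (artifact / partial-volume, respectively) and are
   excluded from every statistic, but no ADC filter touches post-mask
   membership — filtering the post mask would manufacture reversal. The
   window is closed at both ends; values strictly above 760 or strictly
   below 200 are out. Keeping excluded voxels in the table makes every
   denominator auditable.

A fourth, the **1 mL quality gate** (`qc_min_lesion`), drops patients whose
*raw* pre-mask volume (before ADC windowing) is ≤ 1 mL: in small lesions,
segmentation and co-registration error can misclassify a disproportionate
share of voxels. Whether the gate should apply before or after ADC
windowing is genuinely open; we apply it to the raw segmented lesion, since
the gate exists to police segmentation quality, not ADC content.

## Threshold statistics

With fates fixed, ADC is scored as a classifier of reversal. The positive
class is *reversed* and the test is positive when ADC ≥ t: reversed voxels
concentrate at higher ADC, so this orientation gives a concave ROC. "Below
threshold" is strict (ADC < t) everywhere, which makes

sensitivity(t) + (% of all reversed volume below t) = 100

an exact identity on pooled data — a useful internal-consistency check that
the tests assert to machine precision.

`adc_roc()` evaluates the curve at every integer threshold in [200, 760]
(scanner ADC maps are integer-valued at this scale; inputs are rounded
half-up first), integrates by the trapezoid rule, and takes the
Youden-optimal cutoff maximising J = sensitivity + specificity − 100, ties
broken toward the lower threshold. On an integer grid the trapezoidal AUC
equals the Mann–Whitney pair statistic P(ADC_R > ADC_U) + ½ P(tie) exactly;
the test suite checks this equivalence against a brute-force pair count and
against an independent ROC implementation (pROC).

Band probabilities estimate P(reversal | ADC ≈ c) as the reversed fraction
among voxels with ADC in the **closed** band [c − 10, c + 10] (the
halfwidth is a parameter; ±10 is the field's convention). Two modes are
exposed because they answer different questions: `pooled` weights every
voxel equally (large lesions dominate — the dataset-level curve), while
`per_patient_mean` averages the within-patient fractions over patients that
have voxels in the band (the patient-level curve). Bands with no voxels
return `NA` — undefined, never zero.

The headline AUC and optimal threshold pool all voxels from all patients
with equal weight. A patient-level bootstrap (resample patients with
replacement, keep all their voxels) is available for an AUC interval; a
voxel-level bootstrap would pretend voxels were independent across a
spatially correlated lesion and be absurdly narrow.

All of this is packaged behind one estimator, `reversal_fit()`, returning a
classed object with `print`, `summary`, `coef`, `predict` (class by fitted
cutoff; probability by interpolating the pooled band curve), `plot`,
`residuals` and `simulate` methods.

## Eligibility chain

`apply_eligibility()` encodes the cohort-definition chain in a fixed order:
MRI pair (baseline + follow-up 12–36 h) → successful reperfusion (mTICI 2c
or 3) → same scanner/sequence → image quality → lesion > 1 mL → no
re-occlusion → recanalization ≤ 120 min after MRI. The first failure is
reported and later stages are not evaluated, so flow counts are
non-increasing by construction. The ≤ 120 min criterion sits last because
it is part of the cohort's initial screen rather than a separately counted
stage; `synthetic_flow_cohort()` provides a constructed 565-record screening
cohort whose counts (565 → 204 → 146 → 92 → 77 → 73 → 71) serve as known
truth for the flow code.

## Agreement and group statistics

`dice()` is 2|A∩B|/(|A|+|B|) with a consensus gate at 0.7: *strictly* below
0.7 flags re-segmentation (a Dice of exactly 0.7 passes — documented
because the boundary is testable). `compare_groups()` gates on Shapiro–Wilk
at α = 0.05 per group: both normal → two-sample t-test (Welch by default;
the pooled-variance test sits behind a flag, since equal variances are an
assumption we'd rather not default to), otherwise Mann–Whitney U.
Shapiro–Wilk refuses n > 5000, so larger groups are gated on a
deterministic evenly-spaced-rank subsample of 5000 — at such n the gate is
a formality, as any real effect fails normality anyway. `mean_ci()` is a
percentile bootstrap with a fixed seed; reference confidence intervals for
group means are treated as context, not as reproduction targets, because
their method of computation is not public.

## The synthetic cohort generator

No voxel-level patient data of this kind are public, so the generator
produces cohorts with the statistical structure the analysis assumes,
calibrated to the published 71-patient reference sweep shipped as
`reference_sweep()`:

* **Lesion ADC marginal.** Included-voxel ADC follows the piecewise-linear
  CDF through the reference cumulative lesion fractions at the 14
  thresholds (anchored at 0% / 100% at the window edges), sampled by
  inverse transform and rounded half-up to integers. The reference table
  gives class means but not distributional shape; calibrating to the
  cumulative knots pins the marginal up to interpolation, which is a
  modelling choice, not a published fact.
* **Reversal curve.** Each lesion voxel reverses independently with
  probability linear-interpolated through the reference per-band
  probabilities, constant beyond the end knots, clamped to [0, 1]. Voxel
  independence given ADC is the default because the analysis statistics are
  voxel-marginal, and independence makes analytic oracles exact.
* **Consistency.** These two tables jointly imply a pooled reversal
  fraction of 0.371, class-conditional mean ADC of 609.8 (reversed) and
  529.1 (unchanged), and an AUC of 0.706 (`analytic_auc()`) — all close to
  the reference cohort's printed 37.3%, 597.6, 536.7 and 0.708, which is
  the internal-consistency the calibration banks on.
* **Geometry.** One ellipsoidal lesion per patient with in-plane semi-axes
  uniform on 8–32 voxels and through-plane 2–6 (kept separate because slice
  spacing, 6.5 mm, is ~11× the 0.6 mm in-plane spacing). On the default
  96×96×16 grid this spans ~1.3 to ~60 mL with a mean near 16 mL, matching
  the reference cohort's "under 1 mL excluded, mean ~18 mL" regime; the
  lower bound is chosen to clear the 1 mL gate so default cohorts lose no
  patients to QC.
* **Background.** A two-compartment GM/WM pattern (grey 800, white 700,
  Gaussian noise SD 30, integers ≥ 0) — enough to exercise the
  tissue-heterogeneity point without an anatomical atlas. The `noise_sd`
  parameter applies to background only: lesion ADC comes from the
  calibrated marginal, which already describes the observed (noisy)
  distribution, and adding noise on top would smear the calibration knots.
* **Haemorrhage.** With per-patient probability 0.56 (the reference
  cohort's any-bleed rate), an ellipsoid with semi-axes 0.3× the lesion's
  is placed fully inside the lesion and forced into the post mask. Because
  placement is ADC-independent, its only statistical effect is to attenuate
  the observed reversal curve by the expected covered fraction
  h = 0.56 × 0.3³ ≈ 1.5%; the analytic oracles fold this in.
* **Tails.** 1% of lesion voxels get ADC below 200 and 3% above 760, so
  the exclusion rules are exercised; they do not affect included-voxel
  statistics.
* **Determinism.** Every patient derives a sub-seed from
  (config seed, patient index); identical seeds give identical cohorts.
  Metadata is stratified so that for n = 71 exactly 34 patients have mTICI
  3, 5 posterior occlusions, and exactly 20 fall in the canonical subgroup
  (anterior, mTICI 3, ≤ 90 min) — matching the reference cohort's counts
  rather than leaving them to sampling noise.

What the generator does **not** emulate: spatial correlation of fate
(an optional future robustness axis; real reversal happens in connected
regions), anatomy-linked ADC (lesion ADC is independent of the GM/WM
background), partial-volume mixing at lesion edges, scanner drift, or any
MR physics. Passing tests therefore demonstrate that the *pipeline
machinery* is correct and recovers known structure from data obeying the
stated model — not that the model captures everything about real stroke
data.

## Numerical choices and degenerate inputs

* Grid mismatches are errors, never repairs: co-registration is upstream.
  Spacing comparison uses relative tolerance 1e-3 (NIfTI headers round
  pixdim in float32).
* Masks are written as uint8 and ADC as float32, so mask round trips are
  bit-exact and ADC round trips exact at float precision.
* Degenerate inputs raise classed errors rather than returning silent
  zeros: empty pre-mask, no included voxels, a missing voxel class for
  ROC/sensitivity, two empty masks for Dice. Ratios with empty
  denominators inside a sweep (nothing below a threshold) are `NA`.
* Ties on Youden's J break toward the lower threshold, and `which.max`'s
  first-hit semantics implement that on the ascending grid.

## Problem sizes

The shipped tests run small property fixtures (masks of a few hundred
voxels, brute-force pair oracles at n ≤ 500) plus one full-size end-to-end
check: a 71-patient cohort on a 96×96×16 grid (~450k pooled lesion voxels),
which recovers the configured reversal curve at all 14 knots within three
binomial standard errors of the analytic band values and the analytic AUC
within ±0.03. The acceptance script regenerates that cohort from a
command-line seed and re-runs the entire pipeline from NIfTI files on disk.

## Known limitations

* The eligibility chain's stage order interleaves criteria that a given
  study may have applied in a different sequence; counts at intermediate
  stages depend on that order even when the final cohort does not.
* The per-patient-mean band curve is reported alongside the pooled one, but
  which convention a given published table used is not always stated;
  neither is asserted to reproduce any specific published band column.
* The patient bootstrap CI is a design choice where published intervals do
  not state their method; it is not a reproduction of any reference CI.
* `simulate()` resamples fates from the fitted band curve at the training
  voxels' ADC; it does not simulate new lesions (use the generator for
  that).
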