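# GC correction and healthy-reference normalization: raw bin counts ->
# relative copy number x with diploid baseline 2.

GC_USABLE_RANGE <- c(0.28, 0.68)
X_CLAMP <- 0.01  # floor for x before logs; bounds z at sqrt(|log2(0.005)|)

#' Construct a relative copy-number profile
#'
#' @param sample_id sample label.
#' @param x per-bin relative copy number (diploid = 2); `NA` on masked bins.
#' @param masked logical mask per bin.
#' @param chrom chromosome label per bin.
#' @param smoothing `"raw"` or `"segmented"`.
#' @return A `cn_profile` object.
#' @export
cn_profile <- function(sample_id, x, masked, chrom, smoothing = "raw") {
  stopifnot(length(x) == length(masked), length(x) == length(chrom),
            smoothing %in% c("raw", "segmented"))
  if (any(!masked & (is.na(x) | x <= 0)))
    stop("x must be positive on unmasked bins")
  structure(list(sample_id = as.character(sample_id), x = as.numeric(x),
                 masked = as.logical(masked), chrom = as.character(chrom),
                 smoothing = smoothing),
            class = "cn_profile")
}

#' @export
print.cn_profile <- function(x, ...) {
  cat(sprintf(
    "<cn_profile> sample %s (%s): %d bins (%d masked), median x = %.3f\n",
    x$sample_id, x$smoothing, length(x$x), sum(x$masked),
    median(x$x[!x$masked])))
  invisible(x)
}

#' Construct a healthy reference
#'
#' @param level per-bin reference level (median GC-corrected count fraction
#'   across the healthy cohort); `NA` on masked bins.
#' @param masked logical mask per bin.
#' @param cohort_cni_mean,cohort_cni_sd cohort CNI calibration (filled by
#'   [build_reference()] on its second pass; `NA` until then).
#' @param n_samples cohort size behind the reference.
#' @return A `healthy_reference` object with `cutoff = mean + sd`.
#' @export
healthy_reference <- function(level, masked, cohort_cni_mean = NA_real_,
                              cohort_cni_sd = NA_real_,
                              n_samples = NA_integer_) {
  if (any(!masked & (is.na(level) | level <= 0)))
    stop("reference levels must be positive on unmasked bins")
  structure(list(level = as.numeric(level), masked = as.logical(masked),
                 cohort_cni_mean = cohort_cni_mean,
                 cohort_cni_sd = cohort_cni_sd,
                 n_samples = n_samples,
                 cutoff = cohort_cni_mean + cohort_cni_sd),
            class = "healthy_reference")
}

#' @export
print.healthy_reference <- function(x, ...) {
  cat(sprintf(
    "<healthy_reference> %d bins (%d masked), n = %s, cutoff = %s\n",
    length(x$level), sum(x$masked),
    ifelse(is.na(x$n_samples), "?", x$n_samples),
    ifelse(is.na(x$cutoff), "uncalibrated", sprintf("%.3f", x$cutoff))))
  invisible(x)
}

#' GC-bias correction of bin counts
#'
#' Fits a locally weighted regression (tricube weights, 2 robustness
#' iterations) of count on GC over usable bins and divides each count by the
#' fitted bias, rescaled so the mean corrected value equals the mean raw
#' count. Bins with GC outside `[0.28, 0.68]` or zero count are flagged
#' masked for downstream stages. With fewer than 100 usable bins the fit
#' falls back to medians within 2%-wide GC strata, which keeps tiny genomes
#' valid; identical GC everywhere makes the correction the identity.
#'
#' @param counts a `bin_counts` object.
#' @param bins the `genome_bins` grid.
#' @param span loess span in (0, 1] (fraction of bins in each local window).
#' @return List with `corrected` (per-bin intensities, `NA` where masked)
#'   and `masked` (updated logical mask).
#' @export
gc_correct <- function(counts, bins, span = 0.3) {
  stopifnot(inherits(counts, "bin_counts"))
  if (length(counts$counts) != nrow(bins))
    stop("bin-grid mismatch between counts and grid")
  if (span <= 0 || span > 1) stop("span must lie in (0, 1]")
  y <- counts$counts
  gc <- bins$gc
  masked <- bins$masked | is.na(gc) |
    gc < GC_USABLE_RANGE[1L] | gc > GC_USABLE_RANGE[2L] | y == 0
  use <- which(!masked)
  if (length(use) < 30L)
    stop("gc_correct needs >= 30 usable bins, got ", length(use))

  corrected <- rep(NA_real_, length(y))
  if (length(unique(gc[use])) == 1L) {
    corrected[use] <- y[use]  # degenerate GC: identity
  } else {
    fit <- if (length(use) >= 100L) {
      lw <- lowess(gc[use], y[use], f = span, iter = 2L)
      # lowess returns the curve on sorted x; interpolate back to the bins
      # (ties collapsed: duplicated GC values share one fitted level)
      stats::approx(lw$x, lw$y, xout = gc[use], rule = 2L,
                    ties = list("ordered", mean))$y
    } else {
      stratum <- floor(gc[use] / 0.02)
      med <- tapply(y[use], stratum, median)
      as.numeric(med[as.character(stratum)])
    }
    fit[!is.finite(fit) | fit <= 0] <- median(y[use])
    corr <- y[use] / fit
    corrected[use] <- corr * mean(y[use]) / mean(corr)
  }
  list(corrected = corrected, masked = masked)
}

#' Build a healthy reference from a cohort of bin counts
#'
#' Two-pass construction. Pass one: every cohort sample is GC-corrected and
#' scaled to count fractions; the per-bin reference level is the cross-sample
#' median. Bins are masked when zero in more than half the cohort, when the
#' median level is non-positive, or when the cross-sample MAD exceeds
#' `outlier_mult` times the cohort-median MAD (noisy outlier bins). Pass two
#' (unless `calibrate = FALSE`): each cohort sample is scored through the
#' full pipeline (normalize, segment if requested, z transform, CNI score)
#' to fill in the cohort CNI mean/SD and hence the CIN cutoff (mean + SD).
#' Calibration scores sample j against the leave-one-out reference (per-bin
#' median of the other n-1 samples): the cutoff is applied to unseen patient
#' samples, and scoring each donor against a reference its own noise helped
#' define would bias the cutoff low.
#'
#' @param cohort list of `bin_counts` (or the list returned by
#'   [simulate_healthy_cohort()]).
#' @param bins the `genome_bins` grid.
#' @param span GC-correction span.
#' @param outlier_mult MAD outlier masking multiplier.
#' @param calibrate run the second (CNI calibration) pass.
#' @param config pipeline parameters for the calibration pass (see
#'   [default_config()]).
#' @return A `healthy_reference`; when calibrated, its `cohort_scores`
#'   attribute holds the individual cohort CNI scores.
#' @export
build_reference <- function(cohort, bins, span = 0.3, outlier_mult = 5,
                            calibrate = TRUE, config = default_config()) {
  if (!is.null(cohort$samples)) cohort <- cohort$samples
  n <- length(cohort)
  if (n < 2L) stop("reference cohort needs >= 2 samples, got ", n)
  nb <- nrow(bins)

  frac <- matrix(NA_real_, nb, n)
  mask_any <- bins$masked
  zero_ct <- integer(nb)
  for (j in seq_len(n)) {
    zero_ct <- zero_ct + (cohort[[j]]$counts == 0)
    gcres <- gc_correct(cohort[[j]], bins, span = span)
    ok <- !gcres$masked
    frac[ok, j] <- gcres$corrected[ok] / sum(gcres$corrected[ok])
  }
  level <- apply(frac, 1L, function(v) median(v, na.rm = TRUE))
  spread <- apply(frac, 1L, function(v) mad(v, na.rm = TRUE))

  masked <- mask_any | zero_ct > n / 2 | !is.finite(level) | level <= 0
  typical <- median(spread[!masked], na.rm = TRUE)
  if (is.finite(typical) && typical > 0)
    masked <- masked | (is.finite(spread) & spread > outlier_mult * typical)
  level[masked] <- NA_real_

  ref <- healthy_reference(level, masked, n_samples = n)
  scores <- NULL
  if (calibrate) {
    scores <- vapply(seq_len(n), function(j) {
      loo_level <- apply(frac[, -j, drop = FALSE], 1L,
                         function(v) median(v, na.rm = TRUE))
      use <- which(!masked & is.finite(frac[, j]) & is.finite(loo_level) &
                     loo_level > 0)
      f <- frac[use, j] / sum(frac[use, j])
      x <- rep(NA_real_, nb)
      x[use] <- pmax(2 * f / loo_level[use], X_CLAMP)
      msk <- rep(TRUE, nb); msk[use] <- FALSE
      prof <- cn_profile(cohort[[j]]$sample_id, x, msk, bins$chrom)
      score_profile(prof, config = config)$score
    }, numeric(1L))
    ref <- healthy_reference(level, masked,
                             cohort_cni_mean = mean(scores),
                             cohort_cni_sd = sd(scores),
                             n_samples = n)
    attr(ref, "cohort_scores") <- scores
  }
  ref
}

#' Normalize a sample to relative copy number
#'
#' GC-corrects the counts, scales to count fractions, and divides by the
#' healthy reference level, anchored so a diploid (healthy-like) bin sits at
#' x = 2: `x_i = 2 * fraction_i / level_i`. Values are clamped below at 0.01
#' so the downstream log transform stays defined; clamped bins are flagged.
#'
#' @param counts a `bin_counts` object.
#' @param reference a `healthy_reference` on the same grid.
#' @param bins the `genome_bins` grid.
#' @param span GC-correction span.
#' @return A `cn_profile` (smoothing = "raw") whose `clamped` attribute
#'   flags bins floored at 0.01.
#' @export
normalize_to_reference <- function(counts, reference, bins, span = 0.3) {
  stopifnot(inherits(reference, "healthy_reference"))
  if (length(reference$level) != nrow(bins))
    stop("bin-grid mismatch between reference and grid")
  gcres <- gc_correct(counts, bins, span = span)
  masked <- gcres$masked | reference$masked
  use <- which(!masked)
  if (length(use) == 0L) stop("no usable bins after masking")
  frac <- gcres$corrected[use] / sum(gcres$corrected[use])
  x <- rep(NA_real_, nrow(bins))
  x[use] <- 2 * frac / reference$level[use]
  clamped <- !masked & !is.na(x) & x < X_CLAMP
  x[clamped] <- X_CLAMP
  prof <- cn_profile(counts$sample_id, x, masked, bins$chrom,
                     smoothing = "raw")
  attr(prof, "clamped") <- clamped
  prof
}
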