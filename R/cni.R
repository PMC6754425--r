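# The instability score: per-bin z transform, percentile-window CNI score,
# healthy-cohort cutoff, CIN/CNS classification.

#' Default CIN cutoff
#'
#' Published mean + SD of CNI scores across a 100-donor healthy plasma
#' cohort. A data-dependent constant: it is used when no healthy cohort is
#' supplied and is not recomputable from synthetic data.
#' @export
DEFAULT_CNI_CUTOFF <- 56.60

#' Per-bin z values
#'
#' `z_i = sqrt(|log2(x_i / 2)|)`: zero for a diploid bin, 1 for a bin one
#' doubling away in either direction (x = 4 or x = 1). Computed on the
#' segment-smoothed profile by default (see [score_sample()]).
#'
#' @param profile a `cn_profile` (x positive on unmasked bins).
#' @return A `z_vector`: list with `z` (per-unmasked-bin values), `bin`
#'   (their grid indices), `sample_id`, `smoothing`.
#' @export
z_values <- function(profile) {
  stopifnot(inherits(profile, "cn_profile"))
  keep <- which(!profile$masked)
  if (length(keep) == 0L) stop("profile has no unmasked bins")
  z <- sqrt(abs(log2(profile$x[keep] / 2)))
  structure(list(z = z, bin = keep, sample_id = profile$sample_id,
                 smoothing = profile$smoothing),
            class = "z_vector")
}

#' CNI score over a percentile window of z values
#'
#' Sorts z ascending (ties broken by bin index, stable) and sums the values
#' ranked between the m-th and p-th percentile: with N unmasked bins, ranks
#' `m_b = ceil(m/100 * N)` to `p_b = floor(p/100 * N)` (1-based, inclusive).
#' The default window m = 95, p = 99 captures the strongest 4% of deviations
#' while excluding the most extreme 1% as potential artifacts.
#'
#' @param z a `z_vector` from [z_values()].
#' @param m,p window percentiles, `0 <= m < p <= 100`.
#' @return A `cni_result`: list with `score`, `m`, `p`, `m_b`, `p_b`,
#'   `n_bins_used`, `sample_id`.
#' @export
cni_score <- function(z, m = 95, p = 99) {
  stopifnot(inherits(z, "z_vector"))
  if (m < 0 || p > 100 || m >= p)
    stop("need 0 <= m < p <= 100 (got m=", m, ", p=", p, ")")
  N <- length(z$z)
  m_b <- ceiling(m / 100 * N)
  m_b <- max(m_b, 1L)
  p_b <- floor(p / 100 * N)
  if (p_b < m_b)
    stop("empty percentile window: N=", N, ", m=", m, ", p=", p,
         " gives ranks ", m_b, "..", p_b)
  ord <- order(z$z, z$bin)  # stable: ties broken by bin index
  win <- ord[m_b:p_b]
  structure(list(score = sum(abs(z$z[win])), m = m, p = p,
                 m_b = m_b, p_b = p_b, n_bins_used = p_b - m_b + 1L,
                 sample_id = z$sample_id),
            class = "cni_result")
}

#' @export
print.cni_result <- function(x, ...) {
  lab <- if (!is.null(x$label)) paste0(" [", x$label, "]") else ""
  cat(sprintf("<cni_result> %s: CNI = %.3f (window %g-%g%%, %d bins)%s\n",
              x$sample_id, x$score, x$m, x$p, x$n_bins_used, lab))
  invisible(x)
}

#' Estimate the CIN cutoff from healthy-cohort scores
#'
#' Cutoff = arithmetic mean + sample standard deviation (n-1 denominator) of
#' the cohort's CNI scores. With no cohort the published constant
#' [DEFAULT_CNI_CUTOFF] (56.60) applies.
#'
#' @param healthy_scores numeric vector of >= 2 CNI scores, or `NULL`.
#' @return The cutoff value.
#' @export
estimate_cutoff <- function(healthy_scores = NULL) {
  if (is.null(healthy_scores)) return(DEFAULT_CNI_CUTOFF)
  if (length(healthy_scores) < 2L)
    stop("cutoff estimation needs >= 2 healthy scores")
  mean(healthy_scores) + sd(healthy_scores)
}

#' Classify a CNI score as CIN or CNS
#'
#' CIN (chromosomal instability) iff `score > cutoff`, strictly; a score
#' exactly at the cutoff is called CNS (chromosomal stability).
#'
#' @param score CNI score.
#' @param cutoff classification cutoff (default the published 56.60).
#' @return `"CIN"` or `"CNS"`.
#' @export
classify_cni <- function(score, cutoff = DEFAULT_CNI_CUTOFF) {
  stopifnot(is.finite(score), is.finite(cutoff))
  if (score > cutoff) "CIN" else "CNS"
}

#' Score one sample end to end
#'
#' Normalize to the reference, segment (unless `config$z_source = "raw"`),
#' take z values and the percentile-window CNI score, and classify against
#' the cutoff. Segmentation precedes the z transform by default, matching
#' the method's order (segments first, then per-bin z on the smoothed copy
#' numbers).
#'
#' @param counts a `bin_counts` object.
#' @param bins the `genome_bins` grid.
#' @param reference a calibrated (or at least level-filled)
#'   `healthy_reference`.
#' @param config pipeline parameters (see [default_config()]); the
#'   segmentation seed is derived from `config$seed`.
#' @param cutoff classification cutoff; defaults to the reference's
#'   calibrated `mean + SD` cutoff, falling back to [DEFAULT_CNI_CUTOFF].
#' @return A `cni_result` with added `label`, `cutoff`, `profile` (the
#'   profile the z values were computed on) and `segments` fields.
#' @export
score_sample <- function(counts, bins, reference, config = default_config(),
                         cutoff = NULL) {
  if (is.null(cutoff))
    cutoff <- if (is.finite(reference$cutoff %||% NA_real_))
      reference$cutoff else DEFAULT_CNI_CUTOFF
  prof <- normalize_to_reference(counts, reference, bins,
                                 span = config$span)
  score_profile(prof, config = config, cutoff = cutoff)
}

#' Score an already-normalized profile
#'
#' The segmentation / z / CNI / classification tail of [score_sample()], for
#' callers that build the relative copy-number profile themselves.
#'
#' @param prof a raw `cn_profile`.
#' @inheritParams score_sample
#' @return A `cni_result` (see [score_sample()]).
#' @export
score_profile <- function(prof, config = default_config(),
                          cutoff = DEFAULT_CNI_CUTOFF) {
  segs <- NULL
  zprof <- prof
  if (identical(config$z_source, "segmented")) {
    segs <- segment_profile(prof, alpha = config$alpha,
                            n_perm = config$n_perm,
                            min_width = config$min_width,
                            seed = config$seed + 777L)
    zprof <- apply_segments(prof, segs)
  }
  res <- cni_score(z_values(zprof), m = config$m, p = config$p)
  res$cutoff <- cutoff
  res$label <- classify_cni(res$score, cutoff)
  res$profile <- zprof
  res$segments <- segs
  res
}
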