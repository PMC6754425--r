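# Circular binary segmentation of per-chromosome log2(x/2) signals.
# Recursive arc search with a permutation test; the O(n^2) statistic scan
# lives in src/cbs.cpp.

#' Segment a copy-number profile by circular binary segmentation
#'
#' Works per chromosome on `log2(x/2)` of the unmasked bins. At each step the
#' arc `(i, j]` of the circularized current segment maximizing the pooled
#' two-sample t statistic against its complement is found by exhaustive scan;
#' the split is accepted if its permutation p-value (label permutations of
#' the bins within the segment) is below `alpha`, and the resulting pieces
#' are segmented recursively. Accepted segments shorter than `min_width` are
#' merged into the neighbour with the closer mean. Chromosomes are never
#' merged with each other. Deterministic given `seed`.
#'
#' @param profile a `cn_profile` (raw, GC/reference-normalized).
#' @param alpha split significance level in (0, 0.5].
#' @param n_perm number of permutations (>= 100).
#' @param min_width minimum segment width in bins.
#' @param seed RNG seed for the permutation test.
#' @return A `segment_set`: data.frame with one row per segment (`chrom`,
#'   `start_bin`/`end_bin` 1-based grid indices, `loc_start`/`loc_end` bp,
#'   `n_bins` unmasked bins, `seg_log2` mean log2(x/2), `seg_cn` =
#'   `2 * 2^seg_log2`).
#' @export
segment_profile <- function(profile, alpha = 0.01, n_perm = 1000L,
                            min_width = 3L, seed = 1L) {
  stopifnot(inherits(profile, "cn_profile"))
  if (alpha <= 0 || alpha > 0.5) stop("alpha must lie in (0, 0.5]")
  if (n_perm < 100L) stop("n_perm must be >= 100")

  rows <- list()
  with_seed(mix_seed(seed, 404L), {
    for (cl in unique(profile$chrom)) {
      idx <- which(profile$chrom == cl & !profile$masked)
      if (length(idx) == 0L) {
        message("chromosome ", cl, " has no unmasked bins; skipped")
        next
      }
      y <- log2(profile$x[idx] / 2)
      pieces <- cbs_recurse(y, alpha, n_perm)
      pieces <- merge_short_segments(y, pieces, min_width)
      for (pc in pieces) {
        gi <- idx[pc$lo:pc$hi]
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = cl, start_bin = gi[1L], end_bin = gi[length(gi)],
          n_bins = length(gi), seg_log2 = mean(y[pc$lo:pc$hi]),
          stringsAsFactors = FALSE)
      }
    }
  })
  seg <- do.call(rbind, rows)
  seg$seg_cn <- 2 * 2^seg$seg_log2
  attr(seg, "sample_id") <- profile$sample_id
  class(seg) <- c("segment_set", "data.frame")
  seg
}

# recursive CBS on a numeric vector; returns list of (lo, hi) 1-based ranges
cbs_recurse <- function(y, alpha, n_perm) {
  n <- length(y)
  if (n < 2L) return(list(list(lo = 1L, hi = n)))
  res <- .cbs_perm_test(y, as.integer(n_perm), alpha)
  if (res$i < 0L || res$p >= alpha) return(list(list(lo = 1L, hi = n)))
  i <- res$i; j <- res$j  # arc = elements (i+1)..j
  bounds <- sort(unique(c(0L, i, j, n)))
  out <- list()
  for (b in seq_len(length(bounds) - 1L)) {
    lo <- bounds[b] + 1L; hi <- bounds[b + 1L]
    sub <- cbs_recurse(y[lo:hi], alpha, n_perm)
    for (s in sub)
      out[[length(out) + 1L]] <- list(lo = lo + s$lo - 1L, hi = lo + s$hi - 1L)
  }
  out
}

# merge segments shorter than min_width into the neighbour with the closer
# mean; a chromosome whose only segment is short is left as-is
merge_short_segments <- function(y, pieces, min_width) {
  repeat {
    if (length(pieces) <= 1L) return(pieces)
    len <- vapply(pieces, function(p) p$hi - p$lo + 1L, integer(1L))
    short <- which(len < min_width)
    if (length(short) == 0L) return(pieces)
    k <- short[which.min(len[short])]
    mean_of <- function(p) mean(y[p$lo:p$hi])
    m <- mean_of(pieces[[k]])
    left_d <- if (k > 1L) abs(m - mean_of(pieces[[k - 1L]])) else Inf
    right_d <- if (k < length(pieces)) abs(m - mean_of(pieces[[k + 1L]]))
               else Inf
    into <- if (left_d <= right_d) k - 1L else k + 1L
    lo <- min(pieces[[k]]$lo, pieces[[into]]$lo)
    hi <- max(pieces[[k]]$hi, pieces[[into]]$hi)
    pieces[[min(k, into)]] <- list(lo = lo, hi = hi)
    pieces[[max(k, into)]] <- NULL
  }
}

#' Replace bin values by their segment means
#'
#' Returns a `segmented` copy of the profile in which every unmasked bin's x
#' is its segment's `seg_cn`. Idempotent.
#'
#' @param profile the `cn_profile` the segments were fitted on (same grid).
#' @param segments a `segment_set` from [segment_profile()].
#' @return A `cn_profile` with `smoothing = "segmented"`.
#' @export
apply_segments <- function(profile, segments) {
  stopifnot(inherits(profile, "cn_profile"), inherits(segments, "segment_set"))
  x <- profile$x
  covered <- profile$masked  # masked bins need no coverage
  for (r in seq_len(nrow(segments))) {
    span <- segments$start_bin[r]:segments$end_bin[r]
    span <- span[!profile$masked[span] &
                   profile$chrom[span] == segments$chrom[r]]
    x[span] <- segments$seg_cn[r]
    covered[span] <- TRUE
  }
  if (!all(covered))
    stop("segment set does not cover ", sum(!covered),
         " unmasked bin(s): partition violation")
  cn_profile(profile$sample_id, x, profile$masked, profile$chrom,
             smoothing = "segmented")
}
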