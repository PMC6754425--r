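# Shared fixtures, all built in code.

# tiny two-chromosome grid with a spread of GC values
tiny_bins <- function(n_per_chrom = 20L, bin_width = 1e6) {
  lens <- c("1" = n_per_chrom * bin_width, "2" = n_per_chrom * bin_width)
  bins <- build_bins(lens, bin_width)
  bins$gc <- rep(seq(0.35, 0.55, length.out = n_per_chrom), 2L)
  bins
}

# test-speed pipeline config (permutations at the allowed minimum)
quick_config <- function(...) {
  cfg <- utils::modifyList(default_config(),
                           list(n_perm = 200L, ...))
  cfg
}

# cohort of flat, noise-free samples on a grid: every bin carries `level`
flat_cohort <- function(bins, n = 3L, level = 1000L) {
  lapply(seq_len(n), function(i)
    bin_counts(sprintf("flat_%d", i), rep(level, nrow(bins))))
}

# profile straight from a log2-ratio signal (diploid = 0)
profile_from_log2 <- function(y, chrom = rep("1", length(y)),
                              sample_id = "sig") {
  cn_profile(sample_id, x = 2 * 2^y, masked = rep(FALSE, length(y)),
             chrom = chrom, smoothing = "raw")
}

# brute-force arc scan mirroring the segmentation statistic (R oracle);
# arcs ending at n duplicate prefix partitions and are skipped, matching
# the implementation's canonical enumeration
oracle_max_arc <- function(y) {
  n <- length(y)
  best <- list(i = -1L, j = -1L, stat = 0)
  if (n < 2L) return(best)
  for (i in 0:(n - 2L)) {
    for (j in (i + 1L):(n - 1L)) {
      k <- j - i
      arc <- y[(i + 1L):j]
      rest <- y[-((i + 1L):j)]
      d <- abs(mean(arc) - mean(rest))
      wss <- sum((arc - mean(arc))^2) + sum((rest - mean(rest))^2)
      stat <- if (n > 2L && wss > 1e-24) {
        d / sqrt(wss / (n - 2) * (1 / k + 1 / (n - k)))
      } else if (d > 1e-12) 1e12 else 0
      if (stat > best$stat) best <- list(i = i, j = j, stat = stat)
    }
  }
  best
}
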