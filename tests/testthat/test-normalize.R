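test_that("GC correction is the identity under degenerate GC", {
  bins <- build_bins(c("1" = 4e7), 1e6)
  bins$gc <- rep(0.45, 40)
  ct <- bin_counts("s", sample(500:1500, 40))
  res <- gc_correct(ct, bins)
  expect_equal(res$corrected, ct$counts)
})

test_that("GC correction flattens a known smooth bias", {
  sim <- sim_config(seed = 13L)
  bins <- simulate_bins(sim)  # 300 bins, spread of GC
  g <- gc_bias_curve(bins$gc, sim$gc_bias)
  ct <- bin_counts("s", round(5000 * g))  # pure bias, no noise
  res <- gc_correct(ct, bins)
  corr <- res$corrected[!res$masked]
  expect_lt(sd(corr) / mean(corr), 0.01)
  # rescaling preserves the mean count
  expect_equal(mean(corr), mean(ct$counts[!res$masked]), tolerance = 1e-9)

  # corrected depths are decorrelated from GC on noisy simulated libraries
  rhos <- vapply(1:20, function(r) {
    ct <- simulate_counts(NULL, bins, sim, tumor_fraction = 0,
                          seed = 480L + r)
    res <- gc_correct(ct, bins)
    u <- !res$masked
    cor(res$corrected[u], bins$gc[u], method = "spearman")
  }, numeric(1))
  expect_lt(median(abs(rhos)), 0.05)
})

test_that("GC correction masks unusable bins and needs enough of them", {
  bins <- tiny_bins(20L)  # 40 bins -> stratum-median fallback path
  bins$gc[1] <- 0.20   # outside usable range
  y <- rep(1000L, 40); y[2] <- 0L
  res <- gc_correct(bin_counts("s", y), bins)
  expect_true(res$masked[1] && res$masked[2])
  expect_true(all(is.na(res$corrected[res$masked])))

  small <- build_bins(c("1" = 2e7), 1e6)
  small$gc <- runif(20, 0.3, 0.6)
  expect_error(gc_correct(bin_counts("s", rep(100L, 20)), small),
               ">= 30 usable bins")
})

test_that("reference levels are per-bin cohort medians", {
  sim <- sim_config(seed = 17L)
  bins <- simulate_bins(sim)
  nb <- nrow(bins)

  # identical samples: every cohort profile sits at exactly x = 2
  coh <- flat_cohort(bins, n = 3L)
  ref <- build_reference(coh, bins, calibrate = FALSE)
  prof <- normalize_to_reference(coh[[1]], ref, bins)
  expect_equal(prof$x[!prof$masked], rep(2, sum(!prof$masked)),
               tolerance = 1e-12)

  # outlier bin in one sample: median resists it, matches brute force
  bins$gc <- rep(0.45, nb)  # identity GC path isolates the median logic
  counts <- list(rep(1000L, nb), rep(1000L, nb), rep(1000L, nb))
  counts[[2]][17] <- 50000L
  coh <- lapply(1:3, function(i) bin_counts(paste0("s", i), counts[[i]]))
  ref <- build_reference(coh, bins, calibrate = FALSE)
  frac <- vapply(coh, function(s) s$counts / sum(s$counts), numeric(nb))
  oracle <- apply(frac, 1L, median)
  expect_equal(ref$level[!ref$masked], oracle[!ref$masked],
               tolerance = 1e-12)
  expect_error(build_reference(coh[1], bins), ">= 2 samples")
})

test_that("bins zero in most of the cohort are masked", {
  bins <- tiny_bins(20L)
  coh <- flat_cohort(bins, n = 4L)
  for (i in c(1, 2, 3)) coh[[i]]$counts[5] <- 0  # zero in 3/4 samples
  ref <- build_reference(coh, bins, calibrate = FALSE)
  expect_true(ref$masked[5])
  expect_true(is.na(ref$level[5]))
})

test_that("normalization is scale invariant and diploid anchored", {
  sim <- sim_config(seed = 19L)
  bins <- simulate_bins(sim)
  coh <- simulate_healthy_cohort(10L, bins, sim)
  ref <- build_reference(coh, bins, calibrate = FALSE)

  ct <- simulate_counts(NULL, bins, sim, tumor_fraction = 0, seed = 901L)
  p1 <- normalize_to_reference(ct, ref, bins)
  scaled <- bin_counts(ct$sample_id, ct$counts * 7L)
  p2 <- normalize_to_reference(scaled, ref, bins)
  expect_equal(p1$x, p2$x, tolerance = 1e-9)

  # healthy-null calibration: median x stays close to 2 across samples
  med <- vapply(1:30, function(r) {
    p <- normalize_to_reference(
      simulate_counts(NULL, bins, sim, tumor_fraction = 0,
                      seed = 2000L + r), ref, bins)
    median(p$x[!p$masked])
  }, numeric(1))
  expect_gte(median(med), 1.96)
  expect_lte(median(med), 2.04)
})

test_that("a doubled chromosome normalizes to relative copy four", {
  # one small chromosome (2.5% of the genome) gained to copy 4 at tf = 1:
  # its bins double in depth and x lands near 4
  lens <- c("1" = 1.95e8, "2" = 5e6)
  sim <- sim_config(chrom_lengths = lens, total_reads = 1e6,
                    overdispersion = 0,
                    gc_bias = list(amplitude = 0, peak = 0.45, width = 0.12),
                    tumor_fraction = 1, seed = 23L)
  bins <- simulate_bins(sim)
  ref <- build_reference(simulate_healthy_cohort(10L, bins, sim), bins,
                         calibrate = FALSE)
  truth <- structure(list(
    cn = ifelse(bins$chrom == "2", 4, 2), events = data.frame()),
    class = "scna_truth")
  med4 <- vapply(1:10, function(r) {
    p <- normalize_to_reference(
      simulate_counts(truth, bins, sim, seed = 300L + r), ref, bins)
    median(p$x[bins$chrom == "2" & !p$masked])
  }, numeric(1))
  expect_lt(abs(mean(med4) / 4 - 1), 0.03)
})

test_that("tiny relative depths clamp at the x floor", {
  bins <- tiny_bins(20L)
  bins$gc <- rep(0.45, 40)  # identity GC path keeps the arithmetic exact
  coh <- flat_cohort(bins, n = 3L, level = 10000L)
  for (s in seq_along(coh)) coh[[s]]$counts[10] <- 2000000L
  ref <- build_reference(coh, bins, calibrate = FALSE)
  ct <- bin_counts("s", ifelse(seq_len(40) == 10, 1000L, 10000L))
  prof <- normalize_to_reference(ct, ref, bins)
  expect_equal(prof$x[10], 0.01)
  expect_true(attr(prof, "clamped")[10])
  expect_error(normalize_to_reference(
    ct, healthy_reference(rep(0.1, 5), rep(FALSE, 5)), bins),
    "bin-grid mismatch")
})
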