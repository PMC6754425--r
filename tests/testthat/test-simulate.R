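test_that("SCNA truth painting matches an interval oracle", {
  sim <- sim_config(seed = 7L)
  bins <- simulate_bins(sim)

  flat <- simulate_scna_truth(bins, sim_config(n_events = 0L))
  expect_equal(flat$cn, rep(2, nrow(bins)))
  expect_equal(nrow(flat$events), 0L)

  # single whole-chromosome gain on a one-chromosome genome
  one <- sim_config(chrom_lengths = c("5" = 3e7), n_events = 1L,
                    event_bins = c(30L, 30L), event_cn = 4, seed = 3L)
  b1 <- simulate_bins(one)
  tr <- simulate_scna_truth(b1, one)
  expect_equal(tr$cn, rep(4, 30))

  # 5 events, re-painted by brute force from the event list
  cfg5 <- sim_config(n_events = 5L, seed = 7L)
  tr <- simulate_scna_truth(bins, cfg5)
  expect_equal(nrow(tr$events), 5L)
  oracle <- rep(2, nrow(bins))
  for (r in seq_len(nrow(tr$events)))
    oracle[tr$events$start_bin[r]:tr$events$end_bin[r]] <- tr$events$cn[r]
  expect_equal(tr$cn, oracle)
  # events are disjoint
  spans <- unlist(lapply(seq_len(nrow(tr$events)), function(r)
    tr$events$start_bin[r]:tr$events$end_bin[r]))
  expect_equal(anyDuplicated(spans), 0L)

  expect_error(simulate_scna_truth(
    bins, sim_config(n_events = 1L, event_bins = c(200L, 200L))),
    "exceeds every chromosome")
})

test_that("count simulation is deterministic and mean-correct", {
  sim <- sim_config(seed = 5L)
  bins <- simulate_bins(sim)
  a <- simulate_counts(NULL, bins, sim, seed = 11L)
  b <- simulate_counts(NULL, bins, sim, seed = 11L)
  expect_identical(a$counts, b$counts)
  expect_false(identical(
    a$counts, simulate_counts(NULL, bins, sim, seed = 12L)$counts))

  # null model: tf = 0, flat bias, Poisson -> per-bin mean ~ total/n
  null_sim <- sim_config(gc_bias = list(amplitude = 0, peak = 0.45,
                                        width = 0.12),
                         overdispersion = 0, total_reads = 3e5, seed = 2L)
  nb <- nrow(bins)
  reps <- vapply(1:200, function(r)
    simulate_counts(NULL, bins, null_sim, seed = 100L + r)$counts,
    numeric(nb))
  mu <- 3e5 / nb
  se <- sqrt(mu / 200)
  expect_true(all(abs(rowMeans(reps) - mu) < 5 * se))

  # closed-form expectation: tf = 1, one bin at copy 4 doubles its depth
  tr <- structure(list(cn = c(4, rep(2, nb - 1)),
                       events = data.frame()), class = "scna_truth")
  gain_sim <- sim_config(gc_bias = list(amplitude = 0, peak = 0.45,
                                        width = 0.12),
                         overdispersion = 0, total_reads = 1e6,
                         tumor_fraction = 1, seed = 3L)
  counts <- vapply(1:20, function(r)
    simulate_counts(tr, bins, gain_sim, seed = 200L + r)$counts,
    numeric(nb))
  ratio <- mean(counts[1, ]) / mean(counts[-1, ])
  expect_lt(abs(ratio / 2 - 1), 0.03)
})

test_that("healthy cohorts are reproducible element-wise", {
  sim <- sim_config(seed = 9L)
  bins <- simulate_bins(sim)
  expect_error(simulate_healthy_cohort(1L, bins, sim), "n >= 2")
  coh <- simulate_healthy_cohort(5L, bins, sim)
  expect_length(coh$samples, 5L)
  # per-sample seed derivation: sample i depends only on (seed, i)
  again <- simulate_counts(NULL, bins, sim, tumor_fraction = 0,
                           sample_id = "healthy_003", seed = sim$seed + 3L)
  expect_identical(coh$samples[[3]]$counts, again$counts)
  expect_equal(dim(coh$count_matrix), c(nrow(bins), 5L))
  expect_equal(coh$median_counts, apply(coh$count_matrix, 1, median))
})

test_that("timelines share one truth and vary only tumor fraction", {
  sim <- sim_config(seed = 21L)
  bins <- simulate_bins(sim)
  truth <- simulate_scna_truth(bins, sim)
  expect_error(simulate_timeline(data.frame(), truth, bins, sim), "empty")
  expect_error(simulate_timeline(
    data.frame(label = "PR", tumor_fraction = 0), truth, bins, sim),
    "must be BL")
  expect_error(simulate_timeline(
    data.frame(label = c("BL", "CR"), tumor_fraction = c(0.2, 0)),
    truth, bins, sim), "unknown timepoint")

  sc <- data.frame(label = c("BL", "PR", "PD"),
                   tumor_fraction = c(0.3, 0.3, 0.3))
  tl <- simulate_timeline(sc, truth, bins, sim, seed = 40L)
  expect_length(tl, 3L)
  # equal tumor fractions -> timepoints exchangeable up to their seeds:
  # regenerating timepoint 2 with timepoint 3's seed reproduces timepoint 3
  redo <- simulate_counts(truth, bins, sim, tumor_fraction = 0.3,
                          seed = 40L + 3L)
  expect_identical(tl[[3]]$counts$counts, redo$counts)
})

test_that("median CNI rises with tumor fraction on a fixed truth", {
  cfg <- quick_config()
  sim <- sim_config(seed = 31L)
  bins <- simulate_bins(sim)
  ref <- build_reference(simulate_healthy_cohort(20L, bins, sim), bins,
                         config = cfg)
  truth <- simulate_scna_truth(bins, sim)
  med <- vapply(c(0, 0.1, 0.2, 0.4), function(tf)
    median(vapply(1:8, function(r)
      score_sample(simulate_counts(truth, bins, sim, tumor_fraction = tf,
                                   sample_id = "t", seed = 600L + 37L * r),
                   bins, ref, cfg)$score, numeric(1))), numeric(1))
  expect_true(all(diff(med) > 0))
})

test_that("a cleared tumor scores like healthy plasma", {
  # responder at PR with tumor fraction 0: the CNI score distribution is
  # indistinguishable from fresh healthy samples
  cfg <- quick_config()
  sim <- sim_config(seed = 61L)
  bins <- simulate_bins(sim)
  ref <- build_reference(simulate_healthy_cohort(40L, bins, sim), bins,
                         config = cfg)
  truth <- simulate_scna_truth(bins, sim)
  sc <- data.frame(label = c("BL", "PR"), tumor_fraction = c(0.3, 0))
  pr <- vapply(1:25, function(r) {
    tl <- simulate_timeline(sc, truth, bins, sim, seed = 3000L + 7L * r)
    score_sample(tl[[2]]$counts, bins, ref, cfg)$score
  }, numeric(1))
  healthy <- vapply(1:25, function(r)
    score_sample(simulate_counts(NULL, bins, sim, tumor_fraction = 0,
                                 sample_id = "h", seed = 5000L + 11L * r),
                 bins, ref, cfg)$score, numeric(1))
  expect_gt(wilcox.test(pr, healthy)$p.value, 0.01)
  # and well below a baseline tumor sample
  bl <- score_sample(simulate_counts(truth, bins, sim, tumor_fraction = 0.3,
                                     sample_id = "bl", seed = 77L),
                     bins, ref, cfg)$score
  expect_gt(bl, max(pr))
})
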