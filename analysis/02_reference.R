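#!/usr/bin/env Rscript

# Stage 2: build the healthy reference and the CIN cutoff.
#
# Per-bin reference levels are cross-sample medians of GC-corrected count
# fractions; the cohort is then re-scored leave-one-out through the full
# pipeline to calibrate the CNI score distribution of healthy plasma, and
# the classification cutoff is its mean + SD.

suppressPackageStartupMessages(library(cnipipe))

simdir <- "results/sim"
bins <- load_bins(file.path(simdir, "bins.tsv"))
files <- list.files(simdir, pattern = "^healthy_\\d+\\.tsv$",
                    full.names = TRUE)
stopifnot(length(files) >= 2L)
cohort <- lapply(files, load_bin_counts, bins = bins)
message("loaded ", length(cohort), " healthy samples")

cfg <- default_config()
ref <- build_reference(cohort, bins, config = cfg)
save_reference(ref, bins, "results/reference.tsv")

scores <- attr(ref, "cohort_scores")
message(sprintf("cohort CNI: %.2f +/- %.2f  ->  cutoff %.2f",
                ref$cohort_cni_mean, ref$cohort_cni_sd, ref$cutoff))
message(sprintf("%d of %d bins masked; %d cohort members above the cutoff",
                sum(ref$masked), length(ref$masked),
                sum(scores > ref$cutoff)))
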