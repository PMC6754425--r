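#!/usr/bin/env Rscript

# Stage 1: simulate the study material.
#
# One fixed 1000-kb autosomal bin grid with a GC track; a 100-donor healthy
# cfDNA cohort (~5M reads each); and a small panel of tumor patients with
# longitudinal plasma samples (baseline + on-treatment timepoints), each
# patient carrying a fixed SCNA truth whose ctDNA amplitude follows the
# clinical course. Everything is written as plain TSV under results/sim/.

suppressPackageStartupMessages(library(cnipipe))

out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 2024L

sim <- sim_config(seed = seed)
bins <- simulate_bins(sim)
save_bins(bins, file.path(out, "bins.tsv"))
message("grid: ", nrow(bins), " bins of ", sim$bin_width / 1e3, " kb on ",
        length(unique(bins$chrom)), " chromosomes")

cohort <- simulate_healthy_cohort(100L, bins, sim)
for (s in cohort$samples)
  save_bin_counts(s, bins, file.path(out, paste0(s$sample_id, ".tsv")))
message("healthy cohort: ", length(cohort$samples), " samples written")

scenarios <- list(
  pt01 = data.frame(label = c("BL", "PR", "SD", "PD"),
                    tumor_fraction = c(0.30, 0.02, 0.10, 0.20)),
  pt02 = data.frame(label = c("BL", "PR", "PD"),
                    tumor_fraction = c(0.25, 0.03, 0.18)),
  pt03 = data.frame(label = c("BL", "SD", "SD"),
                    tumor_fraction = c(0.15, 0.12, 0.10)),
  pt04 = data.frame(label = c("BL", "PD"),
                    tumor_fraction = c(0.20, 0.35)),
  pt05 = data.frame(label = c("BL", "PR", "SD"),
                    tumor_fraction = c(0.35, 0.01, 0.05)))

manifest <- list()
for (pid in names(scenarios)) {
  psim <- sim_config(seed = seed + match(pid, names(scenarios)))
  truth <- simulate_scna_truth(bins, psim)
  series <- simulate_timeline(scenarios[[pid]], truth, bins, sim,
                              patient_id = pid,
                              seed = seed + 1000L * match(pid, names(scenarios)))
  write.table(
    data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
               true_cn = truth$cn),
    file.path(out, paste0(pid, "_truth.tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE)
  for (tp in series)
    save_bin_counts(tp$counts, bins,
                    file.path(out, paste0(tp$counts$sample_id, ".tsv")))
  manifest[[pid]] <- scenarios[[pid]]
  message(pid, ": ", nrow(scenarios[[pid]]), " timepoints, ",
          nrow(truth$events), " SCNA events")
}

yaml::write_yaml(lapply(manifest, function(m)
  list(label = m$label, tumor_fraction = m$tumor_fraction)),
  file.path(out, "scenarios.yaml"))
message("scenario manifest written to ", file.path(out, "scenarios.yaml"))
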