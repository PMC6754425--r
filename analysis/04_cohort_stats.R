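#!/usr/bin/env Rscript

# Stage 4: cohort-level statistics.
#
# Two analyses. First, the published 55-patient baseline cohort (its
# per-patient CIN calls and best responses are printed in the study and
# used here as inputs): association of pretherapeutic chromosomal
# instability with response by Pearson chi-square, plus response rates.
# Second, the simulated longitudinal panel from stages 1-3: trajectory
# summaries against the simulated cutoff. Results go to
# results/cohort_stats.json.

suppressPackageStartupMessages(library(cnipipe))

## published baseline cohort
cin <- c(rep("CIN", 27), rep("CNS", 28))
rsp <- c(rep("PR", 16), rep("SD", 10), "PD",
         rep("PR", 9), rep("SD", 16), rep("PD", 3))
tab <- build_table(cin, rsp)
chi <- pearson_chi2(tab)
rr <- response_rates(tab)
message(sprintf("published cohort: chi2 = %.3f (df %d), p = %.3f",
                chi$statistic, chi$df, chi$p_value))
message(sprintf("response rate, CIN: %d%% (%d/%d); CNS: %d%% (%d/%d)",
                rr$percent[1], rr$responders[1], rr$n[1],
                rr$percent[2], rr$responders[2], rr$n[2]))

## simulated longitudinal panel
scores <- read.delim("results/scores.tsv")
ref <- load_reference("results/reference.tsv")
timelines <- lapply(split(scores, scores$patient), function(df) {
  df <- df[order(df$timepoint), ]
  patient_timeline(df$patient[1], df$label, df$cni_score, ref$cutoff)
})
summ <- trajectory_summary(timelines, ref$cutoff)
message(sprintf("simulated panel: %d/%d PR timepoints below the cutoff",
                summ$pr_below_cutoff$k, summ$pr_below_cutoff$n))
message(sprintf("                 %d/%d PD timepoints re-elevated",
                summ$pd_elevated$k, summ$pd_elevated$n))
message(sprintf("                 %d/%d PD scores under their baseline",
                summ$pd_below_baseline$k, summ$pd_below_baseline$n))

jsonlite::write_json(
  list(published = list(table = unclass(tab)[1:2, 1:2],
                        chi2 = chi, response_rates = rr),
       simulated = list(cutoff = ref$cutoff, trajectory_summary = summ)),
  "results/cohort_stats.json", auto_unbox = TRUE, digits = NA,
  dataframe = "rows")
message("report written to results/cohort_stats.json")
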