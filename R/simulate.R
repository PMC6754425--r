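# Synthetic cfDNA data generator: healthy cohorts and tumor-patient
# longitudinal series over a configurable autosome model. The defaults give
# a desk-scale genome (4 pseudo-autosomes, 300 x 1000 kb bins) at the
# study-scale depth of 5 million reads per sample.

# Derive a decoupled child seed from (seed, purpose index). Streams seeded
# with nearby integers can be mutually correlated, which couples e.g. the
# GC track with sample noise and distorts cohort score distributions, so
# every consumer mixes its seed through this integer hash (splitmix-style
# multiply-xor-shift, folded into [0, 2^31)).
mix_seed <- function(seed, k) {
  x <- (as.double(seed) * 2654435761 + as.double(k) * 40503 + 12345) %%
    2147483647
  x <- (x * 48271) %% 2147483647
  as.integer(x)
}

# run expr under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Simulation configuration
#'
#' Collects every knob of the generative model. Expected read depth defaults
#' to 5 million reads per sample; the default genome is a scaled-down model
#' of 4 pseudo-autosomes totalling 300 Mb (300 bins of 1000 kb) so the full
#' pipeline runs in seconds, with [hg19_autosome_lengths] available for
#' full-scale runs.
#'
#' @param chrom_lengths named vector of autosome lengths in bp.
#' @param bin_width bin width in bp.
#' @param total_reads expected reads per sample.
#' @param gc_bias list with `amplitude` in `[0,1)`, `peak`, `width`: the
#'   smooth unimodal GC bias curve
#'   `bias(g) = (1 - amplitude) + amplitude * exp(-((g-peak)/width)^2 / 2)`.
#'   `amplitude = 0` gives a flat (bias-free) library.
#' @param overdispersion negative-binomial excess-variance coefficient
#'   `phi >= 0` (variance = mu + phi * mu^2); 0 gives Poisson counts.
#' @param tumor_fraction default ctDNA tumor fraction in `[0,1]`.
#' @param n_events number of segmental SCNA events for simulated tumors.
#' @param event_bins integer range (min, max) of event lengths in bins.
#' @param event_cn copy-number states events are drawn from (diploid = 2);
#'   the defaults are pronounced single-copy losses and one- to two-copy
#'   gains, the large-scale event amplitudes instable tumor genomes show.
#' @param gc_mean,gc_sd per-bin GC fractions are drawn i.i.d. from a normal
#'   with these parameters, clamped to `[0.30, 0.65]`.
#' @param seed base RNG seed; per-sample seeds are derived as seed + index.
#' @return A `sim_config` list.
#' @export
sim_config <- function(chrom_lengths = c("1" = 90e6, "2" = 80e6,
                                         "3" = 70e6, "4" = 60e6),
                       bin_width = 1e6,
                       total_reads = 5e6,
                       gc_bias = list(amplitude = 0.3, peak = 0.45,
                                      width = 0.12),
                       overdispersion = 0.01,
                       tumor_fraction = 0,
                       n_events = 4L,
                       event_bins = c(15L, 40L),
                       event_cn = c(1, 3, 4),
                       gc_mean = 0.45, gc_sd = 0.05,
                       seed = 1L) {
  stopifnot(overdispersion >= 0, tumor_fraction >= 0, tumor_fraction <= 1,
            total_reads >= 1, n_events >= 0,
            gc_bias$amplitude >= 0, gc_bias$amplitude < 1)
  structure(list(chrom_lengths = chrom_lengths, bin_width = bin_width,
                 total_reads = total_reads, gc_bias = gc_bias,
                 overdispersion = overdispersion,
                 tumor_fraction = tumor_fraction,
                 n_events = as.integer(n_events),
                 event_bins = as.integer(event_bins),
                 event_cn = event_cn,
                 gc_mean = gc_mean, gc_sd = gc_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Full-scale simulation configuration
#'
#' [sim_config()] preset on the hg19 autosome grid (~2,900 bins of 1000 kb)
#' with eight arm-scale events of 40-120 Mb, the pattern scale instable
#' gastric tumor genomes show (large gains/losses on around eight
#' chromosomes). Slower than the 300-bin default; used for full-scale
#' reproductions rather than unit tests.
#'
#' @param seed base RNG seed.
#' @param ... further arguments passed to [sim_config()].
#' @return A `sim_config` list.
#' @export
sim_config_fullscale <- function(seed = 1L, ...) {
  sim_config(chrom_lengths = hg19_autosome_lengths,
             n_events = 8L, event_bins = c(40L, 120L), seed = seed, ...)
}

#' GC bias curve
#'
#' Smooth unimodal relative-efficiency curve, peaking near GC = 0.45 as in
#' typical low-coverage WGS libraries.
#' @param gc GC fraction(s).
#' @param gc_bias list with `amplitude`, `peak`, `width` (see [sim_config()]).
#' @return Positive multiplicative bias factor per bin.
#' @export
gc_bias_curve <- function(gc, gc_bias) {
  a <- gc_bias$amplitude
  (1 - a) + a * exp(-0.5 * ((gc - gc_bias$peak) / gc_bias$width)^2)
}

#' Simulate the bin grid (with GC track) for a configuration
#'
#' Deterministic given `config$seed`: the GC track is drawn once per
#' configuration, not per sample, mirroring a fixed reference genome.
#' @param config a `sim_config`.
#' @return A `genome_bins` object.
#' @export
simulate_bins <- function(config) {
  bins <- build_bins(config$chrom_lengths, config$bin_width)
  gc <- with_seed(mix_seed(config$seed, 101L),
                  rnorm(nrow(bins), config$gc_mean, config$gc_sd))
  bins$gc <- pmin(0.65, pmax(0.30, gc))
  bins
}

#' Simulate a segmental SCNA truth profile
#'
#' Paints `n_events` non-overlapping segmental gains/losses onto a diploid
#' genome (copy number 2 everywhere else). Event positions and lengths are
#' drawn uniformly; overlapping proposals are rejected and resampled
#' (bounded retries). Emulates the large-scale per-chromosome gain/loss
#' patterns seen in instable tumor genomes.
#'
#' @param bins the `genome_bins` grid.
#' @param config a `sim_config` (`n_events`, `event_bins`, `event_cn`, seed).
#' @return An `scna_truth` object: list with per-bin `cn` and the `events`
#'   data.frame (`chrom`, `start_bin`, `end_bin`, `cn`; bin indices are
#'   1-based into the grid, inclusive).
#' @export
simulate_scna_truth <- function(bins, config) {
  n <- nrow(bins)
  chrom_sizes <- table(bins$chrom)[unique(bins$chrom)]
  if (config$n_events > 0L && config$event_bins[1L] > max(chrom_sizes))
    stop("event length exceeds every chromosome (min event ",
         config$event_bins[1L], " bins, largest chromosome ",
         max(chrom_sizes), " bins)")
  cn <- rep(2, n)
  events <- data.frame(chrom = character(0), start_bin = integer(0),
                       end_bin = integer(0), cn = numeric(0))
  if (config$n_events > 0L) {
    covered <- logical(n)
    with_seed(mix_seed(config$seed, 202L), {
      placed <- 0L
      tries <- 0L
      while (placed < config$n_events && tries < 1000L) {
        tries <- tries + 1L
        pick1 <- function(v) v[sample.int(length(v), 1L)]
        len <- pick1(seq(config$event_bins[1L], config$event_bins[2L]))
        cl <- pick1(names(chrom_sizes))
        if (len > chrom_sizes[[cl]]) next
        offs <- sample.int(chrom_sizes[[cl]] - len + 1L, 1L)
        idx0 <- which(bins$chrom == cl)[1L] - 1L
        span <- (idx0 + offs):(idx0 + offs + len - 1L)
        if (any(covered[span])) next
        state <- config$event_cn[sample.int(length(config$event_cn), 1L)]
        covered[span] <- TRUE
        cn[span] <- state
        events <- rbind(events,
                        data.frame(chrom = cl, start_bin = span[1L],
                                   end_bin = span[length(span)], cn = state))
        placed <- placed + 1L
      }
      if (placed < config$n_events)
        warning("placed only ", placed, " of ", config$n_events,
                " events after bounded retries")
    })
  }
  structure(list(cn = cn, events = events), class = "scna_truth")
}

#' Simulate binned read counts for one sample
#'
#' The expected count of bin i is proportional to
#' `width_i * bias(gc_i) * mix_i`, with `mix_i = (1-tf)*2 + tf*truth_i`,
#' renormalized so the expectations sum to `total_reads`. Counts are drawn
#' from a negative binomial with variance `mu + phi*mu^2` (Poisson when
#' `phi = 0`). Masked bins receive zero counts. Deterministic given `seed`.
#'
#' @param truth an `scna_truth` (or `NULL` for a flat diploid genome).
#' @param bins the `genome_bins` grid.
#' @param config a `sim_config`.
#' @param tumor_fraction overrides `config$tumor_fraction` if given.
#' @param sample_id label for the sample.
#' @param seed overrides `config$seed` if given.
#' @return A `bin_counts` object.
#' @export
simulate_counts <- function(truth, bins, config,
                            tumor_fraction = config$tumor_fraction,
                            sample_id = "sim", seed = config$seed) {
  n <- nrow(bins)
  usable <- !bins$masked
  if (!any(usable)) stop("all bins are masked; nothing to simulate")
  tf <- tumor_fraction
  stopifnot(tf >= 0, tf <= 1)
  truth_cn <- if (is.null(truth)) rep(2, n) else truth$cn
  mix <- (1 - tf) * 2 + tf * truth_cn
  w <- (bins$end - bins$start) / config$bin_width
  mu <- w * gc_bias_curve(bins$gc, config$gc_bias) * mix
  mu[!usable] <- 0
  mu <- mu / sum(mu) * config$total_reads
  phi <- config$overdispersion
  counts <- with_seed(mix_seed(seed, 303L), {
    if (phi == 0) rpois(n, mu)
    else rnbinom(n, size = 1 / phi, mu = mu)
  })
  counts[!usable] <- 0
  bin_counts(sample_id, counts)
}

#' Simulate a healthy cfDNA cohort
#'
#' `n` tumor-free samples (tumor fraction 0) with per-sample seeds derived
#' as `config$seed + i`, mirroring the 100-donor healthy plasma panels used
#' to calibrate instability cutoffs.
#'
#' @param n cohort size (>= 2; default 100).
#' @param bins the `genome_bins` grid.
#' @param config a `sim_config`.
#' @return List with `samples` (list of `bin_counts`), `count_matrix`
#'   (bins x samples), and `median_counts` (per-bin cross-sample median).
#' @export
simulate_healthy_cohort <- function(n = 100L, bins, config) {
  if (n < 2L) stop("healthy cohort needs n >= 2 (SD undefined otherwise)")
  samples <- lapply(seq_len(n), function(i)
    simulate_counts(NULL, bins, config, tumor_fraction = 0,
                    sample_id = sprintf("healthy_%03d", i),
                    seed = config$seed + i))
  mat <- vapply(samples, function(s) s$counts, numeric(nrow(bins)))
  list(samples = samples, count_matrix = mat,
       median_counts = apply(mat, 1L, median))
}

#' Simulate a patient timeline of plasma samples
#'
#' All timepoints share a single SCNA truth — clone composition is fixed,
#' only the ctDNA tumor fraction changes — so a progression sample recapitulates
#' the baseline alteration pattern at a (typically lower) amplitude, the
#' behaviour reported for acquired-resistance plasmas.
#'
#' @param scenario data.frame with columns `label` (first row must be "BL";
#'   others in "PR", "SD", "PD") and `tumor_fraction`.
#' @param truth the shared `scna_truth`.
#' @param bins the `genome_bins` grid.
#' @param config a `sim_config`.
#' @param patient_id label used in sample ids and seed derivation.
#' @param seed base seed (default `config$seed`); timepoint t uses seed + t.
#' @return List of lists `(label, tumor_fraction, counts)` in timepoint order.
#' @export
simulate_timeline <- function(scenario, truth, bins, config,
                              patient_id = "pt", seed = config$seed) {
  if (nrow(scenario) == 0L) stop("empty timeline scenario")
  if (scenario$label[1L] != "BL")
    stop("first timepoint of a scenario must be BL (baseline)")
  bad <- setdiff(scenario$label, c("BL", "PR", "SD", "PD"))
  if (length(bad) > 0L)
    stop("unknown timepoint label(s): ", paste(bad, collapse = ", "))
  lapply(seq_len(nrow(scenario)), function(t) {
    list(label = scenario$label[t],
         tumor_fraction = scenario$tumor_fraction[t],
         counts = simulate_counts(truth, bins, config,
                                  tumor_fraction = scenario$tumor_fraction[t],
                                  sample_id = sprintf("%s_t%d_%s", patient_id,
                                                      t, scenario$label[t]),
                                  seed = seed + t))
  })
}
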