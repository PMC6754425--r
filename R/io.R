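# On-disk formats. All tables are tab-separated with '#' comment lines
# ignored; internal coordinates are 0-based half-open, SEG output is 1-based
# inclusive (IGV convention), BED input is 0-based half-open.

read_tsv_checked <- function(path, required_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required_cols, names(df))
  if (length(miss) > 0L)
    stop(path, ": malformed header, missing column(s): ",
         paste(miss, collapse = ", "))
  df
}

#' Write a bin grid sidecar TSV
#'
#' Columns `chrom start end gc masked`.
#' @param bins a `genome_bins` object.
#' @param path output path.
#' @export
save_bins <- function(bins, path) {
  validate_bins(bins)
  df <- as.data.frame(bins)[, c("chrom", "start", "end", "gc", "masked")]
  df$masked <- as.integer(df$masked)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a bin grid sidecar TSV
#' @param path file with columns `chrom start end gc masked`.
#' @return A `genome_bins` object.
#' @export
load_bins <- function(path) {
  df <- read_tsv_checked(path, c("chrom", "start", "end", "gc", "masked"))
  df$chrom <- as.character(df$chrom)
  df$masked <- as.logical(df$masked)
  class(df) <- c("genome_bins", "data.frame")
  validate_bins(df)
  df
}

#' Write per-sample bin counts as TSV
#'
#' Columns `chrom start end gc count`; the sample id and total reads are
#' stored in '#'-prefixed header comments.
#' @param counts a `bin_counts` object.
#' @param bins the `genome_bins` grid the counts live on.
#' @param path output path.
#' @export
save_bin_counts <- function(counts, bins, path) {
  stopifnot(inherits(counts, "bin_counts"))
  if (length(counts$counts) != nrow(bins))
    stop("bin-grid mismatch: counts have ", length(counts$counts),
         " bins, grid has ", nrow(bins))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# sample_id=", counts$sample_id),
               paste0("# total_reads=", format(counts$total_reads,
                                               scientific = FALSE))), con)
  df <- data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
                   gc = bins$gc, count = counts$counts)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' Read per-sample bin counts from TSV
#'
#' @param path file written by [save_bin_counts()] (or conforming to its
#'   dialect).
#' @param bins optional `genome_bins` grid to validate coordinates against.
#' @return A `bin_counts` object.
#' @export
load_bin_counts <- function(path, bins = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- readLines(path, n = 50L)
  sid <- sub("^# sample_id=", "", grep("^# sample_id=", hdr, value = TRUE))
  tot <- sub("^# total_reads=", "", grep("^# total_reads=", hdr, value = TRUE))
  df <- read_tsv_checked(path, c("chrom", "start", "end", "count"))
  neg <- which(df$count < 0)
  if (length(neg) > 0L)
    stop(path, ": negative count at data line ", neg[1L],
         " (chrom ", df$chrom[neg[1L]], ", start ", df$start[neg[1L]], ")")
  if (!is.null(bins)) {
    if (nrow(df) != nrow(bins) ||
        any(as.character(df$chrom) != bins$chrom) ||
        any(df$start != bins$start) || any(df$end != bins$end))
      stop(path, ": bin-grid mismatch against supplied grid")
  }
  bin_counts(if (length(sid) > 0L) sid[1L] else basename(path),
             df$count,
             total_reads = if (length(tot) > 0L) as.numeric(tot[1L])
                           else sum(df$count))
}

#' Read read-start positions from a 3-column BED file
#'
#' BED is 0-based half-open; only the start coordinate is used.
#' @param path BED file (`chrom start end`, no header).
#' @param sample_id sample label (defaults to the file name).
#' @return A `read_positions` object.
#' @export
load_reads <- function(path, sample_id = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = FALSE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop(path, ": BED needs >= 3 columns")
  read_positions(sample_id, chrom = sub("^chr", "", as.character(df[[1L]])),
                 pos = df[[2L]])
}

#' Write a segment set as an IGV SEG file
#'
#' Columns `ID chrom loc.start loc.end num.mark seg.mean`, coordinates
#' 1-based inclusive, `seg.mean` = mean log2(x/2) of the segment.
#' @param segments a `segment_set` (see [segment_profile()]).
#' @param path output path.
#' @param bins the `genome_bins` grid, used to translate bin indices to
#'   base-pair coordinates; may be omitted when the segment set already
#'   carries `loc_start`/`loc_end` columns.
#' @param sample_id ID column value (defaults to the segment set's sample).
#' @export
save_segments <- function(segments, path, bins = NULL, sample_id = NULL) {
  stopifnot(inherits(segments, "segment_set"))
  sid <- if (is.null(sample_id)) attr(segments, "sample_id") else sample_id
  if (is.null(sid)) sid <- "sample"
  if (!all(c("loc_start", "loc_end") %in% names(segments))) {
    if (is.null(bins))
      stop("save_segments needs `bins` to derive base-pair coordinates")
    segments$loc_start <- bins$start[segments$start_bin]
    segments$loc_end <- bins$end[segments$end_bin]
  }
  df <- data.frame(ID = sid, chrom = segments$chrom,
                   loc.start = sprintf("%d", as.integer(segments$loc_start + 1)),
                   loc.end = sprintf("%d", as.integer(segments$loc_end)),
                   num.mark = segments$n_bins,
                   seg.mean = segments$seg_log2)
  names(df) <- c("ID", "chrom", "loc.start", "loc.end", "num.mark", "seg.mean")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a copy-number profile as TSV
#'
#' Columns `chrom start end gc x masked`.
#' @param profile a `cn_profile` object.
#' @param bins its `genome_bins` grid.
#' @param path output path.
#' @export
save_profile <- function(profile, bins, path) {
  stopifnot(inherits(profile, "cn_profile"))
  df <- data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
                   gc = bins$gc, x = profile$x,
                   masked = as.integer(profile$masked))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# sample_id=", profile$sample_id),
               paste0("# smoothing=", profile$smoothing)), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' Read a copy-number profile TSV
#' @param path file written by [save_profile()].
#' @return A `cn_profile` object.
#' @export
load_profile <- function(path) {
  hdr <- readLines(path, n = 10L)
  sid <- sub("^# sample_id=", "", grep("^# sample_id=", hdr, value = TRUE))
  smo <- sub("^# smoothing=", "", grep("^# smoothing=", hdr, value = TRUE))
  df <- read_tsv_checked(path, c("chrom", "start", "end", "x", "masked"))
  cn_profile(if (length(sid) > 0L) sid[1L] else basename(path),
             x = df$x, masked = as.logical(df$masked),
             chrom = as.character(df$chrom),
             smoothing = if (length(smo) > 0L) smo[1L] else "raw")
}

#' Write a healthy reference (TSV + JSON sidecar)
#'
#' The per-bin reference levels go to `<path>`; the cohort CNI calibration
#' (mean, SD, n) goes to `<path>.json`.
#' @param reference a `healthy_reference` object.
#' @param bins its grid.
#' @param path output TSV path.
#' @export
save_reference <- function(reference, bins, path) {
  stopifnot(inherits(reference, "healthy_reference"))
  df <- data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
                   level = reference$level,
                   masked = as.integer(reference$masked))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(cohort_cni_mean = reference$cohort_cni_mean,
         cohort_cni_sd = reference$cohort_cni_sd,
         n_samples = reference$n_samples),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a healthy reference written by [save_reference()]
#' @param path the reference TSV path (its `.json` sidecar must sit beside it).
#' @return A `healthy_reference` object.
#' @export
load_reference <- function(path) {
  df <- read_tsv_checked(path, c("chrom", "start", "end", "level", "masked"))
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  healthy_reference(level = df$level, masked = as.logical(df$masked),
                    cohort_cni_mean = meta$cohort_cni_mean %||% NA_real_,
                    cohort_cni_sd = meta$cohort_cni_sd %||% NA_real_,
                    n_samples = meta$n_samples %||% NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a run configuration from YAML or JSON
#'
#' Validates the fields against the pipeline schema (bin_width, m, p,
#' cutoff, CBS parameters, seeds) before any stage runs.
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A named list merged over [default_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  validate_config(utils::modifyList(default_config(), cfg))
}

#' Default pipeline configuration
#'
#' Numeric defaults mirror the method's published parameters: 1000 kb bins,
#' percentile window m = 95, p = 99, CIN cutoff 56.60, CBS alpha 0.01 with
#' 1000 permutations and minimum segment width 3.
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(bin_width = 1e6, m = 95, p = 99, cutoff = 56.60,
       alpha = 0.01, n_perm = 1000L, min_width = 3L,
       z_source = "segmented", span = 0.3, seed = 1L)
}

validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!num1(cfg$bin_width) || cfg$bin_width < 1)
    stop("config: bin_width must be a positive number of bp")
  if (!num1(cfg$m) || !num1(cfg$p) || cfg$m < 0 || cfg$p > 100 ||
      cfg$m >= cfg$p)
    stop("config: need 0 <= m < p <= 100 (got m=", cfg$m, ", p=", cfg$p, ")")
  if (!num1(cfg$cutoff)) stop("config: cutoff must be a number")
  if (!num1(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha > 0.5)
    stop("config: alpha must lie in (0, 0.5]")
  if (!num1(cfg$n_perm) || cfg$n_perm < 100)
    stop("config: n_perm must be >= 100")
  if (!num1(cfg$min_width) || cfg$min_width < 1)
    stop("config: min_width must be >= 1")
  if (!cfg$z_source %in% c("segmented", "raw"))
    stop("config: z_source must be 'segmented' or 'raw'")
  if (!num1(cfg$span) || cfg$span <= 0 || cfg$span > 1)
    stop("config: span must lie in (0, 1]")
  cfg
}
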