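#' @useDynLib cnipipe, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats lowess mad median pchisq quantile rnbinom rnorm rpois
#'   runif sd cor rmultinom
#' @importFrom utils read.delim write.table
NULL

AUTOSOME_LABELS <- as.character(1:22)

#' hg19 autosome lengths
#'
#' Named vector of GRCh37/hg19 autosome lengths in base pairs (chromosomes
#' "1".."22"), totalling about 2.88 Gb. Used as the full-scale genome model;
#' any other autosome length table can be supplied instead.
#'
#' @format Named numeric vector of length 22.
#' @export
hg19_autosome_lengths <- c(
  "1" = 249250621, "2" = 243199373, "3" = 198022430, "4" = 191154276,
  "5" = 180915260, "6" = 171115067, "7" = 159138663, "8" = 146364022,
  "9" = 141213431, "10" = 135534747, "11" = 135006516, "12" = 133851895,
  "13" = 115169878, "14" = 107349540, "15" = 102531392, "16" = 90354753,
  "17" = 81195210, "18" = 78077248, "19" = 59128983, "20" = 63025520,
  "21" = 48129895, "22" = 51304566
)

#' Build a fixed-width autosomal bin grid
#'
#' Tiles each chromosome with non-overlapping windows of `bin_width` base
#' pairs (the last bin of a chromosome may be shorter). The grid is the
#' coordinate frame for all downstream counting, normalization, segmentation
#' and scoring. Coordinates are 0-based half-open.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp;
#'   names must be autosome labels ("1".."22").
#' @param bin_width bin width in bp (default 1e6, i.e. 1000 kb).
#' @param gc per-bin GC fraction in `[0,1]`: either a numeric vector with one
#'   value per bin (in grid order), or `NULL` to leave the track as `NA`
#'   (to be filled by a simulator or loaded from a sidecar file).
#' @return A `genome_bins` object: a data.frame with columns `chrom`,
#'   `start`, `end`, `gc`, `masked`.
#' @export
build_bins <- function(chrom_lengths, bin_width = 1e6, gc = NULL) {
  if (length(chrom_lengths) == 0L)
    stop("chrom_lengths must be non-empty")
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width < 1)
    stop("bin_width must be a positive integer number of base pairs")
  labs <- names(chrom_lengths)
  if (is.null(labs) || any(!nzchar(labs)))
    stop("chrom_lengths must be a named vector")
  bad <- setdiff(labs, AUTOSOME_LABELS)
  if (length(bad) > 0L)
    stop("non-autosomal chromosome label(s) rejected: ",
         paste(bad, collapse = ", "),
         " (only autosomes \"1\"..\"22\" are supported)")
  if (any(chrom_lengths < 1)) stop("chromosome lengths must be >= 1 bp")

  pieces <- lapply(labs, function(cl) {
    len <- chrom_lengths[[cl]]
    n <- ceiling(len / bin_width)
    start <- (seq_len(n) - 1) * bin_width
    end <- pmin(start + bin_width, len)
    data.frame(chrom = cl, start = start, end = end,
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, pieces)
  if (is.null(gc)) {
    bins$gc <- NA_real_
  } else {
    if (length(gc) != nrow(bins))
      stop("gc track length (", length(gc), ") does not match bin count (",
           nrow(bins), ")")
    if (any(!is.na(gc) & (gc < 0 | gc > 1)))
      stop("gc fractions must lie in [0,1]")
    bins$gc <- as.numeric(gc)
  }
  bins$masked <- FALSE
  rownames(bins) <- NULL
  class(bins) <- c("genome_bins", "data.frame")
  validate_bins(bins)
  bins
}

validate_bins <- function(bins) {
  stopifnot(inherits(bins, "data.frame"))
  need <- c("chrom", "start", "end", "gc", "masked")
  miss <- setdiff(need, names(bins))
  if (length(miss) > 0L)
    stop("bin grid missing column(s): ", paste(miss, collapse = ", "))
  for (cl in unique(bins$chrom)) {
    b <- bins[bins$chrom == cl, ]
    if (is.unsorted(b$start, strictly = TRUE))
      stop("bins on chromosome ", cl, " are not sorted")
    if (any(b$end <= b$start))
      stop("empty bin on chromosome ", cl)
    if (nrow(b) > 1L && any(b$start[-1L] != b$end[-nrow(b)]))
      stop("bins on chromosome ", cl, " are not contiguous")
  }
  invisible(bins)
}

#' @export
print.genome_bins <- function(x, ...) {
  cat(sprintf("<genome_bins> %d bins on %d chromosome(s), %d masked\n",
              nrow(x), length(unique(x$chrom)), sum(x$masked)))
  invisible(x)
}

n_bins <- function(bins) nrow(bins)

#' Construct a per-sample bin-count vector
#'
#' @param sample_id sample label.
#' @param counts non-negative integer vector, one entry per bin of the grid.
#' @param total_reads total input reads (defaults to `sum(counts)`); must be
#'   at least `sum(counts)` — the difference is reads discarded upstream.
#' @return A `bin_counts` object.
#' @export
bin_counts <- function(sample_id, counts, total_reads = sum(counts)) {
  counts <- as.numeric(counts)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  if (total_reads < sum(counts))
    stop("total_reads (", total_reads, ") < sum of counts (", sum(counts), ")")
  structure(list(sample_id = as.character(sample_id), counts = counts,
                 total_reads = total_reads),
            class = "bin_counts")
}

#' @export
print.bin_counts <- function(x, ...) {
  cat(sprintf("<bin_counts> sample %s: %d bins, %s reads binned\n",
              x$sample_id, length(x$counts),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' Count read start positions into the bin grid
#'
#' Each read is assigned to exactly one bin by its 0-based start position
#' (half-open bin intervals). Reads on chromosomes absent from the grid are
#' rejected; reads beyond the chromosome end are dropped and tallied.
#'
#' @param reads a `read_positions` object (see [read_positions()]).
#' @param bins a `genome_bins` grid.
#' @return A `bin_counts` object with attribute `discarded` holding the
#'   number of out-of-range reads dropped.
#' @export
count_reads_in_bins <- function(reads, bins) {
  stopifnot(inherits(reads, "read_positions"), inherits(bins, "genome_bins"))
  bad <- setdiff(unique(reads$records$chrom), unique(bins$chrom))
  if (length(bad) > 0L)
    stop("reads on chromosome(s) absent from the grid: ",
         paste(bad, collapse = ", "))
  counts <- numeric(nrow(bins))
  discarded <- 0L
  for (cl in unique(reads$records$chrom)) {
    pos <- reads$records$pos[reads$records$chrom == cl]
    idx <- which(bins$chrom == cl)
    chrom_end <- max(bins$end[idx])
    drop <- pos < 0 | pos >= chrom_end
    discarded <- discarded + sum(drop)
    pos <- pos[!drop]
    bi <- findInterval(pos, bins$start[idx], rightmost.closed = FALSE)
    tab <- tabulate(bi, nbins = length(idx))
    counts[idx] <- counts[idx] + tab
  }
  out <- bin_counts(reads$sample_id, counts,
                    total_reads = sum(counts) + discarded)
  attr(out, "discarded") <- as.integer(discarded)
  out
}

#' Construct a read-position set
#'
#' @param sample_id sample label.
#' @param chrom chromosome label per read.
#' @param pos 0-based start position per read.
#' @return A `read_positions` object.
#' @export
read_positions <- function(sample_id, chrom, pos) {
  if (length(chrom) != length(pos))
    stop("chrom and pos must have equal length")
  structure(list(sample_id = as.character(sample_id),
                 records = data.frame(chrom = as.character(chrom),
                                      pos = as.numeric(pos),
                                      stringsAsFactors = FALSE)),
            class = "read_positions")
}
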