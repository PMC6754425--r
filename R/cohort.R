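# Cohort-level association of baseline CIN status with therapy response,
# and longitudinal trajectory summaries.

#' Build the 2x2 response contingency table
#'
#' Rows are the baseline instability call (CIN, CNS); columns dichotomize
#' RECIST response into responder (PR) versus non-responder (SD or PD).
#'
#' @param baseline_labels per-patient `"CIN"`/`"CNS"` (named or in the same
#'   order as `responses`).
#' @param responses per-patient RECIST best response: `"PR"`, `"SD"`, `"PD"`.
#' @return A `cohort_table`: 2x2 integer matrix (rows CIN, CNS; columns
#'   responder, non_responder) with the raw 2x3 table as attribute `raw`.
#' @export
build_table <- function(baseline_labels, responses) {
  if (length(baseline_labels) == 0L) stop("empty cohort")
  if (length(baseline_labels) != length(responses))
    stop("baseline_labels and responses must cover the same patients")
  bad <- setdiff(unique(baseline_labels), c("CIN", "CNS"))
  if (length(bad) > 0L) stop("unknown instability label(s): ",
                             paste(bad, collapse = ", "))
  bad <- setdiff(unique(responses), c("PR", "SD", "PD"))
  if (length(bad) > 0L) stop("unknown response label(s): ",
                             paste(bad, collapse = ", "))
  lab <- factor(baseline_labels, levels = c("CIN", "CNS"))
  rsp <- factor(responses, levels = c("PR", "SD", "PD"))
  raw <- table(lab, rsp)
  tab <- cbind(responder = raw[, "PR"],
               non_responder = raw[, "SD"] + raw[, "PD"])
  tab <- matrix(as.integer(tab), 2L, 2L,
                dimnames = list(c("CIN", "CNS"),
                                c("responder", "non_responder")))
  if (any(colSums(tab) == 0L))
    attr(tab, "untestable") <- TRUE
  attr(tab, "raw") <- unclass(raw)
  class(tab) <- c("cohort_table", class(tab))
  tab
}

#' Pearson chi-square test on a 2x2 table
#'
#' Statistic `sum((O - E)^2 / E)` without continuity correction (equivalent
#' closed form `n (ad - bc)^2 / (r1 r2 c1 c2)`), df = 1, p-value from the
#' upper tail of the chi-square distribution.
#'
#' @param table 2x2 matrix of counts with positive margins.
#' @param correct apply the Yates continuity correction (off by default).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
pearson_chi2 <- function(table, correct = FALSE) {
  tab <- unclass(table)[1:2, 1:2, drop = FALSE]
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("chi-square test undefined: zero row or column margin")
  n <- sum(tab)
  E <- outer(rowSums(tab), colSums(tab)) / n
  dev <- abs(tab - E)
  if (correct) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / E)
  list(statistic = stat, df = 1L,
       p_value = pchisq(stat, df = 1L, lower.tail = FALSE))
}

#' Per-row response rates
#'
#' @param table a 2x2 `cohort_table` (rows CIN, CNS).
#' @return Data.frame with `group`, `responders`, `n`, `rate` (proportion)
#'   and `percent` (rounded to the nearest integer for display).
#' @export
response_rates <- function(table) {
  tab <- unclass(table)[1:2, 1:2, drop = FALSE]
  rs <- rowSums(tab)
  if (any(rs == 0)) stop("response rate undefined for an empty row")
  rate <- tab[, 1L] / rs
  data.frame(group = rownames(tab) %||% c("CIN", "CNS"),
             responders = as.integer(tab[, 1L]), n = as.integer(rs),
             rate = as.numeric(rate), percent = round(100 * rate),
             row.names = NULL)
}

#' Construct a patient timeline
#'
#' @param patient_id patient label.
#' @param labels RECIST timepoint labels; the first must be `"BL"`.
#' @param scores CNI score at each timepoint.
#' @param cutoff classification cutoff used for per-timepoint CIN/CNS calls.
#' @return A `patient_timeline` data.frame (`timepoint`, `label`, `score`,
#'   `cin_label`).
#' @export
patient_timeline <- function(patient_id, labels, scores,
                             cutoff = DEFAULT_CNI_CUTOFF) {
  if (length(labels) == 0L) stop("empty timeline")
  if (labels[1L] != "BL")
    stop("timeline for ", patient_id, " must start at BL")
  bad <- setdiff(labels, c("BL", "PR", "SD", "PD"))
  if (length(bad) > 0L) stop("unknown timepoint label(s): ",
                             paste(bad, collapse = ", "))
  if (any(scores < 0)) stop("CNI scores must be non-negative")
  df <- data.frame(timepoint = seq_along(labels), label = labels,
                   score = as.numeric(scores),
                   cin_label = vapply(scores, classify_cni, "", cutoff))
  attr(df, "patient_id") <- as.character(patient_id)
  class(df) <- c("patient_timeline", "data.frame")
  df
}

#' Longitudinal trajectory summary
#'
#' Across a set of patient timelines, computes
#' (a) among patients with a PR timepoint, the fraction whose CNI score at
#' (first) PR is below the cutoff — "reduced to the level of chromosomal
#' stability";
#' (b) among patients with a PD timepoint, the fraction whose CNI at PD is
#' strictly above the immediately preceding timepoint's — "elevated again";
#' (c) among patients with both BL and PD, the fraction with CNI(PD) below
#' CNI(BL) — progression scores typically stay under the pretherapeutic
#' level.
#'
#' @param timelines list of `patient_timeline` objects.
#' @param cutoff classification cutoff for (a).
#' @return List of three records `pr_below_cutoff`, `pd_elevated`,
#'   `pd_below_baseline`, each with `k` (numerator), `n` (denominator) and
#'   `fraction`.
#' @export
trajectory_summary <- function(timelines, cutoff = DEFAULT_CNI_CUTOFF) {
  if (length(timelines) == 0L) stop("no timelines supplied")
  for (tl in timelines)
    if (tl$label[1L] != "BL") stop("every timeline must start at BL")
  frac <- function(k, n) list(k = k, n = n,
                              fraction = if (n > 0L) k / n else NA_real_)
  a_n <- 0L; a_k <- 0L
  b_n <- 0L; b_k <- 0L
  c_n <- 0L; c_k <- 0L
  for (tl in timelines) {
    ipr <- which(tl$label == "PR")
    if (length(ipr) > 0L) {
      a_n <- a_n + 1L
      if (tl$score[ipr[1L]] < cutoff) a_k <- a_k + 1L
    }
    ipd <- which(tl$label == "PD")
    if (length(ipd) > 0L) {
      i <- ipd[1L]
      if (i > 1L) {
        b_n <- b_n + 1L
        if (tl$score[i] > tl$score[i - 1L]) b_k <- b_k + 1L
      }
      c_n <- c_n + 1L
      if (tl$score[i] < tl$score[1L]) c_k <- c_k + 1L
    }
  }
  list(pr_below_cutoff = frac(a_k, a_n),
       pd_elevated = frac(b_k, b_n),
       pd_below_baseline = frac(c_k, c_n))
}

#' Concordance of two segmented copy-number patterns
#'
#' Pearson correlation of per-bin segment log2(x/2) ratios over the bins
#' unmasked in both profiles; quantifies whether two plasma samples (e.g.
#' baseline and progression) carry the same alteration pattern regardless
#' of amplitude.
#'
#' @param profile_a,profile_b segmented `cn_profile` objects on one grid.
#' @return Correlation in `[-1, 1]`, or `NA` (with a warning) when either
#'   pattern has zero variance.
#' @export
pattern_concordance <- function(profile_a, profile_b) {
  stopifnot(inherits(profile_a, "cn_profile"),
            inherits(profile_b, "cn_profile"))
  if (length(profile_a$x) != length(profile_b$x))
    stop("profiles are on different grids")
  keep <- !profile_a$masked & !profile_b$masked
  la <- log2(profile_a$x[keep] / 2)
  lb <- log2(profile_b$x[keep] / 2)
  if (sd(la) == 0 || sd(lb) == 0) {
    warning("pattern concordance undefined: zero variance")
    return(NA_real_)
  }
  cor(la, lb)
}
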