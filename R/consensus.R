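# Consensus peaks from replicates: Fisher combination of per-replicate
# p-values plus a support rule. A deliberate simplification of MSPC's
# weak/stringent dual-threshold machinery to a single combined-evidence
# threshold (gamma) and a minimum-support count.

#' Combine p-values by Fisher's method
#'
#' `X^2 = -2 * sum(log(p))` is referred to a chi-square distribution with
#' `2k` degrees of freedom; the combined p-value is its upper-tail
#' probability. With a single p-value the method is the identity.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return The combined p-value.
#' @examples
#' fisher_combine(c(0.01, 0.04))
#' @export
fisher_combine <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0) stop("domain error: empty p-value list", call. = FALSE)
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop("domain error: p-values must lie in (0, 1]", call. = FALSE)
  }
  x2 <- -2 * sum(log(p))
  stats::pchisq(x2, df = 2 * length(p), lower.tail = FALSE)
}

# overlap on data.frame rows of peaks (>= 1 bp, same chrom)
peak_overlaps <- function(chrom1, s1, e1, chrom2, s2, e2) {
  chrom1 == chrom2 & s1 < e2 & s2 < e1
}

#' Consensus peaks from replicate peak sets
#'
#' For every peak in every replicate: (1) collect the single best-p
#' overlapping peak (>= 1 bp) from each other replicate; (2) support = 1 +
#' number of replicates contributing an overlapper, and peaks with support
#' below `min_support` are discarded; (3) the collected p-values (including
#' the peak's own) are combined by [fisher_combine()] and the peak is kept
#' iff the combined p is at most `gamma`; (4) surviving peaks that overlap
#' across replicates are merged into one consensus interval spanning their
#' union, carrying the group's smallest combined p. Replicates lacking
#' p-values contribute p = 1 (weakest evidence). Output is sorted and
#' non-overlapping; ties in combined p break by leftmost start.
#'
#' @param replicate_sets List (length >= 2) of [peak_set()] objects.
#' @param gamma Stringency threshold on the combined p-value.
#' @param min_support Minimum number of replicates a consensus peak must
#'   appear in (>= 1, at most the number of replicates).
#' @return A [peak_set()] of consensus peaks; `score` is
#'   `-log10(combined p)`.
#' @export
consensus_peaks <- function(replicate_sets, gamma = 1e-8, min_support = 2) {
  k <- length(replicate_sets)
  if (k < 2) stop("parameter error: at least two replicate sets required",
                  call. = FALSE)
  if (min_support < 1 || min_support > k) {
    stop("parameter error: min_support must lie in [1, ", k, "]",
         call. = FALSE)
  }
  if (gamma <= 0 || gamma >= 1) {
    stop("parameter error: gamma must lie in (0, 1)", call. = FALSE)
  }
  all <- NULL
  for (r in seq_len(k)) {
    df <- as.data.frame(replicate_sets[[r]])
    if (nrow(df) == 0) next
    p <- df$p_value
    p[is.na(p)] <- 1
    all <- rbind(all, data.frame(rep = r, chrom = df$chrom, start = df$start,
                                 end = df$end, p = p))
  }
  if (is.null(all) || nrow(all) == 0) {
    return(peak_set(character(), numeric(), numeric(), source = "consensus"))
  }
  keep <- logical(nrow(all))
  combined <- numeric(nrow(all))
  for (i in seq_len(nrow(all))) {
    evid <- all$p[i]
    support <- 1L
    for (r in setdiff(seq_len(k), all$rep[i])) {
      cand <- all[all$rep == r &
                  peak_overlaps(all$chrom[i], all$start[i], all$end[i],
                                all$chrom, all$start, all$end) &
                  all$rep == r, , drop = FALSE]
      if (nrow(cand) > 0) {
        evid <- c(evid, min(cand$p))
        support <- support + 1L
      }
    }
    combined[i] <- fisher_combine(evid)
    keep[i] <- support >= min_support && combined[i] <= gamma
  }
  surv <- all[keep, , drop = FALSE]
  surv$combined <- combined[keep]
  if (nrow(surv) == 0) {
    return(peak_set(character(), numeric(), numeric(), source = "consensus"))
  }
  # merge overlapping survivors into union spans; combined p = group min;
  # ties in combined p break by leftmost start via the sort below
  surv <- surv[order(surv$chrom, surv$start, surv$end), , drop = FALSE]
  out <- NULL
  cur <- surv[1, ]
  flush <- function(out, cur) rbind(out, cur)
  for (i in seq_len(nrow(surv))[-1]) {
    row <- surv[i, ]
    if (row$chrom == cur$chrom && row$start < cur$end) {
      cur$end <- max(cur$end, row$end)
      cur$combined <- min(cur$combined, row$combined)
    } else {
      out <- flush(out, cur)
      cur <- row
    }
  }
  out <- flush(out, cur)
  peak_set(out$chrom, out$start, out$end,
           name = paste0("consensus_", seq_len(nrow(out))),
           score = -log10(out$combined), p_value = out$combined,
           source = "consensus")
}

#' Write a peak set as BED6
#'
#' @param peaks A [peak_set()].
#' @param path Output path.
#' @param score Which score to write: the set's `score` column (default).
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path, score = peaks$score) {
  df <- as.data.frame(peaks)
  lines <- sprintf("%s\t%d\t%d\t%s\t%.6g\t.", df$chrom,
                   as.integer(df$start), as.integer(df$end), df$name, score)
  writeLines(lines, path)
  invisible(path)
}
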