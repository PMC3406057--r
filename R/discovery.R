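#' Call SNPs from pooled read counts with a binomial error test
#'
#' A transparent stand-in for a full genotyping model: a site is called
#' variant iff it shows at least `min_nonref` non-reference reads AND the
#' upper-tail probability of seeing that many reads from sequencing error
#' alone, `P[Binomial(depth, error_rate) >= nonref]`, falls below `alpha`.
#' Every parameter is visible, so false positive / false negative
#' trade-offs can be reasoned about directly.
#'
#' @param counts A [site_read_counts()].
#' @param min_nonref Minimum non-reference reads (default 2).
#' @param alpha Tail-probability threshold (default 1e-3), in (0, 1).
#' @param error_rate Assumed per-read error rate (default 1e-3), in (0, 0.5).
#' @return Character vector of called site ids.
#' @export
#' @examples
#' cts <- site_read_counts(c("a", "b"), c(30, 1), c(30, 30))
#' call_snps(cts)
call_snps <- function(counts, min_nonref = 2L, alpha = 1e-3,
                      error_rate = 1e-3) {
  stopifnot(inherits(counts, "site_read_counts"))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)")
  }
  if (!is.numeric(error_rate) || error_rate <= 0 || error_rate >= 0.5) {
    stop("error_rate must lie in (0, 0.5)")
  }
  tail_p <- stats::pbinom(counts$nonref - 1L, counts$depth, error_rate,
                          lower.tail = FALSE)
  counts$site_ids[counts$nonref >= min_nonref & tail_p < alpha]
}

#' Fold a frequency to the minor-allele scale
#'
#' @param f Numeric vector of frequencies in `[0, 1]`.
#' @return `pmin(f, 1 - f)`, in `[0, 0.5]`.
#' @export
fold_freq <- function(f) pmin(f, 1 - f)

#' Default folded-frequency bins for discovery reporting
#'
#' Breakpoints `(0, 0.05, 0.10, 0.50]`: rare (<=5%), low (5-10%) and
#' common (>10%) minor alleles -- the cut-points at which discovery error
#' rates are conventionally summarized.
#' @export
discovery_bins <- function() c(0, 0.05, 0.10, 0.50)

#' Score SNP discovery against a truth panel
#'
#' Compares a called site set with the truth, stratified by folded
#' (minor-allele) frequency bin:
#' * False negative rate per bin: among truth-polymorphic sites whose
#'   folded *truth* frequency falls in the bin, the fraction not called.
#' * False positive rate per bin: among called sites whose folded
#'   *estimated* frequency falls in the bin, the fraction absent from
#'   truth entirely. (False positives have no truth frequency, so
#'   they can only be binned by their estimate; true positives in the same
#'   bin form the denominator.)
#'
#' Two truth modes mirror the two ways "truth" can be defined: the full
#' source population (`truth_freq` of the panel, which may include sites
#' absent from the pooled strains -- inflating apparent false negatives)
#' or only the strains actually pooled (`pooled-strains-only`, the realized
#' genotype column means).
#'
#' @param calls Character vector of called site ids (from [call_snps()]).
#' @param truth A [strain_panel()] covering the site universe.
#' @param est A [freq_table()] with estimated frequencies for called sites.
#' @param bins Folded-frequency bin breakpoints (default [discovery_bins()]).
#' @param truth_mode `"source"` (use `truth$truth_freq`) or `"pooled"`
#'   (use realized panel column means).
#' @return A `discovery_report`: data frame `by_bin` with per-bin
#'   `fpr`, `fnr`, `tp`, `fp`, `fn` (empty bins reported as `NA`, not 0),
#'   plus `totals` and the parameters used.
#' @export
discovery_error_rates <- function(calls, truth, est,
                                  bins = discovery_bins(),
                                  truth_mode = c("source", "pooled")) {
  stopifnot(inherits(truth, "strain_panel"), inherits(est, "freq_table"))
  truth_mode <- match.arg(truth_mode)
  tf <- if (truth_mode == "source") truth$truth_freq else
    colMeans(truth$genotypes)
  site_ids <- truth$site_ids
  called <- site_ids %in% calls
  # a site is "in truth" if any strain carries the variant; fixed
  # non-reference sites (tf = 1) are real variants, not false positives,
  # though their folded frequency 0 keeps them out of polymorphism bins
  in_truth <- tf > 0
  polymorphic <- tf > 0 & tf < 1
  est_f <- est$est_freq[match(site_ids, est$site_ids)]

  bin_of <- function(f) {
    b <- findInterval(f, bins, left.open = TRUE, rightmost.closed = TRUE)
    b[f <= bins[1L] | f > bins[length(bins)]] <- NA_integer_
    b
  }
  truth_bin <- bin_of(fold_freq(tf))
  est_bin <- bin_of(fold_freq(est_f))

  n_bins <- length(bins) - 1L
  rows <- lapply(seq_len(n_bins), function(k) {
    in_truth_bin <- !is.na(truth_bin) & truth_bin == k & polymorphic
    fn <- sum(in_truth_bin & !called)
    tp_truth <- sum(in_truth_bin & called)
    called_in_bin <- called & !is.na(est_bin) & est_bin == k
    fp <- sum(called_in_bin & !in_truth)
    tp_est <- sum(called_in_bin & in_truth)
    data.frame(
      bin_lo = bins[k], bin_hi = bins[k + 1L],
      fpr = if (fp + tp_est > 0L) fp / (fp + tp_est) else NA_real_,
      fnr = if (fn + tp_truth > 0L) fn / (fn + tp_truth) else NA_real_,
      tp = tp_truth, fp = fp, fn = fn)
  })
  by_bin <- do.call(rbind, rows)
  totals <- list(
    fpr = if (sum(called) > 0L) sum(called & !in_truth) / sum(called) else NA_real_,
    fnr = if (sum(polymorphic) > 0L) sum(polymorphic & !called) / sum(polymorphic) else NA_real_,
    n_called = sum(called), n_polymorphic = sum(polymorphic))
  structure(list(by_bin = by_bin, totals = totals, truth_mode = truth_mode,
                 bins = bins),
            class = "discovery_report")
}

#' @export
print.discovery_report <- function(x, ...) {
  cat(sprintf("discovery_report (truth: %s): %d called, %d truth-polymorphic\n",
              x$truth_mode, x$totals$n_called, x$totals$n_polymorphic))
  cat(sprintf("  overall FPR %.4f, FNR %.4f\n", x$totals$fpr, x$totals$fnr))
  b <- x$by_bin
  for (i in seq_len(nrow(b))) {
    cat(sprintf("  folded (%.0f%%, %.0f%%]: FPR %s  FNR %s  (TP %d FP %d FN %d)\n",
                100 * b$bin_lo[i], 100 * b$bin_hi[i],
                ifelse(is.na(b$fpr[i]), "--", sprintf("%.4f", b$fpr[i])),
                ifelse(is.na(b$fnr[i]), "--", sprintf("%.4f", b$fnr[i])),
                b$tp[i], b$fp[i], b$fn[i]))
  }
  invisible(x)
}

#' Write a discovery report as TSV
#'
#' @param report A `discovery_report`.
#' @param path File path.
#' @export
write_discovery_report <- function(report, path) {
  stopifnot(inherits(report, "discovery_report"))
  utils::write.table(report$by_bin, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Minimal VCF writer for called sites
#'
#' Writes called sites as biallelic records on a dummy chromosome with the
#' simulation's REF=A / ALT=T convention; INFO carries the non-reference
#' and total read counts (`NR` and `DP`).
#'
#' @param calls Character vector of called site ids.
#' @param counts The [site_read_counts()] the calls were made from.
#' @param path File path.
#' @param chrom Dummy chromosome name.
#' @export
write_vcf_calls <- function(calls, counts, path, chrom = "sim") {
  stopifnot(inherits(counts, "site_read_counts"))
  idx <- which(counts$site_ids %in% calls)
  header <- c("##fileformat=VCFv4.2",
              "##INFO=<ID=NR,Number=1,Type=Integer,Description=\"Non-reference read count\">",
              "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t%s\tA\tT\t.\tPASS\tNR=%d;DP=%d", chrom, idx,
                  counts$site_ids[idx], counts$nonref[idx], counts$depth[idx])
  writeLines(c(header, body), path)
  invisible(path)
}
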