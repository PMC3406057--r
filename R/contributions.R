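#' Find SNPs private to a single strain
#'
#' A private (singleton) SNP is carried by exactly one strain in the panel
#' and absent from all others. Because every read at such a site carrying
#' the non-reference allele must have come from the carrier strain, the
#' pooled frequency of a private SNP directly estimates that strain's DNA
#' share of the pool. Sites must additionally be covered deeper than
#' `min_pool_depth` in the pooled library (strictly greater, matching a
#' ">10x" style filter). With real per-strain sequencing, eligibility also
#' requires adequate per-strain coverage to trust the genotype calls;
#' synthetic panels have exact genotypes, so `per_strain_depth_ok` defaults
#' to accepting every site but accepts a predicate on site index for
#' real-data use.
#'
#' @param panel A [strain_panel()].
#' @param pool_counts A [site_read_counts()] for the pooled library,
#'   sharing sites with the panel.
#' @param min_pool_depth Pool depth must exceed this (default 10).
#' @param per_strain_depth_ok Function(site index) -> logical; gate for
#'   per-strain coverage eligibility.
#' @return A `private_snp_map`: list with `by_strain` (named list of site
#'   index vectors into the panel) and the filters used.
#' @export
find_private_snps <- function(panel, pool_counts, min_pool_depth = 10L,
                              per_strain_depth_ok = NULL) {
  stopifnot(inherits(panel, "strain_panel"),
            inherits(pool_counts, "site_read_counts"))
  pool_depth <- pool_counts$depth[match(panel$site_ids, pool_counts$site_ids)]
  pool_depth[is.na(pool_depth)] <- 0L
  carriers <- colSums(panel$genotypes)
  eligible <- carriers == 1L & pool_depth > min_pool_depth
  if (!is.null(per_strain_depth_ok)) {
    eligible <- eligible & vapply(seq_len(panel$n_sites), per_strain_depth_ok,
                                  logical(1))
  }
  idx <- which(eligible)
  owner <- if (length(idx) > 0L) {
    apply(panel$genotypes[, idx, drop = FALSE], 2L, which.max)
  } else integer(0)
  by_strain <- split(idx, factor(panel$strain_ids[owner],
                                 levels = panel$strain_ids))
  structure(list(by_strain = by_strain, min_pool_depth = as.integer(min_pool_depth),
                 site_ids = panel$site_ids),
            class = "private_snp_map")
}

#' @export
print.private_snp_map <- function(x, ...) {
  n <- lengths(x$by_strain)
  cat(sprintf("private_snp_map: %d strains, %d private SNPs (per strain: %d-%d, median %.0f)\n",
              length(n), sum(n), min(n), max(n), stats::median(n)))
  invisible(x)
}

#' Estimate per-strain DNA contributions from private SNPs
#'
#' For each strain and each of `reps` replicates, `per_strain` private SNPs
#' are sampled without replacement and the mean pooled frequency of those
#' sites is recorded; the strain's reported DNA share is the mean of the
#' replicate means, with a band of +/- 2 standard deviations (sample SD
#' over the replicate means). Strains with fewer than `per_strain` private
#' SNPs are dropped with a warning -- too few singletons to estimate a
#' share reliably. Strains are sorted by mean share in the report.
#'
#' @param pmap A `private_snp_map` from [find_private_snps()].
#' @param freqs A [freq_table()] for the pooled library.
#' @param per_strain Private SNPs sampled per replicate (default 50).
#' @param reps Number of replicates (default 10).
#' @param seed Optional integer seed.
#' @return A `contribution_report`: data frame `estimates` with columns
#'   `strain_id`, `n_private`, `mean_share`, `sd`, `lo2sd`, `hi2sd`
#'   (sorted by `mean_share`), plus `dropped` strain ids and the design.
#' @export
estimate_contributions <- function(pmap, freqs, per_strain = 50L, reps = 10L,
                                   seed = NULL) {
  stopifnot(inherits(pmap, "private_snp_map"), inherits(freqs, "freq_table"))
  per_strain <- as.integer(per_strain)
  reps <- as.integer(reps)
  freq_at <- freqs$est_freq[match(pmap$site_ids, freqs$site_ids)]
  usable <- lapply(pmap$by_strain, function(idx) idx[!is.na(freq_at[idx])])
  n_private <- lengths(usable)
  keep <- n_private >= per_strain
  if (any(!keep)) {
    warning("dropping strain(s) with fewer than ", per_strain,
            " usable private SNPs: ",
            paste(names(usable)[!keep], collapse = ", "), call. = FALSE)
  }
  strains <- names(usable)[keep]
  if (length(strains) == 0L) {
    stop("no strain has >= ", per_strain, " usable private SNPs")
  }
  seeds <- if (is.null(seed)) rep(list(NULL), length(strains)) else
    as.list(derive_seeds(seed, length(strains)))
  est <- do.call(rbind, lapply(seq_along(strains), function(i) {
    idx <- usable[[strains[i]]]
    rep_means <- with_seed(seeds[[i]], {
      vapply(seq_len(reps), function(r) {
        mean(freq_at[idx[sample.int(length(idx), per_strain)]])
      }, numeric(1))
    })
    data.frame(strain_id = strains[i], n_private = length(idx),
               mean_share = mean(rep_means), sd = stats::sd(rep_means))
  }))
  est$lo2sd <- est$mean_share - 2 * est$sd
  est$hi2sd <- est$mean_share + 2 * est$sd
  est <- est[order(est$mean_share), , drop = FALSE]
  rownames(est) <- NULL
  structure(list(estimates = est, dropped = names(usable)[!keep],
                 per_strain = per_strain, reps = reps),
            class = "contribution_report")
}

#' @export
print.contribution_report <- function(x, ...) {
  e <- x$estimates
  cat(sprintf("contribution_report: %d strains (%d dropped), %d x %d private-SNP resampling\n",
              nrow(e), length(x$dropped), x$reps, x$per_strain))
  cat(sprintf("  mean shares %.4f-%.4f (equal split would be %.4f); sum %.4f\n",
              min(e$mean_share), max(e$mean_share), 1 / nrow(e),
              sum(e$mean_share)))
  invisible(x)
}

#' Write a contribution report as TSV
#'
#' Columns `strain_id`, `n_private`, `mean_share`, `sd`, `lo2sd`, `hi2sd`,
#' sorted by mean share.
#'
#' @param report A `contribution_report`.
#' @param path File path.
#' @export
write_contribution_report <- function(report, path) {
  stopifnot(inherits(report, "contribution_report"))
  utils::write.table(report$estimates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
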