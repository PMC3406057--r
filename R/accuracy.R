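#' Lin's concordance correlation coefficient
#'
#' Agreement between two measurements of the same quantity, penalizing both
#' scatter about the identity line and location/scale shifts:
#' `rho_c = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)`.
#' Moments use population (1/n) denominators; with the 1,000-site samples
#' used throughout the accuracy experiments the 1/n vs 1/(n-1) distinction
#' is far below reported precision. Equals 1 only when x = y exactly.
#'
#' @param x,y Numeric vectors of equal length >= 2, not both constant.
#' @return A single number in `[-1, 1]`.
#' @export
#' @examples
#' lin_ccc(c(0.1, 0.5, 0.9), c(0.2, 0.6, 1.0))
lin_ccc <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 2L) stop("need at least 2 observations")
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2)
  vy <- mean((y - my)^2)
  if (vx == 0 && vy == 0) stop("both vectors are constant: concordance undefined")
  sxy <- mean((x - mx) * (y - my))
  2 * sxy / (vx + vy + (mx - my)^2)
}

#' Squared relative error of frequency estimates
#'
#' Per site, `((est - truth) / truth)^2`; heavily weights proportional
#' misses at rare alleles. Truth values of exactly 0 are a hard error (the
#' formula's denominator): such sites must be excluded upstream.
#'
#' @param est,truth Numeric vectors of equal length; `truth > 0` site-wise.
#' @param site_ids Optional labels used in the zero-truth error message.
#' @return List with `per_site` (vector of squared relative errors) and
#'   `mean`.
#' @export
#' @examples
#' relative_error(0.25, 0.20)$per_site  # 0.0625
relative_error <- function(est, truth, site_ids = NULL) {
  if (length(est) != length(truth)) stop("est and truth must have equal length")
  zero <- which(truth == 0)
  if (length(zero) > 0L) {
    lab <- if (is.null(site_ids)) paste0("index ", zero[1L]) else site_ids[zero[1L]]
    stop("relative error undefined at truth == 0 (first offending site: ",
         lab, "); exclude monomorphic-reference sites upstream")
  }
  per_site <- ((est - truth) / truth)^2
  list(per_site = per_site, mean = mean(per_site))
}

#' Frequency-binned resampling design
#'
#' A site set dominated by rare alleles would let low-frequency sites
#' dominate any accuracy statistic. The resampling design counters this by
#' stratifying: frequencies are cut into `n_bins` bins of width
#' `bin_width` and `per_bin` sites are drawn from each bin per replicate,
#' giving an evenly distributed frequency spectrum in every replicate.
#' Defaults (20 bins x 5% x 50 sites = 1,000 sites per replicate) are the
#' standard design used throughout the accuracy experiments.
#'
#' @param n_bins Number of bins (default 20).
#' @param bin_width Bin width as a fraction (default 0.05);
#'   `n_bins * bin_width` must equal 1 within 1e-12.
#' @param per_bin Sites sampled per bin per replicate (default 50).
#' @return An object of class `resample_design`.
#' @export
resample_design <- function(n_bins = 20L, bin_width = 0.05, per_bin = 50L) {
  if (abs(n_bins * bin_width - 1) > 1e-12) {
    stop("n_bins * bin_width must equal 1 (bins must tile [0, 1])")
  }
  if (per_bin < 1L) stop("per_bin must be >= 1")
  structure(list(n_bins = as.integer(n_bins), bin_width = as.numeric(bin_width),
                 per_bin = as.integer(per_bin)),
            class = "resample_design")
}

# bin index in 1..n_bins; bins [k w, (k+1) w) half-open, last bin closed at 1
freq_bin <- function(freq, design) {
  b <- findInterval(freq, seq(0, 1, by = design$bin_width),
                    rightmost.closed = TRUE)
  pmin(pmax(b, 1L), design$n_bins)
}

#' Draw one frequency-stratified site sample
#'
#' Samples exactly `per_bin` site indices without replacement from each
#' frequency bin of `truth`. Bins are half-open `[low, high)` with the last
#' bin closed at 1, so sites at exactly 0 or 1 land in the end bins. By
#' default a bin with fewer than `per_bin` sites is an error;
#' `allow_short_bins = TRUE` instead downscales `per_bin` to the smallest
#' bin occupancy (with a loud warning), keeping the sample balanced.
#'
#' @param truth Numeric vector of frequencies in `[0, 1]`.
#' @param design A [resample_design()].
#' @param seed Optional integer seed.
#' @param allow_short_bins Downscale instead of erroring on thin bins.
#' @return Integer vector of `n_bins * per_bin` distinct site indices.
#' @export
binned_resample <- function(truth, design = resample_design(), seed = NULL,
                            allow_short_bins = FALSE) {
  stopifnot(inherits(design, "resample_design"))
  if (any(truth < 0 | truth > 1)) stop("truth frequencies must lie in [0, 1]")
  bins <- freq_bin(truth, design)
  occupancy <- tabulate(bins, nbins = design$n_bins)
  per_bin <- design$per_bin
  if (any(occupancy < per_bin)) {
    short <- which(occupancy < per_bin)
    if (!allow_short_bins) {
      stop("bin(s) ", paste(short, collapse = ", "), " hold fewer than ",
           per_bin, " sites (occupancy ",
           paste(occupancy[short], collapse = ", "),
           "); supply more sites or set allow_short_bins = TRUE")
    }
    per_bin <- min(occupancy)
    if (per_bin < 1L) {
      stop("bin(s) ", paste(which(occupancy == 0L), collapse = ", "),
           " are empty; cannot resample")
    }
    warning("short bins: downscaling per_bin from ", design$per_bin,
            " to ", per_bin, " (minimum bin occupancy)", call. = FALSE)
  }
  with_seed(seed, {
    unlist(lapply(seq_len(design$n_bins), function(k) {
      pool <- which(bins == k)
      pool[sample.int(length(pool), per_bin)]
    }), use.names = FALSE)
  })
}

#' Binomial read-sampling expectation of pooled frequency estimates
#'
#' The best-case pooled estimate when the only noise is read sampling:
#' per site, `B / depth` with `B ~ Binomial(depth, truth)`. No strain
#' sampling layer, no sequencing error -- this is the idealized yardstick
#' observed estimates are compared against at their observed depths.
#'
#' @param truth Numeric vector of true frequencies.
#' @param depths Integer vector of per-site depths (>= 1), same length.
#' @param seed Optional integer seed.
#' @return Numeric vector of simulated frequency estimates.
#' @export
binomial_expectation <- function(truth, depths, seed = NULL) {
  if (length(truth) != length(depths)) stop("truth and depths must have equal length")
  if (any(depths < 1)) stop("depths must be >= 1")
  with_seed(seed, stats::rbinom(length(truth), depths, truth) / depths)
}

#' Run a full resampled accuracy experiment
#'
#' For each of `n_reps` replicates: draw one frequency-stratified site
#' sample ([binned_resample()] on the truth frequencies), then compute an
#' observed and an expected statistic pair on that same site set.
#'
#' * `mode = "vs_truth"`: observed = concordance (and mean squared relative
#'   error) of `est_table$est_freq` against `truth_freq`; expected = the
#'   same statistics for a fresh [binomial_expectation()] draw at the
#'   sites' observed depths.
#' * `mode = "replicate"`: observed = concordance of the two libraries'
#'   estimates against each other; expected = concordance of two
#'   *independent* binomial draws from the truth, each at its own library's
#'   depths -- what two biological replicates would show if read sampling
#'   were the only noise.
#'
#' Sites with truth 0 (or, in replicate mode, a zero denominator estimate)
#' are excluded from relative error only, per the formula's guard; they
#' still participate in concordance.
#'
#' @param est_table A [freq_table()] carrying `truth_freq`.
#' @param mode `"vs_truth"` or `"replicate"`.
#' @param est_table2 Second library's [freq_table()] (replicate mode); must
#'   share the site set with `est_table`.
#' @param design A [resample_design()].
#' @param n_reps Number of replicates (default 100).
#' @param seed Optional integer root seed (split across replicates).
#' @param allow_short_bins Passed to [binned_resample()].
#' @return An `accuracy_report`: per-rep vectors `observed_ccc`,
#'   `expected_ccc`, `observed_relerr`, `expected_relerr` and their
#'   min--max `ranges`.
#' @export
accuracy_experiment <- function(est_table, mode = c("vs_truth", "replicate"),
                                est_table2 = NULL,
                                design = resample_design(), n_reps = 100L,
                                seed = NULL, allow_short_bins = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(est_table, "freq_table"))
  if (is.null(est_table$truth_freq)) {
    stop("est_table must carry truth_freq (attach it in estimate_frequencies)")
  }
  if (mode == "replicate") {
    if (is.null(est_table2) || !inherits(est_table2, "freq_table")) {
      stop("replicate mode needs est_table2")
    }
    if (!identical(est_table$site_ids, est_table2$site_ids)) {
      stop("replicate mode requires both tables on the same site set ",
           "(use intersect_on_filter first)")
    }
  }
  n_reps <- as.integer(n_reps)
  truth <- est_table$truth_freq
  seeds <- if (is.null(seed)) rep(list(NULL), n_reps) else
    as.list(derive_seeds(seed, n_reps))

  obs_ccc <- exp_ccc <- obs_re <- exp_re <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    stats_r <- with_seed(seeds[[r]], {
      idx <- binned_resample(truth, design, allow_short_bins = allow_short_bins)
      t_r <- truth[idx]
      if (mode == "vs_truth") {
        e_r <- est_table$est_freq[idx]
        sim <- binomial_expectation(t_r, est_table$depth[idx])
        ok <- t_r > 0
        c(lin_ccc(e_r, t_r),
          lin_ccc(sim, t_r),
          relative_error(e_r[ok], t_r[ok])$mean,
          relative_error(sim[ok], t_r[ok])$mean)
      } else {
        e1 <- est_table$est_freq[idx]
        e2 <- est_table2$est_freq[idx]
        sim1 <- binomial_expectation(t_r, est_table$depth[idx])
        sim2 <- binomial_expectation(t_r, est_table2$depth[idx])
        ok_o <- e2 > 0
        ok_e <- sim2 > 0
        c(lin_ccc(e1, e2),
          lin_ccc(sim1, sim2),
          relative_error(e1[ok_o], e2[ok_o])$mean,
          relative_error(sim1[ok_e], sim2[ok_e])$mean)
      }
    })
    obs_ccc[r] <- stats_r[1L]; exp_ccc[r] <- stats_r[2L]
    obs_re[r] <- stats_r[3L]; exp_re[r] <- stats_r[4L]
  }
  structure(
    list(n_reps = n_reps, mode = mode, design = design,
         observed_ccc = obs_ccc, expected_ccc = exp_ccc,
         observed_relerr = obs_re, expected_relerr = exp_re,
         ranges = list(observed_ccc = range(obs_ccc),
                       expected_ccc = range(exp_ccc),
                       observed_relerr = range(obs_re),
                       expected_relerr = range(exp_re)),
         library_id = est_table$library_id,
         library_id2 = if (mode == "replicate") est_table2$library_id else NULL),
    class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  lib <- if (x$mode == "replicate") {
    paste0(x$library_id, " vs ", x$library_id2)
  } else paste0(x$library_id, " vs truth")
  cat(sprintf("accuracy_report (%s, %d reps of %d x %d binned sites)\n", lib,
              x$n_reps, x$design$n_bins, x$design$per_bin))
  fr <- function(r) sprintf("%.3f-%.3f", r[1], r[2])
  cat(sprintf("  concordance  observed %s | expected %s\n",
              fr(x$ranges$observed_ccc), fr(x$ranges$expected_ccc)))
  cat(sprintf("  rel. error   observed %s | expected %s\n",
              fr(x$ranges$observed_relerr), fr(x$ranges$expected_relerr)))
  invisible(x)
}

#' Write an accuracy report as TSV
#'
#' One row per replicate with the four per-rep statistics, then a final
#' `range` row holding `min-max` summaries -- the presentation used for
#' library comparison tables (Observed/Expected Concordance,
#' Observed/Expected Relative Error).
#'
#' @param report An `accuracy_report`.
#' @param path File path.
#' @export
write_accuracy_report <- function(report, path) {
  stopifnot(inherits(report, "accuracy_report"))
  df <- data.frame(rep = seq_len(report$n_reps),
                   observed_ccc = report$observed_ccc,
                   expected_ccc = report$expected_ccc,
                   observed_relerr = report$observed_relerr,
                   expected_relerr = report$expected_relerr)
  fr <- function(r) sprintf("%.6g-%.6g", r[1], r[2])
  summary_row <- data.frame(rep = "range",
                            observed_ccc = fr(report$ranges$observed_ccc),
                            expected_ccc = fr(report$ranges$expected_ccc),
                            observed_relerr = fr(report$ranges$observed_relerr),
                            expected_relerr = fr(report$ranges$expected_relerr))
  df$rep <- as.character(df$rep)
  for (cn in colnames(df)[-1L]) df[[cn]] <- format(df[[cn]], digits = 8)
  utils::write.table(rbind(df, summary_row), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
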