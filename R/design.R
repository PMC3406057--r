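#' Depth model specification
#'
#' Per-site read depth is drawn either from a Poisson distribution
#' (`depth_model_poisson`, mean `lambda` reads) or from an empirical
#' histogram mapping depth to probability (`depth_model_empirical`),
#' allowing users to plug in an observed read-depth distribution from real
#' sequencing data.
#'
#' @param lambda Mean depth (> 0).
#' @param depths Integer vector of depth values (>= 0).
#' @param prob Probabilities for `depths` (normalized internally).
#' @return An object of class `depth_model`.
#' @export
depth_model_poisson <- function(lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0) {
    stop("poisson depth model needs mean > 0")
  }
  structure(list(kind = "poisson", lambda = as.numeric(lambda)),
            class = "depth_model")
}

#' @rdname depth_model_poisson
#' @export
depth_model_empirical <- function(depths, prob) {
  if (length(depths) == 0L) stop("empirical depth model needs a non-empty histogram")
  if (length(depths) != length(prob)) stop("depths and prob must have equal length")
  if (any(depths < 0) || any(depths != floor(depths))) {
    stop("depths must be non-negative integers")
  }
  if (any(prob < 0) || sum(prob) <= 0) stop("prob must be non-negative with positive sum")
  structure(list(kind = "empirical", depths = as.integer(depths),
                 prob = prob / sum(prob)),
            class = "depth_model")
}

#' Draw read depths from a depth model, optionally conditioned on a minimum
#'
#' With `min_depth > 0`, draws come from the model *conditioned* on
#' depth >= min_depth (inverse-CDF sampling of the truncated Poisson, or a
#' renormalized histogram) -- conditioning, not clipping, so the shape of
#' the upper tail is preserved. This mirrors restricting an analysis to
#' sites passing a coverage filter: the retained sites' depth distribution
#' is the truncated one.
#'
#' @param model A `depth_model`.
#' @param n Number of depths to draw (>= 1).
#' @param min_depth Non-negative integer; 0 disables conditioning.
#' @param seed Optional integer seed.
#' @return Integer vector of `n` depths, all >= `min_depth`.
#' @export
#' @examples
#' d <- sample_depths(depth_model_poisson(20), 1000, min_depth = 10, seed = 1)
#' min(d)
sample_depths <- function(model, n, min_depth = 0L, seed = NULL) {
  stopifnot(inherits(model, "depth_model"), n >= 1L, min_depth >= 0L)
  n <- as.integer(n)
  min_depth <- as.integer(min_depth)
  with_seed(seed, {
    if (model$kind == "poisson") {
      if (min_depth == 0L) {
        stats::rpois(n, model$lambda)
      } else {
        lo <- stats::ppois(min_depth - 1L, model$lambda)
        if (1 - lo < 1e-12) {
          stop("impossible conditioning: P(depth >= ", min_depth,
               ") is numerically zero under Poisson(", model$lambda, ")")
        }
        stats::qpois(lo + stats::runif(n) * (1 - lo), model$lambda)
      }
    } else {
      keep <- model$depths >= min_depth
      if (!any(keep) || sum(model$prob[keep]) <= 0) {
        stop("impossible conditioning: no histogram mass at depth >= ", min_depth)
      }
      vals <- model$depths[keep]
      vals[sample.int(length(vals), n, replace = TRUE,
                      prob = model$prob[keep] / sum(model$prob[keep]))]
    }
  })
}

# E[1/depth] under the (possibly truncated) model, by direct pmf summation.
# Used by variance oracles; exported because accuracy planning needs it too.

#' Expected reciprocal depth under a depth model
#'
#' Computes E\[1/d\] for depths drawn from `model` conditioned on
#' `d >= min_depth`, by direct summation of the probability mass function.
#' The sampling variance of a pooled frequency estimate at fixed pool
#' frequency q is q(1-q) E\[1/d\], so this is the planning quantity for
#' coverage choices.
#'
#' @inheritParams sample_depths
#' @return A single number, E\[1/depth\].
#' @export
expected_inverse_depth <- function(model, min_depth = 0L) {
  stopifnot(inherits(model, "depth_model"))
  min_depth <- max(1L, as.integer(min_depth))  # 1/d undefined at d = 0
  if (model$kind == "poisson") {
    upper <- max(min_depth, stats::qpois(1 - 1e-14, model$lambda))
    d <- seq.int(min_depth, upper)
    pmf <- stats::dpois(d, model$lambda)
    sum(pmf / d) / sum(pmf)
  } else {
    keep <- model$depths >= min_depth
    if (!any(keep)) stop("no histogram mass at depth >= ", min_depth)
    p <- model$prob[keep] / sum(model$prob[keep])
    sum(p / model$depths[keep])
  }
}

#' Draw per-strain DNA contribution weights
#'
#' Each strain's share of the pooled DNA is a library-level property fixed
#' across sites. Unequal contribution is modeled as one draw from a
#' symmetric Dirichlet(alpha) of length `n_strains`: small `concentration`
#' gives strongly unequal shares, large values approach the ideal equal
#' pool, and `concentration = Inf` returns exactly `1/n_strains` each.
#'
#' @param n_strains Number of strains (>= 1).
#' @param concentration Symmetric Dirichlet concentration alpha (> 0), or
#'   `Inf` for exactly equal weights. Default 20 gives the visibly unequal
#'   but gradual spread seen in real small pools.
#' @param seed Optional integer seed.
#' @return Numeric simplex vector of length `n_strains` (sums to 1).
#' @export
#' @examples
#' draw_contributions(22, Inf)
#' draw_contributions(22, 20, seed = 1)
draw_contributions <- function(n_strains, concentration = 20, seed = NULL) {
  if (!is.numeric(n_strains) || n_strains < 1L) stop("n_strains must be >= 1")
  if (!is.numeric(concentration) || length(concentration) != 1L ||
      is.na(concentration) || concentration <= 0) {
    stop("concentration must be a positive real or Inf")
  }
  n_strains <- as.integer(n_strains)
  if (is.infinite(concentration)) {
    return(rep(1 / n_strains, n_strains))
  }
  with_seed(seed, {
    g <- stats::rgamma(n_strains, shape = concentration, rate = 1)
    # guard against all-zero underflow at tiny concentration
    while (sum(g) == 0) g <- stats::rgamma(n_strains, shape = concentration, rate = 1)
    g / sum(g)
  })
}

#' Pooled-library design
#'
#' Bundles everything that defines one pooled sequencing library apart from
#' the strains themselves: the per-strain DNA contribution weights, the
#' read depth model, the per-read sequencing error rate, and the minimum
#' depth analysis filter.
#'
#' @param weights Simplex vector of per-strain DNA shares (non-negative,
#'   summing to 1 within 1e-9).
#' @param depth_model A `depth_model` (default Poisson with mean 20).
#' @param error_rate Per-read allele flip probability in `[0, 0.5)`.
#'   Default 0: frequency-accuracy experiments consider binomial sampling
#'   only; SNP discovery experiments typically use 1e-3.
#' @param min_depth Analysis coverage filter (default 10).
#' @param condition_depth If `TRUE` (default), simulated depths are drawn
#'   conditioned on depth >= `min_depth`, so the simulated library is the
#'   post-filter site set directly. Set `FALSE` to draw raw depths and let
#'   [estimate_frequencies()] drop shallow sites.
#' @return An object of class `pool_design`.
#' @export
pool_design <- function(weights, depth_model = depth_model_poisson(20),
                        error_rate = 0, min_depth = 10L,
                        condition_depth = TRUE) {
  weights <- as.numeric(weights)
  if (any(weights < 0)) stop("weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("weights must sum to 1 within 1e-9 (got ", format(sum(weights)), ")")
  }
  stopifnot(inherits(depth_model, "depth_model"))
  if (!is.numeric(error_rate) || error_rate < 0 || error_rate >= 0.5) {
    stop("error_rate must lie in [0, 0.5)")
  }
  if (min_depth < 0) stop("min_depth must be non-negative")
  structure(list(weights = weights, depth_model = depth_model,
                 error_rate = as.numeric(error_rate),
                 min_depth = as.integer(min_depth),
                 condition_depth = isTRUE(condition_depth)),
            class = "pool_design")
}

#' @export
print.pool_design <- function(x, ...) {
  dm <- if (x$depth_model$kind == "poisson") {
    sprintf("Poisson(mean %g)", x$depth_model$lambda)
  } else "empirical histogram"
  cat(sprintf("pool_design: %d strains, depth %s%s, error rate %g, min depth %d\n",
              length(x$weights), dm,
              if (x$condition_depth) sprintf(" | >= %d", x$min_depth) else "",
              x$error_rate, x$min_depth))
  cat(sprintf("  weights: min %.4f, max %.4f (equal would be %.4f)\n",
              min(x$weights), max(x$weights), 1 / length(x$weights)))
  invisible(x)
}
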