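# Independent oracles and fixture builders, deliberately coded without
# reference to the package's own implementations.

# brute-force Lin's concordance via explicit population moments
ccc_oracle <- function(x, y) {
  n <- length(x)
  xb <- sum(x) / n
  yb <- sum(y) / n
  sxx <- sum((x - xb) * (x - xb)) / n
  syy <- sum((y - yb) * (y - yb)) / n
  sxy <- sum((x - xb) * (y - yb)) / n
  (2 * sxy) / (sxx + syy + (xb - yb) * (xb - yb))
}

# mean of Poisson(lambda) truncated to >= lo, by direct pmf summation
truncated_poisson_mean <- function(lambda, lo) {
  d <- lo:max(lo + 1, ceiling(lambda + 20 * sqrt(lambda)))
  pmf <- stats::dpois(d, lambda)
  sum(d * pmf) / sum(pmf)
}

# E[1/d] for Poisson(lambda) truncated to >= lo, by direct pmf summation
truncated_poisson_inv_mean <- function(lambda, lo) {
  d <- lo:max(lo + 1, ceiling(lambda + 20 * sqrt(lambda)))
  pmf <- stats::dpois(d, lambda)
  sum(pmf / d) / sum(pmf)
}

# panel in which every column has exactly `carriers` carrier strains
# (rotating which strains carry), so the equal-weight pool frequency is
# carriers / n_strains at every site
make_constant_q_panel <- function(n_strains, carriers, n_sites) {
  g <- vapply(seq_len(n_sites), function(j) {
    col <- integer(n_strains)
    col[(((j - 1) + seq_len(carriers) - 1L) %% n_strains) + 1L] <- 1L
    col
  }, integer(n_strains))
  strain_panel(g)
}

# panel holding only private SNPs: `per_strain` sites carried by each
# strain alone
make_private_panel <- function(n_strains, per_strain) {
  n_sites <- n_strains * per_strain
  g <- matrix(0L, n_strains, n_sites)
  for (i in seq_len(n_strains)) {
    g[i, ((i - 1L) * per_strain + 1L):(i * per_strain)] <- 1L
  }
  strain_panel(g)
}
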