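test_that("generate_panel honors the site frequency spectrum and boundary frequencies", {
  # fixed boundary frequencies: monomorphic columns, exact truth
  p0 <- generate_panel(4, 10, sfs_spec("fixed", freqs = 0), seed = 1)
  expect_true(all(p0$genotypes == 0L))
  expect_identical(p0$truth_freq, rep(0, 10))

  p1 <- generate_panel(4, 10, sfs_spec("fixed", freqs = 1), seed = 1)
  expect_true(all(p1$genotypes == 1L))
  expect_identical(p1$truth_freq, rep(1, 10))

  # uniform spectrum, panel mode: mean truth ~ 0.5 within 3 standard errors
  # (law of large numbers; per-site variance = Var(p) + E[p(1-p)]/n_strains)
  pu <- generate_panel(22, 10000, sfs_spec("uniform"), seed = 7)
  se <- sqrt(1 / 12 + (1 / 6) / 22) / sqrt(10000)
  expect_lt(abs(mean(pu$truth_freq) - 0.5), 3 * se)
  # panel-mode truth is exactly the genotype column mean
  expect_equal(pu$truth_freq, colMeans(pu$genotypes))

  # source mode records the drawn population frequency, not the realization
  ps <- generate_panel(5, 2000, sfs_spec("uniform"), truth_mode = "source",
                       seed = 3)
  expect_false(identical(ps$truth_freq, colMeans(ps$genotypes)))
  expect_true(all(ps$truth_freq >= 0 & ps$truth_freq <= 1))

  # neutral spectrum is rare-heavy
  pn <- generate_panel(10, 20000, sfs_spec("neutral"), truth_mode = "source",
                       seed = 5)
  expect_gt(mean(pn$truth_freq < 0.1), mean(pn$truth_freq > 0.9))

  expect_error(generate_panel(1, 10), "n_strains")
  expect_error(generate_panel(4, 0), "n_sites")
  expect_error(sfs_spec("zipf"), "unknown site frequency spectrum")
  expect_error(generate_panel(4, 10, sfs_spec("fixed", freqs = 1.2)), "0, 1")
})

test_that("draw_contributions matches Dirichlet moments and the equal-weight limit", {
  expect_equal(draw_contributions(22, Inf), rep(1 / 22, 22))

  # n = 2, alpha = 1: first weight is Beta(1,1) = Uniform(0,1)
  w1 <- vapply(derive_seeds(42, 10000),
               function(s) draw_contributions(2, 1, seed = s)[1], numeric(1))
  expect_lt(abs(stats::var(w1) - 1 / 12) / (1 / 12), 0.10)

  # symmetric Dirichlet marginal SD, n = 21, alpha = 50
  W <- vapply(derive_seeds(43, 10000),
              function(s) draw_contributions(21, 50, seed = s), numeric(21))
  sd_theory <- sqrt((1 / 21) * (20 / 21) / (21 * 50 + 1))
  expect_lt(abs(stats::sd(as.vector(W)) - sd_theory) / sd_theory, 0.10)

  w <- draw_contributions(30, 0.5, seed = 9)
  expect_lt(abs(sum(w) - 1), 1e-9)
  expect_true(all(w >= 0))
  expect_error(draw_contributions(5, 0), "concentration")
  expect_error(draw_contributions(5, -2), "concentration")
})

test_that("simulate_pool_reads is exact at fixed sites and unbiased at private sites", {
  fixed1 <- generate_panel(6, 50, sfs_spec("fixed", freqs = 1), seed = 1)
  d <- pool_design(draw_contributions(6, 5, seed = 2), error_rate = 0)
  cts <- simulate_pool_reads(fixed1, d, seed = 3)
  expect_identical(cts$nonref, cts$depth)

  fixed0 <- generate_panel(6, 50, sfs_spec("fixed", freqs = 0), seed = 1)
  cts0 <- simulate_pool_reads(fixed0, d, seed = 3)
  expect_identical(cts0$nonref, rep(0L, 50))

  # equal weights over 21 strains, every site private to one strain:
  # mean read fraction ~ 1/21 within 3 SE at depth ~200 over 1000 sites
  priv <- strain_panel(make_private_panel(21, 48)$genotypes[, 1:1000])
  dd <- pool_design(rep(1 / 21, 21), depth_model_poisson(200), min_depth = 10)
  pcts <- simulate_pool_reads(priv, dd, seed = 11)
  q <- 1 / 21
  se <- sqrt(q * (1 - q) * truncated_poisson_inv_mean(200, 10) / 1000)
  expect_lt(abs(mean(pcts$nonref / pcts$depth) - q), 3 * se)

  expect_error(simulate_pool_reads(priv, pool_design(rep(0.5, 2))), "weights")
})

test_that("sequencing error pulls read fractions toward 1/2", {
  panel <- generate_panel(10, 2000, sfs_spec("fixed", freqs = 0), seed = 1)
  d <- pool_design(rep(0.1, 10), depth_model_poisson(50), error_rate = 0.01)
  cts <- simulate_pool_reads(panel, d, seed = 2)
  f <- sum(cts$nonref) / sum(cts$depth)
  expect_gt(f, 0.005)
  expect_lt(f, 0.02)
  expect_error(pool_design(rep(0.1, 10), error_rate = 0.5), "error_rate")
})

test_that("sample_depths conditions (not clips) on the minimum depth", {
  d <- sample_depths(depth_model_poisson(20), 100000, min_depth = 10, seed = 1)
  expect_true(all(d >= 10))
  m <- truncated_poisson_mean(20, 10)
  expect_lt(abs(mean(d) - m) / m, 0.01)
  # conditioning preserves the shape above the cut: P(d = 10) under the
  # truncated law exceeds the raw Poisson probability
  expect_gt(mean(d == 10), stats::dpois(10, 20))

  expect_identical(sample_depths(depth_model_empirical(20, 1), 5, seed = 1),
                   rep(20L, 5))
  emp <- depth_model_empirical(c(5, 15), c(0.5, 0.5))
  de <- sample_depths(emp, 1000, min_depth = 10, seed = 2)
  expect_true(all(de == 15L))

  expect_error(sample_depths(depth_model_empirical(5, 1), 10, min_depth = 10),
               "impossible conditioning")
  expect_error(sample_depths(depth_model_poisson(5), 10, min_depth = 60),
               "impossible conditioning")
  expect_error(depth_model_empirical(integer(0), numeric(0)), "non-empty")
  expect_error(depth_model_poisson(0), "mean > 0")
})

test_that("expected_inverse_depth matches direct summation oracles", {
  expect_equal(expected_inverse_depth(depth_model_poisson(20), 10),
               truncated_poisson_inv_mean(20, 10), tolerance = 1e-10)
  expect_equal(expected_inverse_depth(depth_model_empirical(c(10, 20), c(0.5, 0.5))),
               0.5 / 10 + 0.5 / 20, tolerance = 1e-12)
})

test_that("huge Dirichlet concentration reproduces equal-weight pools", {
  panel <- generate_panel(20, 20000, sfs_spec("uniform"), seed = 1)
  dm <- depth_model_poisson(30)
  cts_eq <- simulate_pool_reads(panel, pool_design(draw_contributions(20, Inf),
                                                   dm), seed = 5)
  cts_big <- simulate_pool_reads(panel, pool_design(
    draw_contributions(20, 1e6, seed = 4), dm), seed = 5)
  f_eq <- cts_eq$nonref / cts_eq$depth
  f_big <- cts_big$nonref / cts_big$depth
  # agreement in mean and variance within Monte-Carlo error
  se_mean <- stats::sd(f_eq) / sqrt(length(f_eq)) * sqrt(2)
  expect_lt(abs(mean(f_eq) - mean(f_big)), 4 * se_mean)
  expect_lt(abs(stats::var(f_eq) - stats::var(f_big)) / stats::var(f_eq), 0.05)
})

test_that("identical seeds reproduce byte-identical draws", {
  panel <- generate_panel(12, 500, seed = 123)
  panel2 <- generate_panel(12, 500, seed = 123)
  expect_identical(panel, panel2)
  d <- pool_design(draw_contributions(12, 20, seed = 7))
  expect_identical(simulate_pool_reads(panel, d, seed = 99),
                   simulate_pool_reads(panel, d, seed = 99))
  expect_identical(derive_seeds(5, 10), derive_seeds(5, 10))
  # seeded calls leave the caller's RNG stream untouched
  set.seed(1); before <- stats::runif(1)
  set.seed(1); invisible(generate_panel(5, 10, seed = 2)); after <- stats::runif(1)
  expect_identical(before, after)
})

test_that("panel and counts round-trip through their text formats", {
  panel <- generate_panel(8, 60, seed = 2)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_panel(panel, tf)
  back <- read_panel(tf)
  expect_identical(back$genotypes[, ], panel$genotypes[, ])
  expect_equal(back$truth_freq, panel$truth_freq)
  expect_identical(back$site_ids, panel$site_ids)

  cts <- simulate_pool_reads(panel, pool_design(rep(1 / 8, 8)), seed = 3)
  cf <- withr::local_tempfile(fileext = ".tsv")
  write_counts(cts, cf)
  cback <- read_counts(cf)
  expect_identical(cback$nonref, cts$nonref)
  expect_identical(cback$depth, cts$depth)

  sf <- withr::local_tempfile(fileext = ".sync")
  write_sync(cts, sf)
  sback <- read_sync(sf, site_ids = cts$site_ids)
  expect_identical(sback$nonref, cts$nonref)
  expect_identical(sback$depth, cts$depth)
})
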