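test_that("lin_ccc agrees with direct moment arithmetic and handles edge cases", {
  expect_equal(lin_ccc(c(0.1, 0.5, 0.9), c(0.1, 0.5, 0.9)), 1.0)
  expect_equal(lin_ccc(c(0, 1), c(1, 0)), -1.0)
  # frozen oracle value: 2 * 0.1066667 / (2 * 0.1066667 + 0.01)
  expect_equal(lin_ccc(c(0.1, 0.5, 0.9), c(0.2, 0.6, 1.0)), 0.9552238806,
               tolerance = 1e-9)
  expect_error(lin_ccc(1:3, 1:4), "equal length")
  expect_error(lin_ccc(1, 2), "at least 2")
  expect_error(lin_ccc(c(2, 2), c(3, 3)), "constant")
  # location shift alone degrades concordance but not Pearson correlation
  x <- seq(0, 1, length.out = 20)
  expect_lt(lin_ccc(x, x + 0.2), 1)
  expect_equal(stats::cor(x, x + 0.2), 1)
})

test_that("relative_error implements the squared relative deviation with a zero guard", {
  re <- relative_error(c(0.1, 0.5), c(0.1, 0.5))
  expect_equal(re$per_site, c(0, 0))
  expect_equal(re$mean, 0)
  expect_equal(relative_error(0.25, 0.20)$per_site, 0.0625)
  expect_error(relative_error(c(0.1, 0.2), c(0.5, 0), site_ids = c("a", "b")),
               "b")
  expect_error(relative_error(1:2, 1:3), "equal length")
})

test_that("binned_resample stratifies exactly and enforces occupancy", {
  expect_error(resample_design(n_bins = 20, bin_width = 0.04), "tile")

  set.seed(10)
  truth <- stats::runif(20000)
  idx <- binned_resample(truth, resample_design(), seed = 1)
  expect_length(idx, 1000)
  expect_length(unique(idx), 1000)
  design <- resample_design()
  bins <- findInterval(truth[idx], seq(0, 1, 0.05), rightmost.closed = TRUE)
  expect_identical(as.vector(table(bins)), rep(50L, 20))

  # boundary frequencies participate in the end bins
  tb <- c(rep(0, 60), stats::runif(20000), rep(1, 60))
  idx2 <- binned_resample(tb, resample_design(), seed = 2)
  expect_length(idx2, 1000)

  expect_error(binned_resample(rep(0.5, 1000), resample_design()),
               "fewer than 50")
  # forced sample: per_bin 1 with one site per bin takes everything
  centers <- seq(0.025, 0.975, by = 0.05)
  expect_setequal(binned_resample(centers, resample_design(per_bin = 1)),
                  seq_along(centers))
  # short-bin relaxation downscales loudly
  expect_warning(
    idx3 <- binned_resample(stats::runif(300), resample_design(), seed = 3,
                            allow_short_bins = TRUE),
    "downscaling")
  expect_length(unique(idx3), length(idx3))
})

test_that("binomial_expectation has the right support and variance", {
  expect_identical(binomial_expectation(c(0, 0), c(7, 30), seed = 1), c(0, 0))
  expect_identical(binomial_expectation(c(1, 1), c(7, 30), seed = 1), c(1, 1))
  sim <- binomial_expectation(rep(0.5, 100000), rep(20L, 100000), seed = 2)
  expect_lt(abs(stats::var(sim) - 0.0125) / 0.0125, 0.05)
  expect_error(binomial_expectation(0.5, integer(0)), "equal length")
  expect_error(binomial_expectation(0.5, 0), ">= 1")
})

test_that("a perfect estimator scores perfect observed statistics", {
  set.seed(20)
  truth <- stats::runif(5000)
  tab <- freq_table(default_ids <- sprintf("s%d", 1:5000), truth,
                    rep(20L, 5000), truth_freq = truth)
  rep <- accuracy_experiment(tab, mode = "vs_truth",
                             design = resample_design(per_bin = 10),
                             n_reps = 5, seed = 1)
  expect_equal(rep$observed_ccc, rep(1, 5))
  expect_equal(rep$observed_relerr, rep(0, 5))
  expect_true(all(rep$expected_ccc < 1))
  expect_true(all(rep$expected_ccc >= -1))
  expect_true(all(rep$expected_relerr >= 0))
})

test_that("expected concordance matches the closed-form uniform-truth limit", {
  # truth ~ U(0,1), constant depth d: CCC = 2 Var(p) / (2 Var(p) + E[p(1-p)]/d)
  #                                       = (1/6) / (1/6 + (1/6)/d) = d/(d+1)
  set.seed(30)
  truth <- stats::runif(60000)
  for (d in c(20L, 40L)) {
    tab <- freq_table(sprintf("s%d", seq_along(truth)), truth,
                      rep(d, length(truth)), truth_freq = truth)
    rep <- accuracy_experiment(tab, mode = "vs_truth", n_reps = 20, seed = d)
    analytic <- 2 * (1 / 12) / (2 * (1 / 12) + (1 / 6) / d)
    expect_equal(analytic, d / (d + 1), tolerance = 1e-12)
    expect_lt(abs(mean(rep$expected_ccc) - analytic), 0.005)
  }
})

test_that("expected concordance rises with depth and drops in replicate mode", {
  set.seed(31)
  truth <- stats::runif(10000)
  ids <- sprintf("s%d", seq_along(truth))
  mean_exp_ccc <- function(lambda, mode) {
    depths <- sample_depths(depth_model_poisson(lambda), length(truth),
                            min_depth = 10, seed = lambda)
    est <- binomial_expectation(truth, depths, seed = lambda + 1)
    tab <- freq_table(ids, est, depths, truth_freq = truth)
    if (mode == "vs_truth") {
      r <- accuracy_experiment(tab, "vs_truth", n_reps = 20, seed = 77)
    } else {
      depths2 <- sample_depths(depth_model_poisson(lambda), length(truth),
                               min_depth = 10, seed = lambda + 2)
      est2 <- binomial_expectation(truth, depths2, seed = lambda + 3)
      tab2 <- freq_table(ids, est2, depths2, truth_freq = truth)
      r <- accuracy_experiment(tab, "replicate", est_table2 = tab2,
                               n_reps = 20, seed = 77)
    }
    mean(r$expected_ccc)
  }
  c10 <- mean_exp_ccc(10, "vs_truth")
  c20 <- mean_exp_ccc(20, "vs_truth")
  c40 <- mean_exp_ccc(40, "vs_truth")
  expect_gt(c40, c20)
  expect_gt(c20, c10)
  # two noisy vectors agree less than one noisy vector and the truth:
  # 2V/(2V + 2c) < 2V/(2V + c)
  expect_lt(mean_exp_ccc(20, "replicate"), c20)
})

test_that("accuracy_experiment validates inputs and is seed-reproducible", {
  truth <- stats::runif(3000)
  tab <- freq_table(sprintf("s%d", 1:3000), truth, rep(20L, 3000),
                    truth_freq = truth)
  notruth <- freq_table(sprintf("s%d", 1:3000), truth, rep(20L, 3000))
  expect_error(accuracy_experiment(notruth), "truth_freq")
  expect_error(accuracy_experiment(tab, "replicate"), "est_table2")
  shuffled <- freq_table(rev(tab$site_ids), rev(truth), rep(20L, 3000),
                         truth_freq = rev(truth))
  expect_error(accuracy_experiment(tab, "replicate", est_table2 = shuffled),
               "same site set")

  des <- resample_design(per_bin = 10)
  r1 <- accuracy_experiment(tab, n_reps = 4, design = des, seed = 5)
  r2 <- accuracy_experiment(tab, n_reps = 4, design = des, seed = 5)
  expect_identical(r1$observed_ccc, r2$observed_ccc)
  expect_identical(r1$expected_ccc, r2$expected_ccc)
  expect_equal(r1$ranges$observed_ccc, range(r1$observed_ccc))

  out <- withr::local_tempfile(fileext = ".tsv")
  write_accuracy_report(r1, out)
  df <- utils::read.delim(out)
  expect_equal(nrow(df), 5)  # 4 reps + range row
  expect_identical(df$rep[5], "range")
})
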