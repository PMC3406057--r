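#' Experiment configuration
#'
#' Validated bag of parameters for end-to-end experiments: the panel
#' (number of sites and the site frequency spectrum), the library family
#' (contribution concentration, depth means, sequencing error), and the
#' analysis (depth filter, resampling design, replicate count).
#'
#' @param n_sites Sites simulated (default 100000).
#' @param sfs Site frequency spectrum kind or [sfs_spec()] (default uniform).
#' @param concentration Dirichlet concentration for DNA contributions
#'   (default 20; `Inf` = ideal equal pool).
#' @param error_rate Per-read error rate (default 0 for accuracy work).
#' @param min_depth Analysis depth filter (default 10).
#' @param n_reps Accuracy replicates per library (default 100).
#' @param n_bins,per_bin Resampling design (defaults 20 and 50).
#' @param depth_a,depth_b Mean depth of the 22-strain library and of each
#'   42/50-strain library (defaults 10 and 20; merged libraries sum reads).
#' @param sweep_strains Pool sizes for the strain-number sweep.
#' @param sweep_reps Accuracy replicates per sweep point (default 20).
#' @param sweep_depth Mean depth used at every sweep point (default 20; a
#'   fixed depth isolates the strain-number effect).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(n_sites = 100000L, sfs = "uniform",
                              concentration = 20, error_rate = 0,
                              min_depth = 10L, n_reps = 100L,
                              n_bins = 20L, per_bin = 50L,
                              depth_a = 10, depth_b = 20,
                              sweep_strains = c(22L, 42L, 92L),
                              sweep_reps = 20L, sweep_depth = 20) {
  fail <- function(field, msg) stop("config field '", field, "': ", msg,
                                    call. = FALSE)
  if (!is.numeric(n_sites) || n_sites < 1) fail("n_sites", "must be a positive integer")
  if (is.character(sfs)) sfs <- tryCatch(sfs_spec(sfs), error = function(e)
    fail("sfs", conditionMessage(e)))
  if (!inherits(sfs, "sfs_spec")) fail("sfs", "must be an sfs kind or sfs_spec")
  if (!is.numeric(concentration) || concentration <= 0) {
    fail("concentration", "must be positive (Inf allowed)")
  }
  if (!is.numeric(error_rate) || error_rate < 0 || error_rate >= 0.5) {
    fail("error_rate", "must lie in [0, 0.5)")
  }
  if (!is.numeric(min_depth) || min_depth < 0) fail("min_depth", "must be >= 0")
  if (!is.numeric(n_reps) || n_reps < 1) fail("n_reps", "must be >= 1")
  design <- tryCatch(resample_design(n_bins, 1 / n_bins, per_bin),
                     error = function(e) fail("n_bins/per_bin", conditionMessage(e)))
  if (!is.numeric(depth_a) || depth_a <= 0) fail("depth_a", "must be > 0")
  if (!is.numeric(depth_b) || depth_b <= 0) fail("depth_b", "must be > 0")
  if (!is.numeric(sweep_strains) || any(sweep_strains < 2)) {
    fail("sweep_strains", "must be pool sizes >= 2")
  }
  if (!is.numeric(sweep_reps) || sweep_reps < 1) fail("sweep_reps", "must be >= 1")
  if (!is.numeric(sweep_depth) || sweep_depth <= 0) fail("sweep_depth", "must be > 0")
  structure(list(n_sites = as.integer(n_sites), sfs = sfs,
                 concentration = concentration, error_rate = error_rate,
                 min_depth = as.integer(min_depth), n_reps = as.integer(n_reps),
                 design = design, depth_a = depth_a, depth_b = depth_b,
                 sweep_strains = as.integer(sweep_strains),
                 sweep_reps = as.integer(sweep_reps), sweep_depth = sweep_depth),
            class = "experiment_config")
}

# simulate one library over a strain subset of `panel` and return its
# post-filter frequency table (truth attached from `truth`)
simulate_library <- function(panel, rows, depth_mean, config, seed, library_id) {
  sub <- strain_panel(panel$genotypes[rows, , drop = FALSE],
                      truth_freq = panel$truth_freq,
                      site_ids = panel$site_ids,
                      strain_ids = panel$strain_ids[rows])
  seeds <- derive_seeds(seed, 2L)
  design <- pool_design(
    draw_contributions(length(rows), config$concentration, seed = seeds[1L]),
    depth_model = depth_model_poisson(depth_mean),
    error_rate = config$error_rate, min_depth = config$min_depth)
  simulate_pool_reads(sub, design, seed = seeds[2L], library_id = library_id)
}

#' Simulate and score the standard library family
#'
#' Reproduces the canonical pooled-library layout: library A pools 22
#' strains at low depth; B1 and B2 pool the *same* 42 strains with
#' independent contribution draws (biological replicates); B4 pools 50
#' disjoint strains; B3 = B1 + B2 (same strains, double depth) and
#' B5 = B1 + B4, B6 = B2 + B4 (92-strain pools) are constructed by merging
#' reads. All strains are independent draws from one source population, so
#' every library is scored against the same source truth. Each library
#' gets a full [accuracy_experiment()] (vs truth), and B1 vs B2 is also
#' scored in replicate mode.
#'
#' @param config An [experiment_config()].
#' @param seed Integer root seed.
#' @return List with `reports` (named accuracy reports, including
#'   `B1_vs_B2`), `summary` (data frame: library, strains pooled, mean
#'   depth, observed/expected concordance ranges and means, gap), and the
#'   resolved `config`.
#' @export
run_library_family <- function(config = experiment_config(), seed = 1L) {
  stopifnot(inherits(config, "experiment_config"))
  seeds <- derive_seeds(seed, 16L)
  truth <- with_seed(seeds[1L], draw_sfs(config$sfs, config$n_sites))
  site_ids <- default_site_ids(config$n_sites)
  # one 114-strain draw from the source population; A uses its own 22
  # strains, the B family shares 92 (B1/B2 the same 42, B4 a disjoint 50)
  panel <- with_seed(seeds[2L], {
    g <- matrix(stats::rbinom(114L * config$n_sites, 1L,
                              rep(truth, each = 114L)), nrow = 114L)
    strain_panel(g, truth_freq = truth, site_ids = site_ids,
                 strain_ids = sprintf("strain_%03d", 1:114))
  })
  rows_a <- 1:22; rows_b12 <- 23:64; rows_b4 <- 65:114
  counts <- list(
    A  = simulate_library(panel, rows_a,  config$depth_a, config, seeds[3L], "A"),
    B1 = simulate_library(panel, rows_b12, config$depth_b, config, seeds[4L], "B1"),
    B2 = simulate_library(panel, rows_b12, config$depth_b, config, seeds[5L], "B2"),
    B4 = simulate_library(panel, rows_b4, config$depth_b, config, seeds[6L], "B4"))
  counts$B3 <- merge_libraries(counts$B1, counts$B2, library_id = "B3")
  counts$B5 <- merge_libraries(counts$B1, counts$B4, library_id = "B5")
  counts$B6 <- merge_libraries(counts$B2, counts$B4, library_id = "B6")

  tables <- lapply(counts, function(ct) {
    tf <- truth[match(ct$site_ids, site_ids)]
    estimate_frequencies(ct, min_depth = config$min_depth, truth_freq = tf)
  })
  tables <- intersect_on_filter(tables)
  names(tables) <- names(counts)

  n_strains <- c(A = 22L, B1 = 42L, B2 = 42L, B4 = 50L, B3 = 42L, B5 = 92L,
                 B6 = 92L)
  lib_order <- c("A", "B1", "B2", "B3", "B4", "B5", "B6")
  rep_seeds <- derive_seeds(seeds[7L], length(lib_order) + 1L)
  reports <- stats::setNames(lapply(seq_along(lib_order), function(i) {
    accuracy_experiment(tables[[lib_order[i]]], mode = "vs_truth",
                        design = config$design, n_reps = config$n_reps,
                        seed = rep_seeds[i])
  }), lib_order)
  reports$B1_vs_B2 <- accuracy_experiment(
    tables$B1, mode = "replicate", est_table2 = tables$B2,
    design = config$design, n_reps = config$n_reps,
    seed = rep_seeds[length(rep_seeds)])

  summary <- do.call(rbind, lapply(lib_order, function(lib) {
    r <- reports[[lib]]
    data.frame(library = lib, n_strains = n_strains[[lib]],
               mean_depth = mean(tables[[lib]]$depth),
               observed_ccc_lo = r$ranges$observed_ccc[1L],
               observed_ccc_hi = r$ranges$observed_ccc[2L],
               expected_ccc_lo = r$ranges$expected_ccc[1L],
               expected_ccc_hi = r$ranges$expected_ccc[2L],
               observed_ccc_mean = mean(r$observed_ccc),
               expected_ccc_mean = mean(r$expected_ccc),
               gap = mean(r$expected_ccc) - mean(r$observed_ccc))
  }))
  list(reports = reports, summary = summary, config = config)
}

#' Sweep pool size at fixed depth
#'
#' The strain-number experiment: simulate pools of increasing numbers of
#' strains from one source population at a *fixed* depth model, and record
#' observed vs binomial-expected concordance for each. The observed -
#' expected gap isolates noise that binomial read sampling cannot explain:
#' finite strain sampling plus unequal DNA contribution, both of which
#' shrink as more strains are pooled.
#'
#' @param config An [experiment_config()]; `sweep_strains`, `sweep_depth`
#'   and `sweep_reps` control the sweep.
#' @param seed Integer root seed.
#' @return Data frame: `n_strains`, `observed_ccc_mean`,
#'   `expected_ccc_mean`, `gap` (expected - observed), one row per pool
#'   size.
#' @export
strain_number_sweep <- function(config = experiment_config(), seed = 1L) {
  stopifnot(inherits(config, "experiment_config"))
  seeds <- derive_seeds(seed, 2L + length(config$sweep_strains))
  truth <- with_seed(seeds[1L], draw_sfs(config$sfs, config$n_sites))
  site_ids <- default_site_ids(config$n_sites)
  rows <- lapply(seq_along(config$sweep_strains), function(i) {
    n <- config$sweep_strains[i]
    sds <- derive_seeds(seeds[2L + i], 4L)
    panel <- with_seed(sds[1L], {
      g <- matrix(stats::rbinom(n * config$n_sites, 1L,
                                rep(truth, each = n)), nrow = n)
      strain_panel(g, truth_freq = truth, site_ids = site_ids)
    })
    design <- pool_design(
      draw_contributions(n, config$concentration, seed = sds[2L]),
      depth_model = depth_model_poisson(config$sweep_depth),
      error_rate = config$error_rate, min_depth = config$min_depth)
    cts <- simulate_pool_reads(panel, design, seed = sds[3L],
                               library_id = paste0("pool", n))
    tab <- estimate_frequencies(cts, min_depth = config$min_depth,
                                truth_freq = truth)
    rep <- accuracy_experiment(tab, mode = "vs_truth", design = config$design,
                               n_reps = config$sweep_reps, seed = sds[4L])
    data.frame(n_strains = n,
               observed_ccc_mean = mean(rep$observed_ccc),
               expected_ccc_mean = mean(rep$expected_ccc),
               gap = mean(rep$expected_ccc) - mean(rep$observed_ccc))
  })
  do.call(rbind, rows)
}
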