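#' Strain panel: genotypes of isogenic strains at biallelic sites
#'
#' A `strain_panel` holds a binary genotype matrix for a panel of fully
#' homozygous (isogenic) strains -- one row per strain, one column per
#' biallelic site, entries 0 (reference) or 1 (non-reference) -- together
#' with per-site "true" allele frequencies. Because strains are isogenic,
#' each strain contributes a single haplotype and there are no
#' heterozygotes: every genotype is exactly 0 or 1.
#'
#' `truth_freq` is either the realized column mean of the genotype matrix
#' (panel mode: the pooled strains ARE the population) or an externally
#' supplied source-population frequency (source mode: the panel is itself
#' a finite sample from a larger population, as a set of pooled strains is
#' a sample from a reference panel).
#'
#' @param genotypes Integer/numeric matrix of 0/1, strains x sites.
#' @param truth_freq Per-site frequency in `[0, 1]`; defaults to the column
#'   means of `genotypes` (panel mode).
#' @param site_ids Optional character vector of site labels; defaults to
#'   `s000001, s000002, ...`.
#' @param strain_ids Optional character vector of strain labels.
#' @return An object of class `strain_panel` with fields `genotypes`,
#'   `truth_freq`, `site_ids`, `strain_ids`, `n_strains`, `n_sites`.
#' @export
strain_panel <- function(genotypes, truth_freq = NULL, site_ids = NULL,
                         strain_ids = NULL) {
  genotypes <- as.matrix(genotypes)
  dimnames(genotypes) <- NULL  # strain/site labels live in their id vectors
  if (!all(genotypes %in% c(0, 1))) {
    stop("genotypes must be exactly 0 or 1 (isogenic strains carry no heterozygotes)")
  }
  storage.mode(genotypes) <- "integer"
  n_strains <- nrow(genotypes)
  n_sites <- ncol(genotypes)
  if (n_strains < 1L || n_sites < 1L) {
    stop("panel needs at least one strain and one site")
  }
  if (is.null(site_ids)) site_ids <- default_site_ids(n_sites)
  if (is.null(strain_ids)) strain_ids <- sprintf("strain_%02d", seq_len(n_strains))
  if (length(site_ids) != n_sites) stop("site_ids length must match n_sites")
  if (length(strain_ids) != n_strains) stop("strain_ids length must match n_strains")
  if (is.null(truth_freq)) {
    truth_freq <- colMeans(genotypes)
  } else {
    if (length(truth_freq) != n_sites) stop("truth_freq length must match n_sites")
    if (any(truth_freq < 0 | truth_freq > 1)) stop("truth_freq must lie in [0, 1]")
  }
  structure(
    list(genotypes = genotypes, truth_freq = as.numeric(truth_freq),
         site_ids = as.character(site_ids), strain_ids = as.character(strain_ids),
         n_strains = n_strains, n_sites = n_sites),
    class = "strain_panel")
}

default_site_ids <- function(n) sprintf("s%06d", seq_len(n))

#' @export
print.strain_panel <- function(x, ...) {
  cat(sprintf("strain_panel: %d isogenic strains x %d biallelic sites\n",
              x$n_strains, x$n_sites))
  cat(sprintf("  truth_freq: mean %.4f, %d monomorphic-0, %d monomorphic-1\n",
              mean(x$truth_freq), sum(x$truth_freq == 0), sum(x$truth_freq == 1)))
  invisible(x)
}

#' Site frequency spectrum specification
#'
#' Describes the distribution population allele frequencies are drawn from
#' when simulating a panel:
#' * `"uniform"` -- frequency ~ Uniform(0, 1). This is the flat spectrum the
#'   binned resampling design targets (equal mass per 5% bin).
#' * `"neutral"` -- density proportional to 1/x on the bounded grid
#'   `1/grid_size, ..., (grid_size-1)/grid_size`, the classic neutral-site
#'   spectrum shape with singleton-class excess.
#' * `"fixed"` -- frequencies taken from `freqs`, recycled across sites in
#'   order.
#'
#' @param kind One of `"uniform"`, `"neutral"`, `"fixed"`.
#' @param freqs Numeric vector of frequencies in `[0, 1]` (kind "fixed").
#' @param grid_size Grid resolution for the neutral spectrum (default 100).
#' @return An object of class `sfs_spec`.
#' @export
sfs_spec <- function(kind = c("uniform", "neutral", "fixed"), freqs = NULL,
                     grid_size = 100L) {
  if (!is.character(kind) || length(kind) < 1L ||
      !(kind[1L] %in% c("uniform", "neutral", "fixed"))) {
    stop("unknown site frequency spectrum kind: ",
         paste(utils::head(kind, 1L), collapse = ""))
  }
  kind <- kind[1L]
  if (kind == "fixed") {
    if (is.null(freqs) || length(freqs) == 0L) {
      stop("kind 'fixed' requires a non-empty freqs vector")
    }
    if (any(freqs < 0 | freqs > 1)) stop("fixed freqs must lie in [0, 1]")
  }
  if (kind == "neutral" && (!is.numeric(grid_size) || grid_size < 2L)) {
    stop("neutral spectrum needs grid_size >= 2")
  }
  structure(list(kind = kind, freqs = freqs, grid_size = as.integer(grid_size)),
            class = "sfs_spec")
}

draw_sfs <- function(sfs, n) {
  switch(sfs$kind,
    uniform = stats::runif(n),
    neutral = {
      grid <- seq_len(sfs$grid_size - 1L) / sfs$grid_size
      grid[sample.int(length(grid), n, replace = TRUE,
                      prob = (1 / grid) / sum(1 / grid))]
    },
    fixed = rep_len(sfs$freqs, n))
}

#' Simulate a panel of isogenic strains
#'
#' Draws a population frequency p_j per site from the requested site
#' frequency spectrum, then lets each strain carry the non-reference allele
#' independently with probability p_j (each isogenic strain is one
#' haplotype sampled from the population). `truth_mode` selects what
#' "truth" means downstream: `"source"` records p_j itself (the panel is a
#' sample from a larger source population), `"panel"` records the realized
#' column mean (the pooled strains are the whole population).
#'
#' @param n_strains Number of strains (>= 2).
#' @param n_sites Number of biallelic sites (>= 1).
#' @param sfs An [sfs_spec()], or a kind string passed to it.
#' @param truth_mode `"panel"` (default) or `"source"`.
#' @param seed Optional integer seed.
#' @return A [strain_panel()].
#' @export
#' @examples
#' p <- generate_panel(22, 1000, sfs_spec("uniform"), seed = 1)
#' mean(p$truth_freq)
generate_panel <- function(n_strains, n_sites, sfs = sfs_spec("uniform"),
                           truth_mode = c("panel", "source"), seed = NULL) {
  if (!is.numeric(n_strains) || n_strains < 2L) stop("n_strains must be >= 2")
  if (!is.numeric(n_sites) || n_sites < 1L) stop("n_sites must be >= 1")
  if (is.character(sfs)) sfs <- sfs_spec(sfs)
  if (!inherits(sfs, "sfs_spec")) stop("sfs must be an sfs_spec")
  truth_mode <- match.arg(truth_mode)
  n_strains <- as.integer(n_strains)
  n_sites <- as.integer(n_sites)
  with_seed(seed, {
    p <- draw_sfs(sfs, n_sites)
    g <- matrix(stats::rbinom(n_strains * n_sites, 1L, rep(p, each = n_strains)),
                nrow = n_strains, ncol = n_sites)
    strain_panel(g, truth_freq = if (truth_mode == "source") p else NULL)
  })
}

#' Write / read a strain panel as TSV
#'
#' Plain-text interchange format: one row per site with columns `site_id`,
#' `truth_freq`, then one 0/1 column per strain.
#'
#' @param panel A [strain_panel()].
#' @param path File path.
#' @return `read_panel` returns a [strain_panel()]; `write_panel` returns
#'   `path` invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "strain_panel"))
  df <- data.frame(site_id = panel$site_ids, truth_freq = panel$truth_freq,
                   t(panel$genotypes), check.names = FALSE)
  colnames(df) <- c("site_id", "truth_freq", panel$strain_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE)
  need <- c("site_id", "truth_freq")
  if (!all(need %in% colnames(df))) {
    stop("panel TSV must have columns: ", paste(need, collapse = ", "))
  }
  strain_cols <- setdiff(colnames(df), need)
  if (length(strain_cols) == 0L) stop("panel TSV has no strain columns")
  g <- t(as.matrix(df[, strain_cols, drop = FALSE]))
  strain_panel(g, truth_freq = df$truth_freq, site_ids = df$site_id,
               strain_ids = strain_cols)
}
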