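#' Per-site read counts for one pooled library
#'
#' The raw observable of pooled sequencing at a known biallelic site: how
#' many reads in total covered the site (`depth`) and how many carried the
#' non-reference allele (`nonref`).
#'
#' @param site_ids Character vector of site labels.
#' @param nonref Non-negative integer vector, `nonref <= depth` site-wise.
#' @param depth Non-negative integer vector.
#' @param library_id Label for the library (default `"lib"`).
#' @return An object of class `site_read_counts`.
#' @export
site_read_counts <- function(site_ids, nonref, depth, library_id = "lib") {
  n <- length(site_ids)
  if (length(nonref) != n || length(depth) != n) {
    stop("site_ids, nonref and depth must have equal length")
  }
  nonref <- as.integer(round(nonref))
  depth <- as.integer(round(depth))
  if (any(depth < 0)) stop("depth must be non-negative")
  if (any(nonref < 0) || any(nonref > depth)) {
    stop("nonref must satisfy 0 <= nonref <= depth at every site")
  }
  structure(list(site_ids = as.character(site_ids), nonref = nonref,
                 depth = depth, library_id = as.character(library_id)),
            class = "site_read_counts")
}

#' @export
print.site_read_counts <- function(x, ...) {
  cat(sprintf("site_read_counts '%s': %d sites, mean depth %.1f\n",
              x$library_id, length(x$site_ids), mean(x$depth)))
  invisible(x)
}

#' Simulate pooled sequencing read counts
#'
#' Per site j, a read is drawn from strain i with probability `weights[i]`
#' and reports that strain's allele, flipped with probability `error_rate`.
#' Marginally over strains this collapses exactly to
#' `nonref ~ Binomial(depth, q (1 - e) + (1 - q) e)` with pool frequency
#' `q = sum_i weights[i] * genotypes[i, j]`, which is how the counts are
#' drawn here. Depths come from the design's depth model (conditioned on
#' the design's `min_depth` when `condition_depth` is set).
#'
#' @param panel A [strain_panel()].
#' @param design A [pool_design()] whose `weights` length equals
#'   `panel$n_strains`.
#' @param seed Optional integer seed.
#' @param library_id Label for the simulated library.
#' @return A [site_read_counts()] over all panel sites.
#' @export
#' @examples
#' panel <- generate_panel(22, 500, seed = 1)
#' design <- pool_design(draw_contributions(22, Inf))
#' simulate_pool_reads(panel, design, seed = 2)
simulate_pool_reads <- function(panel, design, seed = NULL, library_id = "lib") {
  stopifnot(inherits(panel, "strain_panel"), inherits(design, "pool_design"))
  if (length(design$weights) != panel$n_strains) {
    stop("design has ", length(design$weights), " weights but panel has ",
         panel$n_strains, " strains")
  }
  with_seed(seed, {
    depth <- sample_depths(design$depth_model, panel$n_sites,
                           min_depth = if (design$condition_depth) design$min_depth else 0L)
    q <- as.numeric(design$weights %*% panel$genotypes)
    e <- design$error_rate
    # q = sum(weights) at fixed sites can overshoot 1 by float epsilon
    p_read <- pmin(pmax(q * (1 - e) + (1 - q) * e, 0), 1)
    nonref <- stats::rbinom(panel$n_sites, depth, p_read)
    site_read_counts(panel$site_ids, nonref, depth, library_id)
  })
}

#' Write / read library counts as TSV
#'
#' Columns `site_id`, `nonref`, `depth`, `library_id`.
#'
#' @param counts A [site_read_counts()].
#' @param path File path.
#' @export
write_counts <- function(counts, path) {
  stopifnot(inherits(counts, "site_read_counts"))
  utils::write.table(
    data.frame(site_id = counts$site_ids, nonref = counts$nonref,
               depth = counts$depth, library_id = counts$library_id),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path)
  need <- c("site_id", "nonref", "depth")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0L) {
    stop("counts TSV is missing column(s): ", paste(miss, collapse = ", "))
  }
  lib <- if ("library_id" %in% colnames(df)) as.character(df$library_id[1L]) else "lib"
  site_read_counts(df$site_id, df$nonref, df$depth, lib)
}

#' Write / read counts in PoPoolation sync format
#'
#' One line per site: `chrom  pos  ref  A:T:C:G:N:del`. Simulated sites use
#' a dummy chromosome with the convention reference = A, alternate = T, so
#' the A field carries reference reads and the T field non-reference reads.
#' Positions are the 1-based site order; original site ids are recovered as
#' `chrom:pos` on reading unless a panel's ids are supplied.
#'
#' @param counts A [site_read_counts()].
#' @param path File path.
#' @param chrom Dummy chromosome name (default `"sim"`).
#' @param site_ids Optional site labels to assign on reading.
#' @export
write_sync <- function(counts, path, chrom = "sim") {
  stopifnot(inherits(counts, "site_read_counts"))
  lines <- sprintf("%s\t%d\tA\t%d:%d:0:0:0:0", chrom,
                   seq_along(counts$site_ids),
                   counts$depth - counts$nonref, counts$nonref)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sync
#' @export
read_sync <- function(path, site_ids = NULL, library_id = "lib") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = FALSE,
                          col.names = c("chrom", "pos", "ref", "counts"),
                          colClasses = c("character", "integer", "character",
                                         "character"))
  mat <- do.call(rbind, lapply(strsplit(df$counts, ":", fixed = TRUE), as.integer))
  if (ncol(mat) != 6L) stop("malformed sync count string (need A:T:C:G:N:del)")
  depth <- rowSums(mat)
  # ref=A / alt=T convention: everything not in the reference field is non-ref
  nonref <- depth - mat[, 1L]
  if (is.null(site_ids)) site_ids <- paste0(df$chrom, ":", df$pos)
  site_read_counts(site_ids, nonref, depth, library_id)
}
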