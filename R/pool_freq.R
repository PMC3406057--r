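#' Pooled allele-frequency table
#'
#' Per retained site: the estimated non-reference allele frequency (the raw
#' read fraction `nonref / depth`), the depth it was computed at, and
#' optionally the true frequency for accuracy work. Only sites passing the
#' depth filter appear.
#'
#' @param site_ids,est_freq,depth,truth_freq,library_id Field vectors; see
#'   [estimate_frequencies()].
#' @return An object of class `freq_table`.
#' @export
freq_table <- function(site_ids, est_freq, depth, truth_freq = NULL,
                       library_id = "lib") {
  n <- length(site_ids)
  stopifnot(length(est_freq) == n, length(depth) == n)
  if (!is.null(truth_freq) && length(truth_freq) != n) {
    stop("truth_freq length must match site_ids")
  }
  if (n > 0 && (any(est_freq < 0) || any(est_freq > 1))) {
    stop("est_freq must lie in [0, 1]")
  }
  structure(list(site_ids = as.character(site_ids),
                 est_freq = as.numeric(est_freq),
                 depth = as.integer(depth),
                 truth_freq = if (is.null(truth_freq)) NULL else as.numeric(truth_freq),
                 library_id = as.character(library_id)),
            class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  cat(sprintf("freq_table '%s': %d sites, mean depth %.1f, mean est freq %.4f%s\n",
              x$library_id, length(x$site_ids),
              if (length(x$depth)) mean(x$depth) else NA_real_,
              if (length(x$est_freq)) mean(x$est_freq) else NA_real_,
              if (is.null(x$truth_freq)) "" else " (+truth)"))
  invisible(x)
}

#' Estimate pooled allele frequencies from read counts
#'
#' The pooled estimate at a site is simply the fraction of reads carrying
#' the non-reference allele. Sites below the minimum depth are dropped
#' entirely (standard Pool-seq practice: a 10x floor keeps the binomial
#' sampling error of the read fraction bounded); site order is preserved.
#'
#' @param counts A [site_read_counts()].
#' @param min_depth Minimum coverage to retain a site (default 10).
#' @param truth_freq Optional per-site truth aligned with `counts`
#'   (filtered alongside), or a [strain_panel()] whose `truth_freq` is
#'   matched by site id.
#' @return A [freq_table()] of retained sites.
#' @export
#' @examples
#' cts <- site_read_counts(c("a", "b"), c(5, 3), c(20, 9))
#' estimate_frequencies(cts, min_depth = 10)  # site "b" dropped
estimate_frequencies <- function(counts, min_depth = 10L, truth_freq = NULL) {
  stopifnot(inherits(counts, "site_read_counts"))
  if (inherits(truth_freq, "strain_panel")) {
    truth_freq <- truth_freq$truth_freq[match(counts$site_ids, truth_freq$site_ids)]
  }
  if (!is.null(truth_freq) && length(truth_freq) != length(counts$site_ids)) {
    stop("truth_freq length must match counts")
  }
  keep <- counts$depth >= min_depth
  freq_table(counts$site_ids[keep],
             counts$nonref[keep] / counts$depth[keep],
             counts$depth[keep],
             truth_freq = if (is.null(truth_freq)) NULL else truth_freq[keep],
             library_id = counts$library_id)
}

#' Merge two libraries' reads
#'
#' Per-site non-reference and total counts are summed, as if the two
#' libraries' raw reads had been pooled into one: the merged frequency is
#' the depth-weighted mean of the input frequencies. Sites present in only
#' one library are treated as (0, 0) in the other -- reads are merged, not
#' call sets intersected. Site order: first library's order, then new
#' sites in the second library's order.
#'
#' @param a,b [site_read_counts()] objects.
#' @param library_id Label for the merged library (default `"a+b"`).
#' @return A [site_read_counts()] over the union of sites.
#' @export
merge_libraries <- function(a, b, library_id = NULL) {
  stopifnot(inherits(a, "site_read_counts"), inherits(b, "site_read_counts"))
  if (is.null(library_id)) library_id <- paste0(a$library_id, "+", b$library_id)
  ids <- union(a$site_ids, b$site_ids)
  ia <- match(ids, a$site_ids)
  ib <- match(ids, b$site_ids)
  nonref <- ifelse(is.na(ia), 0L, a$nonref[ia]) + ifelse(is.na(ib), 0L, b$nonref[ib])
  depth <- ifelse(is.na(ia), 0L, a$depth[ia]) + ifelse(is.na(ib), 0L, b$depth[ib])
  site_read_counts(ids, nonref, depth, library_id)
}

#' Restrict frequency tables to sites passing the filter in all libraries
#'
#' Cross-library analyses must compare the same sites, so every table is
#' cut down to the common site set -- the sites that survived the depth
#' filter in every library.
#'
#' @param tables A list of [freq_table()] objects (>= 1).
#' @return A list of [freq_table()] objects over the shared sites, each in
#'   the first table's site order.
#' @export
intersect_on_filter <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1L,
            all(vapply(tables, inherits, logical(1), "freq_table")))
  common <- Reduce(intersect, lapply(tables, `[[`, "site_ids"))
  lapply(tables, function(tb) {
    idx <- match(common, tb$site_ids)
    freq_table(common, tb$est_freq[idx], tb$depth[idx],
               truth_freq = if (is.null(tb$truth_freq)) NULL else tb$truth_freq[idx],
               library_id = tb$library_id)
  })
}

#' Write / read a frequency table as TSV
#'
#' Columns `site_id`, `est_freq`, `depth`, `library_id`, plus `truth_freq`
#' when present.
#'
#' @param tab A [freq_table()].
#' @param path File path.
#' @export
write_freq_table <- function(tab, path) {
  stopifnot(inherits(tab, "freq_table"))
  df <- data.frame(site_id = tab$site_ids, est_freq = tab$est_freq,
                   depth = tab$depth, library_id = tab$library_id)
  if (!is.null(tab$truth_freq)) df$truth_freq <- tab$truth_freq
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_freq_table
#' @export
read_freq_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path)
  need <- c("site_id", "est_freq", "depth")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0L) {
    stop("frequency TSV is missing column(s): ", paste(miss, collapse = ", "))
  }
  freq_table(df$site_id, df$est_freq, df$depth,
             truth_freq = if ("truth_freq" %in% colnames(df)) df$truth_freq else NULL,
             library_id = if ("library_id" %in% colnames(df)) as.character(df$library_id[1L]) else "lib")
}

#' Minimal VCF reader for one pooled sample with allelic depths
#'
#' Reads a plain-text VCF and extracts per-site (non-reference, total)
#' allelic depths for a single pooled sample from the `AD` FORMAT field.
#' Only biallelic SNP records are kept; multiallelic or symbolic records
#' are skipped with a message. This is a convenience for feeding real
#' pooled calls into [estimate_frequencies()]; it is not a general VCF
#' parser.
#'
#' @param path Path to an uncompressed VCF file.
#' @param sample Sample name, or `NULL` (default) for the first sample.
#' @param library_id Label for the resulting counts.
#' @return A [site_read_counts()] with site ids `CHROM:POS`.
#' @export
read_vcf_ad <- function(path, sample = NULL, library_id = "vcf") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1L) stop("no #CHROM header line found: not a VCF?")
  cols <- strsplit(sub("^#", "", lines[hdr]), "\t", fixed = TRUE)[[1L]]
  if (length(cols) < 10L) stop("VCF has no sample columns (need FORMAT + one sample)")
  samples <- cols[-(1:9)]
  sidx <- if (is.null(sample)) 1L else match(sample, samples)
  if (is.na(sidx)) stop("sample '", sample, "' not found in VCF")
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    return(site_read_counts(character(0), integer(0), integer(0), library_id))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- lengths(fields) < 9L + sidx
  if (any(bad)) stop("malformed VCF record at line ", hdr + which(bad)[1L])
  rec <- do.call(rbind, fields)
  alt <- rec[, 5L]
  biallelic <- !grepl(",", alt, fixed = TRUE) & alt %in% c("A", "C", "G", "T") &
    rec[, 4L] %in% c("A", "C", "G", "T")
  if (any(!biallelic)) {
    message("read_vcf_ad: skipping ", sum(!biallelic),
            " non-biallelic-SNP record(s)")
  }
  rec <- rec[biallelic, , drop = FALSE]
  fmt <- strsplit(rec[, 9L], ":", fixed = TRUE)
  smp <- strsplit(rec[, 9L + sidx], ":", fixed = TRUE)
  ad <- mapply(function(f, s) {
    k <- match("AD", f)
    if (is.na(k) || k > length(s)) return(c(NA_integer_, NA_integer_))
    as.integer(strsplit(s[k], ",", fixed = TRUE)[[1L]][1:2])
  }, fmt, smp)
  ok <- !is.na(ad[1L, ]) & !is.na(ad[2L, ])
  if (any(!ok)) message("read_vcf_ad: dropping ", sum(!ok), " record(s) without AD")
  site_read_counts(paste0(rec[ok, 1L], ":", rec[ok, 2L]),
                   nonref = ad[2L, ok], depth = ad[1L, ok] + ad[2L, ok],
                   library_id = library_id)
}
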