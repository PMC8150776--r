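## Locus count matrices: per-position, per-library read counts for one
## methylation context, plus sample metadata, normalization and the
## coefficient-of-variation locus filter.

#' Construct a sample sheet
#'
#' A sample sheet describes the sequencing libraries of one comparison:
#' which genotype group each library belongs to, its replicate number and
#' its methylation context (one restriction enzyme per context).
#'
#' @param library_id character vector of unique library identifiers.
#' @param group character vector; exactly two distinct values per comparison
#'   (e.g. `"facultative"` and `"sexual"`). The first value encountered is
#'   treated as group 1 (deltas are group1 - group2).
#' @param replicate positive integer vector.
#' @param context character vector; each entry one of `"CG"`, `"CHG"`,
#'   `"CHH"`, `"6mA"`.
#' @return data.frame with class `mcseed_samples`.
#' @examples
#' sample_sheet(paste0("L", 1:6), rep(c("apo", "sex"), each = 3),
#'              rep(1:3, 2), "CG")
#' @export
sample_sheet <- function(library_id, group, replicate, context) {
  meta <- data.frame(library_id = as.character(library_id),
                     group = as.character(group),
                     replicate = as.integer(replicate),
                     context = as.character(context),
                     stringsAsFactors = FALSE)
  validate_sample_sheet(meta)
}

#' Read a sample sheet from TSV
#'
#' Expects columns `library_id`, `group`, `replicate`, `context`.
#'
#' @param path path to a tab-separated sample sheet.
#' @return validated `mcseed_samples` data.frame.
#' @export
read_sample_sheet <- function(path) {
  meta <- read_tsv(path)
  need <- c("library_id", "group", "replicate", "context")
  missing <- setdiff(need, names(meta))
  if (length(missing))
    stop_format("sample sheet %s lacks column(s): %s", path,
                paste(missing, collapse = ", "))
  sample_sheet(meta$library_id, meta$group, meta$replicate, meta$context)
}

validate_sample_sheet <- function(meta) {
  if (anyDuplicated(meta$library_id))
    stop_config("duplicated library_id in sample sheet")
  bad <- setdiff(unique(meta$context), VALID_CONTEXTS)
  if (length(bad))
    stop_config("unknown methylation context(s): %s",
                paste(bad, collapse = ", "))
  if (any(!is.finite(meta$replicate)) || any(meta$replicate < 1L))
    stop_config("replicate must be a positive integer")
  # each (group, context) needs within-group replication for the tests
  tab <- table(meta$group, meta$context)
  if (any(tab[tab > 0] < 2L))
    stop_config("every (group, context) combination needs >= 2 replicates")
  class(meta) <- c("mcseed_samples", "data.frame")
  meta
}

#' Construct a locus count matrix
#'
#' Holds per-position read counts (one row per genomic position, one column
#' per library) for a single methylation context, together with its sample
#' metadata. Positions are kept sorted by (chrom, pos) and must be unique.
#'
#' @param positions data.frame with columns `chrom`, `pos` (0-based) and
#'   optionally `context`.
#' @param counts numeric matrix, `nrow(positions)` x `nrow(meta)`; column
#'   order must match `meta$library_id`.
#' @param meta sample sheet covering the count columns (single context).
#' @param normalized logical; `TRUE` once counts are per-million scaled.
#' @return object of class `locus_matrix`.
#' @export
locus_matrix <- function(positions, counts, meta, normalized = FALSE) {
  meta <- validate_sample_sheet(as.data.frame(meta))
  counts <- as.matrix(counts)
  if (length(unique(meta$context)) != 1L)
    stop_config("a locus matrix holds a single context; got: %s",
                paste(unique(meta$context), collapse = ", "))
  if (is.null(positions$context)) positions$context <- meta$context[1L]
  positions <- data.frame(chrom = as.character(positions$chrom),
                          pos = as.integer(positions$pos),
                          context = as.character(positions$context),
                          stringsAsFactors = FALSE)
  if (nrow(positions) != nrow(counts))
    stop_config("positions (%d) and counts (%d rows) disagree",
                nrow(positions), nrow(counts))
  if (ncol(counts) != nrow(meta))
    stop_config("counts has %d columns for %d declared libraries",
                ncol(counts), nrow(meta))
  if (is.null(colnames(counts))) colnames(counts) <- meta$library_id
  if (!identical(colnames(counts), meta$library_id))
    stop_config("count column order does not match sample sheet")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop_format("counts must be finite and non-negative")
  if (any(positions$pos < 0L))
    stop_format("positions must be non-negative")
  key <- paste(positions$chrom, positions$pos)
  if (anyDuplicated(key))
    stop_format("duplicated genomic position(s), e.g. %s",
                key[which(duplicated(key))[1L]])
  o <- coord_order(positions$chrom, positions$pos)
  positions <- positions[o, , drop = FALSE]
  rownames(positions) <- NULL
  structure(list(positions = positions,
                 counts = counts[o, , drop = FALSE],
                 meta = meta,
                 normalized = isTRUE(normalized)),
            class = "locus_matrix")
}

#' @export
print.locus_matrix <- function(x, ...) {
  cat(sprintf("locus_matrix: %d positions x %d libraries [%s, %s]\n",
              nrow(x$counts), ncol(x$counts), x$positions$context[1L],
              if (x$normalized) "normalized (CPM)" else "raw counts"))
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s (n=%d)", names(table(x$meta$group)),
                            table(x$meta$group)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.locus_matrix <- function(x) dim(x$counts)

#' Read a per-locus count table
#'
#' The table is TSV with header columns `chrom`, `pos`, then one column per
#' library named by `library_id`. Rows are sorted by coordinate on read;
#' duplicated positions are rejected.
#'
#' @param path path to the TSV count table.
#' @param meta sample sheet; every `library_id` must be a column of the table.
#' @return raw (un-normalized) [locus_matrix()].
#' @export
read_count_table <- function(path, meta) {
  tab <- read_tsv(path)
  if (!all(c("chrom", "pos") %in% names(tab)))
    stop_format("%s: count table must start with chrom, pos columns", path)
  meta <- validate_sample_sheet(as.data.frame(meta))
  missing <- setdiff(meta$library_id, names(tab))
  if (length(missing))
    stop_config("count table lacks column(s) for declared librar%s: %s",
                if (length(missing) > 1) "ies" else "y",
                paste(missing, collapse = ", "))
  cnt <- as.matrix(tab[, meta$library_id, drop = FALSE])
  if (!is.numeric(cnt) || any(is.na(cnt)))
    stop_format("%s: non-numeric or missing count values", path)
  locus_matrix(tab[, c("chrom", "pos")], cnt, meta, normalized = FALSE)
}

#' Write a locus matrix back to TSV
#'
#' @param m a [locus_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(m, path) {
  write_tsv(cbind(m$positions[c("chrom", "pos")], as.data.frame(m$counts)),
            path)
}

#' Library-size normalization (counts per million)
#'
#' Each library column is scaled to counts-per-million of its column sum, so
#' library sequencing depth cancels out of all downstream comparisons. CPM is
#' deterministic and independent of any reference sample. Already-normalized
#' input is returned unchanged (idempotent).
#'
#' @param m raw [locus_matrix()].
#' @return normalized `locus_matrix` (each column sums to 1e6).
#' @export
normalize_counts <- function(m) {
  stopifnot(inherits(m, "locus_matrix"))
  if (m$normalized) return(m)
  cs <- colSums(m$counts)
  if (any(cs <= 0))
    stop_data("library with zero total counts: %s",
              paste(m$meta$library_id[cs <= 0], collapse = ", "))
  m$counts <- sweep(m$counts, 2L, cs, "/") * 1e6
  m$normalized <- TRUE
  m
}

#' Coefficient-of-variation locus filter
#'
#' Per position, CV = sample standard deviation / mean of normalized counts
#' across all libraries of the comparison. Hyper-variable sites are
#' unreliable restriction loci (unstable digestion/amplification) and are
#' discarded: a position is retained iff `CV <= 10^(-colog_threshold)`
#' (the default `colog_threshold = -0.35` retains `CV <= 10^0.35 ~= 2.239`).
#' Positions with mean 0 are always discarded. Set `invert = TRUE` to discard
#' the low-variability side instead (the literal reading of a
#' "co-logarithm of CV above threshold" cut; see the methods vignette).
#'
#' @param m normalized [locus_matrix()].
#' @param colog_threshold cutoff on `-log10(CV)`; default `-0.35`.
#' @param invert logical; flip the retained side of the cutoff.
#' @return list of class `cv_filter` with elements `matrix` (filtered
#'   `locus_matrix`), `report` (position, cv, retained flag) and
#'   `n_discarded`.
#' @export
filter_by_cv <- function(m, colog_threshold = -0.35, invert = FALSE) {
  stopifnot(inherits(m, "locus_matrix"))
  if (!m$normalized)
    stop_state("filter_by_cv requires a normalized matrix; run normalize_counts()")
  mu <- rowMeans(m$counts)
  sdv <- apply(m$counts, 1L, sd)
  cv <- ifelse(mu > 0, sdv / mu, Inf)
  cutoff <- 10^(-colog_threshold)
  keep <- if (invert) cv >= cutoff else cv <= cutoff
  keep <- keep & mu > 0
  report <- data.frame(chrom = m$positions$chrom, pos = m$positions$pos,
                       cv = cv, retained = keep, stringsAsFactors = FALSE)
  out <- m
  out$positions <- m$positions[keep, , drop = FALSE]
  out$counts <- m$counts[keep, , drop = FALSE]
  structure(list(matrix = out, report = report,
                 n_discarded = sum(!keep)),
            class = "cv_filter")
}

#' @export
print.cv_filter <- function(x, ...) {
  cat(sprintf("cv_filter: retained %d / %d positions (%d discarded)\n",
              nrow(x$matrix$counts), nrow(x$report), x$n_discarded))
  invisible(x)
}
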