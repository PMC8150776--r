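## DMR calling: directional sliding-window clustering of DMPs followed by a
## cluster-level (pooled) logistic-regression test, with window-length
## optimization over a candidate grid.

#' Cluster DMPs by directional sliding windows
#'
#' Per chromosome, scanning left to right: the first unclustered DMP anchors
#' a window of `window_length` bp; every subsequent DMP within the window
#' that shares the cluster direction joins it, and the window re-anchors at
#' the newly included DMP (sliding extension, so a chain of same-direction
#' DMPs with consecutive gaps `<= window_length` forms one cluster). By
#' default a significant DMP of the opposite direction inside the window
#' terminates the cluster and anchors the next one
#' (`opposite = "terminate"`); with `opposite = "skip"` the two directions
#' are chained independently and may interleave. When no further DMP falls
#' in the window the cluster closes. Clusters with at least
#' `min_cluster_size` members are returned.
#'
#' @param dmps `dmp_table` (single context), sorted by (chrom, pos).
#' @param window_length window size in bp (> 0); a DMP at distance exactly
#'   `window_length` from the current anchor is still included.
#' @param min_cluster_size minimum member DMPs per cluster, default 2.
#' @param opposite behaviour on an opposite-direction DMP inside the window.
#' @return data.frame of class `dmp_clusters`: one row per cluster with
#'   chrom, start, end (0-based half-open span of member DMPs), direction,
#'   n_dmps, window_length, and a `members` list-column of member positions.
#' @export
cluster_dmps <- function(dmps, window_length, min_cluster_size = 2L,
                         opposite = c("terminate", "skip")) {
  opposite <- match.arg(opposite)
  stopifnot(window_length > 0)
  df <- as.data.frame(dmps)
  if (nrow(df) == 0L) return(empty_clusters(window_length))
  if (!is_coord_sorted(df$chrom, df$pos))
    stop_state("DMPs must be sorted by (chrom, pos)")
  if (length(unique(df$context)) > 1L)
    stop_state("cluster_dmps expects a single context")

  res <- list()
  for (chrom in unique(df$chrom)) {
    cc <- df[df$chrom == chrom, , drop = FALSE]
    if (opposite == "skip") {
      for (dir in unique(cc$direction)) {
        res <- c(res, scan_chrom(cc[cc$direction == dir, , drop = FALSE],
                                 chrom, window_length))
      }
    } else {
      res <- c(res, scan_chrom(cc, chrom, window_length))
    }
  }
  res <- Filter(function(cl) length(cl$members) >= min_cluster_size, res)
  if (length(res) == 0L) return(empty_clusters(window_length))
  out <- data.frame(
    chrom = vapply(res, `[[`, "", "chrom"),
    start = vapply(res, function(cl) min(cl$members), 0L),
    end = vapply(res, function(cl) max(cl$members) + 1L, 0L),
    direction = vapply(res, `[[`, "", "direction"),
    n_dmps = vapply(res, function(cl) length(cl$members), 0L),
    window_length = window_length,
    stringsAsFactors = FALSE)
  out$members <- I(lapply(res, `[[`, "members"))
  o <- coord_order(out$chrom, out$start)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("dmp_clusters", "data.frame")
  out
}

# single left-to-right scan over the DMPs of one chromosome; a DMP of a
# different direction always closes the running cluster (it either lies in
# the window - explicit termination - or the window is already exhausted)
scan_chrom <- function(cc, chrom, window_length) {
  out <- list()
  cur <- NULL
  anchor <- NA_integer_
  for (i in seq_len(nrow(cc))) {
    p <- cc$pos[i]
    d <- cc$direction[i]
    if (is.null(cur)) {
      cur <- list(chrom = chrom, direction = d, members = p)
      anchor <- p
    } else if (p - anchor <= window_length && d == cur$direction) {
      cur$members <- c(cur$members, p)
      anchor <- p
    } else {
      out[[length(out) + 1L]] <- cur
      cur <- list(chrom = chrom, direction = d, members = p)
      anchor <- p
    }
  }
  if (!is.null(cur)) out[[length(out) + 1L]] <- cur
  out
}

empty_clusters <- function(window_length) {
  out <- data.frame(chrom = character(), start = integer(), end = integer(),
                    direction = character(), n_dmps = integer(),
                    window_length = integer(), stringsAsFactors = FALSE)
  out$members <- I(list())
  class(out) <- c("dmp_clusters", "data.frame")
  out
}

#' Region-level test of DMP clusters
#'
#' For each cluster, member positions' pseudo-counts are pooled per library
#' (summed methylated pseudo-reads over summed pseudo-coverage) and the same
#' group-versus-intercept binomial likelihood-ratio test as [call_dmps()] is
#' applied at region level, with Benjamini-Hochberg adjustment across all
#' clusters of the context. Clusters with region `q < fdr` become DMRs with
#' the cluster direction and the minimal span of their member DMPs.
#'
#' @param clusters [cluster_dmps()] output.
#' @param r `relmeth_matrix` containing every member position.
#' @param meta sample sheet (defaults to the one carried by `r`).
#' @param fdr region-level FDR threshold, default 0.05.
#' @param pseudo_coverage per-library, per-position pseudo-coverage.
#' @param overdispersion as in [call_dmps()].
#' @param comparison optional comparison label (e.g. `"FVS"`) carried into
#'   the output.
#' @param return_all if `TRUE`, return all tested clusters with `is_dmr`.
#' @return data.frame of class `dmr_table`: chrom, start, end, context,
#'   direction, n_dmps, region_p, region_q, window_length, comparison, and a
#'   `members` list-column.
#' @export
test_clusters <- function(clusters, r, meta = r$meta, fdr = 0.05,
                          pseudo_coverage = 100L,
                          overdispersion = c("shrink", "MN", "none"),
                          comparison = NA_character_, return_all = FALSE) {
  stopifnot(inherits(r, "relmeth_matrix"))
  overdispersion <- match.arg(overdispersion)
  cl <- as.data.frame(clusters)
  context <- r$positions$context[1L] %||% NA_character_
  if (nrow(cl) == 0L) return(empty_dmrs())
  gi <- group_indices(meta)
  key <- paste(r$positions$chrom, r$positions$pos)
  numC_site <- round(r$relmeth * pseudo_coverage)
  nlib <- ncol(r$relmeth)
  numC <- matrix(0, nrow(cl), nlib)
  coverage <- matrix(0, nrow(cl), nlib)
  for (i in seq_len(nrow(cl))) {
    rows <- match(paste(cl$chrom[i], cl$members[[i]]), key)
    if (anyNA(rows))
      stop_data("cluster member position absent from relmeth matrix (%s)",
                paste(cl$members[[i]][is.na(rows)], collapse = ", "))
    numC[i, ] <- colSums(numC_site[rows, , drop = FALSE])
    coverage[i, ] <- length(rows) * pseudo_coverage
  }
  lrt <- group_lrt(numC, coverage, gi$idx1, gi$idx2, overdispersion)
  q <- p.adjust(lrt$p, method = "BH")
  out <- data.frame(chrom = cl$chrom, start = cl$start, end = cl$end,
                    context = context, direction = cl$direction,
                    n_dmps = cl$n_dmps, region_p = lrt$p, region_q = q,
                    window_length = cl$window_length,
                    comparison = comparison, stringsAsFactors = FALSE)
  out$members <- cl$members
  if (return_all) {
    out$is_dmr <- out$region_q < fdr
  } else {
    out <- out[out$region_q < fdr, , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("dmr_table", "data.frame")
  out
}

empty_dmrs <- function() {
  out <- data.frame(chrom = character(), start = integer(), end = integer(),
                    context = character(), direction = character(),
                    n_dmps = integer(), region_p = numeric(),
                    region_q = numeric(), window_length = integer(),
                    comparison = character(), stringsAsFactors = FALSE)
  out$members <- I(list())
  class(out) <- c("dmr_table", "data.frame")
  out
}

#' Window-length optimization
#'
#' Runs [cluster_dmps()] + [test_clusters()] for every candidate window
#' length and records the DMR count; the chosen length maximizes the number
#' of DMRs, ties broken by the smallest length. The published per-context,
#' per-comparison window lengths (see [default_window_lengths()]) are the
#' recommended defaults for real data; this scan is the fallback when no
#' operator-chosen length is available.
#'
#' @param dmps `dmp_table` for one context.
#' @param r `relmeth_matrix` backing the cluster tests.
#' @param meta sample sheet.
#' @param lengths candidate window lengths in bp (default 100..2000 step 100).
#' @param min_cluster_size,fdr,pseudo_coverage,overdispersion passed through.
#' @return list of class `window_scan`: `scan` (length, n_clusters, n_dmrs),
#'   `chosen_length`, and `empty` flag (TRUE when no DMPs were supplied).
#' @export
optimize_window <- function(dmps, r, meta = r$meta,
                            lengths = seq(100L, 2000L, by = 100L),
                            min_cluster_size = 2L, fdr = 0.05,
                            pseudo_coverage = 100L,
                            overdispersion = c("shrink", "MN", "none")) {
  overdispersion <- match.arg(overdispersion)
  lengths <- sort(unique(as.integer(lengths)))
  if (nrow(as.data.frame(dmps)) == 0L) {
    scan <- data.frame(length = lengths, n_clusters = 0L, n_dmrs = 0L)
    return(structure(list(scan = scan, chosen_length = lengths[1L],
                          empty = TRUE), class = "window_scan"))
  }
  n_clusters <- integer(length(lengths))
  n_dmrs <- integer(length(lengths))
  for (i in seq_along(lengths)) {
    cl <- cluster_dmps(dmps, lengths[i], min_cluster_size)
    n_clusters[i] <- nrow(cl)
    if (nrow(cl)) {
      dm <- test_clusters(cl, r, meta, fdr = fdr,
                          pseudo_coverage = pseudo_coverage,
                          overdispersion = overdispersion)
      n_dmrs[i] <- nrow(dm)
    }
  }
  scan <- data.frame(length = lengths, n_clusters = n_clusters,
                     n_dmrs = n_dmrs)
  chosen <- lengths[which.max(n_dmrs)]  # which.max takes the first (smallest)
  structure(list(scan = scan, chosen_length = chosen, empty = FALSE),
            class = "window_scan")
}

#' @export
print.window_scan <- function(x, ...) {
  cat(sprintf("window_scan: chosen_length = %d bp (max %d DMRs)%s\n",
              x$chosen_length, max(x$scan$n_dmrs),
              if (x$empty) " [no DMPs - flagged empty]" else ""))
  invisible(x)
}

#' Call DMRs from a DMP table
#'
#' Convenience wrapper: cluster at a fixed window length, or optimize the
#' length first when `window_length = "auto"`, then run the region-level
#' test.
#'
#' @param dmps `dmp_table` for one context.
#' @param r `relmeth_matrix`.
#' @param meta sample sheet.
#' @param window_length integer bp, or `"auto"` for [optimize_window()].
#' @param lengths candidate grid for `"auto"`.
#' @param min_cluster_size,fdr,pseudo_coverage,overdispersion,comparison
#'   passed through.
#' @return list with `dmrs` (`dmr_table`), `clusters`, `window_length` and
#'   `scan` (`NULL` unless optimized).
#' @export
call_dmrs <- function(dmps, r, meta = r$meta, window_length = "auto",
                      lengths = seq(100L, 2000L, by = 100L),
                      min_cluster_size = 2L, fdr = 0.05,
                      pseudo_coverage = 100L,
                      overdispersion = c("shrink", "MN", "none"),
                      comparison = NA_character_) {
  overdispersion <- match.arg(overdispersion)
  scan <- NULL
  if (identical(window_length, "auto")) {
    scan <- optimize_window(dmps, r, meta, lengths, min_cluster_size, fdr,
                            pseudo_coverage, overdispersion)
    window_length <- scan$chosen_length
  }
  clusters <- cluster_dmps(dmps, window_length, min_cluster_size)
  dmrs <- test_clusters(clusters, r, meta, fdr, pseudo_coverage,
                        overdispersion, comparison)
  list(dmrs = dmrs, clusters = clusters,
       window_length = as.integer(window_length), scan = scan)
}

#' Published per-context window lengths
#'
#' Operator-chosen window lengths (bp) that maximized the DMR count per
#' context in the three pairwise genotype comparisons of the MCSeEd study of
#' apomictic and sexual weeping lovegrass this package was built around:
#' FVS (facultative vs sexual), AVS (full apomictic vs sexual) and AVF
#' (full apomictic vs facultative).
#'
#' @param comparison `"FVS"`, `"AVS"` or `"AVF"`.
#' @return named integer vector of window lengths for CG, CHG, CHH, 6mA.
#' @examples
#' default_window_lengths("FVS")
#' @export
default_window_lengths <- function(comparison = c("FVS", "AVS", "AVF")) {
  comparison <- match.arg(comparison)
  switch(comparison,
         FVS = c(CG = 900L, CHG = 1000L, CHH = 700L, `6mA` = 400L),
         AVS = c(CG = 1000L, CHG = 900L, CHH = 700L, `6mA` = 400L),
         AVF = c(CG = 700L, CHG = 900L, CHH = 900L, `6mA` = 400L))
}

#' Write a DMR table as TSV
#' @param dmrs a `dmr_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dmr_table <- function(dmrs, path) {
  df <- as.data.frame(dmrs)
  df$member_positions <- vapply(df$members, paste, "", collapse = ",")
  df$members <- NULL
  write_tsv(df, path)
}

#' Read a DMR table written by [write_dmr_table()]
#' @param path TSV path.
#' @return `dmr_table` data.frame (member positions restored).
#' @export
read_dmr_table <- function(path) {
  df <- read_tsv(path)
  if (nrow(df)) {
    df$chrom <- as.character(df$chrom)
    df$members <- I(lapply(strsplit(as.character(df$member_positions), ","),
                           as.integer))
  } else df$members <- I(list())
  df$member_positions <- NULL
  class(df) <- c("dmr_table", "data.frame")
  df
}

#' Write DMRs as BED6
#' @param dmrs a `dmr_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(dmrs, path) {
  df <- as.data.frame(dmrs)
  bed <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                    name = paste(df$context, df$direction, sep = ":"),
                    score = round(pmin(-10 * log10(df$region_q), 1000), 1),
                    strand = ".")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
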