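## Published summary tallies from the MCSeEd survey of DNA methylation in
## apomictic vs. sexual weeping lovegrass (Eragrostis curvula) genotypes
## that this pipeline reimplements: three pairwise comparisons (FVS =
## facultative vs sexual, AVS = full apomictic vs sexual, AVF = full
## apomictic vs facultative) x four contexts. Bundled so the package's
## counting and aggregation conventions can be validated against in-print
## numbers without access to the underlying sequencing archive.

#' Published DMP tallies per comparison and context
#'
#' Numbers of differentially methylated positions (FDR < 0.05) reported for
#' each context in the three genotype comparisons of the reference study.
#'
#' @return data.frame with columns comparison, context, dmps.
#' @export
reference_dmp_tallies <- function() {
  data.frame(
    comparison = rep(c("FVS", "AVS", "AVF"), each = 4L),
    context = rep(VALID_CONTEXTS, 3L),
    dmps = c(13033L, 15385L, 18954L, 72350L,
             9909L, 9598L, 12978L, 48374L,
             10202L, 14026L, 14819L, 61487L),
    stringsAsFactors = FALSE)
}

#' Published DMR tallies per comparison and context
#'
#' @return data.frame with columns comparison, context, dmrs, and the
#'   published grand totals as attribute `totals` (named vector).
#' @export
reference_dmr_tallies <- function() {
  out <- data.frame(
    comparison = rep(c("FVS", "AVS", "AVF"), each = 4L),
    context = rep(VALID_CONTEXTS, 3L),
    dmrs = c(448L, 459L, 383L, 7343L,
             362L, 233L, 251L, 3862L,
             307L, 368L, 232L, 5070L),
    stringsAsFactors = FALSE)
  attr(out, "totals") <- c(FVS = 8633L, AVS = 4708L, AVF = 5977L)
  out
}

#' Published gene-region methylation counts
#'
#' The per-context counts of gene regions (2 kb upstream, gene body, 2 kb
#' downstream) called methylated / de-methylated in each comparison,
#' together with the per-context DMR totals - the same shape
#' [summarize_region_counts()] produces, so [aggregate_region_counts()]
#' applies to both.
#'
#' @param comparison `"FVS"`, `"AVS"` or `"AVF"`.
#' @return `region_count_table` data.frame.
#' @export
reference_region_counts <- function(comparison = c("FVS", "AVS", "AVF")) {
  comparison <- match.arg(comparison)
  cells <- switch(comparison,
    # per context: dmrs, up_meth, up_demeth, body_meth, body_demeth,
    #              down_meth, down_demeth
    FVS = list(CG = c(448, 160, 29, 139, 46, 141, 31),
               CHG = c(459, 98, 16, 214, 29, 117, 22),
               CHH = c(383, 76, 16, 110, 13, 89, 20),
               `6mA` = c(7343, 1473, 191, 1659, 198, 1484, 159)),
    AVS = list(CG = c(362, 108, 55, 94, 63, 109, 44),
               CHG = c(233, 35, 10, 113, 25, 53, 18),
               CHH = c(251, 36, 26, 66, 21, 55, 21),
               `6mA` = c(3862, 625, 260, 875, 305, 629, 250)),
    AVF = list(CG = c(307, 44, 72, 49, 98, 39, 66),
               CHG = c(368, 85, 113, 102, 154, 71, 113),
               CHH = c(232, 22, 35, 35, 41, 33, 34),
               `6mA` = c(5070, 462, 821, 543, 1049, 438, 734)))
  m <- do.call(rbind, cells)
  out <- data.frame(context = rownames(m), dmrs = m[, 1L],
                    upstream_meth = m[, 2L], upstream_demeth = m[, 3L],
                    gene_body_meth = m[, 4L], gene_body_demeth = m[, 5L],
                    downstream_meth = m[, 6L], downstream_demeth = m[, 7L],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("region_count_table", "data.frame")
  out
}

#' Published "regions overlapped at least once" totals
#'
#' The in-print per-region totals of gene regions overlapped at least once
#' by cytosine-context (5mC) DMRs, the 5mC DMR totals, and the 6mA share of
#' DMPs, used by the acceptance suite to verify that this package's
#' aggregation conventions reproduce the printed arithmetic.
#'
#' @return nested list keyed by comparison.
#' @export
reference_region_totals <- function() {
  list(
    FVS = list(five_mc_regions = c(upstream = 395, gene_body = 551,
                                   downstream = 420),
               five_mc_dmrs = 1290),
    AVS = list(five_mc_regions = c(upstream = 270, gene_body = 382,
                                   downstream = 300),
               five_mc_dmrs = 846),
    AVF = list(five_mc_regions = c(upstream = 371, gene_body = 479,
                                   downstream = 356),
               five_mc_dmrs = 907))
}
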