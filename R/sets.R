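## Cross-comparison gene sets: genes methylated / de-methylated in the
## regulatory region (2 kb flanks plus the first/last `core` bp of the gene
## body), Venn-style shared/specific partitions, and the intersection of
## differentially methylated genes (DMGs) with a differential-expression
## table.

#' Regulatory-region gene sets
#'
#' A gene qualifies when at least one DMR overlaps the union of its
#' regulatory region: `flank` bp upstream, the first `core` bp of the gene
#' body (after the ATG), the last `core` bp of the gene body (before the
#' stop codon), and `flank` bp downstream (all strand-resolved). Methylation
#' in this region is the pattern most consistently associated with
#' expression change (silenced when methylated, active when de-methylated).
#' The gene's status is the single direction of its overlapping DMRs over
#' that union; genes with both directions are excluded.
#'
#' @param dmrs `dmr_table` (typically all contexts of one comparison
#'   combined; use `contexts` to restrict).
#' @param gm `gene_models` or genes data.frame.
#' @param core gene-body core margin in bp, default 400.
#' @param flank flank length in bp, default 2000.
#' @param contexts optional character vector restricting the DMR contexts.
#' @return list of class `regulatory_sets`: `methylated`, `de_methylated`
#'   (character vectors of gene ids), `excluded` (mixed-direction genes).
#' @export
regulatory_gene_set <- function(dmrs, gm, core = 400L, flank = 2000L,
                                contexts = NULL) {
  genes <- if (inherits(gm, "gene_models")) gm$genes else as.data.frame(gm)
  dd <- as.data.frame(dmrs)
  if (!is.null(contexts)) dd <- dd[dd$context %in% contexts, , drop = FALSE]
  iv <- regulatory_intervals(genes, core, flank)
  status <- list()
  if (nrow(dd) && nrow(iv)) {
    hits <- overlap_pairs0(dd$chrom, dd$start, dd$end,
                           iv$chrom, iv$start, iv$end)
    if (nrow(hits)) {
      by_gene <- split(dd$direction[hits$query], iv$gene_id[hits$subject])
      status <- lapply(by_gene, unique)
    }
  }
  meth <- names(status)[vapply(status, function(d)
    identical(d, "methylated"), TRUE)]
  demeth <- names(status)[vapply(status, function(d)
    identical(d, "de-methylated"), TRUE)]
  mixed <- setdiff(names(status), c(meth, demeth))
  structure(list(methylated = sort(meth), de_methylated = sort(demeth),
                 excluded = sort(mixed)),
            class = "regulatory_sets")
}

# strand-resolved regulatory union per gene: upstream flank, first and last
# `core` bp of the body, downstream flank (0-based half-open, clipped at 0)
regulatory_intervals <- function(genes, core, flank) {
  len <- genes$end - genes$start
  core1 <- pmin(core, len)
  parts <- rbind(
    data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
               start = ifelse(genes$strand == "+", genes$start - flank,
                              genes$end),
               end = ifelse(genes$strand == "+", genes$start,
                            genes$end + flank)),
    data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
               start = ifelse(genes$strand == "+", genes$end,
                              genes$start - flank),
               end = ifelse(genes$strand == "+", genes$end + flank,
                            genes$start)),
    data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
               start = ifelse(genes$strand == "+", genes$start,
                              genes$end - core1),
               end = ifelse(genes$strand == "+", genes$start + core1,
                            genes$end)),
    data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
               start = ifelse(genes$strand == "+", genes$end - core1,
                              genes$start),
               end = ifelse(genes$strand == "+", genes$end,
                            genes$start + core1)))
  parts$start <- pmax(parts$start, 0L)
  parts[parts$end > parts$start, , drop = FALSE]
}

#' @export
print.regulatory_sets <- function(x, ...) {
  cat(sprintf("regulatory_sets: %d methylated, %d de-methylated, %d excluded (mixed)\n",
              length(x$methylated), length(x$de_methylated),
              length(x$excluded)))
  invisible(x)
}

#' Shared and specific genes between two comparisons
#'
#' Standard Venn partition of two gene sets of the same methylation status
#' (e.g. genes methylated in the facultative-vs-sexual and in the full
#' apomictic-vs-sexual comparisons).
#'
#' @param setA,setB character vectors of gene ids, or `regulatory_sets`
#'   objects together with `status`.
#' @param status when passing `regulatory_sets` objects, which status to
#'   extract (`"methylated"` or `"de_methylated"`); must be available in
#'   both.
#' @return list of class `venn_partition`: `shared`, `a_specific`,
#'   `b_specific`, and `counts`.
#' @export
venn_sets <- function(setA, setB, status = NULL) {
  pick <- function(s) {
    if (inherits(s, "regulatory_sets")) {
      if (is.null(status))
        stop_config("status required when passing regulatory_sets objects")
      if (!status %in% names(s))
        stop_config("status %s not present in set object", status)
      s[[status]]
    } else as.character(s)
  }
  a <- unique(pick(setA))
  b <- unique(pick(setB))
  out <- list(shared = sort(intersect(a, b)),
              a_specific = sort(setdiff(a, b)),
              b_specific = sort(setdiff(b, a)))
  out$counts <- lengths(out[c("shared", "a_specific", "b_specific")])
  class(out) <- "venn_partition"
  out
}

#' @export
print.venn_partition <- function(x, ...) {
  cat(sprintf("venn_partition: shared %d | A-specific %d | B-specific %d\n",
              x$counts[["shared"]], x$counts[["a_specific"]],
              x$counts[["b_specific"]]))
  invisible(x)
}

#' Read a differential-expression table
#'
#' TSV with columns `gene_id`, `logFC`, `FDR` (case-insensitive, `log_fold_change`
#' and `fdr` also accepted). Expression status is `up` for positive
#' log-fold-change, `down` for negative.
#'
#' @param path TSV path.
#' @return data.frame gene_id, log_fold_change, fdr, deg_status.
#' @export
read_deg_table <- function(path) {
  tab <- read_tsv(path)
  names(tab) <- tolower(names(tab))
  lfc <- tab[["logfc"]] %||% tab[["log_fold_change"]]
  fdr <- tab[["fdr"]]
  if (is.null(tab$gene_id) || is.null(lfc) || is.null(fdr))
    stop_format("%s: DE table needs gene_id, logFC, FDR columns", path)
  data.frame(gene_id = as.character(tab$gene_id),
             log_fold_change = as.numeric(lfc),
             fdr = as.numeric(fdr),
             deg_status = ifelse(lfc > 0, "up", "down"),
             stringsAsFactors = FALSE)
}

#' Intersect differentially methylated and differentially expressed genes
#'
#' Inner join on gene id between gene-region methylation calls and a
#' differential-expression table. Each gene is reported once, with all its
#' supporting (context, region, status) annotations collapsed, its
#' expression status, and a human-readable concordance note such as
#' `"6mA gene_body methylated + downregulated"`.
#'
#' @param dmg_calls `gene_region_calls` (ambiguous rows are dropped).
#' @param deg_table data.frame from [read_deg_table()].
#' @return data.frame of class `dmg_deg_table`: gene_id, contexts, regions,
#'   methylation, deg_status, log_fold_change, concordance.
#' @export
cross_dmg_deg <- function(dmg_calls, deg_table) {
  cc <- as.data.frame(dmg_calls)
  cc <- cc[cc$status %in% VALID_DIRECTIONS, , drop = FALSE]
  shared <- intersect(unique(cc$gene_id), unique(deg_table$gene_id))
  if (length(shared) == 0L) {
    message("cross_dmg_deg: no genes shared between DMG and DEG sets")
    out <- data.frame(gene_id = character(), contexts = character(),
                      regions = character(), methylation = character(),
                      deg_status = character(), log_fold_change = numeric(),
                      concordance = character(), stringsAsFactors = FALSE)
    class(out) <- c("dmg_deg_table", "data.frame")
    return(out)
  }
  rows <- lapply(sort(shared), function(g) {
    sub <- cc[cc$gene_id == g, , drop = FALSE]
    deg <- deg_table[match(g, deg_table$gene_id), ]
    reg_word <- if (deg$deg_status == "up") "upregulated" else "downregulated"
    note <- paste(sprintf("%s %s %s + %s", sub$context, sub$region,
                          sub$status, reg_word), collapse = "; ")
    data.frame(gene_id = g,
               contexts = paste(unique(sub$context), collapse = ","),
               regions = paste(unique(sub$region), collapse = ","),
               methylation = paste(unique(sub$status), collapse = ","),
               deg_status = deg$deg_status,
               log_fold_change = deg$log_fold_change,
               concordance = note, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("dmg_deg_table", "data.frame")
  out
}
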