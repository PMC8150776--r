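## Extended gene bodies (EGB): a gene plus 2 kb upstream and 2 kb downstream
## flanks, disaggregated into three strand-resolved regions. DMR assignment,
## per-gene-region methylation calls with the mixed-direction ambiguity
## filter, Table-style summaries, and metagene DMP profiles.

#' Load gene models from GFF3
#'
#' Reads gene/mRNA/exon features (UTRs optional). When a gene has several
#' transcripts the longest one (genomic span) defines the gene body and its
#' exons are kept. Coordinates are converted to 0-based half-open. Records
#' without a strand are skipped with a warning.
#'
#' @param path GFF3 file.
#' @return list of class `gene_models` with `genes`
#'   (gene_id, chrom, strand, start, end) and `exons`
#'   (gene_id, chrom, start, end) data.frames.
#' @export
load_gene_models <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop_format("malformed GFF3 %s: %s",
                                                 path, conditionMessage(e)))
  df <- as.data.frame(gr)
  df$type <- as.character(df$type)
  genes <- df[df$type == "gene", , drop = FALSE]
  mrnas <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  exons <- df[df$type == "exon", , drop = FALSE]
  if (nrow(genes) == 0L) stop_format("%s contains no gene features", path)

  strand <- as.character(genes$strand)
  unstranded <- !strand %in% c("+", "-")
  if (any(unstranded)) {
    warning(sprintf("skipping %d gene(s) without strand", sum(unstranded)))
    genes <- genes[!unstranded, , drop = FALSE]
  }
  gene_id <- as.character(genes$ID)
  out_genes <- data.frame(gene_id = gene_id,
                          chrom = as.character(genes$seqnames),
                          strand = as.character(genes$strand),
                          start = genes$start - 1L,  # to 0-based half-open
                          end = genes$end,
                          stringsAsFactors = FALSE)

  parent_of <- function(x) vapply(x, function(p)
    if (length(p)) as.character(p[[1L]]) else NA_character_, "")
  exon_rows <- list()
  if (nrow(mrnas)) {
    m_parent <- parent_of(mrnas$Parent)
    for (i in seq_len(nrow(out_genes))) {
      gid <- out_genes$gene_id[i]
      mi <- which(m_parent == gid)
      if (length(mi)) {
        spans <- mrnas$end[mi] - mrnas$start[mi] + 1L
        best <- mi[which.max(spans)]
        out_genes$start[i] <- mrnas$start[best] - 1L
        out_genes$end[i] <- mrnas$end[best]
        if (nrow(exons)) {
          tid <- as.character(mrnas$ID[best])
          ei <- which(parent_of(exons$Parent) == tid)
          if (length(ei))
            exon_rows[[gid]] <- data.frame(
              gene_id = gid, chrom = out_genes$chrom[i],
              start = exons$start[ei] - 1L, end = exons$end[ei],
              stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (nrow(exons) && length(exon_rows) == 0L) {
    e_parent <- parent_of(exons$Parent)
    hit <- e_parent %in% out_genes$gene_id
    if (any(hit))
      exon_rows[["."]] <- data.frame(
        gene_id = e_parent[hit],
        chrom = as.character(exons$seqnames[hit]),
        start = exons$start[hit] - 1L, end = exons$end[hit],
        stringsAsFactors = FALSE)
  }
  out_exons <- if (length(exon_rows)) do.call(rbind, unname(exon_rows))
  else data.frame(gene_id = character(), chrom = character(),
                  start = integer(), end = integer())
  o <- coord_order(out_genes$chrom, out_genes$start)
  out_genes <- out_genes[o, , drop = FALSE]
  rownames(out_genes) <- rownames(out_exons) <- NULL
  structure(list(genes = out_genes, exons = out_exons),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes, %d exons on %d sequence(s)\n",
              nrow(x$genes), nrow(x$exons), length(unique(x$genes$chrom))))
  invisible(x)
}

#' Disaggregate genes into extended-gene-body regions
#'
#' Each gene yields three disjoint regions: `upstream` (the `flank` bp 5' of
#' the transcription start on the coding strand), `gene_body`, and
#' `downstream` (`flank` bp 3'). On the minus strand upstream/downstream are
#' mirrored. Flanks are clipped at chromosome bounds when `chrom_lengths`
#' (named vector) is supplied.
#'
#' @param gm `gene_models` or a genes data.frame.
#' @param flank flank length in bp, default 2000.
#' @param chrom_lengths optional named vector of chromosome lengths.
#' @return data.frame of class `egb_regions`: gene_id, region, chrom,
#'   strand, start, end (0-based half-open).
#' @export
disaggregate_egb <- function(gm, flank = 2000L, chrom_lengths = NULL) {
  genes <- if (inherits(gm, "gene_models")) gm$genes else as.data.frame(gm)
  stopifnot(flank > 0)
  up_start <- ifelse(genes$strand == "+", genes$start - flank, genes$end)
  up_end <- ifelse(genes$strand == "+", genes$start, genes$end + flank)
  dn_start <- ifelse(genes$strand == "+", genes$end, genes$start - flank)
  dn_end <- ifelse(genes$strand == "+", genes$end + flank, genes$start)
  out <- rbind(
    data.frame(gene_id = genes$gene_id, region = "upstream",
               chrom = genes$chrom, strand = genes$strand,
               start = up_start, end = up_end, stringsAsFactors = FALSE),
    data.frame(gene_id = genes$gene_id, region = "gene_body",
               chrom = genes$chrom, strand = genes$strand,
               start = genes$start, end = genes$end, stringsAsFactors = FALSE),
    data.frame(gene_id = genes$gene_id, region = "downstream",
               chrom = genes$chrom, strand = genes$strand,
               start = dn_start, end = dn_end, stringsAsFactors = FALSE))
  out$start <- pmax(out$start, 0L)
  if (!is.null(chrom_lengths)) {
    lim <- chrom_lengths[out$chrom]
    if (anyNA(lim)) stop_config("chrom_lengths missing for: %s",
                                paste(unique(out$chrom[is.na(lim)]), collapse = ", "))
    out$end <- pmin(out$end, unname(lim))
    out$start <- pmin(out$start, out$end)
  }
  o <- coord_order(out$chrom, out$start)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("egb_regions", "data.frame")
  out
}

#' Assign DMRs to EGB regions
#'
#' Half-open interval intersection (>= 1 bp). A DMR may hit several regions
#' and several genes; each (DMR, region) pair is emitted once.
#'
#' @param dmrs `dmr_table`.
#' @param regions `egb_regions` from [disaggregate_egb()].
#' @return data.frame of overlaps: dmr_id (row index into `dmrs`), gene_id,
#'   region, context, comparison, direction plus the DMR coordinates.
#' @export
assign_dmrs_to_regions <- function(dmrs, regions) {
  dd <- as.data.frame(dmrs)
  rr <- as.data.frame(regions)
  if (nrow(dd) == 0L || nrow(rr) == 0L)
    return(data.frame(dmr_id = integer(), gene_id = character(),
                      region = character(), context = character(),
                      comparison = character(), direction = character(),
                      chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  hits <- overlap_pairs0(dd$chrom, dd$start, dd$end,
                         rr$chrom, rr$start, rr$end)
  data.frame(dmr_id = hits$query,
             gene_id = rr$gene_id[hits$subject],
             region = rr$region[hits$subject],
             context = dd$context[hits$query],
             comparison = dd$comparison[hits$query],
             direction = dd$direction[hits$query],
             chrom = dd$chrom[hits$query],
             start = dd$start[hits$query],
             end = dd$end[hits$query],
             stringsAsFactors = FALSE)
}

#' Per-gene-region methylation status calls
#'
#' For every (gene, region, context) with at least one overlapping DMR:
#' `methylated` if all overlapping DMRs are methylated-direction,
#' `de-methylated` if all are de-methylated, and `ambiguous` if both
#' directions occur in the same region and comparison (ambiguous regions are
#' excluded from downstream gene sets). Regions without any overlap are not
#' emitted (implicit status "none").
#'
#' @param overlaps output of [assign_dmrs_to_regions()] for one comparison.
#' @return data.frame of class `gene_region_calls`: gene_id, region,
#'   context, comparison, status, n_dmrs, dmr_ids (list-column).
#' @export
classify_gene_regions <- function(overlaps) {
  ov <- as.data.frame(overlaps)
  if (nrow(ov) == 0L) {
    out <- data.frame(gene_id = character(), region = character(),
                      context = character(), comparison = character(),
                      status = character(), n_dmrs = integer(),
                      stringsAsFactors = FALSE)
    out$dmr_ids <- I(list())
    class(out) <- c("gene_region_calls", "data.frame")
    return(out)
  }
  key <- paste(ov$gene_id, ov$region, ov$context, sep = "\r")
  grp <- split(seq_len(nrow(ov)), key)
  rows <- lapply(grp, function(idx) {
    dirs <- unique(ov$direction[idx])
    status <- if (length(dirs) == 1L) dirs else "ambiguous"
    data.frame(gene_id = ov$gene_id[idx[1L]], region = ov$region[idx[1L]],
               context = ov$context[idx[1L]],
               comparison = ov$comparison[idx[1L]],
               status = status, n_dmrs = length(unique(ov$dmr_id[idx])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$dmr_ids <- I(lapply(grp, function(idx) unique(ov$dmr_id[idx])))
  rownames(out) <- NULL
  class(out) <- c("gene_region_calls", "data.frame")
  out
}

#' Summarize gene-region calls into a per-context count table
#'
#' Produces the standard summary shape of this assay: per context, the
#' number of distinct gene regions called methylated and de-methylated at
#' 2 kb upstream, gene body and 2 kb downstream (ambiguous regions are
#' excluded), plus the total DMR count per context when `dmrs` is given.
#' Genes are counted once per region however many DMRs hit it
#' ("overlapped at least once").
#'
#' @param calls `gene_region_calls`.
#' @param dmrs optional `dmr_table` for the per-context DMR totals.
#' @return data.frame of class `region_count_table` with columns context,
#'   dmrs, upstream_meth, upstream_demeth, gene_body_meth, gene_body_demeth,
#'   downstream_meth, downstream_demeth.
#' @export
summarize_region_counts <- function(calls, dmrs = NULL) {
  cc <- as.data.frame(calls)
  contexts <- VALID_CONTEXTS
  out <- data.frame(context = contexts, dmrs = 0L,
                    upstream_meth = 0L, upstream_demeth = 0L,
                    gene_body_meth = 0L, gene_body_demeth = 0L,
                    downstream_meth = 0L, downstream_demeth = 0L,
                    stringsAsFactors = FALSE)
  if (nrow(cc)) {
    cc <- cc[cc$status %in% VALID_DIRECTIONS, , drop = FALSE]
    for (i in seq_along(contexts)) {
      for (reg in c("upstream", "gene_body", "downstream")) {
        sel <- cc$context == contexts[i] & cc$region == reg
        out[[paste0(reg, "_meth")]][i] <-
          length(unique(cc$gene_id[sel & cc$status == "methylated"]))
        out[[paste0(reg, "_demeth")]][i] <-
          length(unique(cc$gene_id[sel & cc$status == "de-methylated"]))
      }
    }
  }
  if (!is.null(dmrs)) {
    dd <- as.data.frame(dmrs)
    tab <- table(factor(dd$context, levels = contexts))
    out$dmrs <- as.integer(tab)
  }
  class(out) <- c("region_count_table", "data.frame")
  out
}

#' Aggregate a region count table
#'
#' Computes the headline totals from a [summarize_region_counts()]-shaped
#' table: per-region totals of methylated + de-methylated gene regions over
#' the cytosine contexts (5mC = CG + CHG + CHH) and over 6mA, the 5mC and
#' 6mA DMR totals, and the grand DMR total.
#'
#' @param x `region_count_table` (columns as in [summarize_region_counts()]).
#' @return list with `five_mc_regions` and `six_ma_regions` (named vectors
#'   upstream/gene_body/downstream), `five_mc_dmrs`, `six_ma_dmrs`,
#'   `total_dmrs`.
#' @export
aggregate_region_counts <- function(x) {
  x <- as.data.frame(x)
  cyt <- x$context %in% c("CG", "CHG", "CHH")
  ade <- x$context == "6mA"
  tot <- function(sel, reg)
    sum(x[[paste0(reg, "_meth")]][sel] + x[[paste0(reg, "_demeth")]][sel])
  regs <- c("upstream", "gene_body", "downstream")
  list(five_mc_regions = setNames(vapply(regs, function(r) tot(cyt, r), 0), regs),
       six_ma_regions = setNames(vapply(regs, function(r) tot(ade, r), 0), regs),
       five_mc_dmrs = sum(x$dmrs[cyt]),
       six_ma_dmrs = sum(x$dmrs[ade]),
       total_dmrs = sum(x$dmrs))
}

#' Metagene profile of DMPs around start and stop codons
#'
#' Bins strand-resolved DMP offsets from the translation start (ATG) and
#' from the stop codon at `bin` bp over +/- `span` bp, summed across genes.
#' Only the gene-body side within `span` of each anchor contributes (gene
#' bodies are truncated at `span` from the anchor); the flank side uses the
#' corresponding EGB flank. Input DMPs should be restricted to members of
#' DMRs (pass `dmp_positions` from a `dmr_table`, see
#' [dmr_member_positions()]).
#'
#' @param dmps data.frame with chrom, pos (0-based DMP positions).
#' @param gm `gene_models` or genes data.frame.
#' @param bin bin width in bp, default 100.
#' @param span half-window around each anchor in bp, default 2000.
#' @return data.frame of class `metagene_profile`: anchor (`"ATG"` or
#'   `"STOP"`), offset (bin left edge), count.
#' @export
metagene_profile <- function(dmps, gm, bin = 100L, span = 2000L) {
  genes <- if (inherits(gm, "gene_models")) gm$genes else as.data.frame(gm)
  dd <- as.data.frame(dmps)
  edges <- seq(-span, span - bin, by = bin)
  counts_atg <- setNames(integer(length(edges)), edges)
  counts_stop <- setNames(integer(length(edges)), edges)
  if (nrow(dd) && nrow(genes)) {
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      p <- dd$pos[dd$chrom == g$chrom]
      if (!length(p)) next
      if (g$strand == "+") {
        off_atg <- p - g$start
        in_atg <- (off_atg < 0 & off_atg >= -span) |
          (off_atg >= 0 & off_atg < span & p < g$end)
        off_stop <- p - g$end
        in_stop <- (off_stop >= 0 & off_stop < span) |
          (off_stop < 0 & off_stop >= -span & p >= g$start)
      } else {
        off_atg <- (g$end - 1L) - p
        in_atg <- (off_atg < 0 & off_atg >= -span) |
          (off_atg >= 0 & off_atg < span & p >= g$start)
        off_stop <- (g$start - 1L) - p
        in_stop <- (off_stop >= 0 & off_stop < span) |
          (off_stop < 0 & off_stop >= -span & p < g$end)
      }
      if (any(in_atg)) {
        b <- table(factor(bin * floor(off_atg[in_atg] / bin), levels = edges))
        counts_atg <- counts_atg + as.integer(b)
      }
      if (any(in_stop)) {
        b <- table(factor(bin * floor(off_stop[in_stop] / bin), levels = edges))
        counts_stop <- counts_stop + as.integer(b)
      }
    }
  }
  out <- rbind(
    data.frame(anchor = "ATG", offset = edges, count = unname(counts_atg)),
    data.frame(anchor = "STOP", offset = edges, count = unname(counts_stop)))
  class(out) <- c("metagene_profile", "data.frame")
  out
}

#' Member DMP positions of a DMR table
#'
#' @param dmrs `dmr_table`.
#' @return data.frame chrom, pos of all member DMPs (one row per DMP per DMR).
#' @export
dmr_member_positions <- function(dmrs) {
  dd <- as.data.frame(dmrs)
  if (nrow(dd) == 0L)
    return(data.frame(chrom = character(), pos = integer()))
  data.frame(chrom = rep(dd$chrom, lengths(dd$members)),
             pos = unlist(dd$members, use.names = FALSE))
}

#' Count DMRs by genomic feature
#'
#' For each DMR, checks overlap with exons, introns (gene body minus exons),
#' upstream/downstream flanks, and whether it is entirely intergenic
#' (no EGB overlap). A DMR can contribute to several feature classes.
#'
#' @param dmrs `dmr_table`.
#' @param gm `gene_models`.
#' @param flank flank length, default 2000.
#' @return named integer vector: exon, intron, upstream, downstream,
#'   intergenic.
#' @export
feature_overlap_counts <- function(dmrs, gm, flank = 2000L) {
  dd <- as.data.frame(dmrs)
  out <- c(exon = 0L, intron = 0L, upstream = 0L, downstream = 0L,
           intergenic = 0L)
  if (nrow(dd) == 0L) return(out)
  regions <- disaggregate_egb(gm, flank)
  ov <- assign_dmrs_to_regions(dd, regions)
  hit_exon <- rep(FALSE, nrow(dd))
  if (nrow(gm$exons)) {
    he <- overlap_pairs0(dd$chrom, dd$start, dd$end,
                         gm$exons$chrom, gm$exons$start, gm$exons$end)
    hit_exon[unique(he$query)] <- TRUE
  }
  hit_body <- seq_len(nrow(dd)) %in% ov$dmr_id[ov$region == "gene_body"]
  out["exon"] <- sum(hit_exon)
  out["intron"] <- sum(hit_body & !hit_exon)
  out["upstream"] <- length(unique(ov$dmr_id[ov$region == "upstream"]))
  out["downstream"] <- length(unique(ov$dmr_id[ov$region == "downstream"]))
  out["intergenic"] <- sum(!seq_len(nrow(dd)) %in% ov$dmr_id)
  out
}
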