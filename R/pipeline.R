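## Pipeline driver: configuration, end-to-end execution with a JSON run
## manifest, and the DMP-based PCA variance report.

#' Pipeline configuration
#'
#' Bundles every path and tunable of one comparison run. Count tables and
#' sample sheets are supplied per context (named lists / vectors keyed by
#' context); window lengths may be integers per context or `"auto"` to run
#' the window-length scan.
#'
#' @param counts named character vector of count-table TSV paths, one per
#'   context to analyze.
#' @param sample_sheets named character vector of sample-sheet TSV paths
#'   (same names as `counts`), or a single path shared by all contexts.
#' @param gff3 gene-model GFF3 path (optional; EGB stages are skipped when
#'   `NULL`).
#' @param deg optional differential-expression TSV path.
#' @param comparison comparison label, e.g. `"FVS"`.
#' @param windows `"auto"`, a single integer, or a named vector per context.
#' @param fdr FDR threshold for DMPs and DMRs, default 0.05.
#' @param flank EGB flank length (bp), default 2000.
#' @param core regulatory gene-body core margin (bp), default 400.
#' @param bin metagene bin width (bp), default 100.
#' @param cv_colog co-logarithm CV-filter threshold, default -0.35.
#' @param pseudo_coverage binomial pseudo-coverage, default 100.
#' @param min_cluster_size minimum DMPs per DMR, default 2.
#' @param overdispersion DMP/DMR test overdispersion handling, see
#'   [call_dmps()].
#' @param seed integer seed recorded in the manifest.
#' @param out_dir output directory.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, sample_sheets, gff3 = NULL, deg = NULL,
                            comparison = "FVS", windows = "auto",
                            fdr = 0.05, flank = 2000L, core = 400L,
                            bin = 100L, cv_colog = -0.35,
                            pseudo_coverage = 100L, min_cluster_size = 2L,
                            overdispersion = "shrink", seed = 1L,
                            out_dir = tempfile("mcseedr_run_")) {
  stopifnot(fdr > 0, fdr < 1, flank > 0, core > 0, bin > 0,
            pseudo_coverage >= 1)
  if (is.null(names(counts)))
    stop_config("counts must be named by context")
  if (length(sample_sheets) == 1L && is.null(names(sample_sheets)))
    sample_sheets <- setNames(rep(sample_sheets, length(counts)),
                              names(counts))
  for (p in c(unname(counts), unname(sample_sheets), gff3, deg))
    if (!file.exists(p)) stop_config("input file does not exist: %s", p)
  structure(list(counts = counts, sample_sheets = sample_sheets,
                 gff3 = gff3, deg = deg, comparison = comparison,
                 windows = windows, fdr = fdr, flank = as.integer(flank),
                 core = as.integer(core), bin = as.integer(bin),
                 cv_colog = cv_colog,
                 pseudo_coverage = as.integer(pseudo_coverage),
                 min_cluster_size = as.integer(min_cluster_size),
                 overdispersion = overdispersion,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

window_for <- function(cfg, context) {
  w <- cfg$windows
  if (identical(w, "auto")) return("auto")
  if (length(w) == 1L && is.null(names(w))) return(as.integer(w))
  if (!context %in% names(w))
    stop_config("no window length configured for context %s", context)
  as.integer(w[[context]])
}

#' Run the full pipeline
#'
#' Executes, per context: normalize, CV filter, relative methylation, DMP
#' calling, DMR calling (fixed or optimized window), then - when gene
#' models are available - EGB annotation, gene-region classification,
#' region-count summaries and metagene profiles; finally the cross-context
#' regulatory gene sets and, when a DE table is configured, the DMG x DEG
#' intersection. All tables are written as TSV/BED under `cfg$out_dir`
#' together with a JSON run manifest with per-stage counts. Deterministic
#' given the config (the seed only matters for `"auto"`-window tie handling
#' and is recorded for provenance).
#'
#' @param cfg a [pipeline_config()].
#' @return the manifest (list), invisibly; the same content is written to
#'   `manifest.json`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    message(sprintf("[%s] %s (%.2fs)", cfg$comparison, name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    out
  }
  gm <- if (!is.null(cfg$gff3)) stage("load_gene_models",
                                      load_gene_models(cfg$gff3)) else NULL
  manifest <- list(package = "mcseedr",
                   version = as.character(utils::packageVersion("mcseedr")),
                   comparison = cfg$comparison, seed = cfg$seed,
                   parameters = cfg[c("fdr", "flank", "core", "bin",
                                      "cv_colog", "pseudo_coverage",
                                      "min_cluster_size", "overdispersion")],
                   contexts = list())
  all_calls <- list()
  all_dmrs <- list()
  for (context in names(cfg$counts)) {
    meta <- read_sample_sheet(cfg$sample_sheets[[context]])
    meta <- meta[meta$context == context, , drop = FALSE]
    m <- stage(paste0(context, ": read"),
               read_count_table(cfg$counts[[context]], meta))
    norm <- stage(paste0(context, ": normalize"), normalize_counts(m))
    filt <- stage(paste0(context, ": cv_filter"),
                  filter_by_cv(norm, cfg$cv_colog))
    r <- stage(paste0(context, ": relmeth"),
               relative_methylation(filt$matrix))
    dmps_all <- stage(paste0(context, ": dmps"),
                      call_dmps(r, fdr = cfg$fdr,
                                pseudo_coverage = cfg$pseudo_coverage,
                                overdispersion = cfg$overdispersion,
                                return_all = TRUE))
    dmps <- dmps_all[dmps_all$is_dmp, , drop = FALSE]
    class(dmps) <- class(dmps_all)
    dmr_run <- stage(paste0(context, ": dmrs"),
                     call_dmrs(dmps, r, window_length = window_for(cfg, context),
                               min_cluster_size = cfg$min_cluster_size,
                               fdr = cfg$fdr,
                               pseudo_coverage = cfg$pseudo_coverage,
                               overdispersion = cfg$overdispersion,
                               comparison = cfg$comparison))
    pca <- if (nrow(dmps) >= 2L)
      pca_variance(r, dmp_positions = dmps[c("chrom", "pos")]) else NULL

    pre <- file.path(cfg$out_dir, context)
    write_tsv(filt$report, paste0(pre, "_cv_filter.tsv"))
    write_dmp_table(dmps, paste0(pre, "_dmps.tsv"))
    write_dmp_bed(dmps, paste0(pre, "_dmps.bed"))
    write_dmr_table(dmr_run$dmrs, paste0(pre, "_dmrs.tsv"))
    write_dmr_bed(dmr_run$dmrs, paste0(pre, "_dmrs.bed"))
    if (!is.null(dmr_run$scan))
      write_tsv(dmr_run$scan$scan, paste0(pre, "_window_scan.tsv"))

    ctx_manifest <- list(
      n_loci = nrow(m$counts),
      n_filtered = nrow(filt$matrix$counts),
      n_discarded = filt$n_discarded,
      n_tested = nrow(dmps_all),
      n_dmps = nrow(dmps),
      n_clusters = nrow(dmr_run$clusters),
      n_dmrs = nrow(dmr_run$dmrs),
      window_length = dmr_run$window_length,
      pca_pc1_pct = if (!is.null(pca)) pca$variance_pct[1L] else NA)

    if (!is.null(gm)) {
      regions <- disaggregate_egb(gm, cfg$flank)
      ov <- assign_dmrs_to_regions(dmr_run$dmrs, regions)
      calls <- classify_gene_regions(ov)
      all_calls[[context]] <- calls
      all_dmrs[[context]] <- dmr_run$dmrs
      prof <- metagene_profile(dmr_member_positions(dmr_run$dmrs), gm,
                               bin = cfg$bin, span = cfg$flank)
      calls_out <- as.data.frame(calls)
      calls_out$dmr_ids <- vapply(calls_out$dmr_ids, paste, "", collapse = ",")
      write_tsv(calls_out, paste0(pre, "_gene_region_calls.tsv"))
      write_tsv(as.data.frame(prof), paste0(pre, "_metagene.tsv"))
      ctx_manifest$n_gene_region_calls <- nrow(calls)
      ctx_manifest$n_ambiguous <- sum(calls$status == "ambiguous")
    }
    manifest$contexts[[context]] <- ctx_manifest
  }

  if (!is.null(gm) && length(all_calls)) {
    combined_calls <- do.call(rbind, lapply(all_calls, as.data.frame))
    combined_dmrs <- do.call(rbind, lapply(all_dmrs, function(d) {
      d <- as.data.frame(d); d$members <- NULL; d
    }))
    summary_tab <- summarize_region_counts(
      do.call(rbind, lapply(all_calls, as.data.frame)),
      dmrs = combined_dmrs)
    write_tsv(as.data.frame(summary_tab),
              file.path(cfg$out_dir, "region_counts.tsv"))
    sets <- regulatory_gene_set(combined_dmrs, gm, core = cfg$core,
                                flank = cfg$flank)
    write_tsv(data.frame(
      gene_id = c(sets$methylated, sets$de_methylated, sets$excluded),
      status = rep(c("methylated", "de-methylated", "ambiguous"),
                   c(length(sets$methylated), length(sets$de_methylated),
                     length(sets$excluded)))),
      file.path(cfg$out_dir, "regulatory_gene_sets.tsv"))
    agg <- aggregate_region_counts(summary_tab)
    manifest$summary <- list(
      five_mc_dmrs = agg$five_mc_dmrs, six_ma_dmrs = agg$six_ma_dmrs,
      total_dmrs = agg$total_dmrs,
      n_meth_genes = length(sets$methylated),
      n_demeth_genes = length(sets$de_methylated),
      n_mixed_genes = length(sets$excluded))
    if (!is.null(cfg$deg)) {
      deg <- read_deg_table(cfg$deg)
      keep <- combined_calls$status %in% VALID_DIRECTIONS
      cross <- cross_dmg_deg(combined_calls[keep, , drop = FALSE], deg)
      write_tsv(as.data.frame(cross),
                file.path(cfg$out_dir, "dmg_deg_intersection.tsv"))
      manifest$summary$n_dmg_deg <- nrow(cross)
    }
  }
  jsonlite::write_json(manifest,
                       file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' PCA variance report on DMP relative methylation
#'
#' Centered principal component analysis of the libraries (samples as
#' observations, DMP relative-methylation values as variables), reporting
#' the per-component variance-explained percentages. The first component
#' separating the two genotype groups with a large share of the variance is
#' the expected signature of genuine group-level methylation differences.
#'
#' @param r `relmeth_matrix`.
#' @param dmp_positions optional data.frame (chrom, pos) restricting the
#'   analysis to DMP rows (recommended, and the pipeline default); `NULL`
#'   uses all rows.
#' @return list of class `pca_result`: `variance_pct` (non-negative, sums
#'   to <= 100) and `scores` (libraries x components).
#' @export
pca_variance <- function(r, dmp_positions = NULL) {
  stopifnot(inherits(r, "relmeth_matrix"))
  x <- r$relmeth
  if (!is.null(dmp_positions)) {
    rows <- match(paste(dmp_positions$chrom, dmp_positions$pos),
                  paste(r$positions$chrom, r$positions$pos))
    if (anyNA(rows)) stop_data("DMP position absent from relmeth matrix")
    x <- x[rows, , drop = FALSE]
  }
  if (ncol(x) < 2L) stop_config("PCA needs >= 2 samples")
  if (nrow(x) < 2L) stop_config("PCA needs >= 2 positions")
  pc <- prcomp(t(x), center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  structure(list(variance_pct = 100 * v / sum(v), scores = pc$x),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("pca_result: variance explained (%):\n")
  print(round(x$variance_pct[seq_len(min(5L, length(x$variance_pct)))], 1))
  invisible(x)
}
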