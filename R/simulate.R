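## Synthetic MCSeEd-like data: negative-binomial per-locus counts with
## planted differential methylation (clustered blocks that should surface as
## DMRs, and isolated positions that must not), plus simulated gene models
## and a truth table for calibration and parameter-recovery testing.

#' Simulation configuration
#'
#' Defaults emulate the study design this package targets: two genotype
#' groups with 3 replicates each per context (the full design is 3 genotypes
#' x 4 contexts x 3 replicates = 36 libraries; one pairwise comparison is
#' simulated at a time), overdispersed negative-binomial counts, and effect
#' loci laid out partly in clustered blocks (planted DMRs) and partly
#' isolated (planted singleton DMPs). Counts anti-correlate with
#' methylation: expected count is `nb_mean * (1 - methylation)`.
#'
#' @param seed integer seed; all randomness derives from it.
#' @param n_chrom number of chromosomes, default 2.
#' @param chrom_length chromosome length in bp, default 1e6.
#' @param loci_per_chrom MCSeEd loci per chromosome per context (default
#'   2000, i.e. one locus per ~500 bp, a desk-scale stand-in for the ~1e6
#'   loci per context of a real run).
#' @param groups two group labels; group 1 is the (facultative/full)
#'   apomictic side of a comparison by convention.
#' @param replicates replicates per group, default 3.
#' @param nb_mean negative-binomial mean count at methylation 0, default 200.
#' @param nb_dispersion NB dispersion (edgeR sense: variance =
#'   `mu + dispersion * mu^2`; biological CV = sqrt(dispersion)), default 0.1.
#' @param frac_dmp fraction of loci with a planted group effect, default
#'   0.03.
#' @param effect_size planted difference in methylation between groups,
#'   default 0.5.
#' @param n_dmr_blocks number of planted clustered blocks, default 20.
#' @param dmr_block_loci loci per planted block, default 4.
#' @param dmr_block_spacing intra-block locus spacing in bp, default 150.
#' @param n_genes genes for [simulate_gene_models()], default 100.
#' @param gene_length min/max gene length in bp, default c(1000, 5000).
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_chrom = 2L, chrom_length = 1e6,
                       loci_per_chrom = 2000L,
                       groups = c("apomictic", "sexual"), replicates = 3L,
                       nb_mean = 200, nb_dispersion = 0.1, frac_dmp = 0.03,
                       effect_size = 0.5, n_dmr_blocks = 20L,
                       dmr_block_loci = 4L, dmr_block_spacing = 150L,
                       n_genes = 100L, gene_length = c(1000L, 5000L)) {
  cfg <- list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
              chrom_length = as.integer(chrom_length),
              loci_per_chrom = as.integer(loci_per_chrom),
              groups = as.character(groups),
              replicates = as.integer(replicates),
              nb_mean = nb_mean, nb_dispersion = nb_dispersion,
              frac_dmp = frac_dmp, effect_size = effect_size,
              n_dmr_blocks = as.integer(n_dmr_blocks),
              dmr_block_loci = as.integer(dmr_block_loci),
              dmr_block_spacing = as.integer(dmr_block_spacing),
              n_genes = as.integer(n_genes),
              gene_length = as.integer(gene_length))
  if (length(cfg$groups) != 2L) stop_config("exactly two groups")
  if (cfg$replicates < 2L) stop_config("replicates must be >= 2")
  if (cfg$frac_dmp < 0 || cfg$frac_dmp > 1)
    stop_config("frac_dmp must be in [0, 1]")
  if (cfg$effect_size < 0 || cfg$effect_size > 1)
    stop_config("effect_size must be in [0, 1]")
  if (cfg$dmr_block_spacing <= 0) stop_config("spacing must be positive")
  if (cfg$nb_dispersion < 0) stop_config("nb_dispersion must be >= 0")
  structure(cfg, class = "sim_config")
}

chrom_names <- function(cfg) sprintf("chr%d", seq_len(cfg$n_chrom))

#' Simulate gene models and write them as GFF3
#'
#' Places non-overlapping genes (separated by more than twice the 2 kb EGB
#' flank so extended gene bodies never collide), with random strands and one
#' mRNA of 1-3 exons each. The written GFF3 round-trips through
#' [load_gene_models()].
#'
#' @param cfg a [sim_config()].
#' @param path optional path; when given, a GFF3 file is written there.
#' @return `gene_models` object (invisibly carries `path` as an attribute
#'   when written).
#' @export
simulate_gene_models <- function(cfg, path = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  per_chrom <- ceiling(cfg$n_genes / cfg$n_chrom)
  min_gap <- 2L * 2000L + 100L
  genes <- list(); exons <- list(); gid <- 0L
  for (ci in seq_len(cfg$n_chrom)) {
    n_here <- min(per_chrom, cfg$n_genes - (ci - 1L) * per_chrom)
    if (n_here <= 0L) break
    cursor <- 3000L
    for (k in seq_len(n_here)) {
      len <- sample(cfg$gene_length[1L]:cfg$gene_length[2L], 1L)
      gap <- min_gap + sample(0:2000, 1L)
      start <- cursor + gap
      end <- start + len
      if (end + 2000L > cfg$chrom_length)
        stop_config("infeasible packing: %d genes of up to %d bp (+ flanks) do not fit %d bp",
                    n_here, cfg$gene_length[2L], cfg$chrom_length)
      gid <- gid + 1L
      id <- sprintf("gene%03d", gid)
      strand <- sample(c("+", "-"), 1L)
      genes[[gid]] <- data.frame(gene_id = id, chrom = chrom_names(cfg)[ci],
                                 strand = strand, start = start, end = end,
                                 stringsAsFactors = FALSE)
      n_ex <- sample(1:3, 1L)
      bounds <- sort(c(start, end,
                       if (n_ex > 1)
                         sample(seq(start + 50L, end - 50L, by = 10L),
                                2L * (n_ex - 1L))))
      ex_start <- bounds[seq(1L, by = 2L, length.out = n_ex)]
      ex_end <- bounds[seq(2L, by = 2L, length.out = n_ex)]
      exons[[gid]] <- data.frame(gene_id = id, chrom = chrom_names(cfg)[ci],
                                 start = ex_start, end = ex_end,
                                 stringsAsFactors = FALSE)
      cursor <- end
    }
  }
  gm <- structure(list(genes = do.call(rbind, genes),
                       exons = do.call(rbind, exons)),
                  class = "gene_models")
  rownames(gm$genes) <- rownames(gm$exons) <- NULL
  if (!is.null(path)) {
    write_gene_models_gff3(gm, path)
    attr(gm, "path") <- path
  }
  gm
}

# GFF3 writer for simulated models (gene -> mRNA -> exon), 1-based closed on
# disk as the format requires
write_gene_models_gff3 <- function(gm, path) {
  g <- gm$genes
  mk <- function(type, id, parent, chrom, start, end, strand) {
    gr <- GenomicRanges::GRanges(chrom,
                                 IRanges::IRanges(start + 1L, end), strand)
    S4Vectors::mcols(gr)$type <- type
    S4Vectors::mcols(gr)$ID <- id
    S4Vectors::mcols(gr)$Parent <- IRanges::CharacterList(as.list(parent))
    gr
  }
  parts <- list(
    mk("gene", g$gene_id, rep(list(character()), nrow(g)),
       g$chrom, g$start, g$end, g$strand),
    mk("mRNA", paste0(g$gene_id, ".t1"), as.list(g$gene_id),
       g$chrom, g$start, g$end, g$strand))
  e <- gm$exons
  if (nrow(e)) {
    st <- g$strand[match(e$gene_id, g$gene_id)]
    ex_id <- paste0(e$gene_id, ".e", stats::ave(seq_len(nrow(e)), e$gene_id,
                                                FUN = seq_along))
    parts[[3L]] <- mk("exon", ex_id, as.list(paste0(e$gene_id, ".t1")),
                      e$chrom, e$start, e$end, st)
  }
  gr <- suppressWarnings(do.call(c, parts))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Simulate per-locus counts with planted differential methylation
#'
#' For each locus a latent baseline methylation `mu ~ Uniform(0.1, 0.9)` is
#' drawn. Effect loci shift the two groups to `mu +/- effect_size/2`
#' (clipped to `[0, 1]`; which group goes up depends on the planted
#' direction - `"methylated"` means hyper-methylated in group 1). Expected
#' counts are `nb_mean * (1 - methylation)` and observed counts are
#' negative-binomial (Poisson when `nb_dispersion = 0`). Effect loci are
#' laid out partly in `n_dmr_blocks` clustered runs of `dmr_block_loci`
#' loci spaced `dmr_block_spacing` bp (planted DMRs) and partly as isolated
#' positions at least 5 kb from any other effect locus (planted singleton
#' DMPs, which must not become DMRs). The per-context random stream is
#' derived deterministically from `cfg$seed` and the context.
#'
#' @param cfg a [sim_config()].
#' @param context methylation context label for the libraries.
#' @return list of class `mcseed_sim`: `matrix` (raw [locus_matrix()]),
#'   `truth` (list with `dmps` - chrom, pos, type, direction, block_id - and
#'   `blocks` - block_id, chrom, start, end, direction), `config`.
#' @export
simulate_counts <- function(cfg, context = "CG") {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 7919L * match(context, VALID_CONTEXTS))
  chroms <- chrom_names(cfg)
  total <- cfg$loci_per_chrom * cfg$n_chrom
  n_block_loci <- cfg$n_dmr_blocks * cfg$dmr_block_loci
  n_effect <- round(cfg$frac_dmp * total)
  n_iso <- max(0L, n_effect - n_block_loci)

  # planted blocks round-robin over chromosomes, well separated
  blocks <- data.frame()
  planted <- data.frame()
  if (cfg$n_dmr_blocks > 0L && cfg$dmr_block_loci > 0L) {
    bchrom <- chroms[(seq_len(cfg$n_dmr_blocks) - 1L) %% cfg$n_chrom + 1L]
    per <- table(factor(bchrom, levels = chroms))
    span <- (cfg$dmr_block_loci - 1L) * cfg$dmr_block_spacing
    starts <- unlist(lapply(chroms, function(ch) {
      k <- per[[ch]]
      if (k == 0L) return(integer())
      round(seq(0.02, 0.95, length.out = k) * cfg$chrom_length)
    }))
    bchrom <- rep(chroms, per)
    dirs <- sample(VALID_DIRECTIONS, cfg$n_dmr_blocks, replace = TRUE)
    blocks <- data.frame(block_id = seq_len(cfg$n_dmr_blocks),
                         chrom = bchrom, start = starts,
                         end = starts + span + 1L, direction = dirs,
                         stringsAsFactors = FALSE)
    planted <- data.frame(
      chrom = rep(bchrom, each = cfg$dmr_block_loci),
      pos = rep(starts, each = cfg$dmr_block_loci) +
        rep(seq(0L, span, by = cfg$dmr_block_spacing), cfg$n_dmr_blocks),
      type = "block",
      direction = rep(dirs, each = cfg$dmr_block_loci),
      block_id = rep(seq_len(cfg$n_dmr_blocks), each = cfg$dmr_block_loci),
      stringsAsFactors = FALSE)
  }
  if (n_iso > 0L) {
    ichrom <- chroms[(seq_len(n_iso) - 1L) %% cfg$n_chrom + 1L]
    iso <- do.call(rbind, lapply(chroms, function(ch) {
      k <- sum(ichrom == ch)
      if (k == 0L) return(NULL)
      # offset grid keeps isolated loci > 5 kb from blocks and each other
      data.frame(chrom = ch,
                 pos = round(seq(0.005, 0.985, length.out = k) *
                               cfg$chrom_length) + 2501L,
                 type = "isolated",
                 direction = sample(VALID_DIRECTIONS, k, replace = TRUE),
                 block_id = NA_integer_, stringsAsFactors = FALSE)
    }))
    # keep isolated loci clear of planted blocks (and of collisions)
    if (nrow(blocks)) {
      near_block <- vapply(seq_len(nrow(iso)), function(i) {
        b <- blocks[blocks$chrom == iso$chrom[i], , drop = FALSE]
        any(iso$pos[i] >= b$start - 5000L & iso$pos[i] < b$end + 5000L)
      }, TRUE)
      iso <- iso[!near_block, , drop = FALSE]
    }
    planted <- rbind(planted, iso)
  }
  planted <- planted[!duplicated(paste(planted$chrom, planted$pos)), ,
                     drop = FALSE]

  # background loci avoid planted positions
  bg <- do.call(rbind, lapply(chroms, function(ch) {
    n_pl <- sum(planted$chrom == ch)
    n_bg <- cfg$loci_per_chrom - n_pl
    taken <- planted$pos[planted$chrom == ch]
    pool <- setdiff(seq(0L, cfg$chrom_length - 1L), taken)
    data.frame(chrom = ch, pos = sort(sample(pool, n_bg)),
               type = "none", direction = NA_character_,
               block_id = NA_integer_, stringsAsFactors = FALSE)
  }))
  loci <- rbind(planted, bg)
  o <- coord_order(loci$chrom, loci$pos)
  loci <- loci[o, , drop = FALSE]
  n <- nrow(loci)

  mu <- runif(n, 0.1, 0.9)
  eff <- cfg$effect_size
  is_eff <- loci$type != "none" & eff > 0
  up1 <- is_eff & loci$direction == "methylated"
  up2 <- is_eff & loci$direction == "de-methylated"
  m1 <- mu; m2 <- mu
  m1[up1] <- pmin(mu[up1] + eff / 2, 1); m2[up1] <- pmax(mu[up1] - eff / 2, 0)
  m1[up2] <- pmax(mu[up2] - eff / 2, 0); m2[up2] <- pmin(mu[up2] + eff / 2, 1)

  draw <- function(meth) {
    mu_c <- cfg$nb_mean * (1 - meth)
    if (cfg$nb_dispersion > 0)
      rnbinom(n, mu = mu_c, size = 1 / cfg$nb_dispersion)
    else rpois(n, mu_c)
  }
  counts <- cbind(
    vapply(seq_len(cfg$replicates), function(s) draw(m1), numeric(n)),
    vapply(seq_len(cfg$replicates), function(s) draw(m2), numeric(n)))
  meta <- sample_sheet(
    library_id = c(sprintf("%s_%s_r%d", cfg$groups[1L], context,
                           seq_len(cfg$replicates)),
                   sprintf("%s_%s_r%d", cfg$groups[2L], context,
                           seq_len(cfg$replicates))),
    group = rep(cfg$groups, each = cfg$replicates),
    replicate = rep(seq_len(cfg$replicates), 2L),
    context = context)
  colnames(counts) <- meta$library_id
  m <- locus_matrix(data.frame(chrom = loci$chrom, pos = loci$pos),
                    counts, meta)
  truth_dmps <- loci[loci$type != "none", c("chrom", "pos", "type",
                                            "direction", "block_id")]
  rownames(truth_dmps) <- NULL
  if (eff == 0) truth_dmps <- truth_dmps[0L, , drop = FALSE]
  structure(list(matrix = m,
                 truth = list(dmps = truth_dmps,
                              blocks = if (eff > 0) blocks else blocks[0L, ],
                              baseline = data.frame(chrom = loci$chrom,
                                                    pos = loci$pos,
                                                    mu = mu)),
                 config = cfg),
            class = "mcseed_sim")
}

#' @export
print.mcseed_sim <- function(x, ...) {
  cat(sprintf("mcseed_sim: %d loci, %d planted DMPs (%d blocks), context %s\n",
              nrow(x$matrix$counts), nrow(x$truth$dmps),
              nrow(x$truth$blocks), x$matrix$positions$context[1L]))
  invisible(x)
}

#' Write a simulation to disk
#'
#' Emits the exact dialects the pipeline readers consume: a count TSV
#' (chrom, pos, one column per library), a sample sheet TSV, and truth
#' tables (planted DMPs and blocks) as TSV.
#'
#' @param sim `mcseed_sim` from [simulate_counts()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix, default the context.
#' @return named character vector of written paths.
#' @export
write_simulation <- function(sim, dir, prefix = NULL) {
  stopifnot(inherits(sim, "mcseed_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prefix <- prefix %||% sim$matrix$positions$context[1L]
  paths <- c(
    counts = file.path(dir, paste0(prefix, "_counts.tsv")),
    samples = file.path(dir, paste0(prefix, "_samples.tsv")),
    truth_dmps = file.path(dir, paste0(prefix, "_truth_dmps.tsv")),
    truth_blocks = file.path(dir, paste0(prefix, "_truth_blocks.tsv")))
  write_count_table(sim$matrix, paths["counts"])
  write_tsv(as.data.frame(sim$matrix$meta), paths["samples"])
  write_tsv(sim$truth$dmps, paths["truth_dmps"])
  write_tsv(sim$truth$blocks, paths["truth_blocks"])
  paths
}
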