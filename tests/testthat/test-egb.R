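test_that("load_gene_models reads GFF3, strands and longest transcripts", {
  gff <- tempfile(fileext = ".gff3")
  write_gff3_fixture(
    gff,
    genes = data.frame(chrom = "chr1", start = 1001, end = 3000,
                       strand = "+", id = "gA"),
    mrnas = data.frame(chrom = "chr1", start = 1001, end = 3000,
                       strand = "+", id = "gA.t1", parent = "gA"),
    exons = data.frame(chrom = "chr1", start = 1001, end = 3000,
                       strand = "+", id = "gA.e1", parent = "gA.t1"))
  gm <- load_gene_models(gff)
  expect_equal(nrow(gm$genes), 1L)
  expect_equal(gm$genes$start, 1000L)  # 0-based half-open conversion
  expect_equal(gm$genes$end, 3000L)
  expect_equal(gm$genes$strand, "+")

  # minus strand: strand recorded, span unchanged
  write_gff3_fixture(gff, genes = data.frame(chrom = "chr1", start = 501,
                                             end = 900, strand = "-",
                                             id = "gB"))
  gm2 <- load_gene_models(gff)
  expect_equal(gm2$genes$strand, "-")
  expect_equal(c(gm2$genes$start, gm2$genes$end), c(500L, 900L))

  # two transcripts (500 and 800 bp): the longer one defines the gene body
  write_gff3_fixture(
    gff,
    genes = data.frame(chrom = "chr1", start = 1001, end = 2000,
                       strand = "+", id = "gC"),
    mrnas = data.frame(chrom = "chr1", start = c(1001, 1001),
                       end = c(1500, 1800), strand = "+",
                       id = c("gC.t1", "gC.t2"), parent = "gC"))
  gm3 <- load_gene_models(gff)
  expect_equal(gm3$genes$end - gm3$genes$start, 800L)

  # unstranded gene skipped with a warning
  write_gff3_fixture(gff, genes = data.frame(
    chrom = "chr1", start = c(11, 501), end = c(400, 900),
    strand = c(".", "+"), id = c("gD", "gE")))
  expect_warning(gm4 <- load_gene_models(gff), "strand")
  expect_equal(gm4$genes$gene_id, "gE")
})

test_that("disaggregate_egb produces strand-resolved, clipped regions", {
  genes <- data.frame(gene_id = "g", chrom = "chr1", strand = "+",
                      start = 5000L, end = 7000L)
  r <- disaggregate_egb(genes, chrom_lengths = c(chr1 = 1e6))
  r <- r[order(match(r$region, c("upstream", "gene_body", "downstream"))), ]
  expect_equal(r$start, c(3000L, 5000L, 7000L))
  expect_equal(r$end, c(5000L, 7000L, 9000L))

  genes$strand <- "-"
  r2 <- disaggregate_egb(genes)
  expect_equal(r2$start[r2$region == "upstream"], 7000L)
  expect_equal(r2$end[r2$region == "upstream"], 9000L)
  expect_equal(r2$start[r2$region == "downstream"], 3000L)

  # clipped at the chromosome start
  genes3 <- data.frame(gene_id = "g", chrom = "chr1", strand = "+",
                       start = 500L, end = 1500L)
  r3 <- disaggregate_egb(genes3)
  expect_equal(r3$start[r3$region == "upstream"], 0L)
  expect_equal(r3$end[r3$region == "upstream"], 500L)
})

test_that("EGB regions partition the extended span exactly once", {
  set.seed(71)
  for (i in 1:20) {
    s <- sample(3000:50000, 1)
    genes <- data.frame(gene_id = "g", chrom = "chr1",
                        strand = sample(c("+", "-"), 1),
                        start = s, end = s + sample(500:9000, 1))
    r <- disaggregate_egb(genes)
    covered <- sort(unlist(Map(seq, r$start, r$end - 1L)))
    expect_equal(covered, seq(genes$start - 2000L, genes$end + 2000L - 1L))
    expect_equal(anyDuplicated(covered), 0L)
  }
})

test_that("assign_dmrs_to_regions matches half-open semantics and brute force", {
  regions <- disaggregate_egb(data.frame(gene_id = "g", chrom = "chr1",
                                         strand = "+", start = 5000L,
                                         end = 7000L))
  dmr1 <- data.frame(chrom = "chr1", start = 5100L, end = 5200L,
                     context = "CG", direction = "methylated",
                     comparison = "FVS")
  expect_equal(nrow(assign_dmrs_to_regions(dmr1, regions)), 1L)
  # spanning the upstream/body boundary -> two overlaps
  dmr2 <- within(dmr1, {start <- 4990L; end <- 5010L})
  ov2 <- assign_dmrs_to_regions(dmr2, regions)
  expect_setequal(ov2$region, c("upstream", "gene_body"))
  # exactly at the boundary -> only the body
  dmr3 <- within(dmr1, {start <- 5000L; end <- 5010L})
  expect_equal(assign_dmrs_to_regions(dmr3, regions)$region, "gene_body")

  # random instance vs quadratic brute force
  set.seed(73)
  genes <- data.frame(gene_id = sprintf("g%02d", 1:30), chrom = "chr1",
                      strand = sample(c("+", "-"), 30, TRUE),
                      start = seq(10000, by = 12000, length.out = 30))
  genes$end <- genes$start + sample(1000:6000, 30)
  regions <- disaggregate_egb(genes)
  dmrs <- data.frame(chrom = "chr1",
                     start = sample(0:400000, 100), context = "CG",
                     direction = "methylated", comparison = "FVS")
  dmrs$end <- dmrs$start + sample(50:3000, 100)
  got <- assign_dmrs_to_regions(dmrs, regions)
  want <- oracle_overlaps(dmrs, regions)
  expect_equal(nrow(got), nrow(want))
  expect_setequal(paste(got$dmr_id, got$gene_id, got$region),
                  paste(want$query, regions$gene_id[want$subject],
                        regions$region[want$subject]))
})

test_that("classify_gene_regions applies the ambiguity filter", {
  ov <- data.frame(dmr_id = c(1L, 2L, 3L),
                   gene_id = c("g1", "g2", "g2"),
                   region = c("upstream", "gene_body", "gene_body"),
                   context = "CG", comparison = "FVS",
                   direction = c("methylated", "methylated", "de-methylated"))
  calls <- classify_gene_regions(ov)
  expect_equal(calls$status[calls$gene_id == "g1"], "methylated")
  expect_equal(calls$status[calls$gene_id == "g2"], "ambiguous")

  # planted single-direction truth recovers exactly
  set.seed(79)
  truth <- data.frame(gene_id = sprintf("g%02d", 1:20),
                      region = sample(c("upstream", "gene_body",
                                        "downstream"), 20, TRUE),
                      direction = sample(c("methylated", "de-methylated"),
                                         20, TRUE))
  ov2 <- data.frame(dmr_id = seq_len(nrow(truth)), gene_id = truth$gene_id,
                    region = truth$region, context = "CHH",
                    comparison = "AVS", direction = truth$direction)
  calls2 <- classify_gene_regions(ov2)
  expect_equal(calls2$status[match(truth$gene_id, calls2$gene_id)],
               truth$direction)
})

test_that("summarize_region_counts matches the published table conventions", {
  empty <- summarize_region_counts(classify_gene_regions(data.frame()))
  expect_equal(sum(as.matrix(empty[, -1])), 0)

  # meth + de-meth totals equal the number of non-ambiguous calls
  set.seed(83)
  ov <- data.frame(dmr_id = 1:40,
                   gene_id = sample(sprintf("g%02d", 1:25), 40, TRUE),
                   region = sample(c("upstream", "gene_body", "downstream"),
                                   40, TRUE),
                   context = sample(c("CG", "6mA"), 40, TRUE),
                   comparison = "FVS",
                   direction = sample(c("methylated", "de-methylated"),
                                      40, TRUE))
  calls <- classify_gene_regions(ov)
  tab <- summarize_region_counts(calls)
  expect_equal(sum(as.matrix(tab[, -(1:2)])),
               sum(calls$status != "ambiguous"))
})

test_that("aggregate_region_counts reproduces printed reference arithmetic", {
  agg <- aggregate_region_counts(reference_region_counts("FVS"))
  expect_equal(agg$five_mc_regions,
               c(upstream = 395, gene_body = 551, downstream = 420))
  expect_equal(agg$five_mc_dmrs, 1290)
  expect_equal(agg$six_ma_dmrs, 7343)
  expect_equal(agg$total_dmrs, 8633)
})

test_that("metagene_profile bins strand-resolved offsets", {
  genes <- data.frame(gene_id = "g", chrom = "chr1", strand = "+",
                      start = 5000L, end = 12000L)
  # DMP 150 bp 5' of the ATG -> bin [-200, -100)
  prof <- metagene_profile(data.frame(chrom = "chr1", pos = 4850L), genes)
  atg <- prof[prof$anchor == "ATG", ]
  expect_equal(atg$count[atg$offset == -200], 1L)
  expect_equal(sum(atg$count), 1L)
  expect_equal(sum(prof$count[prof$anchor == "STOP"]), 0L)

  # strand mirror: reflected gene and DMP give the same bins
  L <- 100000L
  genes_m <- data.frame(gene_id = "g", chrom = "chr1", strand = "-",
                        start = L - 12000L, end = L - 5000L)
  prof_m <- metagene_profile(data.frame(chrom = "chr1", pos = L - 1L - 4850L),
                             genes_m)
  expect_equal(prof_m, prof)

  # gene-body DMPs more than span bp from both anchors do not contribute
  prof2 <- metagene_profile(data.frame(chrom = "chr1", pos = 7500L), genes)
  expect_equal(sum(prof2$count), 0L)
})

test_that("uniform DMPs give an approximately flat metagene profile", {
  set.seed(89)
  genes <- data.frame(gene_id = sprintf("g%d", 1:40), chrom = "chr1",
                      strand = "+",
                      start = seq(10000L, by = 20000L, length.out = 40L))
  genes$end <- genes$start + 8000L
  # DMPs uniform over each gene's ATG window [-2000, 2000)
  pos <- unlist(lapply(genes$start, function(s)
    s + sample(-2000:1999, 60, replace = TRUE)))
  prof <- metagene_profile(data.frame(chrom = "chr1", pos = pos), genes)
  atg <- prof$count[prof$anchor == "ATG"]
  expect_equal(sum(atg), length(pos))
  gof <- suppressWarnings(chisq.test(atg))
  expect_gt(gof$p.value, 0.01)
})

test_that("feature_overlap_counts classifies DMR hits", {
  gm <- structure(list(
    genes = data.frame(gene_id = "g", chrom = "chr1", strand = "+",
                       start = 10000L, end = 14000L),
    exons = data.frame(gene_id = "g", chrom = "chr1",
                       start = c(10000L, 13000L), end = c(11000L, 14000L))),
    class = "gene_models")
  dmrs <- data.frame(chrom = "chr1",
                     start = c(10100L, 11500L, 9000L, 50000L),
                     end = c(10200L, 11600L, 9100L, 50100L),
                     context = "CG", direction = "methylated",
                     comparison = "FVS")
  fc <- feature_overlap_counts(dmrs, gm)
  expect_equal(fc[["exon"]], 1L)
  expect_equal(fc[["intron"]], 1L)
  expect_equal(fc[["upstream"]], 1L)
  expect_equal(fc[["intergenic"]], 1L)
})
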