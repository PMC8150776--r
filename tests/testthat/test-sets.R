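test_that("regulatory_gene_set uses flanks plus the gene-body core margins", {
  genes <- data.frame(gene_id = "g", chrom = "chr1", strand = "+",
                      start = 10000L, end = 20000L)  # 10 kb gene
  mk_dmr <- function(s, e, dir = "methylated")
    data.frame(chrom = "chr1", start = s, end = e, context = "CG",
               direction = dir, comparison = "FVS")
  # inside the 400 bp core after the ATG -> qualifies
  s1 <- regulatory_gene_set(mk_dmr(10100L, 10300L), genes)
  expect_equal(s1$methylated, "g")
  # wholly at the gene-body midpoint -> does not qualify
  s2 <- regulatory_gene_set(mk_dmr(14900L, 15100L), genes)
  expect_equal(length(s2$methylated) + length(s2$de_methylated), 0L)
  # mixed directions over the regulatory union -> excluded
  s3 <- regulatory_gene_set(rbind(mk_dmr(10100L, 10300L),
                                  mk_dmr(9000L, 9100L, "de-methylated")),
                            genes)
  expect_equal(s3$excluded, "g")
  # minus strand: core is measured from the other end
  genes_m <- genes; genes_m$strand <- "-"
  s4 <- regulatory_gene_set(mk_dmr(19700L, 19900L), genes_m)  # after - ATG
  expect_equal(s4$methylated, "g")
})

test_that("regulatory_gene_set equals a brute-force union-overlap oracle", {
  set.seed(97)
  genes <- data.frame(gene_id = sprintf("g%02d", 1:25), chrom = "chr1",
                      strand = sample(c("+", "-"), 25, TRUE),
                      start = seq(20000, by = 25000, length.out = 25))
  genes$end <- genes$start + sample(2000:10000, 25)
  dmrs <- data.frame(chrom = "chr1", start = sample(0:650000, 150),
                     context = "CG",
                     direction = sample(c("methylated", "de-methylated"),
                                        150, TRUE),
                     comparison = "FVS")
  dmrs$end <- dmrs$start + sample(50:1500, 150)
  got <- regulatory_gene_set(dmrs, genes)

  # oracle: union of flank and core intervals per gene, quadratic overlap
  want <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    core <- min(400L, g$end - g$start)
    iv <- rbind(c(g$start - 2000L, g$start), c(g$end, g$end + 2000L),
                c(g$start, g$start + core), c(g$end - core, g$end))
    dirs <- character()
    for (j in seq_len(nrow(dmrs))) {
      if (any(dmrs$start[j] < iv[, 2] & iv[, 1] < dmrs$end[j]))
        dirs <- union(dirs, dmrs$direction[j])
    }
    if (length(dirs)) want[[g$gene_id]] <- dirs
  }
  want_meth <- sort(names(want)[vapply(want, identical, TRUE,
                                       y = "methylated")])
  want_demeth <- sort(names(want)[vapply(want, identical, TRUE,
                                         y = "de-methylated")])
  expect_equal(got$methylated, want_meth)
  expect_equal(got$de_methylated, want_demeth)
  expect_equal(got$excluded,
               sort(setdiff(names(want), c(want_meth, want_demeth))))
})

test_that("venn_sets partitions correctly", {
  v <- venn_sets(c("g1", "g2"), c("g2", "g3"))
  expect_equal(v$shared, "g2")
  expect_equal(v$a_specific, "g1")
  expect_equal(v$b_specific, "g3")

  v2 <- venn_sets(c("a", "b"), c("a", "b"))
  expect_equal(v2$shared, c("a", "b"))
  expect_equal(unname(v2$counts), c(2L, 0L, 0L))

  # random sets: disjoint partition covering the union
  set.seed(101)
  for (i in 1:10) {
    a <- sample(sprintf("g%03d", 1:200), 100)
    b <- sample(sprintf("g%03d", 1:200), 100)
    v3 <- venn_sets(a, b)
    expect_equal(sum(v3$counts), length(union(a, b)))
    expect_equal(length(intersect(v3$shared, v3$a_specific)), 0L)
    expect_equal(length(intersect(v3$a_specific, v3$b_specific)), 0L)
    expect_setequal(c(v3$shared, v3$a_specific, v3$b_specific), union(a, b))
  }

  # status handling for regulatory_sets inputs
  rs <- structure(list(methylated = c("x", "y"), de_methylated = "z",
                       excluded = character()), class = "regulatory_sets")
  v4 <- venn_sets(rs, rs, status = "methylated")
  expect_equal(v4$shared, c("x", "y"))
  expect_error(venn_sets(rs, rs), "status")
  expect_error(venn_sets(rs, rs, status = "nope"), "not present")
})

test_that("cross_dmg_deg joins on gene id and annotates concordance", {
  calls <- data.frame(gene_id = "g1", region = "gene_body", context = "6mA",
                      comparison = "AVS", status = "methylated")
  deg <- data.frame(gene_id = "g1", log_fold_change = -2.1, fdr = 0.001,
                    deg_status = "down")
  x <- cross_dmg_deg(calls, deg)
  expect_equal(nrow(x), 1L)
  expect_match(x$concordance, "6mA gene_body methylated \\+ downregulated")

  # disjoint sets -> empty, with a message, not an error
  expect_message(x2 <- cross_dmg_deg(calls, data.frame(
    gene_id = "other", log_fold_change = 1, fdr = 0.1, deg_status = "up")),
    "no genes shared")
  expect_equal(nrow(x2), 0L)

  # planted join: 30 DMGs x 50 DEGs with exactly 7 shared ids
  set.seed(103)
  dmg_ids <- sprintf("dmg%02d", 1:30)
  deg_ids <- c(dmg_ids[1:7], sprintf("deg%02d", 1:43))
  calls3 <- data.frame(gene_id = rep(dmg_ids, 2),
                       region = "upstream",
                       context = sample(c("CG", "CHH"), 60, TRUE),
                       comparison = "FVS", status = "de-methylated")
  deg3 <- data.frame(gene_id = deg_ids,
                     log_fold_change = rnorm(50), fdr = runif(50, 0, 0.05))
  deg3$deg_status <- ifelse(deg3$log_fold_change > 0, "up", "down")
  x3 <- cross_dmg_deg(calls3, deg3)
  expect_equal(nrow(x3), 7L)
  expect_setequal(x3$gene_id, dmg_ids[1:7])
  expect_lte(nrow(x3), min(length(unique(calls3$gene_id)), nrow(deg3)))
})

test_that("read_deg_table derives expression status from the fold change", {
  tsv <- tempfile(fileext = ".tsv")
  write.table(data.frame(gene_id = c("a", "b"), logFC = c(1.5, -0.5),
                         FDR = c(0.01, 0.02)),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  deg <- read_deg_table(tsv)
  expect_equal(deg$deg_status, c("up", "down"))
  writeLines("gene_id\tfoo\n a\t1", tsv)
  expect_error(read_deg_table(tsv), "needs gene_id")
})
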