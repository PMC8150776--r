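# Fixture builders and independent brute-force oracles. Oracles are written
# from the definitions, independently of the package's implementation paths.

tiny_meta <- function(n1 = 3L, n2 = 3L, context = "CG",
                      groups = c("g1", "g2")) {
  sample_sheet(
    library_id = c(sprintf("%s_%d", groups[1], seq_len(n1)),
                   sprintf("%s_%d", groups[2], seq_len(n2))),
    group = rep(groups, c(n1, n2)),
    replicate = c(seq_len(n1), seq_len(n2)),
    context = context)
}

tiny_matrix <- function(counts, pos = NULL, chrom = "chr1", meta = NULL,
                        normalized = FALSE) {
  counts <- as.matrix(counts)
  meta <- meta %||% tiny_meta(ceiling(ncol(counts) / 2),
                              floor(ncol(counts) / 2))
  colnames(counts) <- meta$library_id
  pos <- pos %||% (seq_len(nrow(counts)) * 100L)
  locus_matrix(data.frame(chrom = chrom, pos = pos), counts, meta,
               normalized = normalized)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# relmeth_matrix built directly from a [0,1] matrix (bypasses count stages)
make_relmeth <- function(rel, pos = NULL, chrom = "chr1", meta = NULL,
                         context = "CG") {
  rel <- as.matrix(rel)
  meta <- meta %||% tiny_meta(ceiling(ncol(rel) / 2), floor(ncol(rel) / 2),
                              context = context)
  colnames(rel) <- meta$library_id
  pos <- pos %||% (seq_len(nrow(rel)) * 100L)
  structure(list(positions = data.frame(chrom = chrom, pos = as.integer(pos),
                                        context = context,
                                        stringsAsFactors = FALSE),
                 relmeth = rel, meta = meta),
            class = "relmeth_matrix")
}

# dmp_table built directly (for clustering tests)
make_dmps <- function(pos, direction, chrom = "chr1", context = "CG",
                      q = 1e-6) {
  out <- data.frame(chrom = rep(chrom, length.out = length(pos)),
                    pos = as.integer(pos),
                    context = rep(context, length.out = length(pos)),
                    delta = ifelse(direction == "methylated", 0.5, -0.5),
                    direction = direction,
                    p_value = rep(q, length.out = length(pos)),
                    q_value = rep(q, length.out = length(pos)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  class(out) <- c("dmp_table", "data.frame")
  out
}

# --- oracles ---------------------------------------------------------------

# brute-force DMP chaining: split sorted DMPs at any direction change or at
# a gap exceeding the window; keep runs of >= min_size
oracle_chain <- function(pos, direction, window, min_size = 2L) {
  if (length(pos) == 0L) return(list())
  o <- order(pos)
  pos <- pos[o]; direction <- direction[o]
  runs <- list(); cur <- 1L
  for (i in seq_along(pos)[-1L]) {
    if (direction[i] != direction[i - 1L] || pos[i] - pos[i - 1L] > window) {
      runs[[length(runs) + 1L]] <- cur
      cur <- i
    } else cur <- c(cur, i)
  }
  runs[[length(runs) + 1L]] <- cur
  runs <- Filter(function(r) length(r) >= min_size, runs)
  lapply(runs, function(r) list(members = pos[r],
                                direction = direction[r[1L]]))
}

# quadratic interval intersection oracle (0-based half-open)
oracle_overlaps <- function(a, b) {
  hits <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] == b$chrom[j] && a$start[i] < b$end[j] &&
        b$start[j] < a$end[i])
      hits[[length(hits) + 1L]] <- c(i, j)
  }
  if (!length(hits)) return(data.frame(query = integer(), subject = integer()))
  m <- do.call(rbind, hits)
  data.frame(query = m[, 1L], subject = m[, 2L])
}

# independent pooled 2x2 binomial LRT (G statistic), written from the
# log-likelihood definition rather than the package's vectorized form
oracle_g2x2 <- function(x1, n1, x2, n2) {
  ll <- function(x, n) {
    if (n == 0) return(0)
    p <- x / n
    s <- 0
    if (x > 0) s <- s + x * log(p)
    if (n - x > 0) s <- s + (n - x) * log(1 - p)
    s
  }
  2 * (ll(x1, n1) + ll(x2, n2) - ll(x1 + x2, n1 + n2))
}

# glm-based logistic-regression LRT p-value for one position
oracle_glm_p <- function(numC, coverage, group) {
  fit1 <- suppressWarnings(
    glm(cbind(numC, coverage - numC) ~ group, family = binomial()))
  fit0 <- suppressWarnings(
    glm(cbind(numC, coverage - numC) ~ 1, family = binomial()))
  pchisq(fit0$deviance - fit1$deviance, df = 1, lower.tail = FALSE)
}

# minimal GFF3 text fixture writer (1-based closed, as the format requires)
write_gff3_fixture <- function(path, genes, mrnas = NULL, exons = NULL) {
  lines <- "##gff-version 3"
  add <- function(df, type, attr_fun) {
    for (i in seq_len(nrow(df)))
      lines <<- c(lines, paste(df$chrom[i], "test", type, df$start[i],
                               df$end[i], ".", df$strand[i], ".",
                               attr_fun(df[i, ]), sep = "\t"))
  }
  add(genes, "gene", function(r) sprintf("ID=%s", r$id))
  if (!is.null(mrnas))
    add(mrnas, "mRNA", function(r) sprintf("ID=%s;Parent=%s", r$id, r$parent))
  if (!is.null(exons))
    add(exons, "exon", function(r) sprintf("ID=%s;Parent=%s", r$id, r$parent))
  writeLines(lines, path)
  path
}
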