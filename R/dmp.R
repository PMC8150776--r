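## Relative methylation and DMP calling.
##
## Methylation of a methylation-sensitive restriction site blocks digestion,
## so normalized read counts anti-correlate with methylation. Relative
## methylation at a site is 1 - n / max(n) across the libraries of the
## comparison, bounded in [0, 1].

#' Per-site relative methylation levels
#'
#' For each position i and library s,
#' `relmeth[i, s] = 1 - n[i, s] / max_t(n[i, t])`, where `n` are normalized
#' counts. The library with the row-maximal count gets 0 (least methylated);
#' a library with no reads at the site gets 1 (fully methylated).
#'
#' @param m normalized (and CV-filtered) [locus_matrix()].
#' @return object of class `relmeth_matrix`: list with `positions`,
#'   `relmeth` (matrix in `[0, 1]`) and `meta`.
#' @export
relative_methylation <- function(m) {
  stopifnot(inherits(m, "locus_matrix"))
  if (!m$normalized)
    stop_state("relative_methylation requires a normalized matrix")
  rmax <- apply(m$counts, 1L, max)
  if (any(rmax <= 0))
    stop_state("rows with zero maximal count present; apply filter_by_cv first")
  rel <- 1 - m$counts / rmax
  structure(list(positions = m$positions, relmeth = rel, meta = m$meta),
            class = "relmeth_matrix")
}

#' @export
print.relmeth_matrix <- function(x, ...) {
  cat(sprintf("relmeth_matrix: %d positions x %d libraries [%s]\n",
              nrow(x$relmeth), ncol(x$relmeth), x$positions$context[1L]))
  invisible(x)
}

## ---- statistical engine ----------------------------------------------------

# Binomial log-likelihood of x successes out of n at the MLE p = x/n,
# with the 0*log(0) = 0 convention.
binom_ll <- function(x, n) {
  p <- ifelse(n > 0, x / n, 0)
  ifelse(x > 0, x * log(p), 0) + ifelse(n - x > 0, (n - x) * log(1 - p), 0)
}

# Vectorized likelihood-ratio test of a binomial GLM with a two-level group
# covariate against the intercept-only model (1 df). With a single binary
# covariate the group-model MLE is the pooled within-group proportion, so the
# deviance difference reduces to the G statistic of the pooled 2x2 table.
#
# Between-replicate (biological) variation makes pseudo-counts overdispersed
# relative to the binomial; the LRT is therefore scaled by a
# McCullagh-Nelder Pearson dispersion estimated from the within-group
# residuals (quasi-binomial scaling, not a beta-binomial model):
#   "shrink" - one genome-wide scale (median of per-row estimates), floored
#              at 1; chi-square reference, 1 df (default);
#   "MN"     - per-row scale, floored at 1; F reference (1, n_lib - 2) df;
#   "none"   - plain binomial LRT (chi-square, 1 df).
#
# numC, coverage: rows x libraries matrices of methylated pseudo-counts and
# pseudo-coverages. Returns stat (G), phi, p.
group_lrt <- function(numC, coverage, idx1, idx2,
                      overdispersion = c("shrink", "MN", "none")) {
  overdispersion <- match.arg(overdispersion)
  s1 <- rowSums(numC[, idx1, drop = FALSE])
  s2 <- rowSums(numC[, idx2, drop = FALSE])
  n1 <- rowSums(coverage[, idx1, drop = FALSE])
  n2 <- rowSums(coverage[, idx2, drop = FALSE])
  G <- 2 * (binom_ll(s1, n1) + binom_ll(s2, n2) - binom_ll(s1 + s2, n1 + n2))
  G <- pmax(G, 0)

  nlib <- length(idx1) + length(idx2)
  df_resid <- nlib - 2L
  p1 <- ifelse(n1 > 0, s1 / n1, 0)
  p2 <- ifelse(n2 > 0, s2 / n2, 0)
  fitted <- matrix(0, nrow(numC), ncol(numC))
  fitted[, idx1] <- p1
  fitted[, idx2] <- p2
  denom <- fitted * (1 - fitted) * coverage
  pearson <- (numC - fitted * coverage)^2 / denom
  pearson[!is.finite(pearson)] <- 0  # saturated groups (p in {0,1}): residual 0
  phi_row <- rowSums(pearson) / df_resid

  if (overdispersion == "none") {
    phi <- rep(1, length(G))
    p <- pchisq(G, df = 1L, lower.tail = FALSE)
  } else if (overdispersion == "MN") {
    phi <- pmax(phi_row, 1)
    p <- pf(G / phi, df1 = 1L, df2 = df_resid, lower.tail = FALSE)
  } else {
    usable <- is.finite(phi_row) & phi_row > 0
    phi_glob <- if (any(usable)) max(1, median(phi_row[usable])) else 1
    phi <- rep(phi_glob, length(G))
    p <- pchisq(G / phi, df = 1L, lower.tail = FALSE)
  }

  # documented fallback for degenerate rows: two-proportion chi-square with
  # continuity correction on the pooled table (closed-form G is finite for
  # all valid inputs, so this only fires on pathological pseudo-counts)
  bad <- !is.finite(p)
  if (any(bad)) {
    for (i in which(bad)) {
      p[i] <- tryCatch(
        prop.test(c(s1[i], s2[i]), c(n1[i], n2[i]), correct = TRUE)$p.value,
        error = function(e) 1)
    }
  }
  list(stat = G, phi = phi, p = pmin(pmax(p, .Machine$double.xmin), 1))
}

group_indices <- function(meta) {
  groups <- unique(meta$group)
  if (length(groups) != 2L)
    stop_config("exactly two groups required, got: %s",
                paste(groups, collapse = ", "))
  idx1 <- which(meta$group == groups[1L])
  idx2 <- which(meta$group == groups[2L])
  if (length(idx1) < 2L || length(idx2) < 2L)
    stop_config("each group needs >= 2 replicates (got %d and %d)",
                length(idx1), length(idx2))
  list(groups = groups, idx1 = idx1, idx2 = idx2)
}

## ---- DMP calling -----------------------------------------------------------

#' Call differentially methylated positions (DMPs)
#'
#' Per position, relative methylation levels are mapped onto binomial
#' pseudo-counts (`numC = round(relmeth * pseudo_coverage)` methylated reads
#' out of `pseudo_coverage` per library) and a logistic regression of
#' methylation proportion on the group indicator is tested against the
#' intercept-only model by likelihood ratio (1 df). Because replicate-level
#' biological noise makes these pseudo-counts overdispersed, the statistic is
#' by default scaled by a genome-wide quasi-binomial dispersion (see
#' `overdispersion`; `"none"` gives the unscaled binomial LRT). P-values are
#' Benjamini-Hochberg adjusted across all tested positions of the context;
#' positions with `q < fdr` are DMPs.
#'
#' Direction is `"methylated"` when mean relative methylation of group 1
#' exceeds group 2 (`delta > 0`, i.e. hyper-methylated in group 1).
#'
#' @param r [relative_methylation()] result.
#' @param meta sample sheet (defaults to the one carried by `r`).
#' @param fdr FDR threshold for calling, default 0.05.
#' @param pseudo_coverage binomial denominator per library, default 100.
#' @param overdispersion `"shrink"` (default), `"MN"` or `"none"`.
#' @param return_all if `TRUE`, return every tested position with an
#'   `is_dmp` flag instead of only the significant ones.
#' @return data.frame with columns chrom, pos, context, delta, direction,
#'   p_value, q_value (and `is_dmp` when `return_all = TRUE`), of class
#'   `dmp_table`, sorted by coordinate.
#' @export
call_dmps <- function(r, meta = r$meta, fdr = 0.05, pseudo_coverage = 100L,
                      overdispersion = c("shrink", "MN", "none"),
                      return_all = FALSE) {
  stopifnot(inherits(r, "relmeth_matrix"))
  overdispersion <- match.arg(overdispersion)
  gi <- group_indices(meta)
  numC <- round(r$relmeth * pseudo_coverage)
  coverage <- matrix(pseudo_coverage, nrow(numC), ncol(numC))
  lrt <- group_lrt(numC, coverage, gi$idx1, gi$idx2, overdispersion)
  delta <- rowMeans(r$relmeth[, gi$idx1, drop = FALSE]) -
    rowMeans(r$relmeth[, gi$idx2, drop = FALSE])
  q <- p.adjust(lrt$p, method = "BH")
  out <- data.frame(chrom = r$positions$chrom,
                    pos = r$positions$pos,
                    context = r$positions$context,
                    delta = delta,
                    direction = ifelse(delta > 0, "methylated", "de-methylated"),
                    p_value = lrt$p,
                    q_value = q,
                    stringsAsFactors = FALSE)
  attr(out, "groups") <- gi$groups
  attr(out, "overdispersion") <- overdispersion
  attr(out, "phi") <- lrt$phi[1L]
  if (return_all) {
    out$is_dmp <- out$q_value < fdr
  } else {
    out <- out[out$q_value < fdr, , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("dmp_table", "data.frame")
  out
}

#' Write a DMP table as TSV
#' @param dmps a `dmp_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dmp_table <- function(dmps, path) write_tsv(as.data.frame(dmps), path)

#' Read a DMP table written by [write_dmp_table()]
#' @param path TSV path.
#' @return `dmp_table` data.frame.
#' @export
read_dmp_table <- function(path) {
  df <- read_tsv(path)
  need <- c("chrom", "pos", "context", "delta", "direction", "p_value",
            "q_value")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop_format("%s lacks DMP column(s): %s", path,
                paste(missing, collapse = ", "))
  df$chrom <- as.character(df$chrom)
  class(df) <- c("dmp_table", "data.frame")
  df
}

#' Write DMPs as BED6
#'
#' One record per DMP; name is `context:direction`, score is
#' `-10 * log10(q)` capped at 1000, strand `.`.
#'
#' @param dmps a `dmp_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dmp_bed <- function(dmps, path) {
  df <- as.data.frame(dmps)
  bed <- data.frame(chrom = df$chrom, start = df$pos, end = df$pos + 1L,
                    name = paste(df$context, df$direction, sep = ":"),
                    score = round(pmin(-10 * log10(df$q_value), 1000), 1),
                    strand = ".")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
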