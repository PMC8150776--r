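## Shared internal helpers: coordinate-sorted tables, interval overlap via
## IRanges (0-based half-open <-> 1-based closed shift done here, once).

# order by (chrom, pos); chrom compared as character
coord_order <- function(chrom, pos) order(chrom, pos)

is_coord_sorted <- function(chrom, pos) {
  if (length(chrom) < 2L) return(TRUE)
  !is.unsorted(order(chrom, pos)) && all(diff(coord_order(chrom, pos)) == 1L)
}

# GRanges from 0-based half-open intervals
as_granges0 <- function(chrom, start, end, strand = "*") {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    strand = strand
  )
}

# all overlapping pairs between two sets of 0-based half-open intervals;
# returns data.frame(query, subject) of indices (>=1 bp overlap)
overlap_pairs0 <- function(q_chrom, q_start, q_end, s_chrom, s_start, s_end) {
  hits <- GenomicRanges::findOverlaps(
    as_granges0(q_chrom, q_start, q_end),
    as_granges0(s_chrom, s_start, s_end),
    minoverlap = 1L
  )
  data.frame(query = S4Vectors::queryHits(hits),
             subject = S4Vectors::subjectHits(hits))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)
stop_format <- function(...) stop(sprintf(...), call. = FALSE)
stop_state  <- function(...) stop(sprintf(...), call. = FALSE)
stop_data   <- function(...) stop(sprintf(...), call. = FALSE)

VALID_CONTEXTS <- c("CG", "CHG", "CHH", "6mA")
VALID_DIRECTIONS <- c("methylated", "de-methylated")
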