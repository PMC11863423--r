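# Shared low-level helpers: error conditions, coordinate arithmetic, DNA
# string utilities.  Internal coordinates are 0-based half-open throughout;
# conversion to 1-based happens only at I/O boundaries (VCF, GTF, GRanges).

.err_input <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("gasfunnel_bad_input", "error", "condition")))
}

.err_infeasible <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("gasfunnel_infeasible", "error", "condition")))
}

# Reverse complement of plain character DNA (vectorized).  Non-ACGT symbols
# other than N are preserved by chartr only where listed; anything else maps
# to itself, which is fine because downstream matching rejects it anyway.
.revcomp <- function(x) {
  vapply(x, function(s) {
    comp <- chartr("ACGTacgtNn", "TGCAtgcaNn", s)
    paste(rev(strsplit(comp, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Substitute `base` at 0-based offset `offset0` of `kmer`.
.subst <- function(kmer, offset0, base) {
  substr(kmer, offset0 + 1L, offset0 + 1L) <- base
  kmer
}

# Gap between half-open intervals [a,b) and [c,d): 0 if they overlap or are
# bookended, otherwise the number of bases strictly between them.
.interval_gap <- function(a, b, c, d) {
  pmax(0L, pmax(c - b, a - d))
}

# GRanges with a shared seqlevel universe so cross-object distance /
# overlap queries never trip on mismatched seqinfo.
.as_granges <- function(chrom, start0, end, universe) {
  GenomicRanges::GRanges(
    seqnames = factor(chrom, levels = universe),
    ranges = IRanges::IRanges(start = start0 + 1L, end = end)
  )
}

# Deterministic TSV writer (fixed formatting; byte-identical across runs).
.write_tsv <- function(df, path, col.names = TRUE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = col.names, na = "NA",
                     eol = "\n")
  invisible(path)
}

.read_first_fasta_names <- function(x) sub("\\s.*$", "", x)
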