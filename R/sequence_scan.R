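# Genome scanning for canonical and near-complete GAS motifs.  Scanning is
# plus-strand only with the full class set: the classes are closed under
# reverse complementation, so a minus-strand occurrence of class X shows up
# as a plus-strand occurrence of revcomp_partner(X) at the same interval,
# and every genomic interval is reported exactly once.

.empty_hits <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             class = character(), kmer = character(),
             deviant_pos = integer(), restore_allele = character(),
             stringsAsFactors = FALSE)
}

#' Scan one sequence for GAS and near-GAS motif occurrences
#'
#' Slides a 9 bp window over the plus strand and reports every window
#' matching one of the seven motif classes.  Soft-masked (lowercase) bases
#' are uppercased before matching; `N` and any other non-ACGT base match
#' nothing.  Overlapping hits of different classes are all reported;
#' sequences shorter than 9 bp yield an empty result.
#'
#' @param seq A single character string (or `DNAString`).
#' @param chrom Sequence name recorded in the output.
#' @param classes Motif class table from [gas_classes()].
#' @return Data frame of hits sorted by `(chrom, start)` with columns
#'   `chrom`, `start`, `end` (0-based half-open), `class`, `kmer`
#'   (plus-strand slice), `deviant_pos` (absolute 0-based position of the
#'   deviant base, `NA` for canonical hits) and `restore_allele` (the
#'   plus-strand base completing the motif, `NA` for canonical hits).
#' @examples
#' scan_sequence("GTCAAAGAA", "chr1") # one T1 hit, restorable by T at 0
#' @export
scan_sequence <- function(seq, chrom = "seq1", classes = gas_classes()) {
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  if (n < 9L) return(.empty_hits())
  code <- match(strsplit(seq, "", fixed = TRUE)[[1]],
                c("A", "C", "G", "T"))
  code[is.na(code)] <- 5L
  npos <- n - 8L
  pieces <- list()
  for (ci in seq_len(nrow(classes))) {
    lk <- .allowed_lookup(classes$pattern[ci])
    ok <- lk[[1]][code[seq_len(npos)]]
    for (j in 2:9) {
      ok <- ok & lk[[j]][code[j:(j + npos - 1L)]]
    }
    s0 <- which(ok) - 1L
    if (length(s0) == 0L) next
    off <- classes$deviant_offset[ci]
    pieces[[length(pieces) + 1L]] <- data.frame(
      chrom = chrom, start = s0, end = s0 + 9L,
      class = classes$name[ci],
      kmer = substring(seq, s0 + 1L, s0 + 9L),
      deviant_pos = if (is.na(off)) NA_integer_ else s0 + off,
      restore_allele = if (is.na(off)) NA_character_
                       else classes$restore_base[ci],
      stringsAsFactors = FALSE)
  }
  if (length(pieces) == 0L) return(.empty_hits())
  hits <- do.call(rbind, pieces)
  hits <- hits[order(hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Scan a FASTA file and write motif hits as BED
#'
#' Reads a (possibly gzip-compressed, possibly multi-sequence) FASTA,
#' scans each sequence with [scan_sequence()] and optionally writes all
#' hits as BED6+3.  Sequence names are truncated at the first whitespace;
#' duplicated names are an error.
#'
#' @param fasta Path to the FASTA file.
#' @param classes Motif class table.
#' @param out_bed Optional BED output path (see [write_hits_bed()]).
#' @return List with `counts` (data frame `seqname`, `class`, `n`,
#'   including zero rows for every class/sequence combination) and `hits`
#'   (the full hit data frame, sequences in file order).
#' @export
scan_fasta <- function(fasta, classes = gas_classes(), out_bed = NULL) {
  seqs <- tryCatch(Biostrings::readDNAStringSet(fasta),
                   error = function(e) .err_input(
                     "cannot read FASTA '", fasta, "': ", conditionMessage(e)))
  nms <- .read_first_fasta_names(names(seqs))
  if (anyDuplicated(nms)) {
    .err_input("duplicate sequence name(s) in '", fasta, "': ",
               paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  names(seqs) <- nms
  per_seq <- lapply(seq_along(seqs), function(i) {
    scan_sequence(as.character(seqs[[i]]), nms[i], classes)
  })
  hits <- do.call(rbind, c(per_seq, list(.empty_hits())))
  rownames(hits) <- NULL
  counts <- expand.grid(seqname = nms, class = classes$name,
                        stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  counts$n <- mapply(function(s, cl) {
    sum(hits$chrom == s & hits$class == cl)
  }, counts$seqname, counts$class)
  counts <- counts[order(match(counts$seqname, nms),
                         match(counts$class, classes$name)), , drop = FALSE]
  rownames(counts) <- NULL
  if (!is.null(out_bed)) write_hits_bed(hits, out_bed)
  list(counts = counts, hits = hits)
}

#' Write motif hits as BED6+3
#'
#' Columns: chrom, start, end, name (class), score (0), strand (`+`),
#' then kmer, deviant position (`.` for canonical) and plus-strand
#' restoring allele (`.` for canonical).
#'
#' @param hits Hit data frame from [scan_sequence()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path) {
  bed <- data.frame(
    chrom = hits$chrom, start = hits$start, end = hits$end,
    name = hits$class, score = 0L, strand = "+",
    kmer = hits$kmer,
    deviant_pos = ifelse(is.na(hits$deviant_pos), ".",
                         as.character(hits$deviant_pos)),
    restore_allele = ifelse(is.na(hits$restore_allele), ".",
                            hits$restore_allele),
    stringsAsFactors = FALSE)
  .write_tsv(bed, path, col.names = FALSE)
}

#' Read motif hits written by [write_hits_bed()]
#'
#' @param path BED6+3 path.
#' @return Hit data frame in the [scan_sequence()] layout.
#' @export
read_hits_bed <- function(path) {
  if (file.size(path) == 0) return(.empty_hits())
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = c("character", "integer", "integer",
                                          "character", "integer", "character",
                                          "character", "character",
                                          "character"))
  data.frame(chrom = bed[[1]], start = bed[[2]], end = bed[[3]],
             class = bed[[4]], kmer = bed[[7]],
             deviant_pos = suppressWarnings(as.integer(bed[[8]])),
             restore_allele = ifelse(bed[[9]] == ".", NA_character_,
                                     bed[[9]]),
             stringsAsFactors = FALSE)
}
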