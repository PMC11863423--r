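# Joining catalogued variants to motif hits: gain-of-function candidates
# complete a near-GAS motif into an intact GAS; loss-of-function candidates
# break a fixed position of a canonical GAS hit.

#' Read a site-only, dbSNP-style VCF
#'
#' Parses CHROM/POS/ID/REF/ALT(/INFO), expands multi-allelic records to one
#' row per alternate allele, uppercases alleles and flags single-nucleotide
#' pairs.  Non-SNV allele pairs (indels, MNVs, symbolic alleles) are kept in
#' the returned frame with `is_snv = FALSE` and are excluded from candidacy
#' by the downstream operations; their number is available as attribute
#' `n_non_snv`.
#'
#' Supporting-evidence counts come from the dbSNP `FREQ` INFO field: the
#' number of `|`-separated entries is the number of distinct frequency
#' studies reporting the variant, the package's proxy for the number of
#' independent subjects.  Set `evidence_key` to a different INFO key to use
#' a plain numeric field instead.
#'
#' @param path VCF path (plain or gzip).
#' @param evidence_key INFO key carrying evidence (`"FREQ"` counts studies;
#'   any other key is read as a number).
#' @param chrom_map Optional named character vector renaming chromosomes on
#'   ingest (e.g. `c("1" = "chr1")`).
#' @return Data frame with columns `chrom`, `pos` (1-based, as in the VCF),
#'   `rsid`, `ref`, `alt`, `evidence_count`, `is_snv`, in file order.
#'   Malformed body lines raise an error naming the line number.
#' @export
read_vcf <- function(path, evidence_key = "FREQ", chrom_map = NULL) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  is_body <- !startsWith(lines, "#") & nzchar(lines)
  body <- lines[is_body]
  lineno <- which(is_body)
  if (length(body) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      rsid = character(), ref = character(),
                      alt = character(), evidence_count = integer(),
                      is_snv = logical(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 5L)) {
    .err_input("malformed VCF record at line ", lineno[which(nf < 5L)[1]],
               " of '", path, "' (fewer than 5 tab-separated fields)")
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  pos <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  if (anyNA(pos)) {
    .err_input("malformed VCF record at line ", lineno[which(is.na(pos))[1]],
               " of '", path, "' (non-integer POS)")
  }
  rsid <- vapply(fields, `[[`, character(1), 3L)
  ref <- toupper(vapply(fields, `[[`, character(1), 4L))
  alt_field <- toupper(vapply(fields, `[[`, character(1), 5L))
  info <- vapply(fields, function(f) if (length(f) >= 8L) f[[8L]] else "",
                 character(1))
  evidence <- .parse_evidence(info, evidence_key)
  if (!is.null(chrom_map)) {
    hitmap <- chrom %in% names(chrom_map)
    chrom[hitmap] <- unname(chrom_map[chrom[hitmap]])
  }
  alts <- strsplit(alt_field, ",", fixed = TRUE)
  nalt <- lengths(alts)
  idx <- rep.int(seq_along(body), nalt)
  out <- data.frame(
    chrom = chrom[idx], pos = pos[idx], rsid = rsid[idx], ref = ref[idx],
    alt = unlist(alts, use.names = FALSE),
    evidence_count = evidence[idx], stringsAsFactors = FALSE)
  acgt <- c("A", "C", "G", "T")
  out$is_snv <- nchar(out$ref) == 1L & nchar(out$alt) == 1L &
    out$ref %in% acgt & out$alt %in% acgt
  attr(out, "n_non_snv") <- sum(!out$is_snv)
  out
}

.parse_evidence <- function(info, key) {
  rx <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regmatches(info, regexec(rx, info))
  vapply(m, function(x) {
    if (length(x) < 2L) return(0L)
    if (key == "FREQ") {
      length(strsplit(x[[2L]], "|", fixed = TRUE)[[1]])
    } else {
      v <- suppressWarnings(as.integer(x[[2L]]))
      if (is.na(v)) 0L else v
    }
  }, integer(1))
}

.empty_candidates <- function() {
  data.frame(rsid = character(), chrom = character(), pos = integer(),
             ref = character(), alt = character(), class = character(),
             motif_start = integer(), motif_end = integer(),
             deviant_pos = integer(), completed_kmer = character(),
             evidence_count = integer(), nearest_gene = character(),
             gene_distance = integer(), distance_to_tss = integer(),
             conserved = logical(), provenance = character(),
             stringsAsFactors = FALSE)
}

#' Gain-of-function candidates: SNPs completing a near-GAS motif
#'
#' Joins single-nucleotide variants to non-canonical motif hits: a
#' candidate is emitted for every (hit, variant, alt) triple where the
#' variant sits exactly on the hit's deviant position, its REF equals the
#' genome base there, and the alternate allele equals the plus-strand
#' restoring allele.  Variants whose REF disagrees with the genome base
#' (a genome/catalogue build mismatch) are skipped with one summary
#' warning.
#'
#' @param hits Motif hits from [scan_sequence()]; canonical `GAS` rows are
#'   ignored.
#' @param variants Variant frame from [read_vcf()].
#' @return Candidate data frame sorted by `(chrom, pos)` with the joined
#'   hit/variant columns, `completed_kmer` (always an intact GAS match) and
#'   annotation placeholders (`nearest_gene`, `gene_distance`,
#'   `distance_to_tss`, `conserved`) filled by later funnel stages.
#' @export
candidate_gof <- function(hits, variants) {
  h <- hits[hits$class != "GAS", , drop = FALSE]
  v <- variants[variants$is_snv, , drop = FALSE]
  if (nrow(h) == 0L || nrow(v) == 0L) return(.empty_candidates())
  v$pos0 <- v$pos - 1L
  m <- merge(h, v, by.x = c("chrom", "deviant_pos"),
             by.y = c("chrom", "pos0"))
  if (nrow(m) == 0L) return(.empty_candidates())
  off <- m$deviant_pos - m$start
  gbase <- substr(m$kmer, off + 1L, off + 1L)
  mismatch <- m$ref != gbase
  if (any(mismatch)) {
    warning(sum(mismatch), " variant record(s) with REF disagreeing with ",
            "the genome base at the motif's deviant position were skipped ",
            "(possible genome/catalogue build mismatch)")
    m <- m[!mismatch, , drop = FALSE]
    off <- off[!mismatch]
  }
  keep <- m$alt == m$restore_allele
  m <- m[keep, , drop = FALSE]
  off <- off[keep]
  if (nrow(m) == 0L) return(.empty_candidates())
  completed <- mapply(.subst, m$kmer, off, m$alt, USE.NAMES = FALSE)
  stopifnot(all(iupac_matches("TTCNNNGAA", completed)))
  out <- data.frame(
    rsid = m$rsid, chrom = m$chrom, pos = m$pos, ref = m$ref, alt = m$alt,
    class = m$class, motif_start = m$start, motif_end = m$end,
    deviant_pos = m$deviant_pos, completed_kmer = completed,
    evidence_count = m$evidence_count,
    nearest_gene = NA_character_, gene_distance = NA_integer_,
    distance_to_tss = NA_integer_, conserved = NA,
    provenance = "snp_gof", stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos, out$motif_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Loss-of-function candidates: SNPs breaking a canonical GAS motif
#'
#' Emits one row per (canonical hit, variant, alt) triple where a
#' single-nucleotide variant falls on one of the six fixed motif positions
#' and its alternate allele destroys the GAS match.  Variants on the three
#' free middle positions can never qualify.
#'
#' @param gas_hits Canonical motif hits (rows with class `GAS`; other rows
#'   are ignored).
#' @param variants Variant frame from [read_vcf()].
#' @return Data frame sorted by `(chrom, pos)` with columns `rsid`,
#'   `chrom`, `pos`, `ref`, `alt`, `motif_start`, `motif_end`,
#'   `broken_kmer`, `evidence_count`.
#' @export
candidate_lof <- function(gas_hits, variants) {
  h <- gas_hits[gas_hits$class == "GAS", , drop = FALSE]
  v <- variants[variants$is_snv, , drop = FALSE]
  empty <- data.frame(rsid = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      motif_start = integer(), motif_end = integer(),
                      broken_kmer = character(), evidence_count = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(h) == 0L || nrow(v) == 0L) return(empty)
  fixed_offsets <- c(0L, 1L, 2L, 6L, 7L, 8L)
  hx <- h[rep(seq_len(nrow(h)), each = length(fixed_offsets)), , drop = FALSE]
  hx$offset <- rep(fixed_offsets, times = nrow(h))
  hx$fpos <- hx$start + hx$offset
  v$pos0 <- v$pos - 1L
  m <- merge(hx, v, by.x = c("chrom", "fpos"), by.y = c("chrom", "pos0"))
  if (nrow(m) == 0L) return(empty)
  gbase <- substr(m$kmer, m$offset + 1L, m$offset + 1L)
  mismatch <- m$ref != gbase
  if (any(mismatch)) {
    warning(sum(mismatch), " variant record(s) with REF disagreeing with ",
            "the genome base inside a canonical GAS hit were skipped")
    m <- m[!mismatch, , drop = FALSE]
  }
  if (nrow(m) == 0L) return(empty)
  broken <- mapply(.subst, m$kmer, m$offset, m$alt, USE.NAMES = FALSE)
  keep <- !iupac_matches("TTCNNNGAA", broken)
  m <- m[keep, , drop = FALSE]
  broken <- broken[keep]
  if (nrow(m) == 0L) return(empty)
  out <- data.frame(rsid = m$rsid, chrom = m$chrom, pos = m$pos,
                    ref = m$ref, alt = m$alt, motif_start = m$start,
                    motif_end = m$end, broken_kmer = broken,
                    evidence_count = m$evidence_count,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos, out$motif_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Multi-subject evidence filter
#'
#' Keeps candidates whose `evidence_count` (number of independent
#' supporting studies) reaches `min_subjects`; the default of 2 guards
#' against singleton calls that may be sequencing errors.
#'
#' @param candidates Candidate data frame with an `evidence_count` column.
#' @param min_subjects Minimum evidence count (default 2).
#' @return Subset of `candidates` (row order preserved).
#' @export
evidence_filter <- function(candidates, min_subjects = 2L) {
  stopifnot(min_subjects >= 0)
  candidates[candidates$evidence_count >= min_subjects, , drop = FALSE]
}

#' Write candidates as TSV
#'
#' @param candidates Candidate data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidates_tsv <- function(candidates, path) {
  .write_tsv(candidates, path)
}

#' Read candidates written by [write_candidates_tsv()]
#'
#' @param path TSV path.
#' @return Candidate data frame.
#' @export
read_candidates_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  for (col in intersect(c("rsid", "chrom", "ref", "alt"), names(df))) {
    df[[col]] <- as.character(df[[col]])
  }
  df
}
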