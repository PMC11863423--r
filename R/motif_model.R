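# The GAS motif algebra: the canonical STAT-dimer binding consensus
# TTCnnnGAA plus the six "near-complete GAS" (ncGAS) classes that deviate
# from it at exactly one of the six fixed positions.  Each deviation class
# excludes the canonical base at its deviant position, so the seven classes
# are pairwise disjoint and a single restoring substitution maps any ncGAS
# 9-mer onto a canonical match.

# IUPAC degeneracy codes.  Sets contain plain bases only: an ambiguous
# genome base ('N' or any non-ACGT symbol) matches no pattern symbol,
# including the free middle positions -- a motif call through an assembly
# gap is meaningless.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# Per-position allowed-base sets for a pattern (list of character vectors).
# Patterns are expanded to explicit sets rather than regexes so that the
# scanner and the regex-based reference oracle are independent code paths.
.pattern_sets <- function(pattern) {
  syms <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(syms, names(IUPAC_SETS))
  if (length(bad) > 0) {
    .err_input("unknown IUPAC symbol(s) in pattern '", pattern, "': ",
               paste(bad, collapse = ", "))
  }
  IUPAC_SETS[syms]
}

# Logical lookup tables for the scanner: one length-5 vector per position,
# indexed by the base code A=1 C=2 G=3 T=4 other=5 (slot 5 always FALSE).
.allowed_lookup <- function(pattern) {
  lapply(.pattern_sets(pattern), function(s) {
    c(c("A", "C", "G", "T") %in% s, FALSE)
  })
}

#' The canonical GAS motif and its six single-deviation classes
#'
#' Returns the seven motif classes used throughout the package: the
#' canonical GAS consensus `TTCNNNGAA` and the six near-complete GAS
#' (ncGAS) classes named for the fixed base that deviates (`T1`, `T2`,
#' `C`, `G`, `A1`, `A2`).  Each non-canonical class carries the 0-based
#' offset of its deviant position within the 9-mer and the base whose
#' substitution there restores an intact GAS motif.
#'
#' The deviation symbols are the IUPAC complements of the canonical base:
#' `V` (A/C/G, not T), `D` (A/G/T, not C), `H` (A/C/T, not G) and
#' `B` (C/G/T, not A), so each class is disjoint from the canonical motif
#' and from every other class.
#'
#' @return A data frame with columns `name`, `pattern` (9-symbol IUPAC
#'   string), `deviant_offset` (integer, `NA` for `GAS`) and
#'   `restore_base` (`NA` for `GAS`), in fixed order
#'   GAS, T1, T2, C, G, A1, A2.
#' @examples
#' gas_classes()
#' @export
gas_classes <- function() {
  data.frame(
    name = c("GAS", "T1", "T2", "C", "G", "A1", "A2"),
    pattern = c("TTCNNNGAA", "VTCNNNGAA", "TVCNNNGAA", "TTDNNNGAA",
                "TTCNNNHAA", "TTCNNNGBA", "TTCNNNGAB"),
    deviant_offset = c(NA, 0L, 1L, 2L, 6L, 7L, 8L),
    restore_base = c(NA, "T", "T", "C", "G", "A", "A"),
    stringsAsFactors = FALSE
  )
}

#' Match DNA k-mers against an IUPAC pattern
#'
#' A k-mer matches when every one of its bases is contained in the
#' allowed-base set of the corresponding pattern position.  A `N` (or any
#' non-ACGT symbol) in the k-mer matches nothing, including pattern `N`.
#'
#' @param pattern A single IUPAC string.
#' @param kmer Character vector of k-mers, each the same length as
#'   `pattern` (an error otherwise).
#' @return Logical vector, one element per k-mer.
#' @examples
#' iupac_matches("TTCNNNGAA", "TTCAAAGAA")
#' iupac_matches("VTCNNNGAA", "TTCAAAGAA") # V excludes T
#' @export
iupac_matches <- function(pattern, kmer) {
  stopifnot(length(pattern) == 1L)
  if (length(kmer) == 0L) return(logical(0))
  if (any(nchar(kmer) != nchar(pattern))) {
    .err_input("k-mer length differs from pattern length (",
               nchar(pattern), ")")
  }
  match_kmers(pattern, kmer)
}

#' Vectorized k-mer/IUPAC matching
#'
#' Workhorse behind [iupac_matches()], efficient for large k-mer sets
#' (e.g. exhaustive enumeration of all 4^9 9-mers).  All k-mers must share
#' the pattern's length.
#'
#' @inheritParams iupac_matches
#' @return Logical vector.
#' @export
match_kmers <- function(pattern, kmer) {
  sets <- .pattern_sets(pattern)
  w <- length(sets)
  if (length(kmer) == 0L) return(logical(0))
  if (any(nchar(kmer) != w)) .err_input("k-mer length differs from pattern length (", w, ")")
  m <- matrix(unlist(strsplit(toupper(kmer), "", fixed = TRUE),
                     use.names = FALSE),
              ncol = w, byrow = TRUE)
  ok <- rep(TRUE, length(kmer))
  for (j in seq_len(w)) ok <- ok & (m[, j] %in% sets[[j]])
  ok
}

#' Enumerate all DNA k-mers of a given width
#'
#' @param width K-mer width (default 9; 4^width strings are returned, so
#'   keep it small).
#' @return Character vector of length `4^width` in lexicographic order.
#' @export
all_kmers <- function(width = 9L) {
  bases <- c("A", "C", "G", "T")
  do.call(paste0, rev(expand.grid(rep(list(bases), width),
                                  stringsAsFactors = FALSE)))
}

#' Reverse-complement partner of a motif class
#'
#' The class set is closed under reverse complementation: the canonical
#' palindrome maps to itself and the deviation classes pair up as
#' T1/A2, T2/A1 and C/G.  This closure is what makes plus-strand-only
#' scanning with all seven classes complete with respect to both strands.
#'
#' @param class_name Character vector of class names.
#' @return Character vector of partner class names.
#' @examples
#' revcomp_partner("T1") # "A2"
#' @export
revcomp_partner <- function(class_name) {
  map <- c(GAS = "GAS", T1 = "A2", T2 = "A1", C = "G",
           G = "C", A1 = "T2", A2 = "T1")
  unknown <- setdiff(class_name, names(map))
  if (length(unknown) > 0) {
    .err_input("unknown motif class: ", paste(unknown, collapse = ", "))
  }
  unname(map[class_name])
}

#' Restoring substitution for a near-GAS 9-mer
#'
#' For a 9-mer matching a non-canonical class, returns the single
#' substitution (0-based offset within the 9-mer, replacement base) that
#' converts it into a canonical GAS match.
#'
#' @param kmer A single 9-mer matching `class_name`'s pattern.
#' @param class_name One of `T1`, `T2`, `C`, `G`, `A1`, `A2`.
#' @param classes Motif class table, normally [gas_classes()].
#' @return List with elements `offset` (integer) and `base` (character).
#' @examples
#' restoring_substitution("GTCAAAGAA", "T1") # offset 0, base "T"
#' @export
restoring_substitution <- function(kmer, class_name, classes = gas_classes()) {
  row <- classes[classes$name == class_name, , drop = FALSE]
  if (nrow(row) != 1L) .err_input("unknown motif class: ", class_name)
  if (is.na(row$deviant_offset)) {
    .err_input("class '", class_name, "' is canonical; nothing to restore")
  }
  if (!iupac_matches(row$pattern, kmer)) {
    .err_input("k-mer '", kmer, "' does not match class '", class_name, "'")
  }
  list(offset = row$deviant_offset, base = row$restore_base)
}

#' Export the motif class table as a MEME-format motif file
#'
#' Writes one letter-probability matrix per class, with uniform
#' probabilities over the allowed bases at each position, for
#' interoperability with MEME-suite scanners.
#'
#' @param path Output file path.
#' @param classes Motif class table.
#' @return `path`, invisibly.
#' @export
write_meme_motifs <- function(path, classes = gas_classes()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -",
               "", "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (i in seq_len(nrow(classes))) {
    sets <- .pattern_sets(classes$pattern[i])
    writeLines(sprintf("MOTIF %s %s", classes$name[i], classes$pattern[i]),
               con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
      length(sets)), con)
    for (s in sets) {
      p <- as.numeric(c("A", "C", "G", "T") %in% s)
      writeLines(paste(sprintf("%.6f", p / sum(p)), collapse = " "), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Export the motif class table as TSV
#'
#' @param path Output file path.
#' @param classes Motif class table.
#' @return `path`, invisibly.
#' @export
write_class_table <- function(path, classes = gas_classes()) {
  .write_tsv(classes, path)
}
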