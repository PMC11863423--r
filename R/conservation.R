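# Cross-species conservation: a candidate survives when the strand-aware
# 10 kb upstream window of an orthologous gene in the second genome
# contains a qualifying motif hit.  Window arithmetic is shared with
# upstream_tss_filter (.upstream_window), so the two stages cannot drift
# apart.

#' Read a two-column ortholog map
#'
#' Tab-separated `gene_id_1`, `gene_id_2`; a header row whose first field
#' starts with "gene" is skipped.  One-to-many mappings are allowed.
#'
#' @param path TSV path.
#' @return Data frame `gene_id_1`, `gene_id_2`.
#' @export
read_orthologs <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#",
                          col.names = c("gene_id_1", "gene_id_2"),
                          colClasses = "character")
  if (nrow(df) > 0L && grepl("^gene", df$gene_id_1[1], ignore.case = TRUE)) {
    df <- df[-1, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Conservation filter against a second genome
#'
#' For each candidate, looks up the orthologs of its annotated target gene
#' (`nearest_gene`), extracts the strand-aware upstream window of each
#' ortholog's TSS from the second genome (clipped to the sequence), scans
#' the plus-strand slice with the full motif class set (the class set is
#' strand-closed, so no special casing for minus-strand genes), and keeps
#' the candidate when a hit satisfying `match_mode` exists in any
#' ortholog's window.
#'
#' @param candidates Candidate data frame with `nearest_gene` populated.
#' @param orthologs Ortholog map from [read_orthologs()].
#' @param genome2 Second-genome FASTA path or a named `DNAStringSet`.
#' @param genes2 Second-genome gene models from [read_gene_models()].
#' @param span Upstream window length in bp (default 10000).
#' @param match_mode `"same_class"` (default: a hit of the candidate's own
#'   near-GAS class), `"any_ncgas"` (any non-canonical class) or
#'   `"canonical"` (an intact GAS).
#' @param classes Motif class table.
#' @return The conserved subset of `candidates`, with `conserved = TRUE`.
#'   Attributes `n_no_ortholog` and `n_not_conserved` report why the
#'   others were dropped (a missing ortholog is logged distinctly from an
#'   ortholog whose window lacks the motif).
#' @export
conservation_filter <- function(candidates, orthologs, genome2, genes2,
                                span = 10000L,
                                match_mode = c("same_class", "any_ncgas",
                                               "canonical"),
                                classes = gas_classes()) {
  match_mode <- match.arg(match_mode)
  if (is.character(genome2)) {
    genome2 <- Biostrings::readDNAStringSet(genome2)
    names(genome2) <- .read_first_fasta_names(names(genome2))
  }
  if (nrow(candidates) == 0L) {
    out <- candidates
    attr(out, "n_no_ortholog") <- 0L
    attr(out, "n_not_conserved") <- 0L
    return(out)
  }
  conserved <- rep(FALSE, nrow(candidates))
  no_orth <- rep(FALSE, nrow(candidates))
  window_cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(candidates))) {
    g1 <- candidates$nearest_gene[i]
    if (is.na(g1)) .err_input("candidate without annotated nearest_gene")
    g2ids <- orthologs$gene_id_2[orthologs$gene_id_1 == g1]
    g2 <- genes2[genes2$gene_id %in% g2ids, , drop = FALSE]
    if (nrow(g2) == 0L) {
      no_orth[i] <- TRUE
      next
    }
    for (j in seq_len(nrow(g2))) {
      key <- g2$gene_id[j]
      hits <- if (!is.null(window_cache[[key]])) window_cache[[key]] else {
        win <- .upstream_window(g2$tss[j], g2$strand[j], span)
        chrom <- g2$chrom[j]
        if (!chrom %in% names(genome2)) {
          .err_input("chromosome '", chrom, "' absent from second genome")
        }
        clen <- Biostrings::nchar(genome2[[chrom]])
        s0 <- max(win$start, 0L)
        e0 <- min(win$end, clen)
        h <- if (e0 - s0 >= 9L) {
          slice <- as.character(Biostrings::subseq(genome2[[chrom]],
                                                   s0 + 1L, e0))
          scan_sequence(slice, chrom, classes)
        } else .empty_hits()
        window_cache[[key]] <- h
        h
      }
      ok <- switch(match_mode,
                   same_class = any(hits$class == candidates$class[i]),
                   any_ncgas = any(hits$class != "GAS"),
                   canonical = any(hits$class == "GAS"))
      if (ok) {
        conserved[i] <- TRUE
        break
      }
    }
  }
  out <- candidates
  out$conserved <- conserved
  out <- out[conserved, , drop = FALSE]
  attr(out, "n_no_ortholog") <- sum(no_orth)
  attr(out, "n_not_conserved") <- sum(!conserved & !no_orth)
  if (any(no_orth)) {
    message(sum(no_orth), " candidate(s) dropped: target gene has no ",
            "ortholog in the second genome")
  }
  out
}
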