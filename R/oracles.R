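# Independent reference implementations ("oracles") used by the scenario
# generator to compute ground-truth tables and by the test suite to
# validate the main code paths.  They deliberately share no machinery with
# the production implementations: motif finding is regex-based and scans
# both strands explicitly, interval logic is quadratic, and gene lookups
# are plain loops.

.iupac_regex <- function(pattern) {
  sets <- .pattern_sets(pattern)
  paste0(vapply(sets, function(s) paste0("[", paste0(s, collapse = ""), "]"),
                character(1)), collapse = "")
}

.regex_starts0 <- function(seq, rx) {
  m <- gregexpr(paste0("(?=", rx, ")"), seq, perl = TRUE)[[1]]
  if (length(m) == 1L && m[1] == -1L) integer(0) else as.integer(m) - 1L
}

#' Reference motif scan (both-strand regex oracle)
#'
#' Scans the plus strand and the reverse complement explicitly with
#' per-class regular expressions, maps minus-strand occurrences back to
#' plus-strand coordinates through [revcomp_partner()], and reports each
#' genomic interval once.  Used to validate [scan_sequence()].
#'
#' @param seq A single DNA string.
#' @param chrom Sequence name.
#' @param classes Motif class table.
#' @return Data frame `chrom`, `start`, `end`, `class` sorted by `start`.
#' @export
oracle_scan <- function(seq, chrom = "chr1", classes = gas_classes()) {
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  rc <- .revcomp(seq)
  rows <- list()
  for (ci in seq_len(nrow(classes))) {
    rx <- .iupac_regex(classes$pattern[ci])
    s_plus <- .regex_starts0(seq, rx)
    if (length(s_plus) > 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        start = s_plus, class = classes$name[ci], stringsAsFactors = FALSE)
    }
    s_minus <- .regex_starts0(rc, rx)
    if (length(s_minus) > 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        start = n - 9L - s_minus,
        class = revcomp_partner(classes$name[ci]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), class = character(),
                      stringsAsFactors = FALSE))
  }
  df <- unique(do.call(rbind, rows))
  df <- df[order(df$start), , drop = FALSE]
  data.frame(chrom = chrom, start = df$start, end = df$start + 9L,
             class = df$class, stringsAsFactors = FALSE, row.names = NULL)
}

#' Reference gain-of-function caller (apply-and-rescan oracle)
#'
#' For every catalogued single-nucleotide allele whose REF matches the
#' genome, substitutes the alternate allele into a local window and diffs
#' the canonical-GAS regex hit sets before and after; any newly created
#' GAS interval covering the variant makes it a candidate.  Used to
#' validate [candidate_gof()].
#'
#' @param seq A single DNA string.
#' @param variants Variant frame in the [read_vcf()] layout.
#' @param chrom Sequence name carried by `seq`.
#' @return Data frame `rsid`, `chrom`, `pos`, `ref`, `alt`,
#'   `evidence_count`, `motif_start`, `motif_end`, `class` (the class of
#'   the pre-substitution 9-mer), sorted by `(pos, motif_start)`.
#' @export
oracle_gof <- function(seq, variants, chrom = "chr1") {
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  gas_rx <- .iupac_regex("TTCNNNGAA")
  classes <- gas_classes()
  rows <- list()
  v <- variants[variants$is_snv & variants$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(v))) {
    pos0 <- v$pos[i] - 1L
    if (pos0 < 0L || pos0 >= n) next
    if (substr(seq, pos0 + 1L, pos0 + 1L) != v$ref[i]) next
    lo <- max(0L, pos0 - 8L)
    hi <- min(n, pos0 + 9L)
    before <- substr(seq, lo + 1L, hi)
    after <- .subst(before, pos0 - lo, v$alt[i])
    new0 <- setdiff(.regex_starts0(after, gas_rx),
                    .regex_starts0(before, gas_rx)) + lo
    new0 <- new0[new0 <= pos0 & pos0 <= new0 + 8L]
    for (s0 in new0) {
      orig <- substr(seq, s0 + 1L, s0 + 9L)
      cls <- classes$name[vapply(classes$pattern, match_kmers,
                                 logical(1), orig)]
      rows[[length(rows) + 1L]] <- data.frame(
        rsid = v$rsid[i], chrom = chrom, pos = v$pos[i], ref = v$ref[i],
        alt = v$alt[i], evidence_count = v$evidence_count[i],
        motif_start = s0, motif_end = s0 + 9L,
        class = if (length(cls) == 1L) cls else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(rsid = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      evidence_count = integer(), motif_start = integer(),
                      motif_end = integer(), class = character(),
                      stringsAsFactors = FALSE))
  }
  out <- unique(do.call(rbind, rows))
  out <- out[order(out$pos, out$motif_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Quadratic reference window join
#'
#' All-pairs gap computation against which [window_join()] is validated.
#'
#' @inheritParams window_join
#' @return The kept rows of `items`.
#' @export
oracle_window_join <- function(items, regions, w = 200L) {
  if (nrow(items) == 0L) return(items)
  cols <- .item_cols(items)
  keep <- vapply(seq_len(nrow(items)), function(i) {
    r <- regions[regions$chrom == items$chrom[i], , drop = FALSE]
    if (nrow(r) == 0L) return(FALSE)
    gaps <- .interval_gap(items[[cols[1]]][i], items[[cols[2]]][i],
                          r$start, r$end)
    min(gaps) <= w
  }, logical(1))
  items[keep, , drop = FALSE]
}

#' Quadratic reference spacing filter
#'
#' @inheritParams spacing_filter
#' @return The kept rows of `candidates`.
#' @export
oracle_spacing_filter <- function(candidates, gas_hits, w = 200L,
                                  drop_clustered = TRUE) {
  if (nrow(candidates) == 0L) return(candidates)
  gas <- gas_hits[gas_hits$class == "GAS", , drop = FALSE]
  n <- nrow(candidates)
  drop <- rep(FALSE, n)
  for (i in seq_len(n)) {
    g <- gas[gas$chrom == candidates$chrom[i], , drop = FALSE]
    if (nrow(g) > 0L) {
      gaps <- .interval_gap(candidates$motif_start[i],
                            candidates$motif_end[i], g$start, g$end)
      if (min(gaps) <= w) drop[i] <- TRUE
    }
    if (drop_clustered) {
      for (j in seq_len(n)) {
        if (j == i) next
        if (candidates$chrom[j] != candidates$chrom[i]) next
        same <- candidates$motif_start[j] == candidates$motif_start[i] &&
          candidates$motif_end[j] == candidates$motif_end[i]
        if (same) next
        gap <- .interval_gap(candidates$motif_start[i],
                             candidates$motif_end[i],
                             candidates$motif_start[j],
                             candidates$motif_end[j])
        if (gap <= w) drop[i] <- TRUE
      }
    }
  }
  candidates[!drop, , drop = FALSE]
}

#' Quadratic reference immune-neighborhood filter
#'
#' @inheritParams neighbor_gene_filter
#' @return Annotated subset of `candidates`.
#' @export
oracle_neighbor_filter <- function(candidates, genes) {
  if (nrow(candidates) == 0L) return(candidates)
  keep <- rep(FALSE, nrow(candidates))
  nearest <- rep(NA_character_, nrow(candidates))
  dist <- rep(NA_integer_, nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    pos0 <- candidates$pos[i] - 1L
    g <- genes[genes$chrom == candidates$chrom[i], , drop = FALSE]
    if (nrow(g) == 0L) next
    left <- g[g$tss <= pos0, , drop = FALSE]
    right <- g[g$tss > pos0, , drop = FALSE]
    fl <- rbind(if (nrow(left) > 0L) left[which.max(left$tss), ],
                if (nrow(right) > 0L) right[which.min(right$tss), ])
    imm <- fl[fl$immune, , drop = FALSE]
    if (nrow(imm) == 0L) next
    keep[i] <- TRUE
    d <- pos0 - imm$tss
    best <- which.min(abs(d))
    nearest[i] <- imm$gene_id[best]
    dist[i] <- d[best]
  }
  out <- candidates
  out$nearest_gene <- nearest
  out$gene_distance <- dist
  out[keep, , drop = FALSE]
}

#' Quadratic reference upstream-of-TSS filter
#'
#' @inheritParams upstream_tss_filter
#' @return Annotated subset of `candidates`.
#' @export
oracle_upstream_filter <- function(candidates, genes, span = 10000L) {
  if (nrow(candidates) == 0L) return(candidates)
  g <- genes[genes$immune %in% TRUE, , drop = FALSE]
  keep <- rep(FALSE, nrow(candidates))
  nearest <- rep(NA_character_, nrow(candidates))
  dist <- rep(NA_integer_, nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    pos0 <- candidates$pos[i] - 1L
    best_d <- Inf
    for (j in seq_len(nrow(g))) {
      if (g$chrom[j] != candidates$chrom[i]) next
      d <- if (g$strand[j] == "+") g$tss[j] - pos0 else pos0 - g$tss[j]
      if (d >= 1L && d <= span && d < best_d) {
        best_d <- d
        keep[i] <- TRUE
        nearest[i] <- g$gene_id[j]
        dist[i] <- d
      }
    }
  }
  out <- candidates
  if (!"nearest_gene" %in% names(out)) out$nearest_gene <- NA_character_
  out$nearest_gene <- ifelse(keep, nearest, out$nearest_gene)
  out$distance_to_tss <- dist
  out[keep, , drop = FALSE]
}

#' Per-base reference signal thresholding
#'
#' Marks every base covered by a passing bedGraph row and run-length
#' encodes the result, against which [threshold_signal()]'s bookended
#' merge is validated.
#'
#' @param bedgraph Data frame `chrom`, `start`, `end`, `value`.
#' @param min_signal Threshold.
#' @return Data frame `chrom`, `start`, `end` of maximal passing runs.
#' @export
oracle_threshold <- function(bedgraph, min_signal = 20) {
  out <- list()
  for (ch in sort(unique(bedgraph$chrom))) {
    b <- bedgraph[bedgraph$chrom == ch & bedgraph$value >= min_signal, ,
                  drop = FALSE]
    if (nrow(b) == 0L) next
    hi <- max(b$end)
    covered <- logical(hi)
    for (i in seq_len(nrow(b))) {
      covered[(b$start[i] + 1L):b$end[i]] <- TRUE
    }
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    sel <- r$values
    if (any(sel)) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = starts[sel], end = ends[sel],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
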