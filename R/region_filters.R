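# Interval-based funnel stages: open-chromatin support, immune-gene
# neighborhood, the strand-aware 10 kb upstream-of-TSS restriction, and
# spacing from existing canonical GAS motifs.  Overlap and nearest-neighbor
# queries go through GenomicRanges; the test suite validates every filter
# against quadratic brute-force reference implementations.

#' Threshold an open-chromatin signal track
#'
#' Reads a 4-column bedGraph (e.g. H3K27ac ChIP-seq coverage), keeps
#' intervals whose signal reaches `min_signal` and merges overlapping or
#' bookended passing intervals into maximal runs.  The default threshold of
#' 20, compared with `>=`, encodes "an acetylation signal of 20 or higher";
#' pass a different `comparator` (e.g. `` `>` ``) to change the boundary
#' rule.
#'
#' @param path bedGraph path.
#' @param min_signal Signal threshold (default 20).
#' @param comparator Two-argument comparison function (default `` `>=` ``).
#' @return Data frame of merged passing intervals: `chrom`, `start`
#'   (0-based), `end`.
#' @export
threshold_signal <- function(path, min_signal = 20, comparator = `>=`) {
  gr <- tryCatch(rtracklayer::import(path, format = "bedGraph"),
                 error = function(e) .err_input(
                   "cannot read bedGraph '", path, "': ",
                   conditionMessage(e)))
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   value = as.numeric(S4Vectors::mcols(gr)$score),
                   stringsAsFactors = FALSE)
  if (anyNA(df$value)) .err_input("non-numeric value column in '", path, "'")
  df <- df[comparator(df$value, min_signal), , drop = FALSE]
  merge_intervals(df)
}

#' Read pre-called peaks from a BED file
#'
#' Alternative to [threshold_signal()] when peaks have already been called.
#'
#' @param path BED path.
#' @return Data frame `chrom`, `start` (0-based), `end`.
#' @export
read_peaks_bed <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) .err_input(
                   "cannot read BED '", path, "': ", conditionMessage(e)))
  merge_intervals(data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                             start = GenomicRanges::start(gr) - 1L,
                             end = GenomicRanges::end(gr),
                             stringsAsFactors = FALSE))
}

#' Merge overlapping or bookended intervals
#'
#' @param intervals Data frame with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return Sorted data frame of maximal merged intervals.
#' @export
merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  intervals <- intervals[order(intervals$chrom, intervals$start,
                               intervals$end), , drop = FALSE]
  out <- list()
  cur <- intervals[1, c("chrom", "start", "end")]
  for (i in seq_len(nrow(intervals))[-1]) {
    row <- intervals[i, ]
    if (row$chrom == cur$chrom && row$start <= cur$end) {
      cur$end <- max(cur$end, row$end)
    } else {
      out[[length(out) + 1L]] <- cur
      cur <- row[, c("chrom", "start", "end")]
    }
  }
  out[[length(out) + 1L]] <- cur
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.item_cols <- function(items) {
  if (all(c("motif_start", "motif_end") %in% names(items))) {
    c("motif_start", "motif_end")
  } else if (all(c("start", "end") %in% names(items))) {
    c("start", "end")
  } else {
    .err_input("items need either motif_start/motif_end or start/end columns")
  }
}

#' Window join: keep items within `w` bp of a region
#'
#' Symmetric-extension join in the spirit of `bedtools window -w`: an item
#' is kept when the gap between its interval and the nearest region is at
#' most `w` (overlapping or bookended intervals have gap 0).  Items on
#' chromosomes with no regions are dropped.
#'
#' @param items Data frame carrying an interval per row (columns
#'   `motif_start`/`motif_end`, or `start`/`end`) plus `chrom`.
#' @param regions Interval data frame (`chrom`, `start`, `end`).
#' @param w Maximum allowed gap in bp (default 200).
#' @return The kept rows of `items` (order preserved).
#' @export
window_join <- function(items, regions, w = 200L) {
  stopifnot(w >= 0)
  if (nrow(items) == 0L || nrow(regions) == 0L) {
    return(items[integer(0), , drop = FALSE])
  }
  cols <- .item_cols(items)
  universe <- unique(c(items$chrom, regions$chrom))
  gi <- .as_granges(items$chrom, items[[cols[1]]], items[[cols[2]]], universe)
  gr <- .as_granges(regions$chrom, regions$start, regions$end, universe)
  nearest <- GenomicRanges::distanceToNearest(gi, gr)
  keep <- rep(FALSE, nrow(items))
  qh <- S4Vectors::queryHits(nearest)
  keep[qh[S4Vectors::mcols(nearest)$distance <= w]] <- TRUE
  items[keep, , drop = FALSE]
}

#' Immune-neighborhood filter: flanking-gene immunity
#'
#' For each candidate SNP position, finds the nearest gene TSS on each
#' side (strand-agnostic; a TSS exactly at the SNP counts as the left
#' neighbor at distance 0) and keeps the candidate when at least one of
#' the two flanking genes is immune.  Kept candidates are annotated with
#' the nearest immune flanking gene (`nearest_gene`, by gene id) and the
#' signed distance `gene_distance = pos0 - tss`.  Candidates on
#' chromosomes without any gene are dropped with a message.
#'
#' @param candidates Candidate data frame with `chrom` and `pos` (1-based).
#' @param genes Gene models from [read_gene_models()] with the `immune`
#'   flag set (see [set_immune_genes()]).
#' @return Annotated subset of `candidates`.
#' @export
neighbor_gene_filter <- function(candidates, genes) {
  if (nrow(candidates) == 0L) return(candidates)
  if (anyNA(genes$immune)) .err_input("gene immune flags are not set")
  keep <- rep(FALSE, nrow(candidates))
  nearest <- rep(NA_character_, nrow(candidates))
  dist <- rep(NA_integer_, nrow(candidates))
  pos0 <- candidates$pos - 1L
  for (ch in unique(candidates$chrom)) {
    ci <- which(candidates$chrom == ch)
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0L) {
      message("no genes on ", ch, "; dropping ", length(ci), " candidate(s)")
      next
    }
    g <- g[order(g$tss), , drop = FALSE]
    li <- findInterval(pos0[ci], g$tss)   # index of nearest TSS <= pos0
    ri <- li + 1L
    for (k in seq_along(ci)) {
      flank_idx <- c(if (li[k] >= 1L) li[k], if (ri[k] <= nrow(g)) ri[k])
      fl <- g[flank_idx, , drop = FALSE]
      imm <- fl[fl$immune, , drop = FALSE]
      if (nrow(imm) == 0L) next
      keep[ci[k]] <- TRUE
      d <- pos0[ci[k]] - imm$tss
      best <- which.min(abs(d))
      nearest[ci[k]] <- imm$gene_id[best]
      dist[ci[k]] <- d[best]
    }
  }
  out <- candidates
  out$nearest_gene <- nearest
  out$gene_distance <- dist
  out[keep, , drop = FALSE]
}

# Strand-aware upstream window of a TSS, 0-based half-open.  Plus strand:
# the `span` bases before the TSS; minus strand: the `span` bases after it.
# The TSS base itself is never part of its own upstream window.
.upstream_window <- function(tss, strand, span) {
  start <- ifelse(strand == "+", tss - span, tss + 1L)
  end <- ifelse(strand == "+", tss, tss + span + 1L)
  data.frame(start = as.integer(start), end = as.integer(end))
}

#' Upstream-of-TSS filter (strand-aware 10 kb windows)
#'
#' Keeps candidates whose SNP lies in the upstream window of at least one
#' immune gene: `[tss - span, tss)` for plus-strand genes and
#' `[tss + 1, tss + span + 1)` for minus-strand genes (0-based half-open).
#' Kept candidates are annotated with the window gene at minimal TSS
#' distance: `nearest_gene` is overwritten with that gene (the putative
#' enhancer target handed to the conservation stage) and
#' `distance_to_tss` records the distance in bp (1 to `span`).
#'
#' @param candidates Candidate data frame with `chrom` and `pos` (1-based).
#' @param genes Gene models with `immune` flags set.
#' @param span Upstream window length in bp (default 10000); must be
#'   positive.
#' @return Annotated subset of `candidates`.
#' @export
upstream_tss_filter <- function(candidates, genes, span = 10000L) {
  if (span <= 0) .err_input("span must be positive")
  if (nrow(candidates) == 0L) return(candidates)
  g <- genes[genes$immune %in% TRUE, , drop = FALSE]
  if (nrow(g) == 0L) return(candidates[integer(0), , drop = FALSE])
  win <- .upstream_window(g$tss, g$strand, span)
  win$start <- pmax(win$start, 0L)
  universe <- unique(c(candidates$chrom, g$chrom))
  gw <- .as_granges(g$chrom, win$start, win$end, universe)
  pos0 <- candidates$pos - 1L
  gp <- .as_granges(candidates$chrom, pos0, pos0 + 1L, universe)
  ov <- GenomicRanges::findOverlaps(gp, gw)
  keep <- rep(FALSE, nrow(candidates))
  nearest <- rep(NA_character_, nrow(candidates))
  dist <- rep(NA_integer_, nrow(candidates))
  if (length(ov) > 0L) {
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    d <- ifelse(g$strand[sh] == "+", g$tss[sh] - pos0[qh],
                pos0[qh] - g$tss[sh])
    for (q in unique(qh)) {
      sel <- which(qh == q)
      best <- sel[which.min(d[sel])]
      keep[q] <- TRUE
      nearest[q] <- g$gene_id[sh[best]]
      dist[q] <- d[best]
    }
  }
  out <- candidates
  if (!"nearest_gene" %in% names(out)) out$nearest_gene <- NA_character_
  out$nearest_gene <- ifelse(keep, nearest, out$nearest_gene)
  out$distance_to_tss <- dist
  out[keep, , drop = FALSE]
}

#' Spacing filter: distance from canonical GAS motifs and candidate
#' clusters
#'
#' Removes candidates whose motif interval lies within `w` bp (gap
#' `<= w`) of any canonical GAS hit, so a newly created site cannot
#' interfere with an existing one.  With `drop_clustered = TRUE`
#' (default), additionally removes every member of any group of candidate
#' motifs mutually within `w` bp of each other: no ranking rule exists to
#' pick a winner, so the whole cluster is discarded.  Both rules are
#' evaluated on the input set.
#'
#' @param candidates Candidate data frame with `chrom`, `motif_start`,
#'   `motif_end`.
#' @param gas_hits Canonical motif hits (class `GAS`) from the same genome.
#' @param w Minimum required gap in bp (default 200).
#' @param drop_clustered Drop mutually close candidate motifs (default
#'   `TRUE`).
#' @return Subset of `candidates` (order preserved).
#' @export
spacing_filter <- function(candidates, gas_hits, w = 200L,
                           drop_clustered = TRUE) {
  if (nrow(candidates) == 0L) return(candidates)
  drop <- rep(FALSE, nrow(candidates))
  universe <- unique(c(candidates$chrom, gas_hits$chrom))
  cm <- .as_granges(candidates$chrom, candidates$motif_start,
                    candidates$motif_end, universe)
  gas <- gas_hits[gas_hits$class == "GAS", , drop = FALSE]
  if (nrow(gas) > 0L) {
    gg <- .as_granges(gas$chrom, gas$start, gas$end, universe)
    nearest <- GenomicRanges::distanceToNearest(cm, gg)
    qh <- S4Vectors::queryHits(nearest)
    drop[qh[S4Vectors::mcols(nearest)$distance <= w]] <- TRUE
  }
  if (drop_clustered) {
    key <- paste(candidates$chrom, candidates$motif_start,
                 candidates$motif_end)
    ukey <- !duplicated(key)
    u <- candidates[ukey, c("chrom", "motif_start", "motif_end"),
                    drop = FALSE]
    if (nrow(u) >= 2L) {
      gu <- .as_granges(u$chrom, u$motif_start, u$motif_end, universe)
      nn <- GenomicRanges::distanceToNearest(gu)
      qh <- S4Vectors::queryHits(nn)
      close_u <- qh[S4Vectors::mcols(nn)$distance <= w]
      if (length(close_u) > 0L) {
        bad_keys <- paste(u$chrom, u$motif_start, u$motif_end)[close_u]
        drop[key %in% bad_keys] <- TRUE
      }
    }
  }
  candidates[!drop, , drop = FALSE]
}

#' Read gene models from GTF/GFF3 or a TSS BED file
#'
#' For GTF/GFF3 input, the TSS of a multi-transcript gene is the most 5'
#' transcript start on the gene's strand (minimum start for plus-strand
#' genes, maximum end for minus-strand genes); `gene` features are used
#' when no transcript features are present.  For 6-column BED input, each
#' record is one gene whose TSS is `start` on the plus strand and
#' `end - 1` on the minus strand, with `name` as the gene id.
#'
#' @param path Gene model path.
#' @param format `"auto"` (by extension), `"gtf"`, `"gff3"` or `"bed"`.
#' @return Data frame `gene_id`, `symbol`, `chrom`, `strand`, `tss`
#'   (0-based), `immune` (initialized to `NA`; see [set_immune_genes()]).
#' @export
read_gene_models <- function(path, format = c("auto", "gtf", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) "bed"
              else if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) "gff3"
              else "gtf"
  }
  if (format == "bed") {
    gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                   error = function(e) .err_input(
                     "cannot read BED '", path, "': ", conditionMessage(e)))
    strand <- as.character(GenomicRanges::strand(gr))
    if (any(strand == "*")) .err_input("TSS BED needs explicit +/- strands")
    tss <- ifelse(strand == "+", GenomicRanges::start(gr) - 1L,
                  GenomicRanges::end(gr) - 1L)
    nm <- as.character(S4Vectors::mcols(gr)$name)
    return(data.frame(gene_id = nm, symbol = nm,
                      chrom = as.character(GenomicRanges::seqnames(gr)),
                      strand = strand, tss = as.integer(tss), immune = NA,
                      stringsAsFactors = FALSE))
  }
  gr <- tryCatch(rtracklayer::import(path, format = format),
                 error = function(e) .err_input(
                   "cannot read ", format, " '", path, "': ",
                   conditionMessage(e)))
  md <- S4Vectors::mcols(gr)
  types <- as.character(md$type)
  use <- gr[types %in% c("transcript", "mRNA")]
  if (length(use) == 0L) use <- gr[types == "gene"]
  if (length(use) == 0L) use <- gr
  md <- S4Vectors::mcols(use)
  gene_id <- as.character(md$gene_id)
  if (all(is.na(gene_id))) .err_input("no gene_id attribute in '", path, "'")
  symbol <- if ("gene_name" %in% names(md)) as.character(md$gene_name)
            else gene_id
  symbol[is.na(symbol)] <- gene_id[is.na(symbol)]
  df <- data.frame(gene_id = gene_id, symbol = symbol,
                   chrom = as.character(GenomicRanges::seqnames(use)),
                   strand = as.character(GenomicRanges::strand(use)),
                   start = GenomicRanges::start(use),
                   end = GenomicRanges::end(use),
                   stringsAsFactors = FALSE)
  if (any(!df$strand %in% c("+", "-"))) {
    .err_input("gene models need explicit +/- strands")
  }
  per_gene <- lapply(split(df, df$gene_id), function(d) {
    tss <- if (d$strand[1] == "+") min(d$start) - 1L else max(d$end) - 1L
    data.frame(gene_id = d$gene_id[1], symbol = d$symbol[1],
               chrom = d$chrom[1], strand = d$strand[1],
               tss = as.integer(tss), immune = NA,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_gene)
  out <- out[order(out$chrom, out$tss), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag immune genes in a gene-model table
#'
#' @param genes Gene models from [read_gene_models()].
#' @param immune_set Character vector of immune gene symbols and/or ids
#'   (from [immune_gene_set()] or [read_gene_list()]).
#' @return `genes` with the `immune` column set.
#' @export
set_immune_genes <- function(genes, immune_set) {
  genes$immune <- genes$symbol %in% immune_set |
    genes$gene_id %in% immune_set
  genes
}
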