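# Synthetic, ground-truthed scenario generation.  A scenario bundles every
# input the funnel consumes (genome FASTA, dbSNP-style VCF, bedGraph
# signal, GTF gene models, immune gene list or OBO+GAF, ortholog map,
# second genome) with planted items whose designed failure stage is known,
# plus a truth table of expected per-stage survivors computed by the
# package's independent brute-force oracles -- never by the pipeline under
# test.
#
# Layout (funnel scenarios): one locus of 13 kb per planted candidate.
# Within a locus, a non-immune "left" gene sits near the locus start, the
# immune "right" (target) gene has its TSS 11 kb in, and the candidate
# ncGAS motif sits 5 kb upstream of that TSS (or just downstream of it for
# candidates designed to fail the upstream-window stage).  Loci are wide
# enough that 10 kb windows and 200 bp spacing rules never reach across
# locus boundaries, so each candidate's fate is decided entirely by its
# own locus.  Background sequence may contain unplanned motif hits --
# realistic and harmless -- except inside a 200 bp exclusion zone around
# each planted candidate motif and inside second-genome upstream windows,
# where the background is rejection-resampled until clean.

.LOCUS_LEN <- 13000L
.MLOCUS_LEN <- 12000L
.FAIL_STAGES <- c("open_chromatin", "immune_neighbor", "upstream_10kb",
                  "evidence_ge2", "spacing_200", "conservation")

#' Ordered funnel stage labels
#'
#' @return Character vector of the eight stage labels in execution order.
#' @export
funnel_stages <- function() {
  c("scan", "snp_gof", "open_chromatin", "immune_neighbor",
    "upstream_10kb", "evidence_ge2", "spacing_200", "conservation")
}

#' Build a scenario configuration
#'
#' `kind = "funnel"` scenarios carry one planted candidate per requested
#' count, each designed either to survive the whole funnel (`n_pass`) or
#' to drop at exactly one stage (`n_fail_*`), plus decoy variants that
#' never become candidates.  `kind = "gof"` scenarios are lighter bundles
#' (genome + variants only) for exercising gain-of-function candidacy:
#' `n_pass` restorable SNPs and `n_decoy` non-restoring decoys.
#'
#' @param kind Scenario flavor.
#' @param genome_length Primary genome length in bp; an error is raised
#'   when the requested plantings do not fit.
#' @param n_pass Candidates designed to survive every stage.
#' @param n_fail_chromatin,n_fail_neighbor,n_fail_upstream Candidates
#'   designed to drop at the open-chromatin, immune-neighbor and
#'   upstream-window stages.
#' @param n_fail_evidence,n_fail_spacing,n_fail_conservation Candidates
#'   designed to drop at the evidence, spacing and conservation stages.
#' @param n_decoy Decoy variants (catalogued SNPs that do not complete any
#'   motif).
#' @param gc Background GC content (default 0.41, human-like).
#' @param chrom,chrom2 Sequence names of the two genomes.
#' @param gene_set_format Emit the immune set as a plain gene list or as a
#'   miniature OBO ontology plus GAF annotations.
#' @return Configuration list of class `gas_scenario_config`.
#' @export
scenario_config <- function(kind = c("funnel", "gof"),
                            genome_length = 120000L,
                            n_pass = 2L,
                            n_fail_chromatin = 1L,
                            n_fail_neighbor = 1L,
                            n_fail_upstream = 1L,
                            n_fail_evidence = 1L,
                            n_fail_spacing = 1L,
                            n_fail_conservation = 1L,
                            n_decoy = 4L,
                            gc = 0.41,
                            chrom = "chr1",
                            chrom2 = "m1",
                            gene_set_format = c("list", "obo")) {
  kind <- match.arg(kind)
  gene_set_format <- match.arg(gene_set_format)
  counts <- c(pass = n_pass, open_chromatin = n_fail_chromatin,
              immune_neighbor = n_fail_neighbor,
              upstream_10kb = n_fail_upstream,
              evidence_ge2 = n_fail_evidence, spacing_200 = n_fail_spacing,
              conservation = n_fail_conservation)
  if (any(counts < 0) || n_decoy < 0) .err_input("negative planting counts")
  if (gc <= 0 || gc >= 1) .err_input("gc must be in (0, 1)")
  cfg <- list(kind = kind, genome_length = as.integer(genome_length),
              counts = counts, n_decoy = as.integer(n_decoy), gc = gc,
              chrom = chrom, chrom2 = chrom2,
              gene_set_format = gene_set_format)
  n_cand <- sum(counts)
  if (kind == "funnel") {
    n_loci <- max(n_cand, 1L)
    if (1000L + n_loci * .LOCUS_LEN > genome_length) {
      .err_infeasible("genome_length ", genome_length, " too short for ",
                      n_loci, " loci of ", .LOCUS_LEN, " bp")
    }
  } else {
    n_motifs <- n_pass + ceiling(n_decoy / 2)
    if (1000L + n_motifs * 1200L > genome_length) {
      .err_infeasible("genome_length ", genome_length, " too short for ",
                      n_motifs, " planted motifs")
    }
  }
  structure(cfg, class = c("gas_scenario_config", "list"))
}

.random_dna <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# Random 9-mer matching `class_name`: canonical fixed bases, random free
# middles, and (for non-canonical classes) a random non-canonical base at
# the deviant offset.
.random_class_kmer <- function(class_name, classes = gas_classes()) {
  row <- classes[classes$name == class_name, ]
  k <- c("T", "T", "C", sample(c("A", "C", "G", "T"), 3, replace = TRUE),
         "G", "A", "A")
  if (!is.na(row$deviant_offset)) {
    allowed <- .pattern_sets(row$pattern)[[row$deviant_offset + 1L]]
    k[row$deviant_offset + 1L] <- sample(allowed, 1L)
  }
  k
}

# Re-randomize background bases until no unplanned motif hit overlaps an
# exclusion zone.  `zone` and `protected` are logical masks over the
# sequence; planted intervals are identified by their "start end" keys.
.scrub_background <- function(chars, zone, protected, planted_keys,
                              chrom, gc, max_iter = 80L) {
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  bases <- c("A", "C", "G", "T")
  for (iter in seq_len(max_iter)) {
    hits <- oracle_scan(paste(chars, collapse = ""), chrom)
    if (nrow(hits) == 0L) return(chars)
    in_zone <- vapply(seq_len(nrow(hits)), function(i) {
      any(zone[(hits$start[i] + 1L):hits$end[i]])
    }, logical(1))
    key <- paste(hits$start, hits$end)
    bad <- which(in_zone & !(key %in% planted_keys))
    if (length(bad) == 0L) return(chars)
    for (i in bad) {
      idx <- (hits$start[i] + 1L):hits$end[i]
      idx <- idx[!protected[idx]]
      if (length(idx) > 0L) {
        chars[idx] <- sample(bases, length(idx), replace = TRUE, prob = prob)
      }
    }
  }
  .err_infeasible("could not clear unplanned motif hits from exclusion ",
                  "zones; genome too short or zones too dense")
}

.freq_info <- function(k) {
  if (k <= 0L) return(".")
  paste0("FREQ=", paste0("Study", seq_len(k), ":0.9,0.1", collapse = "|"))
}

.write_vcf <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##INFO=<ID=FREQ,Number=.,Type=String,",
                      "Description=\"Frequency studies\">"),
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", sep = "\t")), con)
  if (nrow(df) > 0L) {
    df <- df[order(df$chrom, df$pos), , drop = FALSE]
    writeLines(paste(df$chrom, df$pos, df$rsid, df$ref, df$alt, ".", ".",
                     vapply(df$evidence_count, .freq_info, character(1)),
                     sep = "\t"), con)
  }
  invisible(path)
}

.write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

.write_gtf <- function(genes, path) {
  # genes: gene_id, symbol, chrom, strand, tss (0-based), body_len
  lines <- character(0)
  g <- genes[order(genes$chrom, genes$tss), , drop = FALSE]
  for (i in seq_len(nrow(g))) {
    if (g$strand[i] == "+") {
      start <- g$tss[i] + 1L
      end <- g$tss[i] + g$body_len[i]
    } else {
      end <- g$tss[i] + 1L
      start <- end - g$body_len[i] + 1L
    }
    attr_gene <- sprintf("gene_id \"%s\"; gene_name \"%s\";",
                         g$gene_id[i], g$symbol[i])
    attr_tx <- sprintf(
      "gene_id \"%s\"; transcript_id \"%s.t1\"; gene_name \"%s\";",
      g$gene_id[i], g$gene_id[i], g$symbol[i])
    lines <- c(lines,
               paste(g$chrom[i], "gasfunnel", "gene", start, end, ".",
                     g$strand[i], ".", attr_gene, sep = "\t"),
               paste(g$chrom[i], "gasfunnel", "transcript", start, end, ".",
                     g$strand[i], ".", attr_tx, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

.write_bedgraph <- function(df, path) {
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  writeLines(paste(df$chrom, df$start, df$end, df$value, sep = "\t"), path)
  invisible(path)
}

.write_obo_gaf <- function(immune_symbols, other_symbols, obo_path,
                           gaf_path) {
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0002376", "name: immune system process", "",
    "[Term]", "id: GO:0000101", "name: lymphocyte activation program",
    "is_a: GO:0002376 ! immune system process", "",
    "[Term]", "id: GO:0099999", "name: unrelated process", ""), obo_path)
  gaf_row <- function(sym, term) {
    paste("SYN", paste0("ID:", sym), sym, "", term, "REF:0001", "IEA", "",
          "P", sym, "", "protein", "taxon:9606", "20240101", "SYN", "", "",
          sep = "\t")
  }
  writeLines(c("!gaf-version: 2.2",
               vapply(immune_symbols, gaf_row, character(1),
                      term = "GO:0000101"),
               vapply(other_symbols, gaf_row, character(1),
                      term = "GO:0099999")), gaf_path)
  invisible(NULL)
}

# Brute-force funnel over in-memory scenario data; returns stage counts and
# per-stage surviving rsid sets.  Built exclusively on the oracle_*
# reference implementations.
.brute_truth_funnel <- function(seq1, chrom, variants, bedgraph, genes,
                                orth, seq2, chrom2, genes2, params) {
  hits <- oracle_scan(seq1, chrom)
  gof <- oracle_gof(seq1, variants, chrom)
  peaks <- oracle_threshold(bedgraph, params$min_signal)
  s3 <- oracle_window_join(gof, peaks, params$window)
  s4 <- oracle_neighbor_filter(s3, genes)
  s5 <- oracle_upstream_filter(s4, genes, params$span)
  s6 <- s5[s5$evidence_count >= params$min_subjects, , drop = FALSE]
  gas <- hits[hits$class == "GAS", , drop = FALSE]
  s7 <- oracle_spacing_filter(s6, gas, params$window, TRUE)
  keep8 <- vapply(seq_len(nrow(s7)), function(i) {
    g2ids <- orth$gene_id_2[orth$gene_id_1 == s7$nearest_gene[i]]
    for (gid in g2ids) {
      g2 <- genes2[genes2$gene_id == gid, , drop = FALSE]
      for (j in seq_len(nrow(g2))) {
        win <- .upstream_window(g2$tss[j], g2$strand[j], params$span)
        s0 <- max(win$start, 0L)
        e0 <- min(win$end, nchar(seq2))
        if (e0 - s0 < 9L) next
        slice <- substr(seq2, s0 + 1L, e0)
        wh <- oracle_scan(slice, chrom2)
        if (any(wh$class == s7$class[i])) return(TRUE)
      }
    }
    FALSE
  }, logical(1))
  s8 <- s7[keep8, , drop = FALSE]
  survivors <- list(snp_gof = sort(unique(gof$rsid)),
                    open_chromatin = sort(unique(s3$rsid)),
                    immune_neighbor = sort(unique(s4$rsid)),
                    upstream_10kb = sort(unique(s5$rsid)),
                    evidence_ge2 = sort(unique(s6$rsid)),
                    spacing_200 = sort(unique(s7$rsid)),
                    conservation = sort(unique(s8$rsid)))
  counts <- c(scan = nrow(hits),
              vapply(survivors, length, integer(1)))
  list(stage_counts = counts, survivors = survivors)
}

#' Generate a synthetic scenario with ground truth
#'
#' Deterministically (given `seed`) emits the full input bundle for a
#' configuration built by [scenario_config()], plus a truth table of
#' expected per-stage survivors computed with the brute-force oracle
#' implementations.  The generator asserts that the brute-force truth
#' matches the designed fate of every planted item, so a returned scenario
#' is internally consistent by construction.
#'
#' @param config Configuration from [scenario_config()].
#' @param seed Integer seed; same config + seed gives a byte-identical
#'   bundle.
#' @param dir Output directory (created; must not already contain a
#'   scenario).
#' @return List with `dir`, `paths` (named file paths), `truth`
#'   (`stage_counts`, `survivors`), `planted` (data frame of planted
#'   variants with their designed fate) and `config`.
#' @export
generate_scenario <- function(config, seed,
                              dir = tempfile("gas_scenario_")) {
  if (!inherits(config, "gas_scenario_config")) {
    .err_input("config must come from scenario_config()")
  }
  set.seed(seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (config$kind == "gof") {
    return(.generate_gof_scenario(config, dir))
  }
  .generate_funnel_scenario(config, dir)
}

.generate_gof_scenario <- function(config, dir) {
  L <- config$genome_length
  chrom <- config$chrom
  n_planted <- unname(config$counts["pass"])
  n_decoy <- config$n_decoy
  n_motif_decoys <- ceiling(n_decoy / 2)
  n_motifs <- n_planted + n_motif_decoys
  chars <- .random_dna(L, config$gc)
  zone <- logical(L)
  protected <- logical(L)
  planted_keys <- character(0)
  classes <- gas_classes()
  nc <- classes[classes$name != "GAS", , drop = FALSE]
  motifs <- list()
  for (i in seq_len(n_motifs)) {
    pm <- 500L + (i - 1L) * 1200L + 300L
    cls <- nc[sample(nrow(nc), 1L), ]
    k <- .random_class_kmer(cls$name)
    chars[(pm + 1L):(pm + 9L)] <- k
    protected[(pm + 1L):(pm + 9L)] <- TRUE
    zone[max(1L, pm - 249L):min(L, pm + 260L)] <- TRUE
    planted_keys <- c(planted_keys, paste(pm, pm + 9L))
    motifs[[i]] <- list(pm = pm, class = cls$name,
                        dev_off = cls$deviant_offset,
                        dev_base = k[cls$deviant_offset + 1L],
                        restore = cls$restore_base)
  }
  chars <- .scrub_background(chars, zone, protected, planted_keys, chrom,
                             config$gc)
  seq1 <- paste(chars, collapse = "")
  rows <- list()
  for (i in seq_len(n_planted)) {
    m <- motifs[[i]]
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = chrom, pos = m$pm + m$dev_off + 1L,
      rsid = sprintf("rs%06d", 100000L + i), ref = m$dev_base,
      alt = m$restore, evidence_count = 2L, type = "pass",
      stringsAsFactors = FALSE)
  }
  rows <- c(rows, .make_decoys(chars, zone, motifs, n_planted,
                               n_motif_decoys, n_decoy, chrom, L))
  planted <- do.call(rbind, rows)
  paths <- list(genome = file.path(dir, "genome.fa"),
                variants = file.path(dir, "variants.vcf"),
                truth_json = file.path(dir, "truth.json"),
                planted_tsv = file.path(dir, "planted.tsv"))
  .write_fasta(stats::setNames(seq1, chrom), paths$genome)
  .write_vcf(planted, paths$variants)
  vdf <- planted
  vdf$is_snv <- TRUE
  gof <- oracle_gof(seq1, vdf, chrom)
  expected <- sort(planted$rsid[planted$type == "pass"])
  stopifnot(identical(sort(unique(gof$rsid)), expected))
  hits <- oracle_scan(seq1, chrom)
  truth <- list(stage_counts = c(scan = nrow(hits),
                                 snp_gof = length(expected)),
                survivors = list(snp_gof = expected))
  jsonlite::write_json(truth, paths$truth_json, auto_unbox = FALSE,
                       pretty = TRUE, digits = NA)
  .write_tsv(planted, paths$planted_tsv)
  list(dir = dir, paths = paths, truth = truth, planted = planted,
       config = config)
}

.make_decoys <- function(chars, zone, motifs, n_first_decoy_motif,
                         n_motif_decoys, n_decoy, chrom, L) {
  seq1 <- paste(chars, collapse = "")
  bases <- c("A", "C", "G", "T")
  rows <- list()
  made <- 0L
  # decoys sitting on a planted motif's deviant position, non-restoring alt
  for (j in seq_len(n_motif_decoys)) {
    m <- motifs[[n_first_decoy_motif + j]]
    opts <- setdiff(bases, c(m$dev_base, m$restore))
    alt <- NULL
    for (o in sample(opts)) {
      trial <- data.frame(chrom = chrom, pos = m$pm + m$dev_off + 1L,
                          rsid = "trial", ref = m$dev_base, alt = o,
                          evidence_count = 2L, is_snv = TRUE,
                          stringsAsFactors = FALSE)
      if (nrow(oracle_gof(seq1, trial, chrom)) == 0L) {
        alt <- o
        break
      }
    }
    if (is.null(alt)) next
    made <- made + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = chrom, pos = m$pm + m$dev_off + 1L,
      rsid = sprintf("rs%06d", 900000L + made), ref = m$dev_base,
      alt = alt, evidence_count = 2L, type = "decoy",
      stringsAsFactors = FALSE)
  }
  # decoys at random background positions
  while (made < n_decoy) {
    for (try in seq_len(50L)) {
      p0 <- sample(seq(1000L, L - 1000L), 1L)
      if (zone[p0 + 1L]) next
      ref <- chars[p0 + 1L]
      alt <- sample(setdiff(bases, ref), 1L)
      trial <- data.frame(chrom = chrom, pos = p0 + 1L, rsid = "trial",
                          ref = ref, alt = alt, evidence_count = 2L,
                          is_snv = TRUE, stringsAsFactors = FALSE)
      if (nrow(oracle_gof(seq1, trial, chrom)) == 0L) break
    }
    made <- made + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = chrom, pos = p0 + 1L,
      rsid = sprintf("rs%06d", 900000L + made), ref = ref, alt = alt,
      evidence_count = 2L, type = "decoy", stringsAsFactors = FALSE)
  }
  rows
}

.generate_funnel_scenario <- function(config, dir) {
  L <- config$genome_length
  chrom <- config$chrom
  chrom2 <- config$chrom2
  counts <- config$counts
  types <- rep(names(counts), counts)
  types[types == "pass"] <- "pass"
  if (length(types) > 0L) types <- sample(types)
  n_cand <- length(types)
  n_loci <- max(n_cand, 1L)
  L2 <- 1000L + n_loci * .MLOCUS_LEN
  classes <- gas_classes()
  nc <- classes[classes$name != "GAS", , drop = FALSE]

  chars <- .random_dna(L, config$gc)
  chars2 <- .random_dna(L2, config$gc)
  zone <- logical(L)
  protected <- logical(L)
  keys <- character(0)
  zone2 <- logical(L2)
  protected2 <- logical(L2)
  keys2 <- character(0)

  genes <- list()
  genes2 <- list()
  peaks <- list()
  orth <- list()
  cand <- list()

  for (i in seq_len(n_loci)) {
    s <- 500L + (i - 1L) * .LOCUS_LEN
    type <- if (i <= n_cand) types[i] else "filler"
    gidL <- sprintf("GENE%03dL", i)
    gidR <- sprintf("GENE%03dR", i)
    genes[[length(genes) + 1L]] <- data.frame(
      gene_id = gidL, symbol = sprintf("SYML%03d", i), chrom = chrom,
      strand = "-", tss = s + 500L, body_len = 300L,
      immune = FALSE, stringsAsFactors = FALSE)
    genes[[length(genes) + 1L]] <- data.frame(
      gene_id = gidR, symbol = sprintf("SYMR%03d", i), chrom = chrom,
      strand = "+", tss = s + 11000L, body_len = 1500L,
      immune = type != "immune_neighbor", stringsAsFactors = FALSE)
    # second genome: one orthologous gene per locus
    ms <- 500L + (i - 1L) * .MLOCUS_LEN
    gidM <- sprintf("MGENE%03d", i)
    genes2[[length(genes2) + 1L]] <- data.frame(
      gene_id = gidM, symbol = sprintf("MSYM%03d", i), chrom = chrom2,
      strand = "+", tss = ms + 10500L, body_len = 800L,
      immune = TRUE, stringsAsFactors = FALSE)
    orth[[length(orth) + 1L]] <- data.frame(
      gene_id_1 = gidR, gene_id_2 = gidM, stringsAsFactors = FALSE)
    zone2[(ms + 500L + 1L):(ms + 10500L)] <- TRUE
    if (type == "filler") next

    cls <- nc[sample(nrow(nc), 1L), ]
    k <- .random_class_kmer(cls$name)
    pm <- if (type == "upstream_10kb") s + 11800L else s + 6000L
    chars[(pm + 1L):(pm + 9L)] <- k
    protected[(pm + 1L):(pm + 9L)] <- TRUE
    zone[max(1L, pm - 249L):min(L, pm + 260L)] <- TRUE
    keys <- c(keys, paste(pm, pm + 9L))
    if (type == "spacing_200") {
      gk <- .random_class_kmer("GAS")
      pg <- pm + 109L
      chars[(pg + 1L):(pg + 9L)] <- gk
      protected[(pg + 1L):(pg + 9L)] <- TRUE
      keys <- c(keys, paste(pg, pg + 9L))
    }
    peaks[[length(peaks) + 1L]] <- data.frame(
      chrom = chrom, start = pm - 50L, end = pm + 59L,
      value = if (type == "open_chromatin") 5 else 30,
      stringsAsFactors = FALSE)
    if (type != "conservation") {
      mk <- .random_class_kmer(cls$name)
      pmm <- ms + 5000L
      chars2[(pmm + 1L):(pmm + 9L)] <- mk
      protected2[(pmm + 1L):(pmm + 9L)] <- TRUE
      keys2 <- c(keys2, paste(pmm, pmm + 9L))
    }
    cand[[length(cand) + 1L]] <- data.frame(
      chrom = chrom, pos = pm + cls$deviant_offset + 1L,
      rsid = sprintf("rs%06d", 100000L + i),
      ref = k[cls$deviant_offset + 1L], alt = cls$restore_base,
      evidence_count = if (type == "evidence_ge2") 1L else 2L,
      type = type, class = cls$name, motif_start = pm,
      stringsAsFactors = FALSE)
  }

  chars <- .scrub_background(chars, zone, protected, keys, chrom, config$gc)
  chars2 <- .scrub_background(chars2, zone2, protected2, keys2, chrom2,
                              config$gc)
  seq1 <- paste(chars, collapse = "")
  seq2 <- paste(chars2, collapse = "")
  genes <- do.call(rbind, genes)
  genes2 <- do.call(rbind, genes2)
  orth <- do.call(rbind, orth)

  # motif-position decoys plus random-background decoys, verified inert
  motifs_for_decoys <- lapply(cand, function(d) {
    cls <- classes[classes$name == d$class, ]
    list(pm = d$motif_start, class = d$class,
         dev_off = cls$deviant_offset, dev_base = d$ref,
         restore = cls$restore_base)
  })
  n_motif_decoys <- min(config$n_decoy, length(motifs_for_decoys))
  decoys <- .make_decoys(chars, zone,
                         c(vector("list", 0L), motifs_for_decoys),
                         0L, n_motif_decoys, config$n_decoy, chrom, L)
  planted <- do.call(rbind, c(
    lapply(cand, function(d) d[, c("chrom", "pos", "rsid", "ref", "alt",
                                   "evidence_count", "type")]),
    decoys,
    list(data.frame(chrom = character(), pos = integer(),
                    rsid = character(), ref = character(),
                    alt = character(), evidence_count = integer(),
                    type = character(), stringsAsFactors = FALSE))))

  # background signal tiles (always below threshold) around the peaks
  peak_df <- do.call(rbind, c(peaks, list(data.frame(
    chrom = character(), start = integer(), end = integer(),
    value = numeric(), stringsAsFactors = FALSE))))
  bg <- .background_signal(L, chrom, peak_df)
  bedgraph <- rbind(peak_df, bg)
  bedgraph <- bedgraph[order(bedgraph$chrom, bedgraph$start), , drop = FALSE]

  paths <- list(genome = file.path(dir, "genome.fa"),
                variants = file.path(dir, "variants.vcf"),
                signal = file.path(dir, "signal.bedGraph"),
                genes = file.path(dir, "genes.gtf"),
                orthologs = file.path(dir, "orthologs.tsv"),
                genome2 = file.path(dir, "genome2.fa"),
                genes2 = file.path(dir, "genes2.gtf"),
                truth_json = file.path(dir, "truth.json"),
                planted_tsv = file.path(dir, "planted.tsv"))
  immune_symbols <- genes$symbol[genes$immune]
  other_symbols <- genes$symbol[!genes$immune]
  if (config$gene_set_format == "list") {
    paths$gene_list <- file.path(dir, "immune_genes.txt")
    writeLines(immune_symbols, paths$gene_list)
  } else {
    paths$obo <- file.path(dir, "ontology.obo")
    paths$gaf <- file.path(dir, "annotations.gaf")
    .write_obo_gaf(immune_symbols, other_symbols, paths$obo, paths$gaf)
  }
  .write_fasta(stats::setNames(seq1, chrom), paths$genome)
  .write_fasta(stats::setNames(seq2, chrom2), paths$genome2)
  .write_vcf(planted, paths$variants)
  .write_bedgraph(bedgraph, paths$signal)
  .write_gtf(genes, paths$genes)
  .write_gtf(genes2, paths$genes2)
  .write_tsv(orth, paths$orthologs)
  .write_tsv(planted, paths$planted_tsv)

  params <- list(window = 200L, span = 10000L, min_subjects = 2L,
                 min_signal = 20)
  vdf <- planted
  vdf$is_snv <- rep(TRUE, nrow(planted))
  truth <- .brute_truth_funnel(seq1, chrom, vdf, bedgraph, genes, orth,
                               seq2, chrom2, genes2, params)
  .assert_designed_fates(truth, planted)
  jsonlite::write_json(truth, paths$truth_json, auto_unbox = FALSE,
                       pretty = TRUE, digits = NA)
  list(dir = dir, paths = paths, truth = truth, planted = planted,
       config = config)
}

# Tiling background signal, never reaching the threshold, leaving the
# planted peak intervals untouched.
.background_signal <- function(L, chrom, peak_df) {
  breaks <- sort(unique(c(0L, peak_df$start, peak_df$end, L)))
  rows <- list()
  for (i in seq_len(length(breaks) - 1L)) {
    a <- breaks[i]
    b <- breaks[i + 1L]
    if (any(peak_df$start <= a & peak_df$end >= b)) next   # inside a peak
    tile_starts <- seq(a, b - 1L, by = 1000L)
    tile_ends <- pmin(tile_starts + 1000L, b)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = chrom, start = tile_starts, end = tile_ends,
      value = round(stats::runif(length(tile_starts), 0, 8), 1),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(data.frame(
    chrom = character(), start = integer(), end = integer(),
    value = numeric(), stringsAsFactors = FALSE))))
}

# Every planted candidate must drop exactly at its designed stage (or
# survive throughout); decoys must never appear.  A violation is a
# generator bug, caught here rather than in downstream test noise.
.assert_designed_fates <- function(truth, planted) {
  is_cand <- planted$type != "decoy"
  stage_of <- c(open_chromatin = 3L, immune_neighbor = 4L,
                upstream_10kb = 5L, evidence_ge2 = 6L, spacing_200 = 7L,
                conservation = 8L, pass = 99L)
  fail_at <- stage_of[planted$type]
  labels <- funnel_stages()
  for (k in 2:8) {
    expected <- sort(planted$rsid[is_cand & fail_at > k])
    got <- truth$survivors[[labels[k]]]
    if (!identical(expected, got)) {
      stop("scenario generation self-check failed at stage ", labels[k],
           ": designed ", length(expected), " survivors, brute force ",
           "found ", length(got))
    }
  }
  invisible(TRUE)
}
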