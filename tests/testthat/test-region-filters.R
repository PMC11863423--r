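write_bedgraph <- function(df) {
  path <- tempfile(fileext = ".bedGraph")
  writeLines(paste(df$chrom, df$start, df$end, df$value, sep = "\t"), path)
  path
}

test_that("signal thresholding keeps >= threshold and merges bookended runs", {
  bg <- data.frame(chrom = "chr1",
                   start = c(0L, 10L, 40L, 60L),
                   end = c(10L, 20L, 50L, 70L),
                   value = c(25, 30, 20, 19.9))
  peaks <- threshold_signal(write_bedgraph(bg))
  # [0,10) and [10,20) both pass and merge; 20 kept, 19.9 dropped
  expect_equal(peaks$start, c(0L, 40L))
  expect_equal(peaks$end, c(20L, 50L))
  # strict comparator reproduces awk-style behavior at the boundary
  strict <- threshold_signal(write_bedgraph(bg), comparator = `>`)
  expect_equal(strict$start, 0L)   # [0,20) merged; the value-20 run fails >
  expect_equal(strict$end, 20L)
  # per-base oracle agrees on random tracks
  set.seed(8)
  for (rep in 1:5) {
    r <- random_intervals(200, 20000, c("chr1", "chr2"), max_len = 100L)
    r <- r[order(r$chrom, r$start), ]
    # avoid overlapping rows within a chromosome (bedGraph contract)
    keepr <- unlist(lapply(split(seq_len(nrow(r)), r$chrom), function(i) {
      i[c(TRUE, diff(r$start[i]) >= 100L)]
    }))
    r <- r[sort(keepr), ]
    r$value <- round(runif(nrow(r), 0, 40), 1)
    got <- threshold_signal(write_bedgraph(r))
    want <- oracle_threshold(r)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
  bad <- tempfile()
  writeLines("chr1\t0\t10\tnotnum", bad)
  expect_error(threshold_signal(bad), class = "gasfunnel_bad_input")
})

test_that("window join keeps items within the gap bound", {
  items <- data.frame(chrom = "chr1", start = 1000L, end = 1009L,
                      stringsAsFactors = FALSE)
  near <- data.frame(chrom = "chr1", start = 1150L, end = 1200L)
  far <- data.frame(chrom = "chr1", start = 1300L, end = 1350L)
  expect_equal(nrow(window_join(items, near, 200L)), 1L)  # gap 141
  expect_equal(nrow(window_join(items, far, 200L)), 0L)   # gap 291
  # boundary: gap exactly w is kept
  exact <- data.frame(chrom = "chr1", start = 1209L, end = 1250L)
  expect_equal(nrow(window_join(items, exact, 200L)), 1L)
  expect_equal(nrow(window_join(items, exact, 199L)), 0L)
  # other chromosome never joins
  other <- data.frame(chrom = "chr2", start = 1000L, end = 1010L)
  expect_equal(nrow(window_join(items, other, 200L)), 0L)
})

test_that("window join equals the quadratic oracle on random input", {
  set.seed(5)
  items <- random_intervals(800, 50000, c("chr1", "chr2"), 50L)
  items$rsid <- sprintf("i%04d", seq_len(nrow(items)))
  regions <- random_intervals(300, 50000, c("chr1", "chr2"), 400L)
  for (w in c(0L, 50L, 200L)) {
    expect_equal(window_join(items, regions, w)$rsid,
                 oracle_window_join(items, regions, w)$rsid)
  }
})

test_that("flanking-gene immunity decides the neighborhood filter", {
  genes <- data.frame(
    gene_id = c("gL", "gR"), symbol = c("gL", "gR"), chrom = "chr1",
    strand = c("+", "+"), tss = c(45000L, 60000L),
    immune = c(TRUE, FALSE), stringsAsFactors = FALSE)
  cand <- data.frame(rsid = "r1", chrom = "chr1", pos = 50001L,
                     stringsAsFactors = FALSE)
  kept <- neighbor_gene_filter(cand, genes)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$nearest_gene, "gL")
  expect_equal(kept$gene_distance, 5000L)
  # both flanking genes non-immune: dropped even if an immune gene lies
  # further out on the same side
  genes2 <- rbind(genes, data.frame(gene_id = "gFar", symbol = "gFar",
                                    chrom = "chr1", strand = "+",
                                    tss = 10000L, immune = TRUE))
  genes2$immune[genes2$gene_id == "gL"] <- FALSE
  expect_equal(nrow(neighbor_gene_filter(cand, genes2)), 0L)
  # chromosome without genes drops its candidates with a message
  c2 <- data.frame(rsid = "r2", chrom = "chrZ", pos = 5L)
  expect_message(res <- neighbor_gene_filter(c2, genes), "no genes")
  expect_equal(nrow(res), 0L)
})

test_that("neighborhood filter equals the quadratic oracle on random input", {
  set.seed(9)
  genes <- data.frame(
    gene_id = sprintf("g%03d", 1:50), symbol = sprintf("g%03d", 1:50),
    chrom = sample(c("chr1", "chr2"), 50, replace = TRUE),
    strand = sample(c("+", "-"), 50, replace = TRUE),
    tss = sample.int(200000, 50), immune = runif(50) < 0.4,
    stringsAsFactors = FALSE)
  cands <- data.frame(rsid = sprintf("r%04d", 1:1000),
                      chrom = sample(c("chr1", "chr2"), 1000,
                                     replace = TRUE),
                      pos = sample.int(200000, 1000, replace = TRUE),
                      stringsAsFactors = FALSE)
  got <- neighbor_gene_filter(cands, genes)
  want <- oracle_neighbor_filter(cands, genes)
  expect_equal(got$rsid, want$rsid)
  expect_equal(got$nearest_gene, want$nearest_gene)
  expect_equal(got$gene_distance, want$gene_distance)
})

test_that("upstream windows are strand aware and exclude the TSS itself", {
  genes <- data.frame(gene_id = "g1", symbol = "g1", chrom = "chr1",
                      strand = "+", tss = 20000L, immune = TRUE,
                      stringsAsFactors = FALSE)
  mk <- function(pos) data.frame(rsid = "r", chrom = "chr1", pos = pos,
                                 stringsAsFactors = FALSE)
  kept <- upstream_tss_filter(mk(15001L), genes)   # pos0 15000
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$distance_to_tss, 5000L)
  expect_equal(kept$nearest_gene, "g1")
  expect_equal(nrow(upstream_tss_filter(mk(20501L), genes)), 0L) # downstream
  expect_equal(nrow(upstream_tss_filter(mk(20001L), genes)), 0L) # at TSS
  genes$strand <- "-"
  expect_equal(nrow(upstream_tss_filter(mk(25001L), genes)), 1L)
  expect_equal(nrow(upstream_tss_filter(mk(15001L), genes)), 0L)
  expect_error(upstream_tss_filter(mk(1L), genes, span = 0L), "positive")
})

test_that("upstream filtering is invariant under strand reflection", {
  set.seed(15)
  L <- 100000L
  genes <- data.frame(
    gene_id = sprintf("g%02d", 1:40), symbol = sprintf("g%02d", 1:40),
    chrom = "chr1", strand = sample(c("+", "-"), 40, replace = TRUE),
    tss = sample(seq(12000L, L - 12000L), 40), immune = TRUE,
    stringsAsFactors = FALSE)
  cands <- data.frame(rsid = sprintf("r%03d", 1:500), chrom = "chr1",
                      pos = sample.int(L, 500), stringsAsFactors = FALSE)
  kept <- upstream_tss_filter(cands, genes)
  # mirror the coordinate system and flip strands
  mgenes <- genes
  mgenes$tss <- L - 1L - genes$tss
  mgenes$strand <- ifelse(genes$strand == "+", "-", "+")
  mcands <- cands
  mcands$pos <- L - cands$pos + 1L
  mkept <- upstream_tss_filter(mcands, mgenes)
  expect_equal(sort(kept$rsid), sort(mkept$rsid))
  m <- merge(kept[, c("rsid", "distance_to_tss")],
             mkept[, c("rsid", "distance_to_tss")], by = "rsid")
  expect_equal(m$distance_to_tss.x, m$distance_to_tss.y)
})

test_that("spacing removes candidates near canonical motifs and clusters", {
  gas <- data.frame(chrom = "chr1", start = 5000L, end = 5009L,
                    class = "GAS", stringsAsFactors = FALSE)
  mk <- function(starts) {
    data.frame(rsid = sprintf("r%d", seq_along(starts)), chrom = "chr1",
               pos = starts + 3L, motif_start = starts,
               motif_end = starts + 9L, stringsAsFactors = FALSE)
  }
  expect_equal(nrow(spacing_filter(mk(5100L), gas)), 0L)  # gap 91
  expect_equal(nrow(spacing_filter(mk(5300L), gas)), 1L)  # gap 291
  # two candidates 50 bp apart with no canonical hit nearby: both removed
  pair <- mk(c(20000L, 20050L))
  expect_equal(nrow(spacing_filter(pair, gas, drop_clustered = TRUE)), 0L)
  expect_equal(nrow(spacing_filter(pair, gas, drop_clustered = FALSE)), 2L)
  # candidates sharing one motif interval are not a cluster by themselves
  same <- mk(c(20000L, 20000L))
  expect_equal(nrow(spacing_filter(same, gas)), 2L)
})

test_that("spacing filter equals the quadratic oracle on random input", {
  set.seed(17)
  starts <- sample.int(100000, 400) - 1L
  cands <- data.frame(rsid = sprintf("r%04d", seq_along(starts)),
                      chrom = sample(c("chr1", "chr2"), 400, TRUE),
                      pos = starts + 3L, motif_start = starts,
                      motif_end = starts + 9L, stringsAsFactors = FALSE)
  g <- sample.int(100000, 150) - 1L
  gas <- data.frame(chrom = sample(c("chr1", "chr2"), 150, TRUE),
                    start = g, end = g + 9L, class = "GAS",
                    stringsAsFactors = FALSE)
  for (dc in c(TRUE, FALSE)) {
    expect_equal(spacing_filter(cands, gas, 200L, dc)$rsid,
                 oracle_spacing_filter(cands, gas, 200L, dc)$rsid)
  }
})

test_that("gene models from GTF use the most 5' transcript start per gene", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1", "src", "gene", 1000, 3000, ".", "+", ".",
          "gene_id \"gA\"; gene_name \"A\";", sep = "\t"),
    paste("chr1", "src", "transcript", 1200, 3000, ".", "+", ".",
          "gene_id \"gA\"; transcript_id \"gA.1\"; gene_name \"A\";",
          sep = "\t"),
    paste("chr1", "src", "transcript", 1000, 2500, ".", "+", ".",
          "gene_id \"gA\"; transcript_id \"gA.2\"; gene_name \"A\";",
          sep = "\t"),
    paste("chr1", "src", "gene", 5000, 8000, ".", "-", ".",
          "gene_id \"gB\"; gene_name \"B\";", sep = "\t"),
    paste("chr1", "src", "transcript", 5000, 7000, ".", "-", ".",
          "gene_id \"gB\"; transcript_id \"gB.1\"; gene_name \"B\";",
          sep = "\t"),
    paste("chr1", "src", "transcript", 5500, 8000, ".", "-", ".",
          "gene_id \"gB\"; transcript_id \"gB.2\"; gene_name \"B\";",
          sep = "\t")), gtf)
  g <- read_gene_models(gtf)
  expect_equal(g$tss[g$gene_id == "gA"], 999L)    # min start, 0-based
  expect_equal(g$tss[g$gene_id == "gB"], 7999L)   # max end, 0-based
  g <- set_immune_genes(g, c("A"))
  expect_equal(g$immune[order(g$gene_id)], c(TRUE, FALSE))
})

test_that("gene models from a TSS BED honor strand", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t101\tgP\t0\t+", "chr1\t500\t501\tgM\t0\t-"),
             bed)
  g <- read_gene_models(bed)
  expect_equal(g$tss[g$gene_id == "gP"], 100L)
  expect_equal(g$tss[g$gene_id == "gM"], 500L)
})
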