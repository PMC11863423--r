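test_that("read_vcf expands alleles, flags non-SNVs and counts evidence", {
  rows <- data.frame(
    chrom = "chr1", pos = c(101L, 205L, 310L, 400L),
    rsid = c("rs1", "rs2", "rs3", "rs4"),
    ref = c("G", "G", "GA", "T"),
    alt = c("T", "T,C", "G", "A"),
    info = c(freq_info(2), freq_info(1), ".", freq_info(3)),
    stringsAsFactors = FALSE)
  v <- read_vcf(tmp_vcf(rows))
  expect_equal(nrow(v), 5L)   # rs2 expands to two rows
  expect_equal(v$alt[v$rsid == "rs2"], c("T", "C"))
  expect_equal(v$evidence_count[v$rsid == "rs1"][1], 2L)
  expect_equal(v$evidence_count[v$rsid == "rs4"][1], 3L)
  expect_false(v$is_snv[v$rsid == "rs3"])   # indel excluded from candidacy
  expect_equal(attr(v, "n_non_snv"), 1L)
})

test_that("read_vcf reports malformed lines by number and applies chrom aliases", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2", "#CHROM\tPOS\tID\tREF\tALT",
               "chr1\t100\trs1\tG\tT", "broken line"), path)
  expect_error(read_vcf(path), "line 4")
  writeLines(c("##fileformat=VCFv4.2",
               "chr1\tnotanumber\trs1\tG\tT\t.\t.\t."), path)
  expect_error(read_vcf(path), "line 2")

  rows <- data.frame(chrom = "1", pos = 100L, rsid = "rs1", ref = "G",
                     alt = "T", stringsAsFactors = FALSE)
  v <- read_vcf(tmp_vcf(rows), chrom_map = c("1" = "chr1"))
  expect_equal(v$chrom, "chr1")
})

test_that("read_vcf fixed fields agree with vcfR on a round-trip fixture", {
  skip_if_not_installed("vcfR")
  rows <- data.frame(chrom = "chr1", pos = c(50L, 90L),
                     rsid = c("rs10", "rs11"), ref = c("A", "C"),
                     alt = c("G", "T"), info = c(freq_info(2), "."),
                     stringsAsFactors = FALSE)
  path <- tmp_vcf(rows)
  v <- read_vcf(path)
  vr <- vcfR::read.vcfR(path, verbose = FALSE)
  expect_equal(v$pos, as.integer(vr@fix[, "POS"]))
  expect_equal(v$ref, unname(vr@fix[, "REF"]))
  expect_equal(v$alt, unname(vr@fix[, "ALT"]))
})

test_that("gain-of-function candidacy requires the exact restoring allele", {
  set.seed(5)
  s <- plant(rand_dna(300), 100L, strsplit("GTCAAAGAA", "")[[1]])
  hits <- scan_sequence(s, "chr1")
  t1 <- hits[hits$start == 100L & hits$class == "T1", ]
  expect_equal(nrow(t1), 1L)

  mkvar <- function(alt, ref = "G", pos = 101L) {
    data.frame(chrom = "chr1", pos = pos, rsid = "rsX", ref = ref,
               alt = alt, evidence_count = 2L, is_snv = TRUE,
               stringsAsFactors = FALSE)
  }
  cand <- candidate_gof(hits, mkvar("T"))
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$completed_kmer, "TTCAAAGAA")
  expect_equal(cand$motif_start, 100L)
  expect_true(iupac_matches("TTCNNNGAA", cand$completed_kmer))

  # the wrong alternate allele does not restore
  expect_equal(nrow(candidate_gof(hits, mkvar("C"))), 0L)
  # a REF/genome mismatch is skipped with a warning
  expect_warning(res <- candidate_gof(hits, mkvar("T", ref = "A")),
                 "build mismatch")
  expect_equal(nrow(res), 0L)
  # non-SNV records never participate
  v <- mkvar("T")
  v$is_snv <- FALSE
  expect_equal(nrow(candidate_gof(hits, v)), 0L)
})

test_that("candidate sets equal the apply-and-rescan oracle on random input", {
  set.seed(13)
  for (rep in 1:5) {
    s <- rand_dna(5000)
    pos <- sort(sample.int(4990, 120))
    refs <- substring(s, pos, pos)
    # mix of matching and deliberately mismatching REFs, random alts
    refs[sample.int(120, 10)] <- "X"
    v <- data.frame(chrom = "chr1", pos = pos,
                    rsid = sprintf("rs%04d", seq_along(pos)), ref = refs,
                    alt = vapply(refs, function(r) {
                      sample(setdiff(c("A", "C", "G", "T"), r), 1)
                    }, character(1)),
                    evidence_count = 2L, stringsAsFactors = FALSE)
    v$is_snv <- v$ref %in% c("A", "C", "G", "T")
    hits <- scan_sequence(s, "chr1")
    got <- suppressWarnings(candidate_gof(hits, v))
    want <- oracle_gof(s, v, "chr1")
    expect_equal(got[, c("rsid", "pos", "motif_start", "motif_end")],
                 want[, c("rsid", "pos", "motif_start", "motif_end")])
    if (nrow(got) > 0) expect_equal(got$class, want$class)
  }
})

test_that("loss-of-function calls break the motif and spare free positions", {
  set.seed(3)
  s <- plant(rand_dna(200), 50L, strsplit("TTCAAAGAA", "")[[1]])
  hits <- scan_sequence(s, "chr1")
  gas <- hits[hits$class == "GAS" & hits$start == 50L, ]
  expect_equal(nrow(gas), 1L)
  mkvar <- function(pos, ref, alt) {
    data.frame(chrom = "chr1", pos = pos, rsid = "rsL", ref = ref,
               alt = alt, evidence_count = 2L, is_snv = TRUE,
               stringsAsFactors = FALSE)
  }
  # fixed position C -> A destroys the motif
  lof <- candidate_lof(gas, mkvar(53L, "C", "A"))
  expect_equal(nrow(lof), 1L)
  expect_equal(lof$broken_kmer, "TTAAAAGAA")
  expect_false(iupac_matches("TTCNNNGAA", lof$broken_kmer))
  # a free middle position can never be loss-of-function
  expect_equal(nrow(candidate_lof(gas, mkvar(55L, "A", "G"))), 0L)

  # property: every reported LOF alt really destroys the match; every
  # fixed-offset non-reference alt is reported
  n_lof <- 0L
  for (off in 0:8) {
    ref <- substr(s, 50L + off + 1L, 50L + off + 1L)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      res <- candidate_lof(gas, mkvar(50L + off + 1L, ref, alt))
      mutated <- s
      substr(mutated, 50L + off + 1L, 50L + off + 1L) <- alt
      still_gas <- iupac_matches("TTCNNNGAA", substr(mutated, 51L, 59L))
      expect_equal(nrow(res) == 1L, !still_gas)
      n_lof <- n_lof + nrow(res)
    }
  }
  expect_equal(n_lof, 18L)
})

test_that("the evidence filter is a monotone threshold on study counts", {
  cands <- data.frame(rsid = c("a", "b", "c"),
                      evidence_count = c(2L, 1L, 5L),
                      stringsAsFactors = FALSE)
  expect_equal(evidence_filter(cands, 2L)$rsid, c("a", "c"))
  expect_equal(evidence_filter(cands, 0L), cands)   # vacuous threshold
  expect_equal(nrow(evidence_filter(cands, 9999L)), 0L)
  # raising the threshold never adds candidates
  prev <- cands
  for (t in 0:6) {
    cur <- evidence_filter(cands, t)
    expect_true(all(cur$rsid %in% prev$rsid))
    prev <- cur
  }
})
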