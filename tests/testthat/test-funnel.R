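pass_only_config <- function(n) {
  scenario_config("funnel", genome_length = 1000L + n * 13000L + 1000L,
                  n_pass = n, n_fail_chromatin = 0L, n_fail_neighbor = 0L,
                  n_fail_upstream = 0L, n_fail_evidence = 0L,
                  n_fail_spacing = 0L, n_fail_conservation = 0L,
                  n_decoy = 2L)
}

test_that("ten fully qualifying candidates survive all eight stages", {
  sc <- generate_scenario(pass_only_config(10L), seed = 42,
                          dir = tempfile())
  res <- suppressMessages(
    run_pipeline(scenario_pipeline_config(sc, file.path(sc$dir, "out"))))
  expect_equal(nrow(res$report), 8L)
  expect_equal(res$report$stage, funnel_stages())
  expect_equal(res$report$n_out[8], 10L)
  expect_equal(nrow(res$candidates), 10L)
  expect_true(all(res$candidates$conserved))
  # final table is position sorted and carries full provenance
  expect_false(is.unsorted(res$candidates$pos))
  expect_true(all(res$candidates$provenance ==
    paste("snp_gof", "open_chromatin", "immune_neighbor", "upstream_10kb",
          "evidence_ge2", "spacing_200", "conservation", sep = ";")))

  # an impossible evidence threshold empties the funnel there, leaving
  # earlier stages untouched
  res2 <- suppressMessages(run_pipeline(scenario_pipeline_config(
    sc, file.path(sc$dir, "out2"), params = list(min_subjects = 9999L))))
  expect_equal(res2$report$n_out[1:5], res$report$n_out[1:5])
  expect_equal(res2$report$n_out[6:8], c(0L, 0L, 0L))
  expect_equal(nrow(res2$candidates), 0L)
  unlink(sc$dir, recursive = TRUE)
})

test_that("report counts equal the line counts of the stage outputs", {
  sc <- generate_scenario(scenario_config("funnel",
                                          genome_length = 120000L),
                          seed = 9, dir = tempfile())
  res <- suppressMessages(
    run_pipeline(scenario_pipeline_config(sc, file.path(sc$dir, "out"))))
  for (k in seq_len(nrow(res$report))) {
    n_lines <- length(readLines(res$report$path[k]))
    expected <- if (grepl("\\.bed$", res$report$path[k])) {
      res$report$n_out[k]              # BED: no header
    } else {
      res$report$n_out[k] + 1L         # TSV: header line
    }
    expect_equal(n_lines, expected, info = res$report$stage[k])
  }
  unlink(sc$dir, recursive = TRUE)
})

test_that("stage skipping passes candidates through without reordering", {
  sc <- generate_scenario(scenario_config("funnel",
                                          genome_length = 120000L),
                          seed = 10, dir = tempfile())
  res <- suppressMessages(run_pipeline(scenario_pipeline_config(
    sc, file.path(sc$dir, "out"), skip = "open_chromatin")))
  expect_true(res$report$skipped[3])
  expect_equal(res$report$n_in[3], res$report$n_out[3])
  expect_equal(res$report$stage, funnel_stages())
  # the chromatin-fail candidate now reaches (and passes) later stages
  chromatin_fail <- sc$planted$rsid[sc$planted$type == "open_chromatin"]
  expect_true(chromatin_fail %in% res$candidates$rsid)
  unlink(sc$dir, recursive = TRUE)
})

test_that("missing inputs abort before any stage output is written", {
  sc <- generate_scenario(pass_only_config(1L), seed = 11,
                          dir = tempfile())
  cfg <- scenario_pipeline_config(sc, file.path(sc$dir, "out"))
  cfg$inputs$variants <- NULL
  expect_error(run_pipeline(cfg), class = "gasfunnel_bad_input")
  cfg2 <- scenario_pipeline_config(sc, file.path(sc$dir, "out"))
  cfg2$inputs$genome <- file.path(sc$dir, "nope.fa")
  expect_error(run_pipeline(cfg2), class = "gasfunnel_bad_input")
  expect_false(file.exists(file.path(sc$dir, "out", "stage_1_scan.bed")))
  unlink(sc$dir, recursive = TRUE)
})

test_that("filters are idempotent on their own output", {
  sc <- generate_scenario(scenario_config("funnel",
                                          genome_length = 120000L),
                          seed = 12, dir = tempfile())
  hits <- scan_fasta(sc$paths$genome)$hits
  cands <- candidate_gof(hits, read_vcf(sc$paths$variants))
  genes <- set_immune_genes(read_gene_models(sc$paths$genes),
                            read_gene_list(sc$paths$gene_list))
  once <- neighbor_gene_filter(cands, genes)
  expect_equal(neighbor_gene_filter(once, genes), once)
  up_once <- upstream_tss_filter(once, genes)
  expect_equal(upstream_tss_filter(up_once, genes), up_once)
  ev <- evidence_filter(up_once, 2L)
  expect_equal(evidence_filter(ev, 2L), ev)
  gas <- hits[hits$class == "GAS", ]
  sp <- spacing_filter(ev, gas)
  expect_equal(spacing_filter(sp, gas), sp)
  unlink(sc$dir, recursive = TRUE)
})

test_that("known-rsID annotation flags membership without filtering", {
  cands <- data.frame(rsid = c("rs1", "rs2", "rs3"),
                      stringsAsFactors = FALSE)
  path <- tempfile()
  writeLines(c("rs2", "rs2", "rs999"), path)   # duplicates act as a set
  out <- annotate_known(cands, path)
  expect_equal(out$known, c(FALSE, TRUE, FALSE))
  expect_equal(nrow(out), 3L)
  writeLines(character(0), path)
  expect_false(any(annotate_known(cands, path)$known))
})

test_that("YAML configuration files drive the pipeline", {
  sc <- generate_scenario(pass_only_config(1L), seed = 13,
                          dir = tempfile())
  cfg <- scenario_pipeline_config(sc, file.path(sc$dir, "out"))
  yml <- file.path(sc$dir, "config.yaml")
  yaml::write_yaml(cfg, yml)
  res <- suppressMessages(run_pipeline(yml))
  expect_equal(nrow(res$candidates), 1L)
  # the effective config is embedded for provenance
  eff <- jsonlite::read_json(file.path(sc$dir, "out", "config_used.json"))
  expect_equal(eff$params$min_subjects, 2L)
  unlink(sc$dir, recursive = TRUE)
})
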