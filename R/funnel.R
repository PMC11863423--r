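# The eight-stage prioritization funnel: motif scan, gain-of-function SNP
# identification, open-chromatin support, immune-gene neighborhood, 10 kb
# upstream-of-TSS restriction, multi-subject evidence, spacing from
# existing GAS motifs, and cross-species conservation.  Stage order is
# fixed; every stage's output is written before the next stage runs, and
# identical config + inputs reproduce byte-identical outputs.

`%||%` <- function(a, b) if (is.null(a)) b else a

.default_params <- function() {
  list(window = 200L, span = 10000L, min_subjects = 2L, min_signal = 20,
       match_mode = "same_class", drop_clustered = TRUE,
       evidence_key = "FREQ")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' @param path Configuration file path (`.yaml`/`.yml` or `.json`).
#' @return Configuration list (`inputs`, `params`, `outdir`, `skip`).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) .err_input("config file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    .err_input("config must be .yaml/.yml or .json: ", path)
  }
}

.check_inputs <- function(inp, skip) {
  need <- c("genome", "variants")
  if (!"open_chromatin" %in% skip) {
    if (is.null(inp$peaks) && is.null(inp$signal)) {
      .err_input("config needs inputs$signal (bedGraph) or inputs$peaks ",
                 "(BED) unless the open_chromatin stage is skipped")
    }
  }
  if (!all(c("immune_neighbor", "upstream_10kb") %in% skip)) {
    need <- c(need, "genes")
    if (is.null(inp$gene_list) && (is.null(inp$obo) || is.null(inp$gaf))) {
      .err_input("config needs inputs$gene_list or inputs$obo + inputs$gaf")
    }
  }
  if (!"conservation" %in% skip) {
    need <- c(need, "orthologs", "genome2", "genes2")
  }
  for (k in need) {
    if (is.null(inp[[k]])) .err_input("config is missing inputs$", k)
  }
  given <- unlist(inp[vapply(inp, is.character, logical(1))])
  missing <- given[!file.exists(given)]
  if (length(missing) > 0L) {
    .err_input("input file(s) not found: ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

#' Run the full prioritization funnel
#'
#' Executes the eight stages in fixed order, writing each stage's output
#' (`stage_<k>_<label>.*`) to the output directory before the following
#' stage runs, then the final candidate table, a machine-readable JSON
#' report and a human-readable TSV report.  Missing inputs abort before
#' any stage runs; an empty intermediate result simply propagates empty
#' outputs while the report stays complete.
#'
#' @param config Configuration list or path to a YAML/JSON file with
#'   elements `inputs` (paths: `genome`, `variants`, `signal` or `peaks`,
#'   `genes`, `gene_list` or `obo`+`gaf` (+ optional `go_roots`),
#'   `orthologs`, `genome2`, `genes2`, optional `known_rsids`), optional
#'   `params` (`window`, `span`, `min_subjects`, `min_signal`,
#'   `match_mode`, `drop_clustered`, `evidence_key`), `outdir`, and
#'   optional `skip` (stage labels to pass through unchanged; order is
#'   never changed).
#' @return Invisibly, a list with `report` (stage data frame), `candidates`
#'   (final table) and `outdir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  inp <- config$inputs %||% list()
  params <- utils::modifyList(.default_params(), config$params %||% list())
  skip <- as.character(config$skip %||% character(0))
  bad_skip <- setdiff(skip, funnel_stages())
  if (length(bad_skip) > 0L) {
    .err_input("unknown stage label(s) in skip: ",
               paste(bad_skip, collapse = ", "))
  }
  outdir <- config$outdir %||% .err_input("config is missing outdir")
  .check_inputs(inp, skip)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  effective <- list(inputs = inp, params = params, skip = skip,
                    outdir = outdir)
  cfg_path <- file.path(outdir, "config_used.json")
  jsonlite::write_json(effective, cfg_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  cfg_hash <- unname(tools::md5sum(cfg_path))

  report <- list()
  note <- function(stage, n_in, n_out, path, skipped = FALSE) {
    report[[length(report) + 1L]] <<- data.frame(
      stage = stage, n_in = n_in, n_out = n_out, path = path,
      skipped = skipped, stringsAsFactors = FALSE)
    message(sprintf("[%s] %s -> %s%s", stage,
                    ifelse(is.na(n_in), "-", n_in), n_out,
                    if (skipped) " (skipped)" else ""))
  }

  t0 <- Sys.time()
  # stage 1: genome-wide motif scan
  p1 <- file.path(outdir, "stage_1_scan.bed")
  scn <- scan_fasta(inp$genome, out_bed = p1)
  hits <- scn$hits
  gas_hits <- hits[hits$class == "GAS", , drop = FALSE]
  note("scan", NA_integer_, nrow(hits), p1)

  # stage 2: SNPs that complete a near-GAS motif
  variants <- read_vcf(inp$variants, evidence_key = params$evidence_key)
  cands <- candidate_gof(hits, variants)
  p2 <- file.path(outdir, "stage_2_snp_gof.tsv")
  write_candidates_tsv(cands, p2)
  note("snp_gof", nrow(variants), nrow(cands), p2)

  stage_step <- function(label, k, cands, fn) {
    path <- file.path(outdir, sprintf("stage_%d_%s.tsv", k, label))
    if (label %in% skip) {
      write_candidates_tsv(cands, path)
      note(label, nrow(cands), nrow(cands), path, skipped = TRUE)
      return(cands)
    }
    out <- fn(cands)
    if (nrow(out) > 0L) {
      out$provenance <- paste(out$provenance, label, sep = ";")
    }
    write_candidates_tsv(out, path)
    note(label, nrow(cands), nrow(out), path)
    out
  }

  cands <- stage_step("open_chromatin", 3L, cands, function(x) {
    regions <- if (!is.null(inp$peaks)) read_peaks_bed(inp$peaks)
               else threshold_signal(inp$signal, params$min_signal)
    window_join(x, regions, params$window)
  })

  genes <- NULL
  if (!all(c("immune_neighbor", "upstream_10kb") %in% skip) ||
      !"conservation" %in% skip) {
    if (!is.null(inp$genes)) {
      genes <- read_gene_models(inp$genes)
      immune_set <- if (!is.null(inp$gene_list)) {
        read_gene_list(inp$gene_list)
      } else {
        immune_gene_set(inp$obo, inp$gaf,
                        roots = inp$go_roots %||% NULL)
      }
      genes <- set_immune_genes(genes, immune_set)
    }
  }

  cands <- stage_step("immune_neighbor", 4L, cands, function(x) {
    neighbor_gene_filter(x, genes)
  })
  cands <- stage_step("upstream_10kb", 5L, cands, function(x) {
    upstream_tss_filter(x, genes, params$span)
  })
  cands <- stage_step("evidence_ge2", 6L, cands, function(x) {
    evidence_filter(x, params$min_subjects)
  })
  cands <- stage_step("spacing_200", 7L, cands, function(x) {
    spacing_filter(x, gas_hits, params$window, params$drop_clustered)
  })
  cands <- stage_step("conservation", 8L, cands, function(x) {
    conservation_filter(x, read_orthologs(inp$orthologs), inp$genome2,
                        read_gene_models(inp$genes2), params$span,
                        params$match_mode)
  })

  if (!is.null(inp$known_rsids)) {
    cands <- annotate_known(cands, inp$known_rsids)
  }
  cands <- cands[order(cands$chrom, cands$pos), , drop = FALSE]
  rownames(cands) <- NULL
  final_path <- file.path(outdir, "final_candidates.tsv")
  write_candidates_tsv(cands, final_path)

  report_df <- do.call(rbind, report)
  meta <- list(tool = "gasfunnel",
               version = as.character(utils::packageVersion("gasfunnel")),
               config_md5 = cfg_hash, parameters = params)
  jsonlite::write_json(list(stages = report_df, meta = meta),
                       file.path(outdir, "funnel_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  .write_tsv(report_df, file.path(outdir, "funnel_report.tsv"))
  message(sprintf("funnel complete: %d final candidate(s) in %.1fs",
                  nrow(cands), as.numeric(Sys.time() - t0, units = "secs")))
  invisible(list(report = report_df, candidates = cands, outdir = outdir))
}

#' Annotate candidates with membership in a known-variant rsID list
#'
#' Adds a logical `known` column (ClinVar-style lookup by rsID); no row is
#' filtered.  Duplicate list entries behave like a set.
#'
#' @param candidates Candidate data frame with an `rsid` column.
#' @param rsid_list_path Newline-delimited rsID list.
#' @return `candidates` with the `known` column set.
#' @export
annotate_known <- function(candidates, rsid_list_path) {
  ids <- unique(trimws(readLines(rsid_list_path, warn = FALSE)))
  ids <- ids[nzchar(ids)]
  candidates$known <- candidates$rsid %in% ids
  candidates
}

#' Build a run_pipeline configuration from a generated scenario
#'
#' @param scenario Result of [generate_scenario()] (funnel kind).
#' @param outdir Output directory for the pipeline run.
#' @param params Optional parameter overrides.
#' @param skip Optional stage labels to skip.
#' @return Configuration list accepted by [run_pipeline()].
#' @export
scenario_pipeline_config <- function(scenario, outdir, params = list(),
                                     skip = character(0)) {
  p <- scenario$paths
  inputs <- list(genome = p$genome, variants = p$variants,
                 signal = p$signal, genes = p$genes,
                 orthologs = p$orthologs, genome2 = p$genome2,
                 genes2 = p$genes2)
  if (!is.null(p$gene_list)) {
    inputs$gene_list <- p$gene_list
  } else {
    inputs$obo <- p$obo
    inputs$gaf <- p$gaf
  }
  list(inputs = inputs, params = params, outdir = outdir, skip = skip)
}
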