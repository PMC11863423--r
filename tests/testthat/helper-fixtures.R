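# Shared helpers: tiny on-the-fly fixture writers and random-input
# constructors.  Everything is generated in code at test time.

rand_dna <- function(n, gc = 0.41) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

tmp_fasta <- function(seqs) {
  path <- tempfile(fileext = ".fa")
  con <- file(path, "w")
  for (nm in names(seqs)) {
    writeLines(c(paste0(">", nm), seqs[[nm]]), con)
  }
  close(con)
  path
}

tmp_vcf <- function(rows, info = NULL) {
  # rows: data.frame chrom,pos,rsid,ref,alt[,info]
  path <- tempfile(fileext = ".vcf")
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=FREQ,Number=.,Type=String,Description=\"f\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", sep = "\t"))
  inf <- if (is.null(rows$info)) rep(".", nrow(rows)) else rows$info
  body <- paste(rows$chrom, rows$pos, rows$rsid, rows$ref, rows$alt,
                ".", ".", inf, sep = "\t")
  writeLines(c(hdr, body), path)
  path
}

freq_info <- function(k) {
  paste0("FREQ=", paste0("S", seq_len(k), ":0.9,0.1", collapse = "|"))
}

# Plant a k-mer (character vector of bases) into a DNA string at a 0-based
# offset; returns the modified string.
plant <- function(seq, start0, kmer) {
  substr(seq, start0 + 1L, start0 + length(kmer)) <- paste(kmer,
                                                           collapse = "")
  seq
}

random_intervals <- function(n, max_pos, chroms = "chr1",
                             max_len = 500L) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample.int(max_len, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

md5_tree <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  setNames(unname(tools::md5sum(files)),
           sub(paste0("^", dir, "/?"), "", files))
}
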