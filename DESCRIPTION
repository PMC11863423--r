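Package: gasfunnel
Title: Discovery and Prioritization of SNPs That Create STAT-Binding GAS Motifs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scans genomes for the canonical gamma-interferon-activated-site
    (GAS) motif TTCnnnGAA and its six single-deviation (near-complete GAS)
    classes, joins catalogued variants to motif occurrences to call
    gain-of-function SNPs whose alternate allele completes an intact motif,
    and prioritizes candidates through an eight-stage funnel: motif scan,
    SNP identification, open-chromatin support, immune-gene neighborhood,
    10 kb upstream-of-TSS restriction, multi-subject evidence, spacing from
    existing GAS motifs, and cross-species motif conservation. Includes a
    fully synthetic scenario generator with independent brute-force truth
    tables so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
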