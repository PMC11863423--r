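# gasfunnel

Finding and prioritizing SNPs that create STAT-binding GAS motifs.

Phosphorylated STAT dimers activate immune genes by binding
gamma-interferon-activated sites (GAS motifs) with the consensus
**TTCnnnGAA** — six fixed bases around three free middle positions.
Because only six positions are constrained, genomes are full of 9-mers
that miss the consensus by exactly one fixed base (*near-complete GAS*,
ncGAS).  A catalogued SNP whose alternate allele supplies the missing
base converts such a site into an intact motif: a potential
gain-of-function regulatory variant that can put an immune gene under
inappropriate cytokine control.

`gasfunnel` implements the full computational protocol for researchers in
regulatory genomics and immunogenetics:

1. **scan** — enumerate all canonical and ncGAS occurrences.  The seven
   motif classes (`GAS`, and `T1 T2 C G A1 A2`, named for the deviant
   fixed base) are pairwise disjoint, cover 64 + 1,152 of the 262,144
   possible 9-mers, and are closed under reverse complementation, so
   plus-strand scanning with the full class set is complete for both
   strands;
2. **snp_gof** — join a dbSNP-style VCF to the hits: a candidate's REF
   must match the genome at the deviant position and its ALT must be the
   restoring allele (`candidate_lof()` handles the converse,
   motif-destroying case);
3. **open_chromatin** — require H3K27ac-style signal ≥ 20 within 200 bp;
4. **immune_neighbor** — require an immune gene (plain list, or GO
   closure over immune-related root terms from OBO + GAF) among the two
   flanking genes;
5. **upstream_10kb** — require the SNP inside the strand-aware 10 kb
   window upstream of an immune gene TSS;
6. **evidence_ge2** — require support from ≥ 2 independent frequency
   studies (proxy for ≥ 2 subjects, against sequencing errors);
7. **spacing_200** — drop candidates within 200 bp of an existing
   canonical GAS motif, and mutually clustered candidates;
8. **conservation** — require the same motif class in the orthologous
   gene's upstream window of a second genome (e.g. mouse).

A synthetic-scenario generator (`generate_scenario()`) emits every input
format with planted ground truth, so the whole pipeline is testable
without any downloads.

## Worked example

```r
library(gasfunnel)

# one near-complete motif, restorable by T at its first position
scan_sequence("GTCAAAGAA", "chr1")
#>   chrom start end class      kmer deviant_pos restore_allele
#> 1  chr1     0   9    T1 GTCAAAGAA           0              T

# a synthetic scenario: 120 kb genome, 8 planted candidates of which 2
# are designed to survive all stages, plus decoy SNPs
sc <- generate_scenario(scenario_config("funnel",
                                        genome_length = 120000L),
                        seed = 1)
res <- run_pipeline(scenario_pipeline_config(sc, file.path(sc$dir, "out")))
res$report[, c("stage", "n_in", "n_out")]
#>             stage n_in n_out
#> 1            scan   NA   691
#> 2         snp_gof   12     8
#> 3  open_chromatin    8     7
#> 4 immune_neighbor    7     6
#> 5   upstream_10kb    6     5
#> 6    evidence_ge2    5     4
#> 7     spacing_200    4     3
#> 8    conservation    3     2
```

The scan finds 691 motif intervals (8 planted, the rest chance
background occurrences).  Of the 12 catalogued variant alleles, 8
complete a motif; each subsequent stage removes the one candidate
designed to fail it, leaving the 2 designed survivors:

```r
res$candidates[, c("rsid", "pos", "ref", "alt", "class",
                   "completed_kmer", "nearest_gene", "distance_to_tss")]
#>       rsid   pos ref alt class completed_kmer nearest_gene distance_to_tss
#> 1 rs100001  6508   T   A    A1      TTCCGGGAA     GENE001R            4993
#> 2 rs100004 45502   G   T    T2      TTCCCTGAA     GENE004R            4999
```

Each row reads: the SNP at `pos` changes `ref` to `alt` inside a 9-mer of
the given ncGAS class, yielding the intact GAS motif `completed_kmer`
about 5 kb upstream of the immune gene `nearest_gene`, with open
chromatin on top, multi-study evidence, clear spacing and a conserved
motif in the second genome.  On real data the inputs are hg38 FASTA,
dbSNP VCF, H3K27ac bedGraph, GENCODE GTF, GO OBO + GAF and a mouse
genome + ortholog map; formats are identical.

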