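---
title: "Finding SNPs that create GAS motifs: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding SNPs that create GAS motifs: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gasfunnel)
```

## The biological question

Cytokine signaling through the JAK-STAT pathway ends with phosphorylated
STAT dimers binding gamma-interferon-activated sites (GAS motifs) in
regulatory DNA.  The binding consensus is the near-palindrome
`TTCnnnGAA`: six fixed bases flanking three unconstrained middle
positions.  Because only six bases are constrained, a genome contains
millions of 9-mers that miss the consensus by exactly one fixed base.  A
catalogued SNP whose alternate allele supplies that missing base turns
such a *near-complete GAS* (ncGAS) site into an intact binding site — a
potential gain-of-function regulatory variant that could place an immune
gene under inappropriate cytokine control.  Conversely, a SNP inside an
intact motif's fixed positions can destroy binding (loss of function).

`gasfunnel` implements this search end to end: enumerate ncGAS
occurrences, join them to a variant catalogue, and prioritize the
candidates through an eight-stage funnel until the list is short enough
for manual review and experimental design.  The package deliberately ends
at the ranked table; choosing targets for editing experiments is a human
step.

## The motif algebra

The canonical class and its six single-deviation classes are:

```{r}
gas_classes()
```

Each deviation class replaces one fixed base by the IUPAC complement of
the canonical base (`V` = not T, `D` = not C, `H` = not G, `B` = not A).
Three consequences, all enforced by exhaustive enumeration in the test
suite over all $4^9 = 262{,}144$ 9-mers:

* the classes are pairwise disjoint (no 9-mer matches two classes);
* canonical GAS matches exactly $4^3 = 64$ 9-mers and each deviation
  class exactly $3 \times 4^3 = 192$, i.e. 1,152 ncGAS 9-mers in total;
* substituting the class's restoring base at its deviant offset maps
  every ncGAS 9-mer onto a canonical match.

The class set is closed under reverse complementation
(`GAS↔GAS`, `T1↔A2`, `T2↔A1`, `C↔G`), so scanning only the plus strand
with all seven classes is complete with respect to both strands, and each
genomic interval is reported exactly once.  This differs from scanners
that report plus- and minus-strand occurrences separately, where the
palindromic canonical motif and every ncGAS/partner pair would be counted
twice; published genome-wide totals obtained that way may therefore be up
to a factor of two larger than interval counts produced here.

Patterns are stored as explicit per-position allowed-base sets rather
than regular expressions, so the production scanner and the regex-based
reference oracle used in validation are genuinely independent
implementations.  Two matching rules matter in practice:

* a genome `N` (or any non-ACGT symbol) matches nothing, including the
  free middle positions — a motif call through an assembly gap is
  meaningless;
* soft-masked lowercase bases are uppercased before matching, since
  repeats are part of the search space.

## The funnel

`run_pipeline()` executes the stages in fixed order; every stage writes
its output before the next runs, and from the SNP stage onward each stage
returns a subset of its input.

| # | stage | rule | parameter (default) |
|---|-------|------|---------------------|
| 1 | `scan` | all GAS/ncGAS occurrences, plus strand, full class set | — |
| 2 | `snp_gof` | variant sits on the deviant base, REF matches the genome, ALT is the restoring allele | — |
| 3 | `open_chromatin` | motif within `window` bp of a signal region with value ≥ `min_signal` | `window = 200`, `min_signal = 20` |
| 4 | `immune_neighbor` | at least one of the two flanking genes (nearest TSS per side, strand-agnostic) is immune | — |
| 5 | `upstream_10kb` | SNP inside the strand-aware upstream window of an immune gene TSS | `span = 10000` |
| 6 | `evidence_ge2` | evidence count ≥ `min_subjects` | `min_subjects = 2` |
| 7 | `spacing_200` | gap to any canonical GAS hit > `window`; mutually close candidate motifs all removed | `window = 200`, `drop_clustered = TRUE` |
| 8 | `conservation` | ortholog's upstream window in the second genome contains a qualifying hit | `match_mode = "same_class"` |

Parameter rationale, in the funnel's own terms:

* **200 bp** is the approximate footprint of the peak–valley–peak
  geometry around a bound transcription factor; it serves both as the
  join distance to open-chromatin evidence and as the minimum spacing
  from existing GAS motifs so that a newly created site would not compete
  with an established one for the same footprint.
* **Signal ≥ 20** encodes "an acetylation signal of 20 or higher" on
  H3K27ac coverage.  The comparator is configurable
  (`threshold_signal(..., comparator = \`>\`)`) because awk-style
  pipelines with a strict `>` are common; the inclusive default follows
  the stated intent rather than the accidental semantics of such
  one-liners, which test the wrong column anyway when applied to BED
  input.
* **10 kb upstream of the TSS** is the promoter/enhancer-proximal search
  space.  The window is strand-aware and half-open:
  `[tss − span, tss)` on plus-strand genes, `[tss + 1, tss + span + 1)`
  on minus-strand genes, so the TSS base itself is never "upstream" of
  its own gene.  It is applied relative to *immune* genes only, since the
  stage follows the immune-neighborhood restriction in the funnel.
* **Evidence ≥ 2** guards against singleton submissions that may be
  sequencing errors.  dbSNP has no field that directly counts subjects,
  so the number of distinct frequency studies in the `FREQ` INFO field is
  used as the proxy; `read_vcf(evidence_key = ...)` accepts any numeric
  INFO key instead.

## Coordinate and tie-break conventions

* Internally everything is 0-based half-open; conversion to 1-based
  happens only in readers and writers (VCF, GTF, GRanges).  The gap
  between `[a,b)` and `[c,d)` is `max(0, c − b, a − d)`; bookended
  intervals have gap 0.
* The window join keeps an item when the gap is `≤ w` (an item exactly
  `w` away still counts as supported).  Tools that implement the join by
  extending intervals and requiring ≥ 1 bp of overlap drop the boundary
  case; the explicit gap rule was chosen because it is symmetric and
  matches the spacing filter's complementary rule (`> w` required).
* A multi-transcript gene gets one deterministic TSS: the most 5'
  transcript start on its strand.
* In the neighborhood stage a TSS exactly at the SNP counts as the left
  neighbor at distance 0; when both flanking genes are immune the closer
  one is annotated, left winning exact ties.
* Clustered candidate motifs (mutually within 200 bp) are *all* removed:
  no ranking rule exists to pick a winner, and keeping an arbitrary
  member would bias downstream counts.  Candidates sharing one identical
  motif interval are one motif, not a cluster.  `drop_clustered = FALSE`
  disables the rule.
* The immune-neighborhood stage annotates the nearest immune flanking
  gene; the upstream stage then overwrites `nearest_gene` with the immune
  gene whose window actually contains the SNP — that gene is the putative
  enhancer target, and it is the one whose orthologs the conservation
  stage examines.
* "Same type of motif" in the conservation stage defaults to the same
  ncGAS class (`same_class`); `any_ncgas` and `canonical` are exposed
  because the biological reading is genuinely ambiguous.  With
  one-to-many orthology, one qualifying ortholog window suffices.
  A candidate whose target gene has no ortholog is dropped and counted
  separately from one whose ortholog window simply lacks the motif.

## The synthetic scenario generator

`generate_scenario()` emits every input the funnel consumes — genome
FASTA, site-only VCF with `FREQ` evidence, bedGraph signal, GTF gene
models, immune gene list (or a miniature OBO ontology plus GAF), ortholog
map and a second genome — together with a truth table of expected
per-stage survivors computed by quadratic, regex-based reference
implementations that share no code with the pipeline.

Each planted candidate occupies its own 13 kb locus containing a
non-immune filler gene, an immune target gene, a candidate ncGAS motif
5 kb upstream of the target TSS, an H3K27ac-like peak and a catalogued
restoring SNP.  A candidate is assigned a *designed failure stage*: its
locus is modified in exactly one respect (peak below threshold, target
gene not immune, motif downstream of the TSS, single-study evidence, a
canonical GAS planted 100 bp away, or an ortholog window without the
class), so every stage has positive and negative controls in every
scenario.  Decoy SNPs sit on real deviant positions but carry
non-restoring alleles, verified inert by the apply-and-rescan oracle.

Background sequence is sampled at GC 0.41 (human-like) and may contain
unplanned motif hits — they are part of the truth table like any real
background occurrence.  Only inside a 200 bp exclusion zone around each
planted motif, and inside second-genome ortholog windows, is the
background resampled until clean, so a chance hit can never flip a
designed fate.  The generator finishes by asserting that the brute-force
truth equals the designed fates; a scenario that violates its own design
is a bug, not a fixture.

What the generator does *not* emulate: read-level ChIP-seq noise and
peak-calling artefacts, population-genetic structure of allele
frequencies, linkage between variants, multi-gene loci with overlapping
transcripts, and assembly gaps.  Passing the end-to-end tests therefore
demonstrates that the implementation applies the stated rules exactly —
not that the rules themselves are robust to the messiness of real
tracks, which is a property of the protocol, not of this implementation.

## Validation strategy and problem sizes

The test suite validates each operation against an independent reference:
exhaustive enumeration for the motif algebra; a both-strand regex oracle
for the scanner (50 random 100 kb sequences); an apply-every-allele
rescan oracle for candidacy (20 scenarios of 20 planted + 20 decoy SNPs
in 100 kb); quadratic all-pairs oracles for the interval filters (up to a
few thousand items); a strand-reflection property for the upstream
windows; and exact truth-table recovery for the full funnel across 20
scenarios of eight loci each.  These sizes keep the whole suite fast
while every comparison remains exact rather than statistical.

## Known limitations

* Consensus (exact degenerate) matching only: no position-weight-matrix
  scores or p-values, so counts are not expected to reproduce
  FIMO-with-PWM output exactly, and weighted near-misses at two positions
  are invisible by construction.
* Genome-wide totals depend on the single-interval reporting convention
  described above.
* bigWig signal must be converted to bedGraph upstream; the package reads
  text formats only.
* Indels and multi-nucleotide variants are catalogued but never
  candidates; creating a motif by insertion is out of scope.
* The GO closure follows `is_a` (and optionally `part_of`) only, and the
  resulting gene count depends on the ontology release supplied by the
  user.
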