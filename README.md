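# floramark

Organ-specific microsatellite (SSR) marker development and in-silico
screening for plant genomes.

## The problem

Simple sequence repeats — perfect tandem repeats of a 2–6 bp unit — are
workhorse codominant markers in plant breeding and taxonomy, but markers
mined naively from a draft assembly amplify poorly: many primer pairs
anneal at several genomic sites and produce redundant PCR products,
especially in large, repeat-rich, polyploid genomes such as modern rose.
`floramark` implements the marker-development strategy that fixes this at
the screening stage:

1. **Scan** an assembly for perfect SSR loci (unit 2–6 bp, ≥ 5 repeats),
   grouped into canonical motif classes (the class of a unit under cyclic
   rotation and reverse complement, e.g. AG/CT ⊇ {AG, GA, CT, TC}).
2. **Design** one best flanking primer pair per locus under classical
   Primer3-style constraints (length 18–20 bp, GC 45–65 %, Tm 60 ± 3 °C,
   product 120–400 bp spanning the tract) by exhaustive penalty-ranked
   search.
3. **Filter** by electronic PCR: enumerate *every* potential amplicon of
   each pair across the assembly and retain only pairs with exactly one
   product ("unique annealing sites").
4. **Cross-reference** retained genomic pairs against floral transcript
   contigs — tolerating a single mismatch at the 5′-terminal base of the
   reverse primer, never at the 3′ end — to flag gene-targeted markers
   (GTMs) whose amplicons sit in expressed, ideally annotated, genes.
5. **Screen transferability** of retained pairs against related genomes,
   and **analyse polymorphism** of scored panels: PIC = 1 − Σ Pᵢ² over
   allele-carriage proportions, overall gene diversity H_T, Nei (1972)
   distance D = −ln(Σxy / √(Σx²·Σy²)), and UPGMA clustering with Newick
   export.

Utilities cover read QC (drop reads with > 10 % of bases under Q30 or any
N), assembly summary statistics (N50 etc.), 17-mer genome-size estimation
from the k-mer multiplicity peak, and the flow-cytometry conversion
genome size (bp) = 0.978 × 10⁹ × 2C-value (pg).

Every stage is verifiable without external data: seeded fixture
generators plant SSR tracts with exact truth coordinates, inject
paralogous duplications that must flip pairs from *unique* to *multiple*,
express chosen loci as transcripts, simulate reads at known coverage and
genotype panels with a controlled ploidy effect.

## Worked example

```r
library(floramark)

genome <- simulate_genome(30000, gc = 0.5, seed = 7)
fx <- plant_ssrs(genome, data.frame(
  motif        = c("AC", "AAG", "AGAT"),
  repeat_count = c(8, 6, 5),
  position     = c(6000, 15000, 24000)))
fx$truth$planted[, c("start", "end", "motif", "repeat_count", "canonical_class")]
#>   start   end motif repeat_count canonical_class
#> 1  6000  6015    AC            8           AC/GT
#> 2 15000 15017   AAG            6         AAG/CTT
#> 3 24000 24019  AGAT            5       AGAT/ATCT

pairs <- design_primers(fx$genome, fx$truth$planted)
pairs[, c("pair_id", "fwd_seq", "rev_seq", "product_bp")]
#>            pair_id              fwd_seq              rev_seq product_bp
#> 1   ctg1_6000_6015 ACGAGCACGTCGCAGCAGAT CTGATGGCGAAGCCGCAGCT        255
#> 2 ctg1_15000_15017 CGCCCTTGTTATCGCGACGC CGGGGCCACGGTTCTGCATT        180
#> 3 ctg1_24000_24019 ATGCGCCCCCGACCAAAAGA AATCGTACTCGCGCCCGGTT        225

# duplicate the first pair's amplicon region: it must now be filtered out
dup <- inject_duplications(fx$genome,
         data.frame(seq_id = "ctg1", start = pairs$fwd_start[1],
                    end = pairs$rev_end[1]))
ep <- classify_pairs(pairs, dup$assembly)
ep
#> e-PCR of 3 primer pairs: 2 unique (retained), 1 multiple, 0 none

# express two loci as transcripts, annotate half, flag gene-targeted markers
tx <- simulate_transcripts(fx$genome, fx$truth$planted[2:3, ],
                           annotation_fraction = 0.5, seed = 8)
gtm_cross_reference(pairs[pairs$pair_id %in% ep$retained, ],
                    tx$transcripts, annotations = tx$annotations)
#> 2 gene-targeted marker pairs annealing to 2 transcripts (1 annotated genes)
```

The three planted tracts are recovered at exact coordinates; each
designed pair satisfies every constraint and amplifies its own template
exactly once; duplicating an amplicon region demotes its pair to
*multiple* (it would risk redundant PCR products and is discarded); the
two retained pairs whose amplicons fall inside transcripts become GTMs,
one of them annotated ("functional").

A shell interface wrapping the same functions ships at
`inst/cli/floramark.R` (subcommands `scan`, `design`, `epcr`, `gtm`,
`transfer`, `diversity`, `run`), and `run_pipeline()` orchestrates all
stages with a written manifest.

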