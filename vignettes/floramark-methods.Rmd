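---
title: "Methods: SSR marker development and screening in floramark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SSR marker development and screening in floramark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floramark)
```

# Scope and model

`floramark` implements a marker-development funnel for plant genomes:
perfect-microsatellite detection, constraint-based primer design,
electronic-PCR uniqueness filtering, transcript cross-referencing for
gene-targeted markers (GTMs), cross-species transferability screening,
and dominance-scored diversity analysis. This vignette records the
modelling assumptions, the tunable parameters with their defaults and
units, the numerical choices, and what the synthetic fixtures do and do
not establish about real data.

# SSR detection

A locus is a *maximal perfect* tandem repeat of a *primitive* unit of
2–6 bp repeated at least 5 complete times. Primitivity (the unit is not
itself a repetition of a shorter unit) guarantees each tract is described
once: `ATATATATATAT` is AT×6, never ATAT×3. Maximality means the tract
cannot be extended by another full unit on either side; a partial
trailing unit is excluded from the reported span, so an 11-bp AC run is
AC×5 over 10 bp. Mononucleotide runs are out of scope, `N` never
participates in a tract, and coordinates are 1-based inclusive
everywhere the package emits tables or GFF3.

The scanner works per unit length `u` on the lag-`u` self-comparison of
the character vector: runs of equality are maximal period-`u` tracts, the
motif is read at the leftmost position, and non-primitive motifs are
discarded (the tract is reported at its primitive period instead). The
test suite checks set-equality of this scanner against an independent
regex-backreference oracle on random sequences, and exact-coordinate
recovery of planted tracts.

Motif classes group a unit with all of its cyclic rotations and those of
its reverse complement; the class label is
`canonical/min-rotation-of-its-reverse-complement` (AG/CT, AT/AT, ...).
The 12 primitive dinucleotides collapse to exactly 4 classes. Because
published motif tallies are sometimes raw-motif rather than class counts,
`summarize_motifs()` reports either (`by = "canonical_class"` or
`by = "motif"`).

`min_gap` defaults to 0: adjacent distinct tracts are both reported.

# Primer design

Design is a transparent exhaustive search rather than a wrapper around an
external designer: all forward windows upstream and reverse windows
downstream of the tract (within `flank_window` of it, never overlapping
it) are enumerated, hard-filtered on length 18–20 bp (optimum 20), GC
45–65 % (optimum 50 %), and Tm within `tm_opt ± tm_window`, then pairs
are ranked by

```
penalty = Σ|len − len_opt| + Σ|gc − gc_opt|/5 + Σ|tm − tm_opt|
```

with ties broken by smaller product, then leftmost forward start, making
the result deterministic. Reproducibility motivated this choice: a named
external program's internal parameter set is not fully specified by the
constraints above, whereas this search is defined entirely by them. An
independent constraint audit in the tests re-checks every emitted pair.

Choices left open by the constraint set, fixed here:

* `tm_window = ±3 °C` — a "preferred" 60 °C is not decidable without a
  band; ±3 °C is the common wet-lab tolerance.
* `flank_window = 250` bp per side — must admit products up to 400 bp
  plus primer placement slack.
* primers may not overlap the tract, preventing repeat-anchored priming.
* product size 120–400 bp, spanning the full tract (a marker must read
  through the repeat to be length-informative).

Melting temperatures default to the unified nearest-neighbour duplex
model (Allawi & SantaLucia 1997 parameters; terminal initiation terms;
entropic salt correction 0.368·(N−1)·ln[Na⁺]) at 50 nM total strand and
50 mM monovalent cation — the conditions are arguments, so they are
logged in the design configuration. The two-line Wallace rule
(2·AT + 4·GC) is retained for closed-form tests. The nearest-neighbour
implementation is cross-checked in the tests against frozen reference
values from an independent implementation of the same published
parameter table (tolerance 0.5 °C).

# Electronic PCR

A primer site is a full-length, ungapped placement on either strand;
site positions are reported at the primer's 5′-most template base. An
amplicon is a plus-strand forward site paired with a minus-strand
reverse site on the same sequence, forward before reverse,
non-overlapping, with product length in `[amplicon_min_bp,
amplicon_max_bp]` (defaults 50–5000; "any possible amplification" needs
a bound to be decidable, and 5 kb mimics practical PCR).

The genomic filtering policy is zero mismatches. Classification is per
database: `unique` means exactly one amplicon across all contigs, and
only unique pairs are retained — pairs with zero products are discarded
too, since a retained marker must demonstrably amplify its own source.
The transcript-screening policy additionally tolerates **one** mismatch,
**only** at the 5′-terminal base of the **reverse** primer, and never at
the 3′ end, the strictest reading of the screening rule; the tolerated
window is configurable. Matching runs through `Biostrings`
pattern-matching with the position-specific policy applied on top; the
tests compare amplicon enumeration against a brute-force sliding-window
Hamming oracle and exercise the 5′/3′ mismatch asymmetry on constructed
transcripts.

Transferability against a foreign genome is "≥ 1 amplicon under the same
policy". Published cross-species counts additionally depend on the
original assemblies and unstated alignment thresholds, so the fixtures
only verify the procedure (self-transfer identity, planted-region
recovery, zero mapping onto random sequence).

# Diversity analysis

Band data are dominant presence/absence per marker-scoped allele;
band-intensity dosage is deliberately ignored. Consequences:

* **PIC** is computed *verbatim* as 1 − Σ Pᵢ² with Pᵢ the proportion of
  non-missing accessions carrying allele i. Carriage proportions of
  multi-band accessions need not sum to 1, so PIC can fall below 0 on
  strongly multi-allelic columns; `pic_report()` flags such columns
  rather than renormalising. Fidelity to the stated formula was preferred
  over the textbook frequency-based PIC.
* **H_T** normalises carriage counts to per-locus frequencies summing to
  one, takes 1 − Σp² per marker and averages unweighted across markers.
* **Nei 1972** distances are computed between accessions from 0/1
  presence profiles (the qualitative-data convention of classical
  phenetics software); group-frequency profiles are equally valid
  inputs. Zero-overlap pairs have infinite distance; the `sentinel`
  policy returns `Inf` (and UPGMA then directs the user to the `cap`
  policy), `cap` substitutes a finite ceiling (default 10, far beyond
  empirically observed distances ≤ ~1.4). Missing markers are dropped
  pairwise.
* **UPGMA** merges the closest clusters with size-weighted average
  linkage; node height is half the merge distance, ties break by the
  lexicographically smallest pair of cluster labels (cluster label =
  smallest member), making output order-invariant. Newick branch lengths
  are parent-minus-child heights, so the serialisation is ultrametric by
  construction; tests recover random ultrametric matrices exactly and
  cross-check merge heights against average-linkage `hclust`.

**Ploidy comparison.** The published contrast is "average number of
alleles detected by a marker" between diploid and tetraploid groups.
Group-level distinct-allele counts saturate for small allele universes
(both groups eventually see every allele), masking the effect, so the
ANOVA response here is the per-marker *mean number of distinct alleles
per accession* within each group — what band patterns show — with the
group-distinct tally also reported (`response = "group_distinct"`
selects it). Observations are markers within groups, compared by
standard one-way ANOVA (`stats::aov`).

# Synthetic fixtures

Generators are pure functions of their parameters and a seed.

* `simulate_genome()` draws i.i.d. bases at a stated GC. Chance SSRs are
  *recorded in the truth table*, not rejected — rejection sampling would
  bias base composition.
* `plant_ssrs()` makes planted tracts non-extendable by forcing the base
  on each side to differ from the unit's cyclic continuation, so truth
  coordinates are exact; a self-check rescans the emitted sequence
  against the truth table.
* `inject_duplications()` appends copied regions as new contigs — the
  planted cause of `multiple` classifications. It is fully deterministic,
  so it takes no seed.
* `simulate_reads()` uses uniform starts, uniform substitution errors and
  a constant quality consistent with the error rate (Q40 when
  error-free).
* `simulate_genotypes()` draws allele copies per accession from each
  marker's frequency profile: diploids 2 copies, tetraploids
  2 + `tetraploid_extra_draws` (default 2, i.e. one extra genome copy
  pair — the natural ploidy effect; 0 makes the groups exchangeable).
  The default panel mirrors a realistic germplasm study: 17 diploid and
  30 tetraploid accessions, 37 markers, 3 alleles per marker. The default
  `carriage_model = "equal"` fixes uniform allele frequencies across
  markers: with per-marker random (Dirichlet) frequencies the two group
  observations of a marker are positively correlated, which makes the
  between-group ANOVA conservative and a type-I calibration check
  meaningless. The `dirichlet` model remains available for more realistic
  frequency spread.

What passing fixtures do **not** show about real data: interrupted or
compound repeats (out of scope by design), assembly errors and gaps,
non-uniform read coverage or indel errors, null alleles, stutter bands
and dosage effects in gels, and paralogy more subtle than literal
duplication. Results on real assemblies inherit the assembly's quality.

# Genome-size estimation

Canonical 17-mers (lexicographic minimum of k-mer and reverse
complement; strand handling is not observable in a frequency curve, and
canonical counting is the convention that makes shotgun reads of both
strands pool) are tabulated into a multiplicity histogram. Genome size =
(Σ occurrences above the error cutoff) / peak depth, the peak being the
multiplicity with the most distinct k-mers above the cutoff. The cutoff
defaults to the first local minimum of the histogram — the conventional
split between the sequencing-error spike at low multiplicity and the
coverage peak — and can be overridden. Even k is accepted but odd k
(default 17) avoids reverse-complement palindromes. Reported sizes use
decimal units with one decimal (Gb = 10⁹).

Read QC drops reads containing `N` or with more than 10 % of bases below
Q30 before counting; filtering is idempotent.

# Problem sizes used in the test suite

Fixture scales were chosen so the full suite characterises every
operation while remaining desk-scale: scanner/oracle equality on 100
random 10-kb sequences; a standard duplication fixture of ~100 designed
pairs with 20 duplicated regions (retaining exactly the 80 clean pairs);
genome-size recovery within 5 % from 10× error-free 150-bp reads of a
100-kb genome; and ANOVA calibration/power over 500 simulated panels of
20 + 20 accessions × 20 markers (balanced groups isolate the calibration
from group-size heteroscedasticity; the study-scale 17/30 panel is the
generator default elsewhere).

# Known limitations

* Perfect repeats only; no compound/interrupted SSR classes.
* Primer thermodynamics stop at nearest-neighbour Tm: no hairpin, dimer
  or 3′-stability scoring, no degenerate bases, no multiplexing.
* e-PCR is ungapped Hamming matching; it will not find sites split by
  indels, and it does not model annealing efficiency.
* Tetraploid allele dosage is not estimated; all diversity statistics
  treat bands as dominant markers.
* UPGMA assumes rate constancy (ultrametricity); no bootstrap support.
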