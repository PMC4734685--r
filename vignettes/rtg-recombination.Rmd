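---
title: "Calling LOH and recombination events in Return-to-Growth yeast diploids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling LOH and recombination events in Return-to-Growth yeast diploids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtgrecomb)
```

## The biological setting

A diploid budding yeast induced to enter meiosis replicates its genome,
forms Spo11-dependent double-strand breaks, and repairs them by
recombination between homologous chromosomes. If the cell is returned to
rich medium before the first meiotic division it re-enters the mitotic
cycle ("Return To Growth", RTG): it buds without re-replicating, and the
four chromatids segregate *equationally* — one chromatid of each original
sister pair to the mother cell, the other two to the daughter. In a
polymorphic hybrid (two parental haplotypes, here called P1 for the
reference-like parent and P2 for the divergent one, distinguished at tens
of thousands of SNP markers), this segregation converts recombination
events into blocks of homozygosity: loss-of-heterozygosity (LOH) tracts.

Genotyping a mother–daughter pair gives tetrad-like information. Each
marker's alleles distribute over the four chromatids of the pair:

* **2:2, both heterozygous** — the parental configuration;
* **2:2, opposite homozygous** — a *reciprocal LOH* (rLOH): the mother
  homozygous for one parent, the daughter for the other, the signature of a
  crossover (CO) whose recombinant chromatids segregated apart;
* **3:1** — heterozygous in one cell, homozygous in the other: a
  *non-reciprocal LOH* (nrLOH), the signature of gene conversion (GC);
* **4:0** — the same homozygous genotype in both cells: a pre-meiotic
  event, excluded from the analysis.

## Genotype calling

`call_genotypes()` assigns one of `HOM_P1`, `HOM_P2`, `HET`, `NO_CALL`
per marker from parental allele depths. A call requires coverage strictly
greater than 5 reads, and at least 2/3 of all reads carrying a parental
allele (relevant when a non-parental read count is supplied; allele
fractions are then computed over the parental reads). The thresholds are
deliberately asymmetric — `HOM_P1` above 95% P1 reads, `HOM_P2` above 75%
P2 reads, heterozygous inside P1 ∈ [0.25, 0.95] and P2 ∈ [0.05, 0.75] —
because alignment against the P1-like reference depresses the apparent P2
allele fraction. The homozygous cutoffs are strict inequalities and the
heterozygous ranges inclusive, so exactly one label applies to every depth
configuration. All cutoffs are configurable via
`genotyping_thresholds()`.

A small read-ratio bias can convert a single heterozygous marker into a
spurious homozygous call, so a genotype switch is only believed when it
affects at least 3 adjacent markers: `filter_short_runs()` reassigns
shorter homozygous runs embedded in heterozygous context (or touching a
chromosome end) back to `HET`. Two conventions had to be fixed here:

* `NO_CALL` markers are transparent — they neither break nor extend a run.
  The alternative (breaking runs at uncallable markers) would fragment
  tracts at random low-coverage positions.
* The rule is asymmetric by default: it guards against spurious
  *homozygosity* only, since the read-ratio bias works in that direction.
  A `symmetric = TRUE` option also collapses short `HET` islands inside
  homozygous tracts.

Because a reassignment can expose a neighbouring short run, the filter
iterates to a fixed point; it is idempotent and never creates a new
homozygous run. Markers inside coverage windows whose depth ratio departs
from the genome-wide median by ±25% (`coverage_windows()`, 10 kb windows)
are candidate copy-number variants and are excluded from LOH analysis.

## Tract assembly and event classification

`assemble_pair_tracts()` follows a two-step procedure on the markers
genotyped in both strains (4:0 and CNV markers set aside). First the 3:1
markers are ignored and contiguous 2:2-homozygous markers of the same
orientation are grouped into rLOH tracts; then all markers are regrouped
and maximal 3:1 runs of the same orientation become nrLOH tracts. A
consequence of the first step is that conversions *inside* an rLOH tract
(3:1 markers interleaved among the 2:2 markers) do not split it.

Tract coordinates span the first to last member marker; each event
breakpoint is reported as the open interval to the nearest flanking
retained marker of different genotype, which is all the genotypes can
resolve. A tract is *terminal* when it reaches the last genotyped marker
of its chromosomal arm and *interstitial* when flanked by
differently-genotyped markers on both sides. Terminal rLOH tracts reflect
one crossover, interstitial tracts two (`count_cos()`). Conversion tracts
are classified by adjacency (`classify_nrloh()`): abutting an rLOH
boundary → the conversion associated with that crossover (`CO_GC`);
inside heterozygous context or inside an rLOH tract → a non-crossover
(`NCO`); reaching the arm end without touching an rLOH →
`TERMINAL_NCO` (break-induced-replication-like). Closely spaced events can
be merged with `merge_events()`; the default 5 kb gap is a configurable
convention, and merges are logged rather than manually curated.

Two limitations are inherent to genotype space and are deliberately not
"fixed": two crossovers falling within a single marker gap can juxtapose
opposite-orientation tracts with no heterozygous marker between them (the
caller then correctly counts two crossovers per boundary side), and
overlapping conversion tracts can erase each other's markers, leaving no
recoverable trace. The test suite demonstrates both behaviours.

## The masked-crossover model

Under equational segregation a single crossover produces reciprocal LOH
only when its two recombinant chromatids segregate apart — half of the
time. With more crossovers on an arm the combinatorics change.
`enumerate_detection()` enumerates the full generative model exactly:

* four chromatids, two per homolog, sisters paired at the original
  centromere; the two "distal contents" P1 and P2 are each carried by
  exactly two chromatids at all times;
* crossovers applied proximal to distal, each choosing uniformly among the
  four chromatid pairs of *opposite current distal content* and exchanging
  content distal to the site;
* uniform equational segregation (4 outcomes), then each terminal
  homozygous run counts as one detected crossover and each interstitial
  run as two.

This yields 1/2, 5/8, 5/8, 41/64 for k = 1–4 and climbs towards 2/3.
Both an explicit exhaustive enumeration (4^k pair-choice sequences × 4
segregations, exact rational tallies) and an equivalent transfer-matrix
recursion over the six distal-content assignments are implemented; they
agree exactly, and a Monte-Carlo sampler of the same model
(`sample_detection()`) converges to them. The pair-choice rule matters:
the content-blind alternative (uniform over the four original
inter-homolog pairs, selectable as `rule = "inter_homolog"`) gives 0.375
at k = 2 and is provided only as a model contrast — it does not describe
RTG chromatid exchange.

`expected_detection_frequency()` averages the per-crossover detection
probability over a cell's per-arm crossover counts, and
`correct_counts()` converts observed counts into ranges: true crossovers
between observed/p and observed/(1/2) with p = 2/3 the asymptotic
detection bound, GC-associated crossovers as 81% of that (the observed
association rate, configurable), and non-crossovers as observed nrLOH
minus the GC-associated crossovers, pairing endpoints conservatively.
Counts are rounded to the nearest integer to match how such tables are
reported. Crossovers masked by co-segregation can be recovered directly
by sporulating an RTG diploid: `reveal_masked_cos()` finds intervals in
the parent's heterozygous regions where all four spores switch parental
content as two reciprocal pairs — the unique signature of a crossover
already present in the parent — while exchanges arising during the
sporulation itself involve only two spores.

## The simulator

`sim_config()` defaults emulate the hybrid the analysis is designed for:
sixteen yeast chromosomes with their centromere positions, markers at a
mean spacing of 191 bp (exponentially jittered), conversion tract lengths
exponential with mean 2.3 kb, 81% of crossovers with an adjacent
conversion, and a 10 kb crossover exclusion radius around each centromere
(meiotic DSBs are depleted there, which is why centromere-linked markers
stay heterozygous). Event numbers vary enormously between RTG cells;
absent a published per-cell distribution we draw per-arm crossover counts
from a Poisson with mean 0.75 and per-cell non-crossover counts from a
Poisson with mean 42, which reproduce the corrected per-cell totals of a
15-pair cohort on average; both are configurable, and the
paper-scale defaults can be replaced by small genomes for testing.

Gene conversion is modelled as a unidirectional content copy over whole
markers (no heteroduplex or intra-marker breakpoints — genotyping only
scores marker-level alleles). Crossover placement is uniform along the
arm outside the centromere exclusion; 4:0-generating pre-meiotic events
are off by default, matching their rarity. `simulate_rtg_pair()` records
complete ground truth (event list, chromatids, segregation choices) and
`replay_truth()` reproduces the genotypes bit for bit. `sporulate()` runs
a fresh meiosis on a diploid's two haplotypes and returns the four spores;
`simulate_pedigree()` iterates RTG rounds, under which homozygosity is
monotonically non-decreasing (all four chromatids agree at a marker once
both haplotypes do, so no event can undo fixed LOH). `sample_reads()`
adds Poisson depth and symmetric per-read error for genotyper testing.

What the simulator does *not* emulate: DSB hotspot landscapes and
crossover interference, alignment artifacts and mapping bias (the
asymmetric thresholds exist because of them, but reads are simulated
symmetrically), subtelomeric repeats, and aneuploidy or structural
variation beyond the coverage-window screen. Passing tests therefore
validate the calling logic and the segregation combinatorics, not
robustness to alignment pathologies on real data.

## Linkage scans

`lod_scan()` performs a single-marker scan: strains are grouped by
genotype class at each marker and the LOD is the log10 likelihood ratio of
class-specific means (Gaussian model; `n/2 log10(RSS0/RSS1)`) or
class-specific rates (`model = "binary"`) against no association. The
cohort is genotyped at dense markers, so interval mapping and imputation
add nothing. Markers monomorphic across the cohort are skipped. Genome-wide
significance uses `permutation_threshold()`: the 95th percentile
(conservative ceiling-index order statistic) of the maximum LOD over 1000
phenotype permutations. Perfect separation yields an infinite Gaussian
LOD; this is intentional (it exceeds any finite threshold) and the
bounded binary model is available when finite scores are preferred.

## Numerical and testing choices

Enumeration is exact; exhaustive mode is used to k ≤ 7 by default and the
transfer matrix beyond (both exact, cross-checked). The test suite
exercises study-scale behaviour on small genomes (two chromosomes of
300–400 kb, 1–2 kb marker spacing) so the full suite runs in about three
minutes: 500 simulated pairs for crossover-calling exactness and
detection-rate recovery, 200 pairs with conversions for
conversion precision/recall, 15 forced co-segregation pairs plus 15
random pairs for the masked-crossover accounting, and 200 null cohorts of
36 strains (1000 permutations each) for genome-wide type-I control, with
60 cohorts for causal-locus capture. Crossovers whose sites fall distal
of the last marker, or conversion tracts covering no marker, are
invisible in genotype space and are excluded from recall denominators;
this mirrors the resolution limit of any marker-based assay.
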