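---
title: "Measuring piRNA biogenesis defects: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring piRNA biogenesis defects: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pingpongr)
```

## The analysis in one page

Small-RNA libraries from fetal testis contain, on top of a large miRNA
background, 24–33-nt piRNAs of two provenances: *primary* piRNAs processed
from genomic piRNA clusters, biased toward uracil at position 1 (1U), and
*secondary* piRNAs produced when a PIWI protein loaded with a guide piRNA
slices a complementary transcript between guide positions 10 and 11. The
slicing geometry leaves two fingerprints: the new piRNA's 5′ end lies
opposite guide position 10, so the two 5′ ends overlap by exactly 10 bp;
and its 10th base is the Watson–Crick complement of the guide's first base,
so a 1U-biased guide population produces a 10A-biased responder population.
The upstream fragment of the cleaved transcript is occasionally captured
and sequenced; its coordinates are pinned on both sides (guide 3′ end and
responder 5′ end), so its length is guide length − 10 exactly.

The pipeline quantifies each of these signatures and the depletion of each
read class in a knockout library relative to wild type:

1. clip the 3′ adapter, keep reads longer than 10 bp (≥ 11 nt);
2. classify hierarchically: exact miRNA/ncRNA match first, then exact
   genome mapping (unique in-cluster hits define cluster-derived reads)
   and gapless ≤ 2-mismatch mapping to transposon consensus sequences;
3. normalize all counts per million miRNA-mapped reads and compare WT and
   KO per cluster and per transposon family (a fold ≥ 3 is flagged,
   matching the conventional 3-fold reference line);
4. compute length distributions, 1st/10th-position base fractions, 5′–5′
   overlap-distance histograms and byproduct adjacency links;
5. contrast depletion across the MILI-bound (24–27 nt) and MIWI2-bound
   (28–32 nt) size windows.

## Coordinate conventions

All intervals are 0-based half-open with an explicit strand. For an
interval `[start, end)`, the 5′ base coordinate is `start` on `+` and
`end − 1` on `−`; 3′ is the mirror. The overlap distance between a
plus-strand read with 5′ coordinate $s$ and a minus-strand read with 5′
coordinate $e$ on the same reference is $d = e - s + 1$, so a 10-bp 5′–5′
overlap gives $d = 10$. Pairs are counted all-vs-all with read
multiplicity within each consensus, which is the population-level
histogram the field plots; no collapsing to unique sequences is done.

The byproduct scan applies two adjacency rules to each 11–23-nt read with
consensus coordinates: **rule A** (required) — a same-strand 24–33-nt
piRNA starts exactly where the short read ends; **rule B** (recorded when
present) — an opposite-strand 24–33-nt piRNA's 3′ coordinate equals the
short read's 5′ coordinate. When both rules hold and the
downstream/guide pair has $d = 10$, the identity
`short length = guide length − 10` follows from the geometry alone; the
scan reports it as a measurement, and the dominant dual-rule weight falls
on 16 ↔ 26 and 19 ↔ 29. Coincidental dual-rule links (e.g. a degradation
fragment abutting a guide read) occur at singleton weight and are the
reason summaries are weighted by read multiplicity rather than link count.
Because both the A10 statistic's conditioning choices are defensible, the
scan reports the A10 fraction of downstream piRNAs both over all rule-A
links and over dual-rule links.

## Mapping: choices and guarantees

Mismatches are substitutions only — the gapless idiom of classic
short-read mappers, appropriate for 50-bp chemistry. The exact genome
mapper k-mer-seeds (k = 11, the minimum read length) on the read's first
k-mer and verifies candidates, returning *all* occurrences on both
strands; the consensus mapper returns a single best hit with a
deterministic tie-break (fewest mismatches, then consensus input order,
then smaller offset, then `+` before `−`), so family tables never
double-count a read. Reads of length ≥ 8·(max_mm + 1) take a pigeonhole
seed-and-verify path — one of max_mm + 1 disjoint read segments must align
mismatch-free — which visits candidates in tie-break order and is
therefore exactly equivalent to the full scan; both mappers are tested
against brute-force oracles. `N` matches nothing exactly and counts as a
mismatch in Hamming comparisons.

Three points the mapping hierarchy leaves open were resolved as follows.
miRNA/ncRNA matching is exact and full-length in either orientation
(mature miRNAs are a fixed catalogue; the normalization only needs a
countable class). Transposon mapping is applied to *all* non-miRNA reads,
not only genome-unmapped ones, because consensus-based piRNA analyses
must see reads that also map to genomic transposon copies. A cluster
assignment requires the unique genome hit to be *contained* in a cluster
interval; boundary-overlapping reads are not counted as cluster-derived.

## The synthetic generator

The generator emulates the statistical structure the analysis assumes: a
random genome (200 kb by default) carrying non-overlapping stranded
clusters, transposon-consensus insertions (each consensus verbatim at
each insertion, so transposon reads are genome-multi-mapping while
cluster reads are genome-unique) and embedded mature miRNAs. Reads are
drawn from a four-class mixture (40% miRNA, 20% cluster primary, 30%
ping-pong, 10% degradation) at a default depth of 200,000 per library.

* **1U bias** is imposed by choosing 5′ positions whose genomic base is T
  (in read orientation) with probability `u1_bias` = 0.85, so reads remain
  faithful reference substrings.
* **Ping-pong** reads come from 40 cleavage sites per family; each site
  draws a strand, a guide 5′ position (1U-biased) and a guide length from
  {26, 29}. Responders take the opposite strand with 5′ opposite guide
  position 10, lengths from a 29-peaked distribution; guides use the
  site's length. The responder's 10th base therefore complements the
  guide's first base mechanistically — A10 is an emergent property, not a
  painted-on label.
* **Byproducts** are captured per responder event with probability
  `p_byproduct` = 0.15, spanning the guide's 3′ coordinate to one base
  before the responder's 5′ start. Capture happens at cleavage, before
  any stability effect, and byproduct lengths (14–23 nt) fall outside the
  24–33-nt depletion windows — so knockout profiles leave byproducts
  essentially untouched, mirroring the biological observation that the
  16/19-nt species persist when mature piRNAs are depleted.
* **Degradation** reads are uniform genomic fragments of 11–35 nt, a null
  class that produces no ping-pong signal of its own. The 10% default is
  a free choice (real fetal libraries do not come with a stated
  unannotated fraction); it is deliberately nonzero so that background
  robustness is part of every test.
* **Depletion** multiplies the expected count of listed classes within a
  length window in the KO library: preset `hsp90a` thins all 24–33-nt
  piRNA classes to 1/3; preset `fkbp6` thins 28–32 nt only. Thinning is
  per read, so realized class counts stay within multinomial sampling
  error of depth × mix × factor.

Two consequences of this design matter when interpreting recovery tests.
First, the undepleted degradation background maps partly inside clusters
and insertions, so measured WT/KO folds under the uniform 1/3 preset sit
deterministically at ≈ 2.75–2.9 rather than exactly 3.0, and window
ratios sit slightly above 1/3; recovery is therefore checked against
truth-derived expectations, with the 3.0 figure recovered by the family
median within its 10% tolerance. Second, guide length and guide first
base are *per-site* draws, so statistics that depend on the guide-length
mix (the 24–27 vs 28–32 split, the responder A10 fraction) fluctuate at
the between-site scale — SD ≈ √(p(1−p)/S) with S = 120 sites — rather
than the read scale; tolerance bands in the tests account for this
clustering.

What the generator does **not** model: sequencing errors, PCR
duplicates, isomiRs, secondary-piRNA loading kinetics, expression
heterogeneity across clusters or families, or any chromatin/DNA
methylation layer. Passing tests therefore demonstrate that the analysis
recovers planted signal and planted parameters under realistic class
mixtures and background — not that it is robust to base-calling noise or
amplification artifacts, which real libraries add on top.

## Numerical and interface choices

* "More than 10 bp" is read strictly: the filter keeps length ≥ 11.
* Adapter clipping takes the leftmost read suffix matching an adapter
  prefix (exact match; the TruSeq small-RNA 3′ adapter by default).
  Reads with no adapter hit are dropped by default — under 50-bp
  chemistry every insert of small-RNA size runs into the adapter — with a
  flag to retain them.
* Per-million-miRNA normalization refuses a zero miRNA denominator
  (`ppr_input_error`): such a library is unusable for cross-library
  comparison. Fold changes with a zero KO count are reported `NA`, never
  infinite; the ≥ 3-fold flag is inclusive for determinism.
* Overlap histogram mode ties resolve to the smallest distance;
  empty histograms report an `NA` mode and zero counts rather than being
  omitted.
* All randomness derives from one seed; the reference and each genotype
  library use fixed offsets of it, so a WT/KO pair is reproducible byte
  for byte (FASTQ included) while remaining independent draws.
* Quality strings are a constant `I` (Phred 40): no stage consumes
  quality. RNA is represented in the DNA alphabet (T for U) throughout.
* Sizes used by the shipped checks: default-depth libraries (200,000
  reads) for signature and recovery runs, 50,000 reads for the byproduct
  geometry runs, 20,000–30,000 for distributional checks, and ≤ 1,000
  random reads against short references for the mapper-vs-oracle
  equivalences.

## Limitations

The mappers are desk-scale by design (no genome-scale indexing, no
spliced or gapped alignment, no mapping-quality model); references beyond
a few hundred kilobases call for a production aligner upstream, after
which the statistics layer applies unchanged to any table with the
documented columns. No significance testing is attached to the ping-pong
histogram (no z-score), and the byproduct A10 association is reported
descriptively, without a null model for coincidental adjacency.
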