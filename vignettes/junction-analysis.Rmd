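---
title: "Single-split-read junction calling and ageing analyses with juncture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-split-read junction calling and ageing analyses with juncture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(juncture)
```

## The problem and the model

Genome rearrangements in non-dividing cell populations are individually
rare and heterogeneous: a given breakpoint junction usually exists in one
cell of the population and is therefore supported by at most one
sequencing read. Multi-read structural-variant callers are blind to such
events by construction. `juncture` takes the opposite design: every
candidate junction is a single **split read** — one read whose two parts
align to two distant genomic locations as a soft-clipped primary
alignment plus one supplementary alignment — and stringency is recovered
not by requiring read support but by filtering each candidate hard.

A split read passes the filter when

* both aligned segments cover at least `min_segment_length` read bases
  (default **40 bp**),
* both segments carry mapping quality exactly `required_mapq` (default
  **60**, the maximum score emitted by BWA-MEM; other aligners use other
  maxima, hence the parameter), and
* each segment is clipped on exactly one side — its junction side. A
  segment clipped at both ends rejects the read.

The equality (rather than a minimum) on mapping quality, and the
one-sided-clip rule, deliberately trade sensitivity for specificity: on
rearrangement-free synthetic data the caller emits nothing (the package's
null-purity check), so every emitted junction is individually credible.
Reads with more than one supplementary alignment are discarded and
counted; only two-segment junctions are analysed.

Coordinates are 0-based half-open internally; SAM input is converted at
parse time and BEDPE output is 0-based. Each breakend is reported at the
**junction-proximal** reference base — the aligned base adjacent to the
segment's clipped side — and breakend pairs are stored in canonical order
(contig rank, then coordinate, ties by strand).

On a circular contig (the mitochondrial chromosome) a read spanning the
linearisation point aligns to both the contig start and end and would be
miscalled as a junction; such same-contig junctions with one breakend
within `end_window` of either contig end are removed. The window defaults
to one read length (126 bp), a value the package chooses since no
canonical figure exists.

## Breakpoint signatures

With both segments' read intervals expressed in original-read
orientation and ordered `[a1,b1)`, `[a2,b2)` with `a1 ≤ a2`, the overlap
`b1 − a2` classifies the junction:

* `> 0` — **microhomology** of that length: both genomic loci share the
  overlapping read bases, the hallmark of microhomology-mediated end
  joining (MMEJ);
* `= 0` — **blunt** joint, as left by canonical non-homologous end
  joining;
* `< 0` — non-homologous **insertion** of the gap length.

The signature is computed purely from CIGAR-derived read coordinates, not
by re-aligning reference flanks. This matters: the aligner absorbs
imperfect homology (including small indels inside the homologous tract)
into one alignment or the other, so the read-coordinate overlap remains
well-defined where a strict sequence comparison would not be. Spectra are
tabulated over signed lengths (negative = insertion, 0 = blunt, positive
= microhomology), with a display cap of ±20 bp mirroring the reporting
convention for microhomology lengths; raw values are always retained.

## Null models

`admixture_expectation()` asks what the junction distribution between
chromosomes would look like if free DNA ends joined at random. Per-contig
mapped-read counts are converted to proportions `p_i`; each junction's two
ends are drawn independently, so the closed-form expectation for `n`
junctions is `n·2·p_i·p_j` for `i ≠ j` and `n·p_i²` on the diagonal. One
thousand Monte-Carlo simulations are run alongside (the package treats
end-drawing as with-replacement sampling; a permutation-of-ends variant
would converge to the same expectations). `simulate_random_junctions()`
provides matched-size uniformly placed junction sets for the intersection
analyses; only nuclear contigs are used and simulated there.

`validation_harness()` re-creates the pipeline's validation design:
random 100 bp fragments *of the reference itself* are inserted at random
loci, each creating two novel junctions (one per fragment flank), carrier
reads are synthesized and the complete calling pipeline scored against
the truth with a ±5 bp breakend tolerance (chosen to absorb
microhomology-induced coordinate ambiguity). Because the package
synthesizes lossless, error-free alignments, the harness recovers 100% of
planted junctions with zero false positives; with an external read
simulator and aligner in the loop, sensitivity would drop (alignment
losses), while the zero-false-positive property is the one that matters
for the filter's credibility.

## Hotspot matrices

Junctions are binned into `window_size` (default 20 kb) window-pair
count matrices, one cell per (window, window) combination across all
contig pairs, each junction incrementing exactly one canonical cell. The
old/young (e.g. Day-5 over Day-0) element-wise ratio highlights
age-associated enrichment; a pseudocount (default 1) regularises empty
young cells — with pseudocount 0 zero-denominator cells are masked rather
than infinite. The **global hotspot score** of a bin is the mean of its
symmetrised ratio row across every window genome-wide, so a bin that
gains junctions to many *remote* partners scores high, while a purely
local cluster does not. The bin's own diagonal cell is included by
default (toggleable); with ~150 bins its effect on the mean is
negligible. `coverage_ratio()` provides the matching per-bin median
read-depth ratio as a control: a hotspot driven by repeat expansion would
gain depth, a junction-formation hotspot does not.

## Ageing metrics

JPMR and IPMR are junctions and indel-bearing reads per mapped read.
Genome-wide metrics are normalised to the **median** at Day 0 per
genotype; feature-level JPMR (junctions with a breakend within feature
± 500 bp, half-open windows) is normalised to the Day-0 **mean** —
the two conventions deliberately follow the respective analyses they
implement. Coding-region depletion is tested per replicate against a
matched-size simulated set with a one-sided Mann-Whitney U (observed <
expected); complete separation of 8 vs 8 replicates gives the minimal
statistic U = 0. A junction "intersects" a feature when **either**
breakend falls inside (switchable in principle to both-breakends; the
either-breakend reading is the package default since whole-junction BED
intersection hits on any overlap). 3'UTR outliers are genes whose
junction count strictly exceeds the population mean + 2 population
standard deviations (divisor *n*); a zero-variance population flags
nothing.

## The synthetic-data generator

The generator emulates the structure of the study data so the pipeline
can be tested end to end without external sequencing:

* **Genome** — three 1 Mb nuclear contigs plus a 20 kb circular
  mitochondrial stand-in, GC 0.36, densely annotated with gene models
  (5'UTR–CDS–3'UTR, one gene per ~4 kb, matching a compact yeast-like
  genome) and tRNAs.
* **Events** — microhomology is planted by *editing the reference* so
  both loci genuinely share the seed k-mer at junction-adjacent
  positions; blunt chimeras are exact flank concatenations; insertion
  chimeras carry novel bases that extend neither flank. The classifier is
  therefore tested against real sequence structure, not labels.
* **Reads** — each event yields one chimeric carrier read (events are
  heterogeneous, as in aged non-dividing populations) emitted as
  already-aligned SAM (soft-clipped primary + supplementary with mutual
  `SA:Z` tags), so tests require no external aligner and are immune to
  aligner version drift; `write_fastq()` exists for users who do want to
  run an aligner. Reads are single-end 126 nt by default, quality strings
  constant, base-call errors 0 unless configured.
* **Series** — `ageing_design()` defaults to six daily timepoints × eight
  replicates; per-day junction and indel counts are Poisson draws at the
  configured per-mapped-read rates (the study-scale JPMR magnitude is
  ~3×10⁻³; fixture rates are scaled up with depth scaled down so the same
  signal is visible at desk scale). A coding-depletion factor thins
  CDS-hitting junctions by rejection sampling to plant intersection
  signal.

What the generator does **not** model: paired-end insert sizes, empirical
base-error and quality profiles, alignment ambiguity in repeats, PCR
duplicates. Passing tests therefore demonstrate the correctness of the
pipeline's arithmetic and logic — CIGAR inversion, filtering, signature
classification, binning, statistics — not robustness to aligner
idiosyncrasies on real libraries.

## Numerical and design choices

* Rank-sum tests use the exact distribution for small tie-free samples
  (min n ≤ 10) and the tie-corrected normal approximation otherwise.
* Paired t-tests on zero-variance differences are reported as degenerate
  (t = 0, p = 1 when all differences are zero) rather than erroring.
* "No clipped alignments at both ends" is interpreted **per segment** —
  each alignment must be clipped on exactly its junction side — because
  that guarantees the two segments jointly tile the read, making the
  signature well-defined; the mapping-quality criterion is applied to
  both alignments. Both choices are configurable or documented where
  ambiguity exists.
* All randomness flows through explicit seeds; identical seeds give
  byte-identical outputs (FASTA, SAM, BEDPE, TSV).

## Problem sizes used in the checks

The package's acceptance checks run on a 3 × 1 Mb + 20 kb genome with
200 planted junctions (round-trip), ten 10⁵-read clean fixtures (null
purity), a 10⁴-read mixed fixture (filter oracle against brute-force
re-evaluation), 10⁴ junctions × 1000 simulations (admixture), 20 seeded
six-day series (hotspot recovery), 8 × 500-junction replicate sets with
depletion factor 0.5 plus 100 null runs (depletion behaviour), and a
6-day × 8-replicate doubling-rate series (JPMR monotonicity). These sizes
were chosen to give the statistical tests unambiguous signal while
keeping a full run on a single CPU in minutes.

## Known limitations

* One junction per read: reads with two supplementary alignments
  (three-segment rearrangements) are counted and discarded.
* The caller does not assemble or cluster junctions across reads — by
  design; recurrence analyses happen downstream on binned matrices.
* Microhomology length is bounded above by read length, and signatures
  at the very ends of reads are unrecoverable under the 40 bp segment
  minimum (the truth tables flag such planted events).
* The GFF3/BED interfaces assume the simple feature vocabulary used here
  (CDS, UTRs, tRNA, gene); arbitrary annotation hierarchies are not
  parsed.
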