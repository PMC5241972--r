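---
title: "Assembly reconciliation and tandem-repeat analysis with recweave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembly reconciliation and tandem-repeat analysis with recweave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recweave)
library(dplyr)
```

## The problem

Draft genome assemblies of the same individual built from different read
technologies and assemblers have complementary strengths: short-read
assemblies tend to be accurate but fragment at repetitive loci, long-read
assemblies span repeats but may have fewer scaffolds anchored to
chromosomes. In highly repetitive genomes — the motivating case is a
teleost genome in which tandem repeats (TRs) cover roughly a tenth of the
assembly and dinucleotide repeats dominate — short-read contigs break
preferentially *at* TR loci, so the gaps of one draft often correspond to
sequence that another draft assembled through.

recweave implements a reconciliation workflow that weaves several drafts
into one improved assembly, guided by two external sources of truth: a
genetic linkage map (markers with chromosome-scale group and map position)
and whole-genome multiple alignments of the drafts (MAF blocks). Around it
sit the analyses that motivated it: a score-thresholded TR detector,
heterozygous-TR calling from filtered indel calls, and attribution of
contig termini to the annotations they fall in.

## The reconciliation procedure

One draft is designated the **skeleton**; its sequences and their order are
followed throughout. The passes run in a fixed order:

1. **Containment removal.** A sequence aligning over at least 99% of its
   length inside a different sequence at identity strictly above 98%
   (both configurable) is removed. Self-alignments are an input (any
   whole-genome aligner produces them); shorter sequences are processed
   first so a container is never consumed before it is used.
2. **Linkage-conflict splitting.** A scaffold whose placed markers belong
   to more than one linkage group is misassembled. For each transition
   between maximal same-group marker runs, the scaffold is split: the kept
   pieces run from the scaffold start to the end of the flank of the last
   marker of one run, and from the start of the flank of the first marker
   of the next run to the scaffold end. The middle segment — whose true
   group is unknowable — is discarded and logged. A two-group conflict
   therefore yields three pieces: two kept, one discarded.
3. **Length filtering.** Sequences shorter than 1000 bp are removed
   (strictly shorter; a 1000-bp sequence is kept).
4. **Gap closing.** For every N-run of the skeleton that lies wholly
   inside one alignment block with at least one aligned skeleton base on
   each side, the donor sequence opposite the gap columns replaces the
   run. Donor choice: the first assembly in the configured priority list
   whose filling is N-free; otherwise the filling with the fewest Ns
   (ties: priority rank, then longer filling, then name). A filling that
   still contains Ns, but fewer than the gap, *shrinks* the gap and is
   recorded separately. Because the replaced column run includes adjacent
   alignment gap columns, a wrong gap-size estimate (more or fewer Ns than
   truly missing bases) still restores the donor's sequence exactly.
   Non-gap skeleton bases are never touched.
5. **Scaffold joining.** Two skeleton scaffolds are joined when a single
   donor scaffold aligns within a terminal window (default 5000 bp) of the
   first scaffold's end and the second scaffold's start, on a consistent
   strand and in consistent order; the donor's intervening sequence fills
   the junction. Competing proposals are ranked by tightness (filler
   length plus the distance of the aligned blocks from the termini), each
   scaffold end participates in at most one join, circular proposals are
   refused, and — when marker placements are available — joins that would
   unite scaffolds carrying different linkage groups are refused. Joins
   requiring a skeleton scaffold to be reverse complemented are not
   attempted; orientation is the anchoring step's job.

Gap filling changes coordinates downstream of each filled gap, so the
engine keeps an offset ledger per sequence and shifts the remaining block
coordinates through it before the joining pass; blocks that straddle a
modified gap are dropped from joining.

## Anchoring to the linkage map

Scaffolds whose markers all belong to one group are ordered within that
group by the **median** map position of their markers (the choice of
median over mean is a deliberate robustness decision; with noise-free
placements they agree). Ties break by scaffold length (longer first), then
name. Orientation is decided by a pairwise vote: every unordered pair of
same-scaffold markers with distinct map positions and distinct scaffold
positions votes "reverse" when scaffold order disagrees with map order; a
scaffold is reverse complemented only when strictly more than half of the
decidable pairs vote reverse, so an exact tie — and any single-marker
scaffold — keeps its orientation. Adjacent scaffolds are joined with
exactly 100 Ns. Markerless scaffolds are reported unplaced, as are
(pathological) scaffolds still touching several groups after splitting.

## Tandem-repeat detection

A repeat candidate is a region scored by wraparound dynamic programming
against the infinite periodic extension of its unit, anchored at phase 0
with a free end phase: match +1, mismatch −5, indel −5 (both penalties
configurable), minus the unit size. A perfect repeat of length $L$ with
unit size $k$ thus scores $L-k$, which pins the thresholds: at the default
minimum score of 12 (compared with $\ge$), the shortest accepted perfect
repeats are exactly 13, 14 and 15 bp for unit sizes 1, 2 and 3 — i.e. 13
mononucleotide, 7 dinucleotide or 5 trinucleotide units. Units run from 1
to 50 bp by default.

Operational details that make detection deterministic and fast:

* **Anchors.** A candidate anchor $(a, k)$ uses the unit written at
  $[a, a+k)$ and must be followed immediately by a period-$k$ self-match
  run of length $\min(4, \text{min\_score})$. A perfect tract anchors at
  its first position, so perfect repeats above the threshold are always
  found; a tract with an error within the first few post-unit positions is
  reported from the next clean anchor instead.
* **Bounded extension.** Extension from an anchor stops when the running
  best falls more than $25 + 2k$ below the best seen, or when the residual
  sequence cannot reach the threshold nor improve the current best. Both
  rules are exact or conservative for the repeats of interest and are part
  of the operational definition.
* **Candidate generation.** The production detector seeds candidate
  windows from period-$k$ self-match runs and enumerates anchors inside
  them (Rcpp); an independently coded exhaustive scanner
  (`detect_trs_exhaustive()`) enumerates every anchor of every position
  and is used in the test suite as a brute-force oracle. A third, pure-R
  implementation of the scoring (`score_repeat()`) cross-checks both and
  is itself validated against a fixpoint-relaxation reference in the
  tests.
* **Canonicalization.** An N terminates extension (no repeat spans an N);
  internally periodic units are suppressed in favor of their primitive
  unit; among overlapping candidates the highest score wins, ties broken
  by smaller unit size, then leftmost start; units are reported as their
  lexicographically least rotation on the strand as written.

The separate "at least 20 bp, units 2–6" definition used for repeat-library
work is available as the preset `tr_config_library()`.

## Variants, heterozygous repeats, and contig termini

Variant records are classified from allele shape (SNP, MNP, pure indel
after trimming the shared affix, otherwise complex), filtered at quality
strictly above 20 and — for heterozygous analyses — genotype 0/1 with depth
of at least 5 reads. A repeat is called heterozygous when at least one
filtered indel's REF span overlaps it; the headline quantity is the het
fraction among all repeats. Promoters are the 2000 bp immediately upstream
of a gene on its strand, clipped at sequence boundaries.

Contig termini are the 1-bp reference positions of the first and last
*aligned* contig bases, taken only from primary alignments with mapping
quality at least 3; a clipped end emits no terminus. Attribution reports,
per annotation track, the percent of termini overlapping it — classes are
deliberately non-exclusive, with an explicit "no annotation" residual.

## The synthetic fixture generator

All end-to-end guarantees are demonstrated on seeded, truth-known
fixtures (`fixture_config()`, `simulate_genome()`, `simulate_diploid()`,
`fragment_assemblies()`). Defaults emulate the motivating genome: TR
density 10% of the assembly with a dinucleotide-dominated unit mix, SNP
rate 4.07e-3, indel rate 0.98e-3, 21% of repeat loci heterozygous with
whole-unit indels. Fragmentation plants breaks at TR loci (probability 0.1
per repeat by default) plus a low random rate for the short-read-like
drafts, while the long-read-like draft breaks only at planted TE-like
duplicates; a fraction of skeleton breaks separate scaffolds (junctions
for the joining pass) and the rest leave N-gaps. By default the estimated
gap length equals the true missing length; a range can be configured, and
the gap-closing engine is tested against both. Alignment blocks are
emitted from truth coordinates — one block per skeleton gap and a pair of
blocks per junction-spanning donor contig — which keeps the tests hermetic
(no aligner run) while exercising exactly the block geometry the engine
consumes. A random subset of skeleton scaffolds (those with at least two
markers and no junction involvement) is reverse complemented so anchoring
has real orientation signal to recover.

What the generator does **not** emulate: sequencing errors and read-level
artifacts (drafts are exact substrings of the truth), misassemblies other
than linkage chimeras, donor drafts with their own N-gaps (donors are
emitted as contig sets), diverged repeat copies, and GC or composition
bias (background is uniform). Passing the recovery suites therefore shows
the bookkeeping and decision rules are correct under clean evidence, not
that the method is robust to noisy alignments — on real data the quality
of the input MAF dominates.

## Problem sizes and numerical choices in the test suite

The recovery suite uses a 1-Mbp, 2-chromosome fixture with three drafts
(roughly 200 gaps and 50 junctions), on which reconciliation must close
100% of gaps whose locus is intact in the long-read-like draft, make every
planted join, leave every non-gap base untouched (checked by verbatim
substring comparison of all reconciled contigs against the truth genome),
and anchoring must recover the true scaffold order (rank correlation 1)
and every orientation. Detector–oracle equivalence is checked on 200
random sequences of up to 200 bp with units up to 20 (a third with planted
clean or mutated repeats); interval intersection against an all-pairs scan
on 1000 intervals; N50 against a definition-driven oracle on 1000 random
multisets. Planted-repeat recall (at least 0.95 required; 1.0 observed) is
measured on a 100-kbp genome at 10% TR density. These sizes were chosen as
the smallest at which every phenomenon of interest (chained joins, flipped
scaffolds, unclosable gaps) actually occurs in the fixtures.

## A worked example

```{r example, eval = FALSE}
cfg <- fixture_config(seed = 7, genome_len = 2e5, n_chromosomes = 2,
                      te_count = 8, break_at_tr_prob = 0.15,
                      scaffold_break_prob = 0.3)
truth <- simulate_genome(cfg)
fx <- fragment_assemblies(truth, cfg)
pl <- resolve_placements(fx$hits, fx$map)
rec <- reconcile(fx$drafts, fx$maf,
                 reconcile_config(fx$skeleton,
                                  donor_priority = fx$donor_priority),
                 map = fx$map, placements = pl)
glance(rec)
bind_rows(assembly_stats(fx$drafts[[fx$skeleton]]),
          assembly_stats(rec$assembly))
```

## Known limitations

* Joins are only attempted end-to-start in the skeleton's written
  orientation; junctions requiring a skeleton flip are left to anchoring.
* Gap closing does not stitch flanking evidence across *separate* blocks;
  a gap must sit inside one block with anchored flanks.
* The TR detector's anchor and extension-abandonment rules trade a small
  amount of sensitivity at heavily mutated repeat boundaries for
  determinism and speed; the exhaustive scanner shares them, so the
  equivalence tests validate the seeding, not those rules themselves.
* Identity/coverage for containment are taken from the input alignments
  at face value; the package validates but never recomputes alignments.
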