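---
title: "Methods: transcriptional slippage and RNA editing in plastomes"
author: "chloroslip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcriptional slippage and RNA editing in plastomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chloroslip)
```

## The problem

Chloroplast (plastid) genomes are circular molecules of 120–210 kb with a
quadripartite layout: two identical inverted repeats (IRa/IRb) separating a
large and a small single-copy region (LSC/SSC). Their transcripts deviate
from the DNA template in two systematic ways. First, C-to-U **RNA editing**
changes specific cytidines to uridines post-transcriptionally, often
restoring conserved amino acids, creating start codons (ACG→AUG) or stop
codons. Second, the plastid-encoded RNA polymerase, a bacterial-type enzyme,
stutters at mononucleotide simple sequence repeats (SSRs), producing
transcripts with one repeat unit more or fewer than the template —
**transcriptional slippage** (TS). Deep RNA-seq makes both phenomena
measurable as, respectively, base substitutions and single-base indels in
reads aligned to the plastome.

chloroslip implements this measurement pipeline end to end, plus the two
comparative analyses that usually accompany it (SNV/indel comparison of
near-identical plastomes, and heteroplasmy assessment of an offspring
against parent-distinguishing variants), and a synthetic-data generator so
that every stage is testable against known truth without any downloads.

## Definitions and estimators

For an SSR locus, a read is **spanning** if it covers the full run plus at
least `min_anchor` (default 1) non-run bases on each side; anything less
leaves the run length ambiguous. A spanning read is a **slippage read** if
it carries at least one indel whose left-normalized position falls within
`[run_start - 1, run_end]` and whose bases consist of the run motif; indels
of other bases in that window are reported separately (`other_indel_reads`)
and never attributed to slippage. The **TS frequency** of a locus is
`indel_reads / spanning_reads`. Reads are counted once per locus and
classified by their net length change; loci with zero spanning reads are
flagged rather than divided. The customary phrasing of this denominator,
"total aligned reads", is ambiguous about partially overlapping reads; we
use spanning reads, the interpretation under which the run-length change of
every counted read is well defined.

An **editing site** is called where the reference base is C under a
plus-strand gene model (or G under a minus-strand one — a transcript C-to-U
edit appears as genomic G→A there), total depth is at least `min_depth`
(default 20) and the **editing level** — T/(C+T), or A/(G+A) on the minus
strand — is at least `min_level` (default 0.05). The denominator is the
edited-plus-unedited read count, matching the U/C ratio convention in which
editing levels are reported; other bases at the site are treated as
sequencing error. Both strands are tested at intergenic positions. U-to-C
candidates are screened with the same rule and reported in a separate
table; none are expected in chloroplasts. Levels are binned at exact thirds
(low < 1/3 ≤ moderate ≤ 2/3 < high), with moderate closed on both ends; a
31% site is therefore "low" here even though verbal accounts sometimes
round it into the moderate bin.

The slippage–length relationship is summarized by ordinary least squares of
the **per-length mean** TS frequency on SSR length, not per-locus points,
because that is the relationship the field plots (mean ± SE per repeat
length) and attaches an R² to. Lengths represented by a single locus lack a
standard error and are excluded by default (`exclude_singleton_lengths`).

## Consequence annotation

Codon annotation uses the bacterial/plastid genetic code (NCBI table 11),
with alternative initiation codons rendered as M only at codon 1. Effects
are `synonymous`, `nonsynonymous`, `start_gain` (ACG→AUG at codon 1) and
`stop_gain`. Frameshift consequences of ±1 indels are predicted by building
the mutant transcript (editing applied first, strand-aware), translating
from the gene's start to the first in-frame stop, and scanning past the
reference stop into downstream sequence when the shift removes it. A
variant protein is reported without its terminal stop; the longest common
N-terminal prefix with the reference protein is reported alongside. When
the read-through terminates exactly at a downstream gene's own stop codon
the downstream gene is named as a fusion partner; a stop inside an
intergenic spacer is not a fusion.

The package ships a small **synthetic psbF–psbL operon analog**
(`inst/extdata/psbF_operon_synthetic.*`, labelled synthetic) engineered by
constraint search so that the canonical frameshift arithmetic is fully
exercised: a 39-aa reference protein with a 9-bp poly-T run abutting the
editing site, a +1 U-insertion yielding a 42-aa variant sharing 27
N-terminal residues, and a −1 U-deletion reading through to the downstream
gene's stop, an 85-aa fusion protein. The real operon lives in accessioned
genomes this package deliberately does not bundle; the analog reproduces
the structure of the outcome, not the organism's sequence.

## Genome comparison

`align_plastomes()` produces an end-to-end alignment under unit mismatch /
affine gap costs (mismatch 1, gap open 2, gap extend 1) — a scoring under
which one 2-bp gap (cost 4) is preferred to two 1-bp gaps (cost 6), so
adjacent gap columns merge into single events the way indel counts are
reported. Short pairs are aligned directly by Needleman–Wunsch
(`Biostrings::pairwiseAlignment`); long pairs are anchored on collinear
unique shared 31-mers (longest-increasing-subsequence filtered) and the
inter-anchor segments aligned the same way, which is exact for isolated
variants between anchors. Inputs must share rotation and orientation;
rotation normalization is the caller's job and lengths differing by more
than 5% are rejected with that hint. Variants are called per alignment
column, indels left-normalized in homopolymer context, SNVs classed as
transitions (A↔G, C↔T) or transversions. The comparison runs on the full
linearized genome including both IR copies, so a variant present in both
IRs yields two records.

Heteroplasmy is assessed per parent-distinguishing variant as the fraction
of offspring reads carrying the maternal (reference) allele. The verdict is
`maternal` only if every adequately covered variant has a maternal fraction
of at least `1 - minor_fraction`; `mixed` if any site shows both alleles
above `minor_fraction` (default 0.01 at `min_depth` 1000, sensible for the
several-thousand-fold depths of organellar sequencing and configurable for
anything shallower).

## The synthetic-data generator

`build_plastome()` emulates the features the callers consume, with a truth
table: a circular genome of configurable quadripartite dimensions in which
IRb is the exact reverse complement of IRa (with the SSC junction bases
forced off mutual complementarity, so the maximal reverse-complement pair
is exactly the planted IR); planted mononucleotide (and
optionally dinucleotide) runs of 8–16 bp whose flanks are forced off the
run base; protein-coding genes on both strands (random sense codons between
a start and stop); and one C-to-U editing site per request, placed at codon
position 2 of a C codon inside the gene. The background is scrubbed —
generation followed by deterministic point substitutions — until no
mono- or dinucleotide run of ≥ 8 bp exists other than the planted ones, so
the truth table is exhaustive and SSR recovery can be asserted exactly.

`simulate_reads()` draws uniform read starts, then applies, per read:
editing at each covered truth site with probability `true_level`
(strand-reflected); at most one ±1 same-base indel per spanning read per
SSR with probability `true_indel_prob` (insertion with probability
`insertion_fraction`, breakpoint uniform in the run so left-normalization
is exercised); and uniform substitution errors at `error_rate`. Reads whose
slippage insertion would shrink the reference span below the spanning
window are shifted one base left, so the simulated spanning set coincides
exactly with `scan_ssr_indels()`'s and the TS estimator is unbiased. The
default "sharp" error profile keeps errors out of SSR runs (±1) and editing
sites so truth-recovery bounds stay exact binomial statements; the
"realistic" profile lifts that restriction. Reads are emitted in genome
orientation with a transcript-strand tag, the way a spliced mapper presents
minus-strand genes, and written as minimal SAM 1.6.

No generative model of slippage is established in the literature — only
observed frequencies, from 0 up to roughly 74% of transcripts at long
runs, with about 22% at a 9-bp poly-U and about 12% at the psbF run. The
default `slip_model`, `p(L) = 0.05 · (L − 7)` capped at 0.9, is a linear
stand-in chosen to cover that observed range over 8–16 bp runs, and is
documented as a stand-in: tests that rely on it assert estimator recovery
and monotonicity, not the shape of nature's p(L). Editing levels default to
the high-level regime typical of published tables; the per-base error
default is 0.001. What passing tests show is that the estimators recover
planted truth at the simulated depths; they cannot show robustness to
mapper artifacts, strand bias, splice junctions or coverage
heterogeneity, which the simulator does not model.

## Numerical and design choices

* Coordinates are 1-based inclusive everywhere, the R/Bioconductor
  convention; BED output converts to 0-based half-open at the boundary.
* SSR threshold: "longer than 8 bp" readings conflict with histograms that
  list 8-mers; `min_total_length = 8` (≥ 8 bp) reproduces such histograms
  and is the default. Only motif sizes 1–2 are scanned; dinucleotide runs
  are counted in whole units, and a "dinucleotide" motif that is a
  homopolymer pair is reported as a mononucleotide run only.
* Circularity: a run spanning the origin is reported once, attributed to
  its leftmost base, via a doubled-sequence scan with wrap deduplication.
  IRs spanning the origin are not searched; plastome assemblies
  conventionally start in the LSC.
* IR ties are broken toward the smallest start coordinate; the reported
  pair is maximal under single-base extension because maximal exact seed
  chains cannot be extended.
* A spanning read with equal insertions and deletions (net 0) appears in
  the net-length histogram but not in `indel_reads`, keeping
  `indel_reads == insertion_reads + deletion_reads`; the default simulator
  never produces such reads.
* `min_mapq` 20 and `min_baseq` 13 are conventional and config-exposed;
  no published values exist for them in this context.
* Problem sizes in the test suite: estimator-recovery properties use 100
  seeded replicates of ~19k–30k reads (≥ 1000 spanning reads per locus,
  deep coverage for the regression genomes); oracle-agreement properties
  use ≥ 200 random instances per operation; the genome-scale checks use a
  synthetic 151,281-bp plastome with published dimensions. These sizes were
  chosen so the binomial 3-SE bounds and R² thresholds hold with large
  margin under the stated models.

## Limitations

* The slippage model plants at most one ±1 indel per read per locus;
  multi-unit slips exist in nature and would appear in `net` histograms at
  |Δ| ≥ 2 but are not simulated by default.
* `detect_inverted_repeats()` assumes exact IR copies (true of the
  quadripartite definition) and does not search origin-spanning IRs.
* Heteroplasmy assessment of insertion variants matches exact inserted
  strings at the recorded pileup position; in long homopolymers the
  supporting counts are conservative.
* The pipeline consumes alignments as given: no re-alignment, duplicate
  marking or paired-end logic.
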