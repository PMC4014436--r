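---
title: "Methods: gene-family networks, retention profiling and compaction statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-family networks, retention profiling and compaction statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phycocomp)
```

## The question the package addresses

When a free-living alga becomes an obligate parasite, its genome usually
shrinks. The interesting question is *how*: does the parasite lose whole
metabolic capabilities (fewer pathways), or does it keep its metabolism
and instead thin out gene *families* and pack genes more densely?
`phycocomp` implements the comparative analyses needed to tell these
apart for a focal compact genome against free-living relatives:

1. **Gene-family complexity** — a sequence-similarity network over the
   predicted proteomes, whose connected components approximate gene
   families; per-family member counts yield contraction/expansion calls.
2. **Metabolic retention** — presence/absence of reference pathway genes
   (KEGG-ortholog- or GreenCut2-style lists) across proteome, genome and
   transcriptome, with per-pathway retention fractions and a test for
   whether loss concentrates in particular pathways.
3. **Family expansion detail** — GH18 chitinase motif scanning, because a
   chitinase amplification is the canonical counter-example of gain under
   parasitism (digesting the chitinous barriers of an insect host).
4. **Compaction statistics** — N50, GC, coding density, exon/intron
   geometry, and genome size from read coverage.
5. **Synteny** — reciprocal-best-hit anchors chained into colinear
   clusters, to quantify how much gene-order conservation survives.

A synthetic-data module generates three-taxon datasets with known ground
truth so that the complete pipeline is testable without any downloads.

## The similarity network and its edge criteria

Vertices are proteins; an undirected edge joins two proteins only if
**both** directed local-alignment hits satisfy all four criteria:

| criterion | default | boundary |
|---|---|---|
| E-value | < 1e-10 | strict |
| percent identity | > 20 | strict |
| identical residues / shorter sequence | ≥ 0.20 | inclusive |
| alignment length | > 20 aa | strict |

The strict-versus-inclusive readings follow the natural-language forms of
the criteria ("less than", "at least", "greater than"); the boundary
behaviour is pinned by tests. Relaxing any one threshold can only grow
the edge set (a tested monotonicity property).

Internal alignments are Smith–Waterman local alignments (BLOSUM62, gap
open 11, extend 1 — classic protein-BLAST defaults) computed with
`Biostrings::pairwiseAlignment`. E-values use the Karlin–Altschul form
`E = K·m·n·exp(−λS)` with the gapped BLOSUM62 constants λ = 0.267,
K = 0.041, m the query length and n the total residue count of the
subject taxon's proteome. Identity is counted over aligned columns; gap
columns count toward alignment length but never toward identity. The
aligner is validated against an independent exhaustive affine-gap dynamic
programming oracle (with full co-optimal traceback) on short sequences.
Per ordered pair only the best HSP is kept (lowest E, then most
identities); self-hits are dropped, since self-loops cannot affect
components.

Connected components (singletons included) are ordered by decreasing
size, ties by lexicographically smallest member. Representation calls
against a focal taxon with comparator taxa are:

* **contracted**: `1 ≤ focal < min(comparators)`
* **absent-in-focal**: `focal = 0` and every comparator ≥ 1
* **expanded**: `focal > max(comparators)` and every comparator ≥ 1
* **balanced**: everything else

We require the focal count to be below (or above) **every** comparator,
not just one; with a single comparator the definitions coincide, and with
two the both-comparator rule is the conservative reading of "lower
representation than its relatives". Functional categories are assigned
per component by majority vote over annotated members (ties are
`ambiguous`, no annotations `unknown`) — a deterministic stand-in for
manual curation — and a category blacklist lets the user exclude, e.g.,
photosynthesis-related components from a contraction census.

## Presence/absence profiling

A reference gene is *present* in a dataset iff its best hit E-value is
strictly below the dataset's threshold: 1e-10 for protein-versus-proteome
and 1e-5 for protein-versus-genome/transcriptome searches (translated
searches are ingest-only; the package does not implement a TBLASTN
engine). A gene found in none of the three datasets is *absent* — the
`overall_present` flag is exactly the OR of the three dataset flags, an
invariant asserted in tests. Strict inequality at the threshold was
chosen for consistency with the network criteria's "E-value < 1e-10".

Retention is reported per pathway label and overall. Genome/transcriptome
congruence (both / genome-only / transcriptome-only) is reported over two
denominators — all reference genes and only overall-present genes —
because the natural denominator is ambiguous. Whether losses concentrate
in a focus group of pathways is tested with a two-sided Fisher exact test
on the lost/retained × focus/other table; the choice of test is this
package's decision (any exact 2×2 test would do), and the p-value is
checked in tests against direct hypergeometric enumeration. Degenerate
tables (an empty margin) report p = 1 with a warning rather than failing.

## Chitinase motif scanning

GH18 chitinases carry the catalytic motif `DxxDxDxE` (three aspartates
and the catalytic glutamate at fixed offsets, wildcards free). The
scanner reports:

* **canonical** — the full pattern matches somewhere (leftmost wins);
* **variant** — otherwise, a window matches with *exactly one* conserved
  position substituted (e.g. the terminal E replaced by P), reporting
  which position (D1/D2/D3/E) changed and to what. Single substitutions
  at these positions occur in real predicted chitinases and may abolish
  activity, which is why they are tracked separately rather than counted
  as matches or discarded;
* **absent** — neither.

Variant tolerance is limited to one substitution: two or more conserved
changes are no longer recognisably the motif. Three accessory motifs of
catalytically active insect/bacterial chitinases — `Kx6GG`, `MxYDx(x)G`
(either arity) and `Gx3Wx2DxD` — are matched exactly, with no variant
tolerance. Peptide masses use average-isotopic residue masses plus one
water (18.0153 Da), on the full predicted peptide (no signal-peptide
cleavage), reported to 2 decimals in kDa. The scanners are validated
against sliding-window regex oracles and an exhaustive window enumerator,
and planted motifs round-trip losslessly from the synthetic generator.

## Compaction statistics

* Contig filtering keeps contigs of **at least** the minimum length
  (500 bp default, inclusive).
* N50 is the largest length L such that contigs ≥ L hold at least half
  the total bases; ties resolve to the larger L by construction.
* GC excludes ambiguity codes from numerator and denominator.
* Coding density is genes per kbp computed **from the printed assembled
  size in Mbp**, rounded half away from zero to 3 decimals. This matters:
  6,035 genes over 12,373,820 bp gives 0.488, but over the printed
  12.4 Mbp gives the published 0.487 — published density tables are
  derived from the rounded sizes, and the package reproduces that
  convention (all nine values of the standard green-algal comparison
  table recompute exactly in the test suite).
* Intron lengths are implied gaps between consecutive exons
  (`next_start − prev_end − 1`, 1-based closed GFF3 coordinates).
  Per-gene means are reported to 1 decimal and sizes as integer bp.
* Genome size is estimated as total mapped bases over mean coverage. The
  companion `simulate_coverage` summary is closed-form arithmetic (read
  count × read length, mean coverage = bases/size): the module
  deliberately does no read-level simulation, so the round trip is exact
  rather than approximate.

## Synteny clusters

Orthologs are reciprocal best hits on bitscore (ties: lower E-value, then
lexicographic id), so each gene anchors at most one pair. Anchors on a
contig pair are chained by dynamic programming: consecutive anchors in a
chain may be separated by at most `max_gap` intervening genes on *each*
genome (default 2 — tolerant of the occasional absent or relocated gene)
and must be strictly monotone in position on both genomes, ascending or
descending. Chains are selected greedily, longest first (ties to the
leftmost chain on genome A), each anchor used once; chains below
`min_cluster_size` (default 2) are discarded.

One deliberate asymmetry: a **descending chain of exactly two anchors is
not reported**. Two genes adjacent on both genomes but in swapped order
are a local transposition, not evidence of conserved gene order — and
since any two anchors adjacent on both genomes form *some* monotone
chain, admitting 2-anchor inversions would make orientation meaningless
at the minimum size. Inverted clusters therefore need at least three
anchors; co-oriented pairs of two suffice. Self-comparison of a genome
against a relabelled copy of itself yields one full-length cluster per
contig, a tested invariant.

The syntenic fraction over a contig selection (by default the ten largest
contigs) is reported with two denominators — all selected genes, and only
those with an ortholog — again because the natural denominator is
ambiguous.

## The synthetic data generator

The generator's job is to emulate the *decision structure* of a
three-proteome comparison, not the biology of sequence evolution:

* Each family derives its members from one ancestral sequence drawn
  uniformly over the 20 canonical residues; members mutate each position
  independently with probability `within_divergence`, substituting
  uniformly over the 19 alternatives. No indels, no rate matrix, no
  codon structure — the network edge criteria depend only on identity
  fractions, so a substitution-only model exercises them fully.
* Two members of one family then agree at a fraction of positions
  concentrating near `(1−d)² + d²/19`; at the default d = 0.1 that is
  ≈ 81%, far above the 20% edge floor. Members of different families
  share no ancestry, and uniform background sequences align at ≈ 5–7%
  identity with E-values far above 1e-10, so planted families and
  recovered components coincide — which is exactly what the
  perfect-precision/recall acceptance property asserts, for the regime
  `within_divergence ≤ 0.2`, lengths ≥ 100.
* The canned contraction study plants 30 families: 10 contracted, 14
  balanced, 3 expanded and 3 absent-in-focal, over five annotation
  categories. The canned chitinase study plants one 14-member focal
  family (vs 2 and 1 in the comparators): ten canonical catalytic
  carriers, three single-substitution variants (D1→T, D3→G, E→P) and one
  member with accessory motifs only, so 13 of 14 carry the catalytic
  motif.
* Toy genomes draw contig lengths from a truncated normal, bases i.i.d.
  at the target GC, exon counts as `1 + Poisson(mean−1)`, and exon/intron
  lengths as Poisson around their means; genes are apportioned to contigs
  by largest remainder and placed with evenly split intergenic gaps.
  Defaults (0.487 genes/kbp, 2.3 exons/gene, 366 bp exons, 168 bp
  introns, 62% GC) describe a compact trebouxiophyte-like genome.
  Infeasible densities (gene spans exceeding contig space) are rejected.
* Determinism: one master seed; each family uses a seed stream derived by
  a fixed offset, so outputs (including written FASTA/GFF3 bytes) are
  identical across runs.

What the generator does **not** emulate — indels and alignment ambiguity,
compositional bias, domain-level homology (shared domains between
otherwise unrelated families, which in real data can chain families into
one component), paralog divergence gradients, fragmented gene models —
is exactly what passing tests do *not* establish about real data.
Recovering planted families perfectly shows the machinery is correct, not
that component counts on real proteomes are biologically clean.

## Problem sizes and numerical choices

The default test and reproduction runs use the 30-family study
(≈ 185 proteins, ≈ 17,000 pairwise alignments, tens of seconds), toy
genomes of ≈ 1 Mbp / ≈ 550 genes, and oracle sweeps at n ≤ 50 (graphs)
and ≤ 12 residues (alignments) — sizes chosen so every oracle is
exhaustively checkable while each run stays in seconds to a few minutes
on one CPU. Rounding of reported statistics is half away from zero at
the precision stated for each statistic. All randomness flows from
explicit integer seeds.

## Known limitations

* The aligner is desk-scale (no heuristic seeding); real proteome
  comparisons at BLAST scale should be ingested from tabular files via
  `read_hit_table()`.
* Statistics that depend on the real deposited datasets (the published
  component count, retention percentages, congruence fractions, the
  synteny fraction of a real genome pair) are not recomputable from
  synthetic data; the package reproduces their *procedures* and checks
  them by parameter recovery instead.
* E-values from the internal aligner use fixed Karlin–Altschul constants
  without composition-based adjustment, so they approximate but do not
  duplicate BLAST's reported values.
* Category assignment by majority vote is a deterministic proxy for
  manual curation; with thin annotation it will report `unknown` often.
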