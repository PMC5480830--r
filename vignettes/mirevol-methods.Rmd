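---
title: "Models and methods behind mirevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mirevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`mirevol` re-implements, as a tested pipeline, the comparative analysis
of miRNA evolution across a primate-like clade: homolog clustering of
mature sequences, mature-region variant calling with functional-region
classification, precursor-hairpin structural-conservation statistics,
seed-shift detection, flank-anchored paralog presence/absence calling,
and distance-based trees. This vignette explains the models, the
parameters that matter, the numerical choices, and what the synthetic
data generator does and does not emulate.

## Sequence alphabet and coordinates

The internal alphabet is DNA (`T`, not `U`); conversion happens at I/O
boundaries only, because genomic windows and small-RNA reads mix
conventions in practice. All internal coordinates are 0-based half-open;
all user-facing report positions are 1-based, the convention of
published variant tables. When a mature sequence occurs more than once
inside its hairpin the leftmost occurrence is taken (with a warning):
prediction output does not disambiguate multi-mapping matures, so a
deterministic rule is required.

## Alignment

Homology search between ~22 nt matures uses an affine-gap
Smith–Waterman aligner (match +1, mismatch −1, gap open −2, extend −1; a
gap of length L costs `open + L·extend`). The original analysis used
blastn at a permissive e-value followed by an identity/length filter;
the e-value gate is subsumed here by that same filter (≥ 70 % identity
over ≥ 18 columns), which is the operative criterion — removing the
external binary while keeping the decision rule. Identity is defined as
matched columns over *all* aligned columns, gaps counting as mismatches:
the denominator is not stated in most method descriptions, and this is
the stricter convention. Traceback is deterministic (diagonal over up
over left at ties, longer path preferred), but note that the two
directions of a pair can still resolve ties differently; everything that
depends on symmetry therefore either computes each unordered pair once
(`all_vs_all`) or checks both directions (the simulator's separation
rule).

Multiple alignment of near-identical sequences (mature groups, hairpin
groups) is center-star: the sequence with the highest mean pairwise
identity anchors the alignment, all others are globally aligned to it,
and insertions are merged column-wise. For inputs at ≥ 85 % identity
this reproduces the exhaustive global alignment and keeps gap-free
columns in 1:1 correspondence with anchor positions, which is what the
variant caller needs.

Ortholog subdivision within a homology group uses *global* (full-length)
identity at a default threshold of 0.85. Two deliberate choices here:
the original subdivision was done by visual assessment of alignments and
trees, so a reproducible numeric stand-in is required and the threshold
is exposed as configuration; and local identity would be wrong for this
purpose, because optimal local alignments of diverged paralogs trim
their mismatch-rich ends and report inflated identity, defeating the
threshold.

## Variant calling

Within an ortholog-group alignment, the reference base per column is the
majority base among non-gap rows, ties broken by a designated reference
species (if given) and then alphabetically; every minority base becomes
one variant listing all carrier species. Positions are numbered on the
consensus mature: columns where more than half the rows are gaps are
insertion columns and are skipped. Columns involving gaps are reported
as indels, never as substitutions, because published mature-variant
tables contain substitutions only. Lineage-level counts are
variant–species *pairs* (a variant carried by three species counts
three), which is the unit that makes the published per-lineage fractions
(14/21 Strepsirrhine, 5/21 New World monkey) add up from 17 table rows.
Regions follow the standard functional partition of the mature: seed
1–8, central 9–12, 3' supplementary 13–16, tail 17+.

## Folding model and structural statistics

Secondary structure is scored with a weighted Nussinov model: nested
canonical pairs (GC −3, AU −2, GU −1) with a minimum hairpin loop of
3 nt, minimised by dynamic programming with a deterministic traceback
(prefer unpaired, then the smallest partner). This replaces the Turner
nearest-neighbour model of Vienna-style folders on purpose: the engine
is self-contained and its optimum can be verified against exhaustive
enumeration (`brute_force_fold`, restricted to length ≤ 14), and every
downstream statistic — z-score, SCI, covariance contribution — is
defined *relative to the folding model*, so the package's claims are
property-based rather than tied to the numeric output of an external
folder. The pair scores order pair stabilities the standard way
(GC > AU > GU).

The **z-score** null replaces a sequence by dinucleotide-preserving
shuffles (Altschul–Erickson Eulerian walks; first and last residues
fixed, exact 16-bin dinucleotide counts preserved). Dinucleotide
preservation is stricter than the mononucleotide null implied by "same
length and base composition" and is the field's standard guard against
stacking artifacts; a mononucleotide option is exposed. With fewer than
numerically distinguishable shuffle energies (e.g. homopolymers) the
z-score is defined as 0 and flagged degenerate. The convention "z below
−3 indicates a very stable structure" carries over unchanged.

The **consensus fold** of an alignment runs the same DP over column
pairs. A column pair is admissible when more than 50 % of rows can form
a canonical pair there; its score is the mean of the rows' pair scores
(non-pairable rows contribute 0) plus a covariance term
`−b·(t−1) + q·m` with `t` the number of distinct canonical pair types
and `m` the number of non-pairable rows (defaults `b = q = 1`,
RNAalifold-like, exposed as configuration). The consensus energy then
decomposes exactly into a thermodynamic part and a **covariance
contribution**; compensatory substitutions (t > 1) drive the latter
negative, inconsistent ones (m > 0) positive. **SCI** is the consensus
energy divided by the mean individual folding energy of the rows; for
identical rows this is exactly 1 with covariance 0, and SCI > 1 is
possible under compensation. When the mean individual energy is within
`1e-9` of zero the index is undefined and flagged rather than reported.
Whether the published per-alignment z is a mean over rows is not
determinable from the method description, so the per-group report
carries per-species z-scores alongside their mean; likewise the sign and
normalisation of a "covariance contribution" can be per-column or total,
and the total is reported here.

Structural statistics are computed on the pre-miRNA portion of excised
sequences (the mature-through-star extent located from the prediction
record), not on the flanking sequence the excision windows add.

## Seed shifts

A register shift of the mature within its hairpin (e.g. 1 nt downstream
in one clade) changes the seed and hence the target repertoire, without
any mature-internal substitution being required. `detect_seed_shift`
aligns the hairpins, maps each species' mature start to an alignment
column, and reports the signed offset from the modal start column. The
measurement is in column space on purpose: an upstream indel that does
not move the mature's aligned placement yields shift 0.

## Paralog presence/absence

A locus query is the pre-miRNA plus up to 1000 nt of flank per side.
Scanning uses iterative best-local-alignment with masking of previously
matched subject intervals — a blast-like multi-hit emulation that lets
the two flanks of a deleted locus surface as separate matches — behind a
shared-12-mer prefilter that skips contigs which cannot host a
permissive match (a 300 nt alignment at 70 % identity shares a conserved
12-mer except with negligible probability). Matches are filtered at
≥ 70 % identity over ≥ 300 columns, the stated operative criterion;
repetitive query regions (more than `max_hits = 100` overlapping
matches) are masked, standing in for removal of elements "found in
thousands of locations".

One subtlety drives the call logic: an affine-gap local alignment will
happily bridge a deleted pre-miRNA with a single long gap, because
~1000 matching columns on each side dwarf the gap cost. Span overlap
with the pre-miRNA is therefore *not* sufficient for presence. The
caller requires the aligned columns restricted to the pre-miRNA span to
reach the rescue identity (default ≥ 0.70 over ≥ 60 % of the pre-miRNA);
otherwise the match is only flank evidence, the hypothetical location
(100 nt upstream to 200 nt downstream of the expected pre-miRNA start)
is extracted and aligned to the pre-miRNA, and the locus is called
`present` (rescued) or `absent_flanks_conserved` accordingly. The rescue
threshold replaces a visual-inspection decision and is exposed as
configuration.

## Trees

Trees are built by neighbor joining on p-distances (1 − pairwise
identity, same pair rule as the identity statistic), with negative
branch lengths clamped to zero and flagged. Maximum-likelihood inference
is deliberately out of scope: the trees serve visual grouping of
paralogs, which NJ supports, and NJ recovers additive metrics exactly —
a testable property. Newick I/O and the NJ core go through `ape`.

## The synthetic-data generator

The generator defines the study conditions the tests run under: 20
independent families of 22 nt matures seated on the 5' arm of
perfect-complement hairpins (stem 32, loop 16 → 80 nt pre-miRNA, in the
~83 nt range), 1000 nt flanks, evolved along a fixed 13-taxon
primate-like tree (6 apes, 2 Old World monkeys, 2 New World monkeys, 3
Strepsirrhines; invented branch lengths, root-to-tip depth 0.65).
Substitutions are drawn per site with probability `1 − exp(−rate·bl)`
and uniform base exchange; the default region rates (per site per unit
branch length) encode the observed conservation gradient — seed 0.002,
supplementary 0.01, central/tail 0.04, other stem 0.04, loop 0.10, flank
0.15 — chosen so that within-family mature identity stays ≥ 0.85 between
any two tips while flanks remain alignable (~0.80 identity at the
deepest split) for presence calling. A stem substitution is accompanied
by the complement-restoring partner change with probability 0.3 by
default (instantaneous compensation; no intermediate state is
modelled). The default event list contains one pre-miRNA deletion on the
Strepsirrhini stem branch, reproducing the flank-conserved absence
pattern of a post-split insertion event; duplication and register-shift
events are available as explicit parameters.

Family separation is part of the construction, not left to chance:
besides a cheap ancestor prescreen (pairwise mature alignment score
≤ 7), a freshly evolved family is re-drawn whenever any of its matures
passes the homolog clustering filter against an earlier family, checked
in both alignment directions. Measurement showed why this is necessary:
with random independent ancestors, gapped chance alignments at ≥ 70 %
identity over ≥ 18 columns arise between unrelated descendant matures
often enough to bridge two families in most simulations, which would
make cluster-recovery assertions meaningless. With the construction in
place, clustering recovers the simulated families exactly (Rand index 1)
across seeds. The check is skippable (`enforce_separation = FALSE`) for
large simulations where separability is not under study, such as the
200-family region-rate recovery test.

What the generator does *not* emulate: sequencing reads and their error
profiles (read depths and prediction scores are drawn, not simulated
from reads), indel-rich evolution (the mature and hairpin evolve without
indels except for whole-pre-miRNA deletion events), rate heterogeneity
along branches, base-composition bias, and genomic context beyond one
window per locus. Passing the recovery tests therefore shows the
pipeline's logic is correct under clean, known-truth conditions — not
that it is robust to artifacts real small-RNA data can carry
(mis-excised hairpins, expression dropouts, assembly gaps).

## Problem sizes and determinism

The shipped tests run the full recovery suite at the study's design
size — 20 families × 13 taxa with 1000 nt flanks for clustering and
presence recovery — and scale the Monte-Carlo suites to 500 folding
oracles, 200 shuffle checks, 100 z-score nulls of 50 shuffles each, and
50 NJ recoveries; the 200-family simulation backs the region-rate
recovery property. Every stochastic step is seeded: the simulator from
`sim_params(seed=)`, z-scores from an explicit per-call seed, and the
acceptance script derives all sub-seeds from its `--seed` argument.
Pipelines re-run on the same bundle and configuration byte-identically.

## Known limitations

The folding model ignores stacking energetics, dangles, temperature and
pseudoknots; z-scores and SCIs are comparable within this package but
not numerically against Turner-model tools. The center-star aligner is
not a general MSA method and is only appropriate at the high identities
this pipeline operates on. Presence calls depend on flank
alignability — at divergences where flanks fall below the 70 %/300 nt
filter, a true locus degrades to `not_found` rather than `absent`.
E-value statistics are not computed anywhere; filters are raw
identity/length criteria.
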