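# mirevol

Comparative analysis of microRNA evolution across a primate-like clade.

MicroRNAs are ~22 nt post-transcriptional regulators whose target
repertoire is dominated by the **seed region** (mature positions 1–8),
with a secondary role for the 3' supplementary region (positions 13–16).
Because a one-nucleotide change in the seed — or a structural change in
the ~83 nt pre-miRNA hairpin that shifts the excision register — can
re-target a miRNA wholesale, comparative studies of miRNA repertoires
need to (i) group experimentally validated mature sequences into homolog
and ortholog families across species, (ii) locate and classify
mature-region variants by functional region, (iii) quantify structural
conservation of the precursor hairpins, and (iv) decide, genome by
genome, whether a paralogous locus is present, absent despite conserved
flanking sequence (an insertion/deletion event), or simply not found.
`mirevol` implements that pipeline for small-RNA survey data of the kind
produced for a dozen primate genomes, together with a synthetic-data
generator that evolves miRNA families along a 13-taxon primate-like tree
so every stage can be tested against known ground truth.

## Core statistics

* **Homolog clustering.** All-versus-all Smith–Waterman matching of
  mature sequences (affine gaps; match +1, mismatch −1, gap open −2,
  extend −1), retained at ≥ 70 % identity over ≥ 18 aligned columns, then
  single-linkage clustering: groups are the connected components of the
  match graph. Ortholog groups are connected components at ≥ 0.85
  full-length identity with one representative per species.
* **Folding model.** A weighted Nussinov minimisation over nested
  canonical structures with pair scores GC −3, AU −2, GU −1 and a
  3 nt minimum hairpin loop. `MFE(s) = min over structures Σ pair scores`.
  The optimum is brute-force verifiable, and every statistic below is
  defined relative to this model.
* **Thermodynamic z-score.** `z = (E_obs − mean(E_shuffled)) / sd(E_shuffled)`
  over dinucleotide-preserving (Altschul–Erickson) shuffles; z below −3
  indicates a structure very unlikely to arise from composition alone.
* **Structure Conservation Index.**
  `SCI = E_consensus / mean(E_individual)`, where the consensus energy of
  an alignment scores a column pair by the mean pair score over rows plus
  a covariance term `−b·(t−1) + q·m` (t = distinct canonical pair types,
  m = non-pairable rows, b = q = 1). SCI near 1 means the structure is
  conserved; a negative covariance contribution means compensatory
  substitutions support it.
* **Presence/absence.** Each locus query (pre-miRNA + up to 1000 nt
  flanks) is scanned against every genome by iterative masked local
  alignment (≥ 70 % identity over ≥ 300 nt); the call is `present` when
  the best match actually covers the pre-miRNA, `absent_flanks_conserved`
  when only the flanks align and the hypothetical location (−100/+200 nt)
  lacks the pre-miRNA, and `not_found` otherwise.
* **Trees.** Neighbor joining on p-distances (1 − pairwise identity),
  written as Newick.

## Worked example

Simulate a four-family study, write the bundle, and run the pipeline:

```r
library(mirevol)
p      <- sim_params(n_families = 4, flank_len = 300, seed = 7)
bundle <- file.path(tempdir(), "bundle")
write_study_bundle(simulate_study(p), bundle)
report <- run_pipeline(bundle, file.path(tempdir(), "out"),
                       pipeline_config(n_shuffles = 30))
print(report)
```

```
mirevol pipeline report
  matures:             49
  homology groups:     4 (singletons: 0 )
  ortholog groups:     4
  structural groups:   4
  mature variants:     4
```

49 matures (one family is deleted in the three Strepsirrhines by
default, emulating a lineage-specific insertion event) cluster into
exactly the 4 simulated families. The structural table reports, per
ortholog group, the mean pairwise identity, per-species z-scores, SCI
and covariance contribution:

```
               group n_species mean_pairwise_identity     mean_z       sci cov
1  HG:fam01|baboon.1        10                  0.966      -8.21     0.962   0
2 HG:fam02|aye_aye.1        13                  0.966      -8.56     0.967   0
3 HG:fam03|aye_aye.1        13                  0.977     -11.45     0.944   2
4 HG:fam04|aye_aye.1        13                  0.950      -8.46     0.963  -1
```

Hairpins are strongly stable (mean z far below −3) and structurally
conserved (SCI ≈ 0.95–0.97); group 4 carries a compensatory substitution
(covariance contribution −1). The presence matrix shows the deletion
pattern — family 1 is `absent_flanks_conserved` in exactly the three
Strepsirrhines and `present` in the other ten species:

```
        absent_flanks_conserved present
  fam01                       3      10
  fam02                       0      13
```

The packaged table of published mature-region variants can be
re-summarised directly:

```r
table1_check()
#> $n_mirna   15
#> $n_pairs   21
#> $by_lineage  ape=2  new_world_monkey=5  old_world_monkey=0  strepsirrhine=14
#> $by_region   seed=0  central=11  supplementary=1  tail=5
```

Fifteen miRNA ortholog groups carry variation; none of the 21
variant-species pairs falls in the seed region, one falls in positions
13–16, and 14/21 are Strepsirrhine — the basal-lineage excess expected
under the hominoid slowdown.

A shell entry point for the same stages ships in
`inst/scripts/mirevol-pipeline.R`
(`simulate`, `run-all`, `table1-check`).

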