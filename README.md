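# phycocomp

Comparative-genomic analysis of genome compaction in green algae — built
for the question of whether a small parasite genome reflects genuine
metabolic reduction, or merely denser packing and thinner gene families.

When an obligate parasite evolves from a free-living alga (as happened
within the trebouxiophytes, where a parasite of insects sits among
free-living relatives like *Chlorella* and *Coccomyxa*), the textbook
expectation is functional loss. Testing that expectation takes five
analyses, all implemented here:

* **Gene-family networks** — an undirected graph over three predicted
  proteomes, with an edge between two proteins only if *both* directed
  local-alignment hits satisfy E < 1e-10, identity > 20%, identical
  residues ≥ 20% of the shorter sequence, and alignment length > 20 aa.
  Connected components approximate gene families; a family with fewer
  focal members than every comparator is *contracted*, with more,
  *expanded*.
* **Pathway retention** — presence/absence of reference gene sets
  (KEGG-ortholog or GreenCut2 style) against proteome/genome/
  transcriptome at strict thresholds (1e-10 protein-vs-protein, 1e-5
  translated), per-pathway retention fractions, and a Fisher exact test
  for whether loss concentrates in a pathway group.
* **Chitinase motifs** — GH18 catalytic-motif (`DxxDxDxE`) scanning with
  single-substitution variant calls (e.g. E→P), three accessory motifs,
  and Table-style per-protein reports with peptide length and mass.
* **Compaction statistics** — contig filtering, N50, GC, coding density
  (genes/kbp), exon/intron geometry, and genome size from read coverage
  (`bases / coverage`).
* **Synteny** — reciprocal-best-hit anchors chained into colinear
  clusters (gap tolerance 2 genes, either orientation) and the fraction
  of genes on selected contigs lying in clusters.

A synthetic-data module generates three-taxon proteomes, motif-planted
chitinase-like families and annotated toy genomes with a JSON truth
ledger, so the full pipeline runs and is validated end-to-end with no
external data.

## Worked example

Thirty planted families (10 contracted, 14 balanced, 3 expanded, 3
absent from the focal taxon), recovered from scratch by alignment,
network construction and classification:

```r
library(phycocomp)

specs <- contraction_study_specs()
pr    <- generate_proteomes(specs, seed = 1)
hits  <- all_vs_all(pr$proteomes)                  # ~17k alignments, <1 min
cl    <- classify_components(
  connected_components(build_network(hits)),
  focal = "focal", comparators = c("comparator1", "comparator2"))

table(cl$components$representation_call)
#> absent-in-focal        balanced      contracted        expanded
#>               3              14              10               3
```

The calls match the planted truth exactly — 10 contracted components, no
false positives. Per-category summary of the contracted families:

```r
summ <- summarize_categories(cl, contraction_study_annotation(pr$truth, specs))
summ$table[summ$table$representation_call == "contracted", ]
#>      category representation_call n_components focal_genes comparator_genes
#> 1   chromatin          contracted            3           3               17
#> 5 translation          contracted            3           3               13
#> 6   transport          contracted            4           6               23
```

Motif report for the planted 14-member chitinase-like family (rows 11–14:
the three single-substitution variants and the one non-carrier):

```r
rep_out <- build_motif_report(
  generate_proteomes(list(chitinase_study_spec()), seed = 1)$proteomes$focal)
rep_out$report[11:14, c("protein_id", "catalytic_status", "catalytic_variant",
                        "motif_order", "length", "mass_kda")]
#>       protein_id catalytic_status catalytic_variant     motif_order length mass_kda
#> 11 focal_GH18_11          variant              D->G catalytic,Kx6GG    220    26.64
#> 12 focal_GH18_12          variant              D->T catalytic,Kx6GG    220    26.65
#> 13 focal_GH18_13          variant              E->P catalytic,Kx6GG    220    26.97
#> 14 focal_GH18_14           absent              <NA>           Kx6GG    220    26.46
rep_out$summary$n_catalytic
#> [1] 13
```

So 13 of the 14 focal proteins carry the catalytic motif (variants
included) — the planted ground truth. Compaction arithmetic reproduces
published green-algal density values from printed gene counts and
assembled sizes:

```r
coding_density(6035, 12.4)   # compact focal genome
#> [1] 0.487
coding_density(9629, 49)     # a free-living relative
#> [1] 0.197
```

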