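# mhcscan

Localization and comparative characterization of MHC-like genomic regions
in draft assemblies.

The major histocompatibility complex (MHC) is gene-dense and repeat-rich,
and in draft reptile genomes it typically ends up split between one long
scaffold and a pile of short unplaced scaffolds. `mhcscan` is a tested R
implementation of the full desk-scale workflow for such a region:

* **Localization** — homology hits counted in 100 kb windows on scaffolds
  longer than 1 Mb, quantile-seeded candidate region calls with gap
  bridging, coverage-quartile binning, and reporting filters for unplaced
  scaffolds (≥ 100 hits and density > 4 per 100 bp; ≥ 5 BAC-end links).
* **Region map** — gene-delineated spans and sizes, marker-pair sizing
  (e.g. *GABBR1*–*DAXX*), cross-species gene presence/duplication
  matrices, reciprocal best hits.
* **Scaffolding** — alignment-based placement (confident iff ≥ 5 kb
  aligned and ≥ 0.7 orientation majority), transcript and read-pair
  corroboration with conflict detection, and a composed region path that
  inserts tentative scaffolds at the gene-order-optimal slot.
* **Landscape** — gap-aware windowed GC (undefined above 10% N), merged
  and clipped repeat proportions, per-gene GC3 from the longest-CDS
  transcript (minus-strand and multi-exon aware), intron and intergenic
  statistics.
* **Statistics** — tie-corrected Kruskal–Wallis (via `stats`), a
  hand-verified Dunn post hoc test, pooled Bonferroni families across
  test batches, and median-based percent-decrease effect sizes.
* **Pockets** — outer join of per-codon selection classes with
  peptide-binding-pocket membership across species and structures.
* **Synthetic data** — a two-species generator with planted truth
  (region location, gene GC3, repeat composition, fragment order and
  orientation, hit provenance) used to validate everything end to end.

All internal coordinates are 0-based half-open; conversions happen only in
the readers/writers for FASTA, GFF3, RepeatMasker `.out`, 12-column
tabular homology hits, PAF and link tables.

## Worked example

`analysis/01_simulate.R` (seed 42) writes a complete synthetic system to
`results/simulation/`: a reference and a focal species, the focal region
shattered into six scaffolds, plus hits, links and truth tables. The
planted reference region is `chr2:2500000-3160189` (660 kb).

Localizing from the on-disk hit table (`analysis/02_localize.R`):

```
1 candidate region(s); top call:
  scaffold   start     end n_windows n_hits
1     chr2 2500000 3100000         6   1740
```

The call overlaps the planted region at Jaccard 0.91 (window resolution
caps this at ~0.9 for a region ending mid-window). Re-scaffolding the
fragmented focal region (`analysis/03_scaffold.R`) recovers the planted
order and orientation exactly:

```
  position scaffold orientation confidence
1        1  frag_01        same  confident
2        2  frag_02        same  confident
3        3  frag_03        same  confident
4        4  frag_04    opposite  confident
5        5  frag_05        same  confident
6        6  frag_06    opposite  confident
```

Gene-delineated and marker-pair sizes agree here because the anchor genes
are the outermost (`analysis/04_region_map.R`): reference 641,118 bp,
focal 619,298 bp. The landscape comparison (`analysis/05_landscape_stats.R`,
pooled Bonferroni family m = 4) recovers the planted contrasts:

```
        metric         kw_p dunn_p_adjusted percent_decrease
   gc_fraction 1.670340e-02    6.681362e-02        0.3170301
     prop_LINE 2.906095e-08    1.162438e-07      -26.6666667
      gene_gc3 5.483355e-19    2.193342e-18      -21.8767665
 intergenic_bp 1.208995e-12    4.835981e-12       38.4370016
```

i.e. more LINEs, higher GC3 and 38% shorter intergenic gaps inside the
region (the planted contraction is 35%). The pocket cross-reference
(`analysis/06_pockets.R`) finds codons 68 and 72 under diversifying
selection in both species and flags pocket F as the only pocket with zero
diversifying codons.

## Reproduction

```sh
Rscript analysis/01_simulate.R   # synthetic system -> results/simulation/
Rscript analysis/02_localize.R   # windows, counts, candidate regions
Rscript analysis/03_scaffold.R   # placements, corroboration, region path
Rscript analysis/04_region_map.R # spans, sizes, presence matrix
Rscript analysis/05_landscape_stats.R
Rscript analysis/06_pockets.R
```

The acceptance summary simulates 20 systems and reports recovery metrics,
permutation-oracle agreement and null calibration as JSON:

```sh
Rscript scripts/acceptance.R --seed 123 --out results/acceptance.json
```

With seed 123: 20/20 planted regions recovered at Jaccard ≥ 0.8 (minimum
0.887), Kendall τ = 1 with 0 orientation errors on all 20 scaffold paths,
Kruskal–Wallis/Dunn p-values within 0.004 of a 10,000-permutation oracle,
familywise null rejection rate 0.037, and a mean recovered intergenic
decrease of 35.08% against the planted 35%.

See `vignettes/methods.Rmd` for the model, parameter rationale (including
the calibrated region-calling threshold and generator variance choices)
and the generator's limits.
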