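---
title: "Methods: localizing and characterizing an MHC-like region"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: localizing and characterizing an MHC-like region}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhcscan)
```

# Problem

The major histocompatibility complex (MHC) is a gene-dense, repeat-rich
region that is notoriously hard to assemble: in draft reptile genomes it is
typically shattered across a long chromosome-scale scaffold and a set of
short unplaced scaffolds. `mhcscan` implements a desk-scale, fully tested
version of the standard workflow for such a region:

1. **Localize** the region on a draft assembly from homology-hit density.
2. **Delineate and size** it from annotated anchor genes.
3. **Order and orient** unplaced scaffolds against a better assembly, with
   transcript and read-pair corroboration.
4. Describe the **genomic landscape** (GC, repeats, GC3, intron and
   intergenic lengths) inside versus outside the region.
5. **Compare** region versus background with rank statistics under one
   pooled Bonferroni family.
6. Cross-reference per-codon **selection classes** with peptide-binding
   **pocket** membership.

Because real assemblies are too large for a reproducible test suite, the
package ships a two-species synthetic genome generator with planted truth;
every pipeline stage is validated against that truth and against
brute-force oracles.

# Coordinate conventions

Internally every interval is **0-based, half-open** `[start, end)`.
Conversions happen only at file boundaries: GFF3 and RepeatMasker `.out`
are 1-based inclusive, tabular homology hits are 1-based with strand
encoded by subject coordinate order, PAF is already 0-based half-open.
Round-trip tests pin each conversion.

# Localization

`build_windows()` tiles non-overlapping 100 kb windows over scaffolds
strictly longer than 1 Mb (shorter scaffolds are reported separately, not
windowed). Hits are assigned to the window containing their **start**
(`rule = "midpoint"` is available; for sub-window hits the two rules
differ only at window edges, and the start rule is kept as the default
because it never depends on hit length). Hits are **not** deduplicated by
default: overlapping hits from different queries are independent evidence
of gene density, which is the signal being measured.

`call_candidate_regions()` seeds on windows whose count reaches the
`quantile_threshold` quantile (type 7) of the **nonzero** window counts,
merges seeds across gaps of at most `max_gap_windows` (default 2) windows,
and ranks merged regions by summed hits.

**Choice of `quantile_threshold = 0.78`.** This default is explicitly a
calibrated quantity: it exists to make planted-region recovery work on
assemblies shaped like the bundled generator's output, where roughly a
quarter of windowed windows are inside the true region. It was selected by
scanning a grid of quantiles over 60 generator seeds **disjoint from the
seeds used in the acceptance tests**. Low thresholds (0.70) let
background-level windows near the region edge extend calls (48/60 runs
recovered the region at Jaccard ≥ 0.8); 0.78–0.80 recovered 60/60 (minimum
Jaccard 0.852 at 0.78); thresholds ≥ 0.82 increasingly land inside the
in-region count distribution and truncate calls. The default takes the
higher-margin edge of the passing plateau. On data with a different
hit-density profile this knob should be re-examined.

Reporting filters mirror common practice and are tested verbatim: unplaced
scaffolds are reported when they have **at least 100 hits and strictly more
than 4 hits per 100 bp** (`filter_unplaced_for_report()`), and BAC-end-style
link filtering keeps scaffolds with **at least 5** mapped ends
(`filter_by_bes_links()`). `kmer_depth_profile()` gives a canonical k-mer
(default k = 27) multiplicity track for inspecting putative collapsed
duplications; k-mers spanning `N` have `NA` depth.

# Region delineation and size

`delineate_and_size()` spans, per scaffold, from the start of the first to
the end of the last MHC-classed gene; the total size is the sum of
per-scaffold spans, so a single-gene region has exactly that gene's length.
`marker_pair_size()` sizes the region a second way, between two boundary
markers (e.g. *GABBR1* and *DAXX*), orientation-agnostically. **Both
estimates are reported side by side and labeled** (see
`analysis/04_region_map.R`); they answer slightly different questions and
are not averaged. Orthology helpers provide reciprocal best hits and a
stringent one-way mode (minimum bitscore 200) for asymmetric evidence.

# Scaffold ordering and orientation

`place_by_alignment()` aggregates alignment blocks per scaffold: the target
is chosen by majority aligned bp, position is the aligned-bp-weighted
median of block midpoints, and orientation is the majority orientation by
aligned bp. A placement is **confident** iff total aligned bp ≥ 5000 and
the majority orientation fraction ≥ 0.7; otherwise tentative.
`corroborate_links()` marks adjacent joins supported by transcripts
spanning both scaffolds or read pairs (pairs whose implied gap exceeds the
library's maximum insert size become `pe_gap` conflicts rather than
support). `compose_region_path()` orders confident scaffolds by target
midpoint and inserts each tentative scaffold at the slot and orientation
that maximize the longest common subsequence of the resulting gene order
with a reference gene order; an orientation tie is reported as `"unknown"`,
never guessed.

# Landscape

* `window_gc()`: GC over A/C/G/T only; a window is **undefined (`NA`) iff
  its `N` fraction strictly exceeds 0.10** (a window at exactly 10% `N` is
  still reported).
* `window_repeats()`: per-class proportions after merging overlapping
  annotations of the same class and clipping to the window — verified
  base-by-base against a brute-force tally.
* `gene_gc3()`: per gene, the representative transcript is the one with
  the longest total CDS; CDS pieces are concatenated in ascending genomic
  order and reverse-complemented for minus-strand genes; a trailing
  partial codon is dropped and flagged; codons whose third base is `N` are
  excluded from the denominator. Verified codon-by-codon, including a
  minus-strand multi-exon oracle.
* `intron_and_intergenic()`: introns from the representative transcript;
  intergenic distances are strand-ignored gaps between consecutive gene
  bodies, clamped at 0 for overlapping neighbors (flagged), `NA` on a
  gene's scaffold-terminal side.
* `label_regions()`: a feature is "MHC" iff its midpoint lies in a region
  span — an unambiguous rule for boundary-straddling windows.

# Statistics

`kruskal_wallis()` wraps `stats::kruskal.test()` (tie-corrected).
`dunn_posthoc()` implements Dunn's z on midranks with the tie term
$\sum_t (t^3-t) / (12(N-1))$; correctness is pinned against a
10,000-permutation oracle at $n \le 30$. The Bonferroni family is the
**pooled** count of pairwise comparisons across every test in a batch,
`bonferroni_family()`; e.g. four tests with 102, 12, 12 and 12 groups give
$m = 5151 + 3 \times 66 = 5349$, and each Dunn p-value is multiplied by
that single $m$. Under a simulated null the familywise rejection rate of
the corrected test stays below the nominal 0.05. Effects are summarized as
medians and the percent decrease
$100\,(\mathrm{med}_{\mathrm{ref}} - \mathrm{med}_{\mathrm{focal}}) /
\mathrm{med}_{\mathrm{ref}}$.

# Pocket cross-referencing

`join_selection_pockets()` outer-joins per-codon selection classes (one
column per species) with pocket membership (one list column per structure)
on the shared alignment codon numbering, with an optional native-to-
alignment remap. The pooled **CDE label of the chicken structure is kept
as its own label**, not expanded into C, D and E — expansion would
fabricate resolution the source structure does not have.
`shared_selection()` intersects per-species codon sets;
`pocket_summary()` counts codons per pocket, species and class (a codon in
k pockets counts in all k) and flags pockets with zero diversifying codons
in every species. Synthetic demonstration fixtures ship in
`inst/extdata/`.

# The synthetic generator

`simulate_genomes()` builds two related species. Each genome has one
region-bearing chromosome (2.5 Mb of background followed by the planted
region) and four 0.8 Mb background scaffolds that sit below the 1 Mb
windowing floor, mimicking unplaced scaffolds. The region gene plan anchors
*GABBR1* first and *DAXX* last and interleaves some class I genes into the
class II neighborhood. Region length is **emergent** from gene-structure
and spacing draws, never clamped, so planted spacing distributions are
exact. Planted contrasts: higher DNA/LINE content, higher GC3 and
`region_spacing_ratio = 0.65` times the background intergenic spacing
inside the region. Realized per-gene GC3 is recorded as truth, so
`gene_gc3()` must match it exactly, not just in distribution.

**Why `intergenic_sdlog = intron_sdlog = 0.35`.** These defaults come from
a power analysis done before any recovery run, not from tuning on
outcomes: recovering the planted percent decrease within ±2 points from a
20-run mean of per-run median ratios requires the per-run estimator's
standard error (≈ $1.2533\,\sigma_{\log}/\sqrt{n}$ per median, with n ≈ 40
region gaps per species) to keep the 20-run SE well under 1 point; 0.35
with both species pooled per run achieves ≈ 0.6 points.

`fragment_and_link()` shatters the focal region into fragments (a third
reversed), emits alignment blocks, junction-spanning transcripts, and read
pairs, and remaps all annotation; fragment sequences reconstruct the
original region exactly in tests. `simulate_hits()` plants clustered hits
in genes over a Poisson background (2 per 100 kb) and writes standard
12-column tabular hits.

Limits: sequences are i.i.d. within composition blocks (no true repeat
copies, so k-mer depth inside planted repeats is realistic only for exact
motif fills), gene structures are simplified (exons = CDS plus UTR-free
models), and both species share one gene plan with independent sequence
draws — adequate for validating coordinate arithmetic and statistics, not
for benchmarking aligners.

# Reproducing the analysis

```sh
R CMD INSTALL .
Rscript analysis/01_simulate.R
Rscript analysis/02_localize.R
Rscript analysis/03_scaffold.R
Rscript analysis/04_region_map.R
Rscript analysis/05_landscape_stats.R
Rscript analysis/06_pockets.R
```

All outputs land under `results/`. The acceptance summary is

```sh
Rscript scripts/acceptance.R --seed 123 --out results/acceptance.json
```
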