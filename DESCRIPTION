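Package: mhcscan
Title: Localization and Comparative Characterization of MHC-Like Genomic Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for localizing a major histocompatibility
    complex (MHC)-like gene region in fragmented genome assemblies and
    characterizing it comparatively. Provides windowed homology-hit density
    localization with reporting filters, anchor-gene region delineation and
    sizing, synteny-based placement and orientation of unplaced scaffolds with
    transcript and paired-end corroboration, gap-aware windowed GC and repeat
    landscapes, per-gene GC3 and intron/intergenic statistics, region-versus-
    background Kruskal-Wallis/Dunn/Bonferroni comparisons with median effect
    sizes, reciprocal best-hit orthology, peptide-binding-pocket
    cross-referencing of per-codon selection classes, and a two-species
    synthetic genome generator with planted truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
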