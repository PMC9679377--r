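#!/usr/bin/env Rscript
# 02: localize the MHC region on the reference assembly from homology
# hits: 100 kb windows on >1 Mb scaffolds, hit counts, coverage bins,
# candidate region calls, and the unplaced-scaffold report filter.

library(mhcscan)

simdir <- "results/simulation"
outdir <- "results/localization"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
tsv <- function(x, f) write.table(x, file.path(outdir, f), sep = "\t",
                                  quote = FALSE, row.names = FALSE)

genome <- read_fasta(file.path(simdir, "reference.fa"))
lens <- scaffold_lengths(genome)
query_meta <- read.delim(file.path(simdir, "query_meta.tsv"))
hits <- read_blast_tab(file.path(simdir, "hits_reference.tsv"), query_meta)

grid <- build_windows(lens)
cnt <- count_hits(hits, grid, lens)
binned <- bin_by_coverage(hits)
cand <- call_candidate_regions(cnt$window_counts)
unplaced <- filter_unplaced_for_report(cnt$scaffold_totals)

tsv(cnt$window_counts, "window_counts.tsv")
tsv(cnt$scaffold_totals, "scaffold_totals.tsv")
tsv(binned$summary, "coverage_bins.tsv")
tsv(cand, "candidate_regions.tsv")
tsv(unplaced, "unplaced_report.tsv")

cat(nrow(cand), "candidate region(s); top call:\n")
print(cand[1, c("scaffold", "start", "end", "n_windows", "n_hits")])
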