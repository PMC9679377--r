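#!/usr/bin/env Rscript
# 03: order and orient the fragmented focal scaffolds against the
# reference: alignment placement, transcript / paired-end corroboration,
# and the composed region path.

library(mhcscan)

simdir <- "results/simulation"
outdir <- "results/scaffolding"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
tsv <- function(x, f) write.table(x, file.path(outdir, f), sep = "\t",
                                  quote = FALSE, row.names = FALSE)

blocks <- read_paf(file.path(simdir, "fragments.paf"))
tx <- read_tx_links(file.path(simdir, "tx_links.tsv"))
pe <- read_pe_links(file.path(simdir, "pe_links.tsv"))

placements <- place_by_alignment(blocks, unique(blocks$source))
corr <- corroborate_links(placements, tx, pe)
path <- compose_region_path(placements, corroboration = corr)

tsv(placements, "placements.tsv")
tsv(corr$joins, "joins.tsv")
tsv(corr$conflicts, "conflicts.tsv")
path$join_tx_ids <- NULL; path$join_pe_ids <- NULL
tsv(path, "region_path.tsv")

cat("composed path:\n")
print(path[, c("position", "scaffold", "orientation", "confidence")])
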