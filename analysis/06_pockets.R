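#!/usr/bin/env Rscript
# 06: cross-reference per-codon selection classifications with peptide-
# binding-pocket membership, using the packaged synthetic fixtures.

library(mhcscan)

outdir <- "results/pockets"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
tsv <- function(x, f) write.table(x, file.path(outdir, f), sep = "\t",
                                  quote = FALSE, row.names = FALSE)

cls <- read_codon_classifications(
  system.file("extdata", "fel_classifications_synthetic.tsv",
              package = "mhcscan"))
pm <- read_pocket_map(
  system.file("extdata", "pocket_map_synthetic.tsv", package = "mhcscan"))

joined <- join_selection_pockets(cls, pm)
shared <- shared_selection(cls, class_filter = "diversifying")
summ <- pocket_summary(joined)

flat <- joined
for (cc in grep("^pockets_", names(flat), value = TRUE))
  flat[[cc]] <- vapply(flat[[cc]], paste, character(1), collapse = ",")
tsv(flat, "joined_codons.tsv")
tsv(summ$counts, "pocket_counts.tsv")
writeLines(c(paste("shared diversifying codons:",
                   paste(shared$shared, collapse = ", ")),
             paste("pockets with zero diversifying codons:",
                   paste(summ$zero_diversifying, collapse = ", "))),
           file.path(outdir, "summary.txt"))

cat("per-species diversifying codons:\n")
print(lapply(shared$per_species, identity))
cat("shared:", paste(shared$shared, collapse = ", "), "\n")
cat("zero-diversifying pockets:",
    paste(summ$zero_diversifying, collapse = ", "), "\n")
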