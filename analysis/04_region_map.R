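#!/usr/bin/env Rscript
# 04: delineate and size the region from annotated MHC genes, size it a
# second way between the boundary markers GABBR1 and DAXX, and build the
# cross-species gene presence matrix.

library(mhcscan)

simdir <- "results/simulation"
outdir <- "results/region_map"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
tsv <- function(x, f) write.table(x, file.path(outdir, f), sep = "\t",
                                  quote = FALSE, row.names = FALSE)

region_symbols <- function(gff) {
  ann <- read_gff3(gff)
  rs <- delineate_and_size(ann$genes)
  lab <- label_regions(ann$genes, rs)
  list(ann = ann, span = rs,
       symbols = lab$symbol[lab$region_label == "MHC"])
}

ref <- region_symbols(file.path(simdir, "reference.gff3"))
foc <- region_symbols(file.path(simdir, "focal.gff3"))

sizes <- data.frame(
  species = c("reference", "focal"),
  gene_delineated_bp = c(ref$span$total_size, foc$span$total_size),
  marker_pair_bp = c(
    marker_pair_size(ref$ann$genes, "GABBR1", "DAXX"),
    marker_pair_size(foc$ann$genes, "GABBR1", "DAXX")))

pres <- gene_presence_matrix(
  list(reference = ref$symbols, focal = foc$symbols),
  reference_symbols = sort(unique(ref$symbols)))

tsv(ref$span$spans, "reference_spans.tsv")
tsv(foc$span$spans, "focal_spans.tsv")
tsv(sizes, "region_sizes.tsv")
write.table(pres$matrix, file.path(outdir, "gene_presence_matrix.tsv"),
            sep = "\t", quote = FALSE, col.names = NA)
tsv(pres$duplicated, "duplicated_genes.tsv")

cat("region sizes (bp):\n"); print(sizes)
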