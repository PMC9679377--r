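#!/usr/bin/env Rscript
# 05: genomic landscape of the reference assembly (windowed GC, repeat
# proportions, per-gene GC3, intron / intergenic statistics), labeled
# MHC vs non-MHC from the annotation, then compared with Kruskal-Wallis
# and Dunn's post hoc test under one pooled Bonferroni family.

library(mhcscan)

simdir <- "results/simulation"
outdir <- "results/landscape"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
tsv <- function(x, f) write.table(x, file.path(outdir, f), sep = "\t",
                                  quote = FALSE, row.names = FALSE)

genome <- read_fasta(file.path(simdir, "reference.fa"))
ann <- read_gff3(file.path(simdir, "reference.gff3"))
repeats <- read_repeatmasker_out(file.path(simdir, "reference.out"))

span <- delineate_and_size(ann$genes)
grid <- build_windows(scaffold_lengths(genome))
gc <- label_regions(window_gc(genome, grid), span)
rp <- label_regions(window_repeats(repeats, grid), span)
gc3 <- gene_gc3(genome, ann)
gc3 <- merge(gc3, ann$genes[, c("gene_id", "scaffold", "start", "end")],
             by = "gene_id")
gc3 <- label_regions(gc3, span)
ii <- label_regions(intron_and_intergenic(ann), span)

tsv(gc, "window_gc.tsv"); tsv(rp, "window_repeats.tsv")
tsv(gc3, "gene_gc3.tsv"); tsv(ii, "intron_intergenic.tsv")

# one pooled Bonferroni family across the four two-group comparisons
metrics <- list(
  gc_fraction = list(v = gc$gc_fraction, g = gc$region_label),
  prop_LINE = list(v = rp$prop_LINE, g = rp$region_label),
  gene_gc3 = list(v = gc3$gc3, g = gc3$region_label),
  intergenic_bp = list(v = ii$intergenic_next, g = ii$region_label))
m <- bonferroni_family(rep(2L, length(metrics)))

stats <- do.call(rbind, lapply(names(metrics), function(nm) {
  x <- metrics[[nm]]
  kw <- kruskal_wallis(x$v, x$g)
  dn <- dunn_posthoc(x$v, x$g, m = m)
  ef <- effect_and_decrease(x$v, x$g)
  data.frame(metric = nm, H = kw$statistic, df = kw$df,
             kw_p = kw$p_value, dunn_z = dn$z,
             dunn_p_adjusted = dn$p_adjusted,
             median_MHC = ef$median_focal,
             median_nonMHC = ef$median_reference,
             percent_decrease = ef$percent_decrease)
}))
tsv(stats, "comparisons.tsv")

cat("pooled Bonferroni family m =", m, "\n")
print(stats[, c("metric", "kw_p", "dunn_p_adjusted", "percent_decrease")],
      row.names = FALSE)
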