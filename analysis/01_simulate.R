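#!/usr/bin/env Rscript
# 01: generate the synthetic two-species system that every later step
# consumes. All downstream drivers read the on-disk files, so the whole
# workflow exercises the same formats a real analysis would.

library(mhcscan)

seed <- 42L
outdir <- "results/simulation"
obj <- write_simulation(sim_config(seed = seed), outdir)

cat("simulated system written to", outdir, "\n")
cat("reference scaffolds:",
    paste(names(obj$sim$reference$genome), collapse = ", "), "\n")
tr <- obj$sim$truth$region
cat(sprintf("planted region (%s): %s:%d-%d (%d kb)\n",
            tr$species, tr$scaffold, tr$start, tr$end,
            (tr$end - tr$start) %/% 1000L))
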