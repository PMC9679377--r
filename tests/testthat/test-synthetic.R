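# synthetic_data: determinism, structural consistency, planted-truth
# self-consistency, fragmentation round trips

test_that("sim_config validates its inputs", {
  expect_error(sim_config(), "seed")
  expect_error(sim_config(1, region_repeat_props = c(DNA = 0.9, LINE = 0.3)),
               "sum")
  expect_error(sim_config(1, region_repeat_props = c(Bogus = 0.1)),
               "unknown repeat class")
  expect_error(sim_config(1, n_fragments = 0L), "n_fragments")
  expect_error(sim_config(1, n_fragments = 1000L), "exceeds")
  expect_error(sim_config(1, chrom_background_length = 123456),
               "multiple of window_size")
  expect_s3_class(sim_config(7L), "sim_config")
})

test_that("the generator is deterministic under its seed", {
  a <- simulate_genomes(sim_config(seed = 5L))
  b <- simulate_genomes(sim_config(seed = 5L))
  expect_identical(as.character(a$reference$genome),
                   as.character(b$reference$genome))
  expect_identical(a$truth$genes, b$truth$genes)
  c <- simulate_genomes(sim_config(seed = 6L))
  expect_false(identical(as.character(a$reference$genome),
                         as.character(c$reference$genome)))
})

test_that("gene plan anchors and interleaving match the configuration", {
  cfg <- sim_config(seed = 1L)
  plan <- mhcscan:::plan_region_genes(cfg)
  expect_identical(nrow(plan), cfg$n_class1_genes + cfg$n_class2_genes +
                     cfg$n_class3_genes + cfg$n_framework_genes)
  expect_identical(plan$symbol[1], "GABBR1")
  expect_identical(plan$symbol[nrow(plan)], "DAXX")
  expect_identical(sum(plan$mhc_class == "I"), cfg$n_class1_genes)
  # some class I genes sit inside the class II neighborhood
  ii <- range(which(plan$mhc_class == "II"))
  expect_gte(sum(plan$mhc_class[ii[1]:ii[2]] == "I"), 1L)
})

test_that("planted structures are internally consistent", {
  s <- shared_sim()
  sim <- s$sim
  for (sp in list(sim$reference, sim$focal)) {
    ann <- sp$annotation
    lens <- scaffold_lengths(sp$genome)
    expect_true(all(ann$genes$end <= lens[ann$genes$scaffold]))
    # exons inside their gene body
    g2t <- setNames(ann$transcripts$gene_id, ann$transcripts$transcript_id)
    gid <- g2t[ann$exons$transcript_id]
    gi <- match(gid, ann$genes$gene_id)
    expect_true(all(ann$exons$start >= ann$genes$start[gi]))
    expect_true(all(ann$exons$end <= ann$genes$end[gi]))
    # CDS lengths in multiples of 3
    cds_len <- tapply(ann$cds$end - ann$cds$start, ann$cds$transcript_id, sum)
    expect_true(all(cds_len %% 3 == 0))
    # repeats never overlap gene bodies, stay inside scaffolds
    for (sc in unique(sp$repeats$scaffold)) {
      rr <- sp$repeats[sp$repeats$scaffold == sc, ]
      gg <- ann$genes[ann$genes$scaffold == sc, ]
      expect_true(all(rr$end <= lens[[sc]]))
      if (nrow(gg)) {
        ov <- IRanges::overlapsAny(
          IRanges::IRanges(rr$start + 1L, rr$end),
          IRanges::IRanges(gg$start + 1L, gg$end))
        expect_false(any(ov))
      }
    }
    # N gaps are exactly the planted gaps
    for (i in seq_len(nrow(sp$gaps))) {
      gp <- sp$gaps[i, ]
      piece <- substr(as.character(sp$genome[[gp$scaffold]]),
                      gp$start + 1, gp$end)
      expect_identical(piece, strrep("N", gp$end - gp$start))
    }
  }
})

test_that("the region starts at the configured boundary and is gene-delineated", {
  s <- shared_sim()
  tr <- s$sim$truth$region
  expect_identical(tr$start, rep(s$cfg$chrom_background_length, 2))
  # all MHC-classed genes lie inside the truth region
  g <- s$sim$truth$genes
  mhc <- g[g$mhc_class != "none", ]
  for (sp in unique(mhc$species)) {
    r <- tr[tr$species == sp, ]
    m <- mhc[mhc$species == sp, ]
    expect_true(all(m$scaffold == r$scaffold))
    expect_true(all(m$start >= r$start & m$end <= r$end))
  }
})

test_that("planted window repeat proportions approach the configured targets", {
  s <- shared_sim()
  tw <- s$sim$truth$window_repeats
  # full background windows on background-only scaffolds
  bg <- tw[tw$scaffold != "chr2" & tw$end - tw$start == s$cfg$window_size, ]
  for (cl in c("DNA", "LINE", "SINE")) {
    med <- median(bg$proportion[bg$repeat_class == cl])
    expect_lt(abs(med - s$cfg$background_repeat_props[[cl]]), 0.02)
  }
  # region windows carry the shifted composition
  reg <- tw[tw$scaffold == "chr2" & tw$start >= s$cfg$chrom_background_length &
              tw$end - tw$start == s$cfg$window_size, ]
  expect_lt(abs(median(reg$proportion[reg$repeat_class == "DNA"]) -
                  s$cfg$region_repeat_props[["DNA"]]), 0.03)
})

test_that("realized GC3 truth matches the emitted sequence exactly", {
  s <- shared_sim()
  sp <- s$sim$reference
  out <- gene_gc3(sp$genome, sp$annotation)
  tg <- s$sim$truth$genes
  tg <- tg[tg$species == "reference", ]
  m <- match(out$gene_id, tg$gene_id)
  expect_false(anyNA(m))
  expect_equal(out$gc3, tg$gc3[m], tolerance = 1e-12)
  expect_false(any(out$partial_codon_dropped))
})

test_that("fragmentation reconstructs the focal region sequence exactly", {
  s <- shared_sim()
  frag <- s$frag
  tfr <- frag$truth_fragments
  region <- s$sim$focal$region
  chr2 <- as.character(s$sim$focal$genome[["chr2"]])
  rebuilt <- vapply(seq_len(nrow(tfr)), function(i) {
    fs <- as.character(frag$genome[[tfr$fragment[i]]])
    if (tfr$orientation[i] == "opposite") mhcscan:::revcomp_chr(fs) else fs
  }, character(1))
  expect_identical(paste(rebuilt, collapse = ""),
                   substr(chr2, region$start + 1, region$end))
  # truncated chr2 retains only the background portion
  expect_identical(scaffold_lengths(frag$genome)[["chr2"]],
                   as.integer(region$start))
  # at least one fragment is reversed under the default fraction
  expect_gte(sum(tfr$orientation == "opposite"), 1L)
})

test_that("fragment gene models survive remapping (GC3 invariant)", {
  s <- shared_sim()
  frag <- s$frag
  out <- gene_gc3(frag$genome, frag$annotation)
  tg <- s$sim$truth$genes
  tg <- tg[tg$species == "focal", ]
  m <- match(out$gene_id, tg$gene_id)
  expect_false(anyNA(m))
  expect_equal(out$gc3, tg$gc3[m], tolerance = 1e-12)
})

test_that("junction links join adjacent fragments near their junctions", {
  s <- shared_sim()
  frag <- s$frag
  tfr <- frag$truth_fragments
  lens <- scaffold_lengths(frag$genome)
  n <- nrow(tfr)
  tx <- frag$tx_links
  expect_identical(nrow(tx), 2L * (n - 1L) * s$cfg$tx_links_per_join)
  for (tid in unique(tx$transcript_id)) {
    t <- tx[tx$transcript_id == tid, ]
    io <- match(t$scaffold, tfr$fragment)
    expect_equal(abs(diff(tfr$order_index[io])), 1)
    expect_true(all(t$start >= 0 & t$end <= lens[t$scaffold]))
  }
  pe <- frag$pe_links
  expect_identical(nrow(pe), 2L * (n - 1L) * s$cfg$pe_links_per_join)
})

test_that("simulated hits land inside their source genes", {
  s <- shared_sim()
  sp <- s$sim$reference
  hs <- simulate_hits(sp$genome, sp$genes_truth, s$cfg)
  h <- hs$hits
  lens <- scaffold_lengths(sp$genome)
  expect_true(all(h$sstart >= 1 & h$send >= 1))
  expect_true(all(pmax(h$sstart, h$send) <= lens[h$sseqid]))
  planted <- hs$truth_hits != "background"
  gi <- match(hs$truth_hits[planted], sp$genes_truth$gene_id)
  lo <- pmin(h$sstart, h$send)[planted] - 1L
  hi <- pmax(h$sstart, h$send)[planted]
  expect_true(all(lo >= sp$genes_truth$start[gi]))
  expect_true(all(hi <= sp$genes_truth$end[gi]))
  # strand encodes subject coordinate order
  expect_true(any(h$sstart > h$send))
})

test_that("write_simulation emits a readable, consistent file set", {
  outdir <- file.path(tempdir(), "simout")
  cfg <- sim_config(seed = 42L, n_background_scaffolds = 1L)
  obj <- write_simulation(cfg, outdir)
  expect_true(all(file.exists(file.path(outdir, c(
    "reference.fa", "reference.gff3", "reference.out",
    "focal_fragmented.fa", "fragments.paf", "tx_links.tsv", "pe_links.tsv",
    "hits_reference.tsv", "query_meta.tsv", "truth_region.tsv")))))
  g <- read_fasta(file.path(outdir, "reference.fa"))
  expect_identical(as.character(g), as.character(obj$sim$reference$genome))
  ann <- read_gff3(file.path(outdir, "reference.gff3"))
  expect_identical(sort(ann$genes$gene_id),
                   sort(obj$sim$reference$annotation$genes$gene_id))
  rp <- read_repeatmasker_out(file.path(outdir, "reference.out"))
  expect_identical(nrow(rp), nrow(obj$sim$reference$repeats))
  pf <- read_paf(file.path(outdir, "fragments.paf"))
  expect_identical(pf$source, obj$fragmented$blocks$source)
  unlink(outdir, recursive = TRUE)
})
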