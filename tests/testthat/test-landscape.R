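# landscape: windowed GC with the gap rule, repeat proportions with a
# per-base oracle, GC3, intron/intergenic statistics, region labeling

test_that("window GC is exact on crafted sequence", {
  g <- dna(s = paste0(strrep("G", 40), strrep("A", 60),
                      strrep("C", 30), strrep("T", 70)))
  grid <- build_windows(scaffold_lengths(g), window_size = 100,
                        min_scaffold_length = 0)
  out <- window_gc(g, grid)
  expect_equal(out$gc_fraction, c(0.40, 0.30))
  expect_equal(out$gap_fraction, c(0, 0))
})

test_that("GC is undefined iff the N fraction exceeds 0.10", {
  # window 1: exactly 10% N -> defined; window 2: 11% N -> undefined
  g <- dna(s = paste0(strrep("N", 10), strrep("G", 45), strrep("A", 45),
                      strrep("N", 11), strrep("G", 45), strrep("A", 44)))
  grid <- build_windows(scaffold_lengths(g), window_size = 100,
                        min_scaffold_length = 0)
  out <- window_gc(g, grid)
  expect_equal(out$gap_fraction, c(0.10, 0.11))
  expect_equal(out$gc_fraction[1], 0.5)   # N excluded from the denominator
  expect_true(is.na(out$gc_fraction[2]))
})

test_that("an all-N window has NA GC even without the gap rule", {
  g <- dna(s = paste0(strrep("N", 100), strrep("A", 100)))
  grid <- build_windows(scaffold_lengths(g), window_size = 100,
                        min_scaffold_length = 0)
  out <- window_gc(g, grid, max_gap_fraction = 1)
  expect_true(is.na(out$gc_fraction[1]))
  expect_equal(out$gc_fraction[2], 0)
})

test_that("window repeat proportions merge overlaps and clip to windows", {
  grid <- data.frame(scaffold = "s", start = c(0, 100), end = c(100, 200),
                     partial = FALSE)
  attr(grid, "window_size") <- 100
  reps <- data.frame(
    scaffold = "s",
    start = c(10, 30, 90, 150), end = c(40, 60, 120, 160),
    repeat_class = c("LINE", "LINE", "LINE", "DNA"),
    family = NA, name = "x", stringsAsFactors = FALSE)
  out <- window_repeats(reps, grid)
  # window 1 LINE: [10,60) u [90,100) = 60 bp; window 2 LINE: [100,120) = 20
  expect_equal(out$prop_LINE, c(0.60, 0.20))
  expect_equal(out$prop_DNA, c(0, 0.10))
  expect_equal(out$prop_SINE, c(0, 0))
})

test_that("identical overlapping annotations are not double-counted", {
  grid <- data.frame(scaffold = "s", start = 0, end = 100, partial = FALSE)
  reps <- data.frame(scaffold = "s", start = c(0, 0), end = c(50, 50),
                     repeat_class = "SINE", family = NA, name = "x",
                     stringsAsFactors = FALSE)
  expect_equal(window_repeats(reps, grid)$prop_SINE, 0.5)
})

test_that("window repeat proportions match a per-base brute-force tally", {
  s <- shared_sim()
  sp <- s$sim$reference
  lens <- scaffold_lengths(sp$genome)
  grid <- build_windows(lens[c("scaf01")], min_scaffold_length = 0)
  out <- window_repeats(sp$repeats, grid)
  rr <- sp$repeats[sp$repeats$scaffold == "scaf01", ]
  for (i in sample(nrow(grid), 3)) {
    covered <- rep(FALSE, grid$end[i] - grid$start[i])
    for (cl in c("DNA", "LINE", "Unknown")) {
      covered[] <- FALSE
      ri <- rr[rr$repeat_class == cl, ]
      for (j in seq_len(nrow(ri))) {
        lo <- max(ri$start[j], grid$start[i]); hi <- min(ri$end[j], grid$end[i])
        if (hi > lo) covered[(lo - grid$start[i] + 1):(hi - grid$start[i])] <- TRUE
      }
      expect_equal(out[[paste0("prop_", cl)]][i],
                   mean(covered), tolerance = 1e-12)
    }
  }
})

test_that("GC3 matches a codon-by-codon oracle on a minus-strand gene", {
  # gene on "-": genomic exons carry the revcomp of the sense CDS
  sense <- "ATGGCCTTACGAGGT"               # 5 codons; 3rd positions G,C,A,A,T
  exon1_len <- 9
  sense1 <- substr(sense, 1, exon1_len)
  sense2 <- substr(sense, exon1_len + 1, nchar(sense))
  lead <- strrep("T", 20); mid <- strrep("A", 10); tail <- strrep("T", 20)
  gseq <- paste0(lead, mhcscan:::revcomp_chr(sense2), mid,
                 mhcscan:::revcomp_chr(sense1), tail)
  g <- dna(s = gseq)
  genes <- data.frame(gene_id = "g1", symbol = "X", scaffold = "s",
                      strand = "-", start = 20L,
                      end = 20L + 6L + 10L + 9L,
                      mhc_class = "I", stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = "g1",
                      start = c(20L, 36L), end = c(26L, 45L))
  ann <- make_ann(genes, exons)
  out <- gene_gc3(g, ann)
  third <- c("G", "C", "A", "A", "T")
  expect_equal(out$gc3, mean(third %in% c("G", "C")))
  expect_identical(out$n_codons, 5L)
  expect_false(out$partial_codon_dropped)
})

test_that("GC3 drops a trailing partial codon and flags it", {
  g <- dna(s = paste0("ATGACA", "AT", strrep("A", 20)))
  genes <- data.frame(gene_id = "g1", symbol = "X", scaffold = "s",
                      strand = "+", start = 0L, end = 8L,
                      mhc_class = "I", stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = "g1", start = 0L, end = 8L)
  out <- gene_gc3(g, make_ann(genes, exons))
  expect_true(out$partial_codon_dropped)
  expect_identical(out$n_codons, 2L)
  expect_equal(out$gc3, 0.5)   # thirds: G, A
})

test_that("GC3 skips N third positions and uses the longest-CDS transcript", {
  g <- dna(s = paste0("ATN", "GCC", strrep("A", 20)))
  genes <- data.frame(gene_id = "g1", symbol = "X", scaffold = "s",
                      strand = "+", start = 0L, end = 6L,
                      mhc_class = "I", stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = "g1", start = 0L, end = 6L)
  ann <- make_ann(genes, exons)
  # add a second, shorter transcript with different content
  ann$transcripts <- rbind(ann$transcripts,
                           data.frame(transcript_id = "t_short",
                                      gene_id = "g1"))
  ann$exons <- rbind(ann$exons,
                     data.frame(transcript_id = "t_short", start = 3L,
                                end = 6L, exon_rank = 1L))
  ann$cds <- rbind(ann$cds,
                   data.frame(transcript_id = "t_short", start = 3L,
                              end = 6L, frame = 0L))
  out <- gene_gc3(g, ann)
  expect_identical(out$transcript_id, "t_g1")
  expect_equal(out$gc3, 1)    # thirds: N (skipped), C
})

test_that("intron and intergenic statistics are exact on crafted genes", {
  genes <- data.frame(
    gene_id = c("gA", "gB", "gC"), symbol = c("A", "B", "C"),
    scaffold = "s", strand = c("+", "-", "+"),
    start = c(100L, 1000L, 900L), end = c(500L, 2000L, 1100L),
    mhc_class = "none", stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = c("gA", "gA", "gB", "gC"),
                      start = c(100L, 300L, 1000L, 900L),
                      end = c(200L, 500L, 2000L, 1100L))
  out <- intron_and_intergenic(make_ann(genes, exons))
  a <- out[out$gene_id == "gA", ]
  expect_equal(a$mean_intron_length, 100)
  expect_identical(a$n_introns, 1L)
  expect_true(is.na(a$intergenic_prev))          # scaffold-terminal side
  expect_equal(a$intergenic_next, 400)           # 900 - 500
  b <- out[out$gene_id == "gB", ]
  expect_true(is.na(b$mean_intron_length))       # intronless
  expect_equal(b$intergenic_prev, 0)             # overlap clamps to 0
  expect_true(b$overlaps_prev)
  expect_true(is.na(b$intergenic_next))
  c_ <- out[out$gene_id == "gC", ]
  expect_equal(c_$intergenic_prev, 400)
  expect_equal(c_$intergenic_next, 0)
})

test_that("region labels follow the midpoint rule", {
  feats <- data.frame(scaffold = c("s", "s", "s", "other"),
                      start = c(0, 90, 200, 100), end = c(100, 130, 300, 140))
  spans <- data.frame(scaffold = "s", start = 100, end = 200)
  out <- label_regions(feats, spans)
  # midpoints: 50 (out), 110 (in), 250 (out), other scaffold (out)
  expect_identical(out$region_label, c("nonMHC", "MHC", "nonMHC", "nonMHC"))
  # boundary: midpoint exactly at span start is in; at span end is out
  feats2 <- data.frame(scaffold = "s", start = c(50, 150), end = c(150, 250))
  expect_identical(label_regions(feats2, spans)$region_label,
                   c("MHC", "nonMHC"))
  # region_span objects and empty regions work
  rs <- delineate_and_size(data.frame(gene_id = "g", symbol = "X",
                                      scaffold = "s", start = 100, end = 200,
                                      mhc_class = "I"))
  expect_identical(label_regions(feats, rs)$region_label, out$region_label)
  empty <- delineate_and_size(data.frame(gene_id = "g", symbol = "X",
                                         scaffold = "s", start = 1, end = 2,
                                         mhc_class = "none"))
  expect_identical(unique(label_regions(feats, empty)$region_label), "nonMHC")
})

test_that("planted landscape contrasts are recovered on the shared sim", {
  s <- shared_sim()
  sp <- s$sim$reference
  region <- s$sim$truth$region[s$sim$truth$region$species == "reference", ]
  spans <- data.frame(scaffold = region$scaffold, start = region$start,
                      end = region$end)
  gc3 <- gene_gc3(sp$genome, sp$annotation)
  g <- sp$annotation$genes
  gc3 <- merge(gc3, g[, c("gene_id", "scaffold", "start", "end")], by = "gene_id")
  gc3 <- label_regions(gc3, spans)
  med <- tapply(gc3$gc3, gc3$region_label, median)
  expect_gt(med[["MHC"]], med[["nonMHC"]])
  ii <- intron_and_intergenic(sp$annotation)
  ii <- label_regions(ii, spans)
  ig <- tapply(ii$intergenic_next, ii$region_label, median, na.rm = TRUE)
  expect_lt(ig[["MHC"]], ig[["nonMHC"]])
})
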