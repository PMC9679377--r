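# Two-species synthetic system: a contiguous reference genome and a focal
# genome whose planted MHC-like region is fragmented into unplaced scaffolds,
# with full truth tables. The generator plants: a gene-dense region with
# class-clustered multi-class paralogs (a few class I genes interleaved in
# the class II neighborhood), repeat composition shifted in-region relative
# to background, elevated GC3 at region genes, log-scale intergenic/intron
# contrasts, N gaps, and spanning transcript + paired-end links across the
# fragmentation joins.

#' Simulation configuration
#'
#' Builds a validated configuration for the synthetic two-species system.
#' Defaults are the study conditions the pipeline is validated under:
#' 16 class I and 6 class II region genes; in-region window repeat
#' proportions of 0.19 (LINE) and 0.19 (DNA transposon) against background
#' 0.15 and 0.13; elevated region GC3; region intergenic/intron medians at
#' `region_spacing_ratio` times the background medians (log-normal draws);
#' the region fragmented into `n_fragments` unplaced scaffolds joined by
#' spanning transcript and paired-end links.
#'
#' @param seed Mandatory integer seed; the whole system is deterministic
#'   under it.
#' @param n_background_scaffolds,background_scaffold_length Number and
#'   length (bp) of background-only scaffolds. The default length (0.8 Mb)
#'   keeps them below the 1 Mb windowing floor, like unplaced scaffolds.
#' @param chrom_background_length Length (bp) of the background portion of
#'   the region-bearing chromosome; the planted region follows it at the
#'   chromosome end. A multiple of the window size keeps the region aligned
#'   to window boundaries.
#' @param region_length Nominal region length (bp); the realized length is
#'   emergent from gene counts and spacing draws.
#' @param n_class1_genes,n_class2_genes,n_class3_genes,n_framework_genes
#'   Planted region gene counts per MHC class.
#' @param region_repeat_props,background_repeat_props Named per-class target
#'   window proportions of planted repeat bp (must sum to <= 1).
#' @param region_gc3_mean,background_gc3_mean,gc3_sd Per-gene GC3 target
#'   distribution (normal, truncated to [0.05, 0.95]).
#' @param intergenic_meanlog,intergenic_sdlog Log-normal intergenic distance
#'   parameters for the background. The default sdlog (0.35) keeps the
#'   sampling error of a per-run median-ratio estimate over ~40 region gaps
#'   near 3 percentage points, so a 20-run average recovers the planted
#'   percent decrease to within ~1 point.
#' @param intron_meanlog,intron_sdlog Log-normal intron length parameters
#'   for the background.
#' @param region_spacing_ratio Ratio of region to background median
#'   intergenic distance and intron length (r < 1 plants the in-region
#'   contraction; expected percent decrease is 100 * (1 - r)).
#' @param background_gc Background GC fraction of non-repeat, non-coding
#'   sequence.
#' @param n_gaps_per_scaffold,gap_length Planted N gaps.
#' @param n_fragments Number of unplaced scaffolds the focal region is
#'   split into.
#' @param fragment_reversed_frac Fraction of fragments emitted
#'   reverse-complemented (truth records orientation).
#' @param tx_links_per_join,pe_links_per_join Spanning links planted per
#'   adjacent fragment pair.
#' @param insert_size_max Paired-end maximum insert size (bp).
#' @param background_hit_rate Poisson background homology hits per 100 kb.
#' @param hits_per_gene_mean Mean clustered hits per planted region gene.
#' @param hit_coverage_shape1,hit_coverage_shape2 Beta parameters of planted
#'   hit coverage.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_background_scaffolds = 4L,
                       background_scaffold_length = 8e5,
                       chrom_background_length = 2.5e6,
                       region_length = 7.5e5,
                       n_class1_genes = 16L,
                       n_class2_genes = 6L,
                       n_class3_genes = 12L,
                       n_framework_genes = 10L,
                       region_repeat_props = c(
                         DNA = 0.19, LINE = 0.19, SINE = 0.02, LTR = 0.03,
                         RC = 0.01, Satellite = 0.005, Simple_repeat = 0.01,
                         Low_complexity = 0.005, Unknown = 0.02),
                       background_repeat_props = c(
                         DNA = 0.13, LINE = 0.15, SINE = 0.03, LTR = 0.03,
                         RC = 0.01, Satellite = 0.005, Simple_repeat = 0.01,
                         Low_complexity = 0.005, Unknown = 0.02),
                       region_gc3_mean = 0.55,
                       background_gc3_mean = 0.45,
                       gc3_sd = 0.05,
                       intergenic_meanlog = log(16000),
                       intergenic_sdlog = 0.35,
                       intron_meanlog = log(1200),
                       intron_sdlog = 0.35,
                       region_spacing_ratio = 0.65,
                       background_gc = 0.40,
                       n_gaps_per_scaffold = 2L,
                       gap_length = 5000L,
                       n_fragments = 6L,
                       fragment_reversed_frac = 1 / 3,
                       tx_links_per_join = 1L,
                       pe_links_per_join = 1L,
                       insert_size_max = 100000L,
                       background_hit_rate = 2,
                       hits_per_gene_mean = 40,
                       hit_coverage_shape1 = 5,
                       hit_coverage_shape2 = 2,
                       window_size = 1e5) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("sim_config: seed is mandatory")
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  for (p in list(cfg$region_repeat_props, cfg$background_repeat_props)) {
    if (any(p < 0) || any(p > 1))
      stop("sim_config: repeat proportions must lie in [0, 1]")
    if (sum(p) > 1)
      stop("sim_config: repeat proportions sum to more than 1 (infeasible composition)")
    if (!all(names(p) %in% REPEAT_CLASSES))
      stop("sim_config: unknown repeat class in proportions")
  }
  if (cfg$n_fragments < 1) stop("sim_config: n_fragments must be >= 1")
  if (cfg$region_spacing_ratio <= 0)
    stop("sim_config: region_spacing_ratio must be positive")
  n_region_genes <- with(cfg, n_class1_genes + n_class2_genes +
                           n_class3_genes + n_framework_genes)
  if (n_region_genes < 1) stop("sim_config: no region genes configured")
  if (cfg$n_fragments > n_region_genes)
    stop("sim_config: n_fragments exceeds the region gene count")
  if (cfg$chrom_background_length %% cfg$window_size != 0)
    stop("sim_config: chrom_background_length must be a multiple of window_size")
  structure(cfg, class = "sim_config")
}

# deterministic region gene plan shared by both species:
# framework anchors at both ends, class II neighborhood with a few class I
# genes interleaved, then class III, then the main class I cluster,
# remaining framework genes spread between blocks
plan_region_genes <- function(config) {
  n1 <- config$n_class1_genes; n2 <- config$n_class2_genes
  n3 <- config$n_class3_genes; nf <- config$n_framework_genes
  sym <- function(fmt, n) if (n > 0) sprintf(fmt, seq_len(n)) else character(0)
  c1 <- sym("MHC1-%02d", n1); c2 <- sym("MHC2B-%02d", n2)
  c3 <- sym("C3G-%02d", n3); fw <- sym("FRW-%02d", nf)
  if (nf >= 1) fw[1] <- "GABBR1"
  if (nf >= 2) fw[nf] <- "DAXX"
  n_inter <- min(3L, n1)          # class I genes inside the class II block
  inter <- head(c1, n_inter); c1rest <- c1[seq_len(n1) > n_inter]
  # interleave the borrowed class I genes into the class II block
  block2 <- character(0)
  if (length(c2) || length(inter)) {
    slots <- max(length(c2) + length(inter), 1L)
    pos <- unique(round(seq(2, slots, length.out = length(inter))))
    block2 <- c2
    for (k in seq_along(inter))
      block2 <- append(block2, inter[k],
                       after = min(pos[k] - 1, length(block2)))
  }
  mid_fw <- if (nf > 2) fw[-c(1, nf)] else character(0)
  order_sym <- c(if (nf >= 1) fw[1],
                 head(mid_fw, ceiling(length(mid_fw) / 2)),
                 block2, c3, c1rest,
                 tail(mid_fw, floor(length(mid_fw) / 2)),
                 if (nf >= 2) fw[nf])
  cls <- c(setNames(rep("I", n1), c1), setNames(rep("II", n2), c2),
           setNames(rep("III", n3), c3),
           setNames(rep("framework", nf), fw))
  data.frame(symbol = order_sym, mhc_class = unname(cls[order_sym]),
             stringsAsFactors = FALSE)
}

# draw one gene structure: exon count, exon/intron lengths, strand, GC3 target
draw_gene_structure <- function(config, in_region) {
  n_exons <- sample(3:6, 1)
  exon_len <- rep(300L, n_exons)   # CDS == exons; multiples of 3
  ratio <- if (in_region) config$region_spacing_ratio else 1
  introns <- if (n_exons > 1) {
    pmax(50L, as.integer(round(rlnorm(n_exons - 1,
                                      config$intron_meanlog + log(ratio),
                                      config$intron_sdlog))))
  } else integer(0)
  gc3_mean <- if (in_region) config$region_gc3_mean else config$background_gc3_mean
  gc3 <- min(0.95, max(0.05, rnorm(1, gc3_mean, config$gc3_sd)))
  list(exon_len = exon_len, introns = introns,
       strand = sample(c("+", "-"), 1), gc3_target = gc3,
       length = sum(exon_len) + sum(introns))
}

# generate a sense-strand CDS with the given GC3 target; returns the
# sequence and the realized GC3
generate_cds <- function(n_codons, gc3_target, background_gc) {
  p12 <- c(A = (1 - background_gc) / 2, C = background_gc / 2,
           G = background_gc / 2, T = (1 - background_gc) / 2)
  pos12 <- sample(names(p12), 2 * n_codons, replace = TRUE, prob = p12)
  p3 <- c(G = gc3_target / 2, C = gc3_target / 2,
          A = (1 - gc3_target) / 2, T = (1 - gc3_target) / 2)
  pos3 <- sample(names(p3), n_codons, replace = TRUE, prob = p3)
  m <- rbind(matrix(pos12, nrow = 2), pos3)
  list(seq = paste(m, collapse = ""),
       gc3 = mean(pos3 %in% c("G", "C")))
}

random_seq <- function(n, gc) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# repeat fill motifs, one per class (low-complexity tandem fill; downstream
# consumes the annotations, not the sequence)
REPEAT_MOTIFS <- c(DNA = "TTAACCGGTTAA", LINE = "TTAGGCATTAGG",
                   SINE = "GGCCAATT", LTR = "TGTTACAACG", RC = "TATACGCG",
                   Satellite = "AATGG", Simple_repeat = "AT",
                   Low_complexity = "A", Unknown = "CATTGA")

motif_fill <- function(class, n) {
  m <- REPEAT_MOTIFS[[class]]
  substr(strrep(m, ceiling(n / nchar(m))), 1, n)
}

# Place genes sequentially along a coordinate axis starting at `origin`.
# Returns gene table rows and the cursor after the final tail.
place_genes <- function(config, symbols, classes, in_region, origin,
                        species, id_prefix, fixed_end = NA) {
  ratio <- if (in_region) config$region_spacing_ratio else 1
  meanlog <- config$intergenic_meanlog + log(ratio)
  genes <- list()
  cursor <- origin + 2000   # short fixed lead-in before the first gene
  for (i in seq_along(symbols)) {
    st <- draw_gene_structure(config, in_region)
    if (!is.na(fixed_end) && cursor + st$length + 2000 > fixed_end) break
    gid <- sprintf("%s_%s_g%03d", species, id_prefix, i)
    genes[[length(genes) + 1]] <- list(
      gene_id = gid, symbol = symbols[i], mhc_class = classes[i],
      start = as.integer(round(cursor)),
      structure = st)
    cursor <- round(cursor) + st$length
    if (i < length(symbols) || is.na(fixed_end))
      cursor <- cursor + pmax(500, round(rlnorm(1, meanlog,
                                                config$intergenic_sdlog)))
  }
  list(genes = genes, cursor = cursor + 2000)  # short tail after last gene
}

# Assemble one scaffold: genes -> N gaps -> per-window repeat planting ->
# sequence emission. `region_start` is NA for background-only scaffolds.
build_scaffold <- function(config, scaffold, species, bg_symbols,
                           region_plan = NULL, region_start = NA,
                           fixed_length = NA) {
  # --- gene placement
  placed <- list()
  if (length(bg_symbols)) {
    bg_end <- if (!is.na(region_start)) region_start else fixed_length
    pb <- place_genes(config, bg_symbols,
                      rep("none", length(bg_symbols)), FALSE, 0,
                      species, paste0(scaffold, "bg"), fixed_end = bg_end)
    placed <- pb$genes
  }
  if (!is.null(region_plan)) {
    pr <- place_genes(config, region_plan$symbol, region_plan$mhc_class,
                      TRUE, region_start, species, paste0(scaffold, "mhc"))
    placed <- c(placed, pr$genes)
    scaf_len <- as.integer(pr$cursor)
  } else {
    scaf_len <- as.integer(fixed_length)
  }
  gene_tab <- do.call(rbind, lapply(placed, function(g)
    data.frame(gene_id = g$gene_id, symbol = g$symbol,
               mhc_class = g$mhc_class, start = g$start,
               end = g$start + g$structure$length,
               strand = g$structure$strand, stringsAsFactors = FALSE)))
  if (is.null(gene_tab)) gene_tab <- data.frame(
    gene_id = character(0), symbol = character(0), mhc_class = character(0),
    start = integer(0), end = integer(0), strand = character(0))

  # --- N gaps inside large inter-gene intervals
  occupied <- gene_tab[, c("start", "end")]
  free_iv <- function() {
    ir <- IRanges::IRanges(start = 1, end = scaf_len)  # 1-based internal calc
    occ <- IRanges::IRanges(start = occupied$start + 1, end = occupied$end)
    IRanges::setdiff(ir, IRanges::reduce(occ))
  }
  gaps <- data.frame(start = integer(0), end = integer(0))
  fr <- free_iv()
  big <- which(IRanges::width(fr) > config$gap_length + 4000)
  if (config$n_gaps_per_scaffold > 0 && length(big)) {
    pick <- sample(big, min(config$n_gaps_per_scaffold, length(big)))
    for (j in pick) {
      mid <- IRanges::start(fr)[j] - 1 + IRanges::width(fr)[j] %/% 2
      g0 <- mid - config$gap_length %/% 2
      gaps <- rbind(gaps, data.frame(start = g0, end = g0 + config$gap_length))
    }
    occupied <- rbind(occupied, gaps)
  }

  # --- per-window repeat planting into free (inter-gene, non-gap) space
  win_starts <- seq(0, scaf_len - 1, by = config$window_size)
  rep_list <- list()
  fr <- free_iv()
  free_df <- data.frame(start = IRanges::start(fr) - 1, end = IRanges::end(fr))
  for (ws in win_starts) {
    we <- min(ws + config$window_size, scaf_len)
    wlen <- we - ws
    p <- if (!is.na(region_start) && ws >= region_start)
      config$region_repeat_props else config$background_repeat_props
    need <- setNames(round(p * wlen), names(p))
    # free sub-intervals clipped to the window
    f <- free_df[free_df$end > ws & free_df$start < we, , drop = FALSE]
    if (!nrow(f)) next
    f$start <- pmax(f$start, ws); f$end <- pmin(f$end, we)
    for (i in seq_len(nrow(f))) {
      pos <- f$start[i]
      while (pos < f$end[i] && any(need > 0)) {
        open <- names(need)[need > 0]
        cl <- if (length(open) == 1) open else
          sample(open, 1, prob = need[open] / sum(need[open]))
        len <- min(sample(600:2000, 1), need[[cl]], f$end[i] - pos)
        rep_list[[length(rep_list) + 1]] <- data.frame(
          scaffold = scaffold, start = pos, end = pos + len,
          repeat_class = cl, family = paste0(cl, "_sim"),
          name = paste0(cl, "_sim"), stringsAsFactors = FALSE)
        need[[cl]] <- need[[cl]] - len
        pos <- pos + len
      }
    }
  }
  repeats <- if (length(rep_list)) do.call(rbind, rep_list) else
    data.frame(scaffold = character(0), start = integer(0), end = integer(0),
               repeat_class = character(0), family = character(0),
               name = character(0), stringsAsFactors = FALSE)

  # --- emit sequence and exon/CDS structure
  ann <- build_gene_models(placed, scaffold, config)
  seq <- emit_sequence(scaf_len, placed, ann, gaps, repeats, config)

  gene_tab$scaffold <- rep(scaffold, nrow(gene_tab))
  gene_tab$gc3 <- as.numeric(attr(ann, "realized_gc3"))
  list(scaffold = scaffold, length = scaf_len, seq = seq,
       genes = gene_tab, annotation = ann, repeats = repeats, gaps = gaps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exon/intron genomic layout and CDS generation for the placed genes;
# mutates each placed gene with realized_gc3 and exon sequences (by
# environment trick: returns annotation plus per-gene seq chunks)
build_gene_models <- function(placed, scaffold, config) {
  genes <- list(); txs <- list(); exons <- list(); cds <- list()
  for (k in seq_along(placed)) {
    g <- placed[[k]]
    st <- g$structure
    n_ex <- length(st$exon_len)
    # genomic exon intervals, left to right
    ex_start <- g$start + c(0, cumsum(st$exon_len[-n_ex] + st$introns))
    ex_end <- ex_start + st$exon_len
    n_codons <- sum(st$exon_len) %/% 3
    cdsgen <- generate_cds(n_codons, st$gc3_target, config$background_gc)
    placed[[k]]$realized_gc3 <- cdsgen$gc3
    # sense CDS split into transcript-order exon chunks
    offs <- c(0, cumsum(st$exon_len))
    sense_chunks <- substring(cdsgen$seq, offs[-length(offs)] + 1, offs[-1])
    # genomic content: for "-" genes, genomic exon i carries the reverse
    # complement of the sense exon in reverse transcript order
    genomic_chunks <- if (st$strand == "+") sense_chunks else
      rev(vapply(sense_chunks, revcomp_chr, character(1)))
    tid <- paste0("t_", g$gene_id)
    genes[[k]] <- data.frame(gene_id = g$gene_id, symbol = g$symbol,
                             scaffold = scaffold, strand = st$strand,
                             start = g$start, end = g$start + st$length,
                             mhc_class = g$mhc_class, stringsAsFactors = FALSE)
    txs[[k]] <- data.frame(transcript_id = tid, gene_id = g$gene_id,
                           stringsAsFactors = FALSE)
    exons[[k]] <- data.frame(transcript_id = tid, start = ex_start,
                             end = ex_end, exon_rank = seq_len(n_ex),
                             exon_seq = genomic_chunks,
                             intron_lengths = I(rep(list(st$introns), n_ex)),
                             stringsAsFactors = FALSE)
    cds[[k]] <- data.frame(transcript_id = tid, start = ex_start,
                           end = ex_end, frame = 0L, stringsAsFactors = FALSE)
  }
  gc3 <- vapply(placed, function(g) g$realized_gc3 %||% NA_real_, numeric(1))
  ann <- new_annotation(
    if (length(genes)) do.call(rbind, genes) else empty_annotation()$genes,
    if (length(txs)) do.call(rbind, txs) else empty_annotation()$transcripts,
    if (length(exons)) do.call(rbind, lapply(exons, function(e)
      e[, c("transcript_id", "start", "end", "exon_rank")])) else
        empty_annotation()$exons,
    if (length(cds)) do.call(rbind, cds) else empty_annotation()$cds
  )
  attr(ann, "exon_seqs") <- if (length(exons)) do.call(rbind, lapply(
    exons, function(e) e[, c("transcript_id", "start", "end", "exon_seq")]))
    else NULL
  attr(ann, "realized_gc3") <- gc3
  ann
}

# assemble the scaffold sequence from its segments
emit_sequence <- function(scaf_len, placed, ann, gaps, repeats, config) {
  segs <- list()
  exseq <- attr(ann, "exon_seqs")
  if (!is.null(exseq)) {
    for (i in seq_len(nrow(exseq)))
      segs[[length(segs) + 1]] <- list(start = exseq$start[i],
                                       end = exseq$end[i],
                                       seq = exseq$exon_seq[i])
  }
  # introns: gene body minus exons, random background-GC fill
  for (g in placed) {
    st <- g$structure
    if (length(st$introns)) {
      n_ex <- length(st$exon_len)
      ex_start <- g$start + c(0, cumsum(st$exon_len[-n_ex] + st$introns))
      for (j in seq_len(n_ex - 1)) {
        is0 <- ex_start[j] + st$exon_len[j]
        segs[[length(segs) + 1]] <- list(
          start = is0, end = is0 + st$introns[j],
          seq = random_seq(st$introns[j], config$background_gc))
      }
    }
  }
  for (i in seq_len(nrow(gaps)))
    segs[[length(segs) + 1]] <- list(start = gaps$start[i], end = gaps$end[i],
                                     seq = strrep("N", gaps$end[i] - gaps$start[i]))
  for (i in seq_len(nrow(repeats)))
    segs[[length(segs) + 1]] <- list(
      start = repeats$start[i], end = repeats$end[i],
      seq = motif_fill(repeats$repeat_class[i],
                       repeats$end[i] - repeats$start[i]))
  if (length(segs)) {
    ord <- order(vapply(segs, `[[`, numeric(1), "start"))
    segs <- segs[ord]
  }
  pieces <- character(0)
  cursor <- 0
  for (s in segs) {
    if (s$start > cursor)
      pieces <- c(pieces, random_seq(s$start - cursor, config$background_gc))
    pieces <- c(pieces, s$seq)
    cursor <- s$end
  }
  if (cursor < scaf_len)
    pieces <- c(pieces, random_seq(scaf_len - cursor, config$background_gc))
  paste(pieces, collapse = "")
}

# build one species (reference or focal): region-bearing chromosome +
# background scaffolds
build_species <- function(config, species, plan) {
  scafs <- list()
  n_bg_chr2 <- max(0L, as.integer(round(
    config$chrom_background_length /
      exp(config$intergenic_meanlog + config$intergenic_sdlog^2 / 2 + log(1.4)))))
  bg_sym_chr2 <- sprintf("BG2-%03d", seq_len(max(n_bg_chr2, 200)))
  scafs$chr2 <- build_scaffold(config, "chr2", species, bg_sym_chr2,
                               region_plan = plan,
                               region_start = config$chrom_background_length)
  for (i in seq_len(config$n_background_scaffolds)) {
    nm <- sprintf("scaf%02d", i)
    scafs[[nm]] <- build_scaffold(
      config, nm, species, sprintf("BG%02d-%03d", i, 1:200),
      fixed_length = config$background_scaffold_length)
  }
  genome <- Biostrings::DNAStringSet(
    setNames(vapply(scafs, `[[`, character(1), "seq"), names(scafs)))
  ann <- merge_annotations(lapply(scafs, `[[`, "annotation"))
  repeats <- do.call(rbind, c(lapply(scafs, `[[`, "repeats"),
                              make.row.names = FALSE))
  genes_truth <- do.call(rbind, c(lapply(scafs, function(s) s$genes),
                                  make.row.names = FALSE))
  genes_truth$species <- species
  gaps <- do.call(rbind, c(lapply(scafs, function(s)
    if (nrow(s$gaps)) cbind(s$gaps, scaffold = s$scaffold) else NULL),
    make.row.names = FALSE))
  region <- data.frame(species = species, scaffold = "chr2",
                       start = config$chrom_background_length,
                       end = scafs$chr2$length, stringsAsFactors = FALSE)
  list(species = species, genome = genome, annotation = ann,
       repeats = repeats, genes_truth = genes_truth, region = region,
       gaps = if (is.null(gaps)) data.frame(start = integer(0),
                                            end = integer(0),
                                            scaffold = character(0)) else gaps)
}

merge_annotations <- function(anns) {
  out <- new_annotation(
    do.call(rbind, c(lapply(anns, `[[`, "genes"), make.row.names = FALSE)),
    do.call(rbind, c(lapply(anns, `[[`, "transcripts"), make.row.names = FALSE)),
    do.call(rbind, c(lapply(anns, `[[`, "exons"), make.row.names = FALSE)),
    do.call(rbind, c(lapply(anns, `[[`, "cds"), make.row.names = FALSE))
  )
  out
}

#' Simulate the two-species synthetic system
#'
#' Generates a contiguous reference genome and a focal genome, each with a
#' planted MHC-like region at the end of `chr2`, plus truth tables. Both
#' species share one region gene plan (order, symbols, classes) so the focal
#' fragments can be placed against the reference by synteny; coordinates,
#' spacing, GC3 and repeat draws are realized independently per species.
#' Fully deterministic under `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with elements `reference`, `focal` (each: `genome`,
#'   `annotation`, `repeats`, `genes_truth`, `region`, `gaps`), `plan`,
#'   and `truth` (region spans, per-gene classes and realized GC3,
#'   per-window planted repeat proportions).
#' @export
simulate_genomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  plan <- plan_region_genes(config)
  reference <- build_species(config, "reference", plan)
  focal <- build_species(config, "focal", plan)
  truth_windows <- rbind(
    planted_window_repeats(reference, config),
    planted_window_repeats(focal, config))
  list(reference = reference, focal = focal, plan = plan,
       truth = list(
         region = rbind(reference$region, focal$region),
         genes = rbind(reference$genes_truth, focal$genes_truth),
         window_repeats = truth_windows))
}

# truth per-window repeat proportions recomputed from the planted intervals
planted_window_repeats <- function(sp, config) {
  lens <- scaffold_lengths(sp$genome)
  out <- list()
  for (sc in names(lens)) {
    ws <- seq(0, lens[[sc]] - 1, by = config$window_size)
    we <- pmin(ws + config$window_size, lens[[sc]])
    rr <- sp$repeats[sp$repeats$scaffold == sc, , drop = FALSE]
    for (cl in REPEAT_CLASSES) {
      ri <- rr[rr$repeat_class == cl, , drop = FALSE]
      bp <- vapply(seq_along(ws), function(i) {
        if (!nrow(ri)) return(0)
        sum(pmax(0, pmin(ri$end, we[i]) - pmax(ri$start, ws[i])))
      }, numeric(1))
      out[[length(out) + 1]] <- data.frame(
        species = sp$species, scaffold = sc, start = ws, end = we,
        repeat_class = cl, bp = bp, proportion = bp / (we - ws),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

# ---- fragmentation and links -----------------------------------------------

#' Fragment the focal region into unplaced scaffolds with link evidence
#'
#' Splits the focal region (the end of `chr2`) into `config$n_fragments`
#' unplaced scaffolds at inter-gene cut points, reverse-complementing a
#' configured fraction of them, and emits: the fragmented focal assembly,
#' alignment blocks (PAF-style) from each fragment to its true interval on
#' the reference, and transcript / paired-end links spanning each adjacent
#' fragment pair. Truth records the fragment order and orientation.
#'
#' @param sim Output of [simulate_genomes()].
#' @param config The same [sim_config()].
#' @return List with `genome` (fragmented focal assembly), `annotation`,
#'   `repeats` (both remapped to fragment coordinates), `blocks`,
#'   `tx_links`, `pe_links`, and `truth_fragments`.
#' @export
fragment_and_link <- function(sim, config) {
  set.seed(config$seed + 1L)
  focal <- sim$focal
  region <- focal$region
  rg <- focal$genes_truth
  rg <- rg[rg$scaffold == "chr2" & rg$mhc_class != "none", , drop = FALSE]
  rg <- rg[order(rg$start), ]
  n <- config$n_fragments
  if (n > nrow(rg)) stop("n_fragments exceeds the region gene count")
  chr2_len <- scaffold_lengths(focal$genome)[["chr2"]]

  # cut points at inter-gene midpoints nearest to even splits of the region
  cuts <- integer(0)
  if (n > 1) {
    mids <- (rg$end[-nrow(rg)] + rg$start[-1]) %/% 2
    targets <- region$start + (region$end - region$start) * seq_len(n - 1) / n
    for (t in targets) {
      j <- which.min(abs(mids - t))
      cuts <- c(cuts, mids[j]); mids[j] <- NA
    }
    cuts <- sort(cuts)
  }
  bounds <- c(region$start, cuts, region$end)

  n_rev <- floor(config$fragment_reversed_frac * n)
  reversed <- rep(FALSE, n)
  if (n_rev > 0) reversed[sample(n, n_rev)] <- TRUE

  frag_names <- sprintf("frag_%02d", seq_len(n))
  chr2_seq <- as.character(focal$genome[["chr2"]])

  seqs <- list(chr2 = substr(chr2_seq, 1, region$start))
  for (sc in setdiff(names(focal$genome), "chr2"))
    seqs[[sc]] <- as.character(focal$genome[[sc]])
  truth_fragments <- data.frame(
    fragment = frag_names, order_index = seq_len(n),
    orientation = ifelse(reversed, "opposite", "same"),
    focal_start = head(bounds, -1), focal_end = bounds[-1],
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    s <- substr(chr2_seq, bounds[i] + 1, bounds[i + 1])
    if (reversed[i]) s <- revcomp_chr(s)
    seqs[[frag_names[i]]] <- s
  }
  genome <- Biostrings::DNAStringSet(unlist(seqs))

  # remap an interval [s,e) on focal chr2 into fragment coordinates
  remap <- function(s, e) {
    i <- findInterval(s, bounds, rightmost.closed = FALSE)
    i <- pmin(pmax(i, 1L), n)
    L <- bounds[i + 1] - bounds[i]
    rs <- s - bounds[i]; re <- e - bounds[i]
    flip <- reversed[i]
    data.frame(scaffold = frag_names[i],
               start = ifelse(flip, L - re, rs),
               end = ifelse(flip, L - rs, re),
               flipped = flip)
  }

  # annotation: keep non-chr2 scaffolds, truncated chr2 genes, remap region
  ann <- focal$annotation
  g <- ann$genes
  keep <- g$scaffold != "chr2" | g$end <= region$start
  reg_gene <- g$scaffold == "chr2" & g$start >= region$start
  new_genes <- g[keep | reg_gene, , drop = FALSE]
  mg <- remap(new_genes$start[reg_gene[keep | reg_gene]],
              new_genes$end[reg_gene[keep | reg_gene]])
  sel <- which(reg_gene[keep | reg_gene])
  new_genes$scaffold[sel] <- mg$scaffold
  new_genes$start[sel] <- mg$start
  new_genes$end[sel] <- mg$end
  new_genes$strand[sel] <- ifelse(mg$flipped,
                                  ifelse(new_genes$strand[sel] == "+", "-", "+"),
                                  new_genes$strand[sel])
  tx_keep <- ann$transcripts$gene_id %in% new_genes$gene_id
  new_tx <- ann$transcripts[tx_keep, , drop = FALSE]
  remap_feats <- function(ft) {
    ft <- ft[ft$transcript_id %in% new_tx$transcript_id, , drop = FALSE]
    g2t <- setNames(new_tx$gene_id, new_tx$transcript_id)
    on_frag <- new_genes$gene_id[sel]
    is_reg <- g2t[ft$transcript_id] %in% on_frag
    if (any(is_reg)) {
      mf <- remap(ft$start[is_reg], ft$end[is_reg])
      ft$start[is_reg] <- mf$start; ft$end[is_reg] <- mf$end
    }
    ft
  }
  new_ex <- remap_feats(ann$exons)
  # exon_rank follows genomic re-sorting on flipped fragments
  new_ex <- new_ex[order(new_ex$transcript_id, new_ex$start), , drop = FALSE]
  new_ex$exon_rank <- stats::ave(new_ex$start, new_ex$transcript_id,
                                 FUN = seq_along)
  new_cds <- remap_feats(ann$cds)
  new_ann <- new_annotation(new_genes, new_tx, new_ex, new_cds)

  # repeats: split at cut points, then remap
  rp <- focal$repeats
  keep_rp <- rp$scaffold != "chr2" | rp$end <= region$start
  reg_rp <- rp[rp$scaffold == "chr2" & rp$end > region$start, , drop = FALSE]
  if (nrow(reg_rp)) {
    pieces <- list()
    for (i in seq_len(nrow(reg_rp))) {
      b <- bounds[bounds > reg_rp$start[i] & bounds < reg_rp$end[i]]
      ss <- c(reg_rp$start[i], b); ee <- c(b, reg_rp$end[i])
      pieces[[i]] <- data.frame(reg_rp[i, setdiff(names(reg_rp),
                                                  c("start", "end"))],
                                start = ss, end = ee, row.names = NULL)
    }
    reg_rp <- do.call(rbind, pieces)
    mr <- remap(reg_rp$start, reg_rp$end)
    reg_rp$scaffold <- mr$scaffold
    reg_rp$start <- mr$start; reg_rp$end <- mr$end
  }
  new_repeats <- rbind(rp[keep_rp, , drop = FALSE],
                       reg_rp[, names(rp), drop = FALSE])

  # alignment blocks: per fragment, one block per gene half, targeting the
  # reference interval of the same plan genes
  ref_genes <- sim$reference$genes_truth
  ref_genes <- ref_genes[ref_genes$mhc_class != "none" &
                           ref_genes$scaffold == "chr2", , drop = FALSE]
  ref_pos <- ref_genes[match(rg$symbol, ref_genes$symbol), ]
  blocks <- list()
  frag_lens <- scaffold_lengths(genome)
  for (i in seq_len(n)) {
    in_frag <- which(rg$start >= bounds[i] & rg$end <= bounds[i + 1])
    if (!length(in_frag)) next
    halves <- if (length(in_frag) >= 2)
      split(in_frag, cut(seq_along(in_frag), 2, labels = FALSE))
    else list(in_frag)
    for (h in halves) {
      src_s <- max(bounds[i], min(rg$start[h]) - 1000)
      src_e <- min(bounds[i + 1], max(rg$end[h]) + 1000)
      m <- remap(src_s, src_e)
      tgt_s <- max(0, min(ref_pos$start[h]) - 1000)
      tgt_e <- max(ref_pos$end[h]) + 1000
      blocks[[length(blocks) + 1]] <- data.frame(
        source = frag_names[i], source_start = m$start, source_end = m$end,
        source_length = frag_lens[[frag_names[i]]],
        target = "chr2", target_start = tgt_s, target_end = tgt_e,
        target_length = scaffold_lengths(sim$reference$genome)[["chr2"]],
        orientation = ifelse(reversed[i], "opposite", "same"),
        aligned_length = as.integer(round(0.9 * min(src_e - src_s,
                                                    tgt_e - tgt_s))),
        stringsAsFactors = FALSE)
    }
  }
  blocks <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(source = character(0), source_start = integer(0),
               source_end = integer(0), source_length = integer(0),
               target = character(0), target_start = integer(0),
               target_end = integer(0), target_length = integer(0),
               orientation = character(0), aligned_length = integer(0))
  rownames(truth_fragments) <- NULL
  truth_fragments$ref_target_start <- NA_real_
  truth_fragments$ref_target_end <- NA_real_
  for (i in seq_len(n)) {
    b <- blocks[blocks$source == frag_names[i], , drop = FALSE]
    if (nrow(b)) {
      truth_fragments$ref_target_start[i] <- min(b$target_start)
      truth_fragments$ref_target_end[i] <- max(b$target_end)
    }
  }

  # spanning links across each adjacent fragment pair
  tx_links <- list(); pe_links <- list()
  junction_pos <- function(i, side) {
    # emitted-coordinate interval of length 500 within 1.5 kb of the
    # junction-side end of fragment i; side = "right" (toward i+1) or "left"
    L <- bounds[i + 1] - bounds[i]
    orig <- if (side == "right") c(L - 1500, L - 1000) else c(1000, 1500)
    if (reversed[i]) orig <- c(L - orig[2], L - orig[1])
    orig
  }
  for (i in seq_len(max(0, n - 1))) {
    for (k in seq_len(config$tx_links_per_join)) {
      p1 <- junction_pos(i, "right"); p2 <- junction_pos(i + 1, "left")
      tx_links[[length(tx_links) + 1]] <- data.frame(
        transcript_id = sprintf("txlink_%02d_%d", i, k),
        scaffold = c(frag_names[i], frag_names[i + 1]),
        start = c(p1[1], p2[1]), end = c(p1[2], p2[2]),
        strand = c(ifelse(reversed[i], "-", "+"),
                   ifelse(reversed[i + 1], "-", "+")),
        exon_rank = 1:2, stringsAsFactors = FALSE)
    }
    for (k in seq_len(config$pe_links_per_join)) {
      p1 <- junction_pos(i, "right"); p2 <- junction_pos(i + 1, "left")
      pe_links[[length(pe_links) + 1]] <- data.frame(
        link_id = sprintf("clone_%02d_%d", i, k), end = 1:2,
        scaffold = c(frag_names[i], frag_names[i + 1]),
        position = c(p1[1], p2[1]),
        strand = c("+", "-"),
        insert_size_max = config$insert_size_max, stringsAsFactors = FALSE)
    }
  }
  empty_tx <- data.frame(transcript_id = character(0), scaffold = character(0),
                         start = integer(0), end = integer(0),
                         strand = character(0), exon_rank = integer(0))
  empty_pe <- data.frame(link_id = character(0), end = integer(0),
                         scaffold = character(0), position = integer(0),
                         strand = character(0), insert_size_max = integer(0))
  list(genome = genome, annotation = new_ann, repeats = new_repeats,
       blocks = blocks,
       tx_links = if (length(tx_links)) do.call(rbind, tx_links) else empty_tx,
       pe_links = if (length(pe_links)) do.call(rbind, pe_links) else empty_pe,
       truth_fragments = truth_fragments)
}

# ---- homology hit simulation -----------------------------------------------

#' Simulate a protein-vs-genome homology hit table
#'
#' Each planted MHC-classed gene yields a Poisson number of clustered hits
#' (coverage drawn from a Beta distribution); background hits arrive as a
#' Poisson process of `config$background_hit_rate` per 100 kb, uniformly
#' placed. Per-hit source gene is recorded in the truth table.
#'
#' @param genome `DNAStringSet` of the target assembly.
#' @param genes_truth Truth gene table of that assembly (needs `gene_id`,
#'   `scaffold`, `start`, `end`, `strand`, `mhc_class`).
#' @param config The [sim_config()].
#' @param seed_offset Added to `config$seed` so reference and focal hit
#'   tables are independent.
#' @return List with `hits` (raw 12-column outfmt-6 style data frame),
#'   `query_meta`, and `truth_hits` (hit row -> source gene or
#'   `"background"`).
#' @export
simulate_hits <- function(genome, genes_truth, config, seed_offset = 2L) {
  set.seed(config$seed + seed_offset)
  classes <- c("I", "II", "III", "framework")
  qlen <- c(250L, 320L, 380L)
  query_meta <- do.call(rbind, lapply(classes, function(cl)
    data.frame(query_id = sprintf("Q_%s_%d", cl, 1:3),
               symbol = sprintf("QSYM_%s_%d", cl, 1:3),
               query_length = qlen, mhc_class = cl,
               stringsAsFactors = FALSE)))
  rows <- list(); src <- character(0)
  add_hit <- function(scaffold, s0, e0, strand, q, cov, source) {
    alen <- max(1L, as.integer(round(cov * q$query_length)))
    ss <- if (strand == "+") c(s0 + 1L, e0) else c(e0, s0 + 1L)
    rows[[length(rows) + 1]] <<- data.frame(
      qseqid = q$query_id, sseqid = scaffold,
      pident = round(runif(1, 35, 95), 2), length = alen,
      mismatch = as.integer(round(alen * 0.3)), gapopen = 0L,
      qstart = 1L, qend = alen, sstart = ss[1], send = ss[2],
      evalue = 1e-20, bitscore = round(50 + 200 * cov, 1),
      stringsAsFactors = FALSE)
    src[length(src) + 1] <<- source
  }
  mhc_genes <- genes_truth[genes_truth$mhc_class != "none", , drop = FALSE]
  for (i in seq_len(nrow(mhc_genes))) {
    g <- mhc_genes[i, ]
    nh <- 1L + rpois(1, max(0, config$hits_per_gene_mean - 1))
    qpool <- query_meta[query_meta$mhc_class == g$mhc_class, , drop = FALSE]
    for (j in seq_len(nh)) {
      q <- qpool[sample(nrow(qpool), 1), ]
      cov <- rbeta(1, config$hit_coverage_shape1, config$hit_coverage_shape2)
      span <- min(g$end - g$start,
                  max(30L, as.integer(round(cov * q$query_length * 3))))
      s0 <- g$start + sample.int(max(1L, g$end - g$start - span + 1L), 1) - 1L
      add_hit(g$scaffold, s0, s0 + span, g$strand, q, cov, g$gene_id)
    }
  }
  lens <- scaffold_lengths(genome)
  for (sc in names(lens)) {
    nb <- rpois(1, config$background_hit_rate * lens[[sc]] / 1e5)
    for (j in seq_len(nb)) {
      q <- query_meta[sample(nrow(query_meta), 1), ]
      cov <- rbeta(1, 1.2, 4)
      span <- max(30L, as.integer(round(cov * q$query_length * 3)))
      s0 <- sample.int(max(1L, lens[[sc]] - span), 1) - 1L
      add_hit(sc, s0, s0 + span, sample(c("+", "-"), 1), q, cov, "background")
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(qseqid = character(0), sseqid = character(0),
               pident = numeric(0), length = integer(0),
               mismatch = integer(0), gapopen = integer(0),
               qstart = integer(0), qend = integer(0), sstart = integer(0),
               send = integer(0), evalue = numeric(0), bitscore = numeric(0))
  list(hits = hits, query_meta = query_meta, truth_hits = src)
}

#' Write a raw hit table in BLAST outfmt-6 layout
#' @param hits Raw hit data frame from [simulate_hits()].
#' @param path Output path.
#' @export
write_blast_tab <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write the full synthetic system to a directory
#'
#' Emits reference and focal FASTA / GFF3 / RepeatMasker `.out`, the
#' fragmented focal assembly with PAF + link TSVs, a simulated hit table
#' with query metadata, and all truth tables as TSV.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the list of generated objects.
#' @export
write_simulation <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_genomes(config)
  frag <- fragment_and_link(sim, config)
  hits_ref <- simulate_hits(sim$reference$genome, sim$reference$genes_truth,
                            config, seed_offset = 2L)
  hits_frag <- simulate_hits(frag$genome, frag$annotation$genes, config,
                             seed_offset = 3L)
  p <- function(...) file.path(outdir, paste0(...))
  tsv <- function(x, path) write.table(x, path, sep = "\t", quote = FALSE,
                                       row.names = FALSE)
  write_fasta(sim$reference$genome, p("reference.fa"))
  write_gff3(sim$reference$annotation, p("reference.gff3"))
  write_repeatmasker_out(sim$reference$repeats, p("reference.out"))
  write_fasta(sim$focal$genome, p("focal.fa"))
  write_gff3(sim$focal$annotation, p("focal.gff3"))
  write_repeatmasker_out(sim$focal$repeats, p("focal.out"))
  write_fasta(frag$genome, p("focal_fragmented.fa"))
  write_gff3(frag$annotation, p("focal_fragmented.gff3"))
  write_repeatmasker_out(frag$repeats, p("focal_fragmented.out"))
  write_paf(frag$blocks, p("fragments.paf"))
  tsv(frag$tx_links, p("tx_links.tsv"))
  tsv(frag$pe_links, p("pe_links.tsv"))
  write_blast_tab(hits_ref$hits, p("hits_reference.tsv"))
  write_blast_tab(hits_frag$hits, p("hits_fragmented.tsv"))
  tsv(hits_ref$query_meta, p("query_meta.tsv"))
  tsv(sim$truth$region, p("truth_region.tsv"))
  tsv(sim$truth$genes, p("truth_genes.tsv"))
  tsv(sim$truth$window_repeats, p("truth_window_repeats.tsv"))
  tsv(frag$truth_fragments, p("truth_fragments.tsv"))
  tsv(data.frame(row = seq_along(hits_ref$truth_hits),
                 source = hits_ref$truth_hits), p("truth_hits_reference.tsv"))
  invisible(list(sim = sim, fragmented = frag, hits_ref = hits_ref,
                 hits_frag = hits_frag))
}
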