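# Windowed GC (with the assembly-gap rule), windowed repeat-class
# proportions, per-gene GC3, intron and intergenic statistics, and
# MHC/non-MHC labeling. Landscape windows run over all scaffolds (no
# length floor): the 1 Mb floor applies to localization only.

#' Windowed GC content with the assembly-gap rule
#'
#' Per window: `gap_fraction` is the N fraction; `gc_fraction` is
#' (G+C)/(A+C+G+T), case-insensitive, and is undefined (`NA`) when the gap
#' fraction exceeds 0.10 — windows dominated by assembly gaps otherwise
#' show spurious GC fluctuations.
#'
#' @param genome `DNAStringSet`.
#' @param grid Window grid from [build_windows()] (typically built with
#'   `min_scaffold_length = 0`).
#' @param max_gap_fraction Gap-rule threshold (default 0.10, strict
#'   inequality triggers undefined).
#' @return The grid with `gap_fraction` and `gc_fraction` columns.
#' @export
window_gc <- function(genome, grid, max_gap_fraction = 0.10) {
  gap <- numeric(nrow(grid)); gc <- numeric(nrow(grid))
  for (sc in unique(grid$scaffold)) {
    rows <- which(grid$scaffold == sc)
    v <- Biostrings::Views(genome[[sc]],
                           start = grid$start[rows] + 1L,
                           end = grid$end[rows])
    f <- Biostrings::letterFrequency(v, c("A", "C", "G", "T", "N"))
    acgt <- rowSums(f[, c("A", "C", "G", "T"), drop = FALSE])
    gap[rows] <- f[, "N"] / (grid$end[rows] - grid$start[rows])
    gc[rows] <- ifelse(acgt > 0,
                       rowSums(f[, c("C", "G"), drop = FALSE]) / acgt,
                       NA_real_)
  }
  grid$gap_fraction <- gap
  grid$gc_fraction <- ifelse(gap > max_gap_fraction, NA_real_, gc)
  grid
}

#' Windowed repeat-class proportions
#'
#' Per window and nine-way repeat class: overlapping same-class annotations
#' are merged, clipped to the window, and their bp summed; the proportion
#' is bp over window length.
#'
#' @param repeats Repeat annotation data frame
#'   ([read_repeatmasker_out()]).
#' @param grid Window grid.
#' @return The grid with one proportion column per repeat class
#'   (`prop_DNA`, `prop_LINE`, ...).
#' @export
window_repeats <- function(repeats, grid) {
  for (cl in REPEAT_CLASSES) grid[[paste0("prop_", cl)]] <- 0
  for (sc in unique(grid$scaffold)) {
    rows <- which(grid$scaffold == sc)
    win <- IRanges::IRanges(start = grid$start[rows] + 1L,
                            end = grid$end[rows])
    rr <- repeats[repeats$scaffold == sc, , drop = FALSE]
    if (!nrow(rr)) next
    for (cl in unique(rr$repeat_class)) {
      ri <- rr[rr$repeat_class == cl, , drop = FALSE]
      merged <- IRanges::reduce(IRanges::IRanges(start = ri$start + 1L,
                                                 end = ri$end))
      ov <- IRanges::findOverlaps(win, merged)
      if (!length(ov)) next
      w <- IRanges::width(IRanges::pintersect(
        win[S4Vectors::queryHits(ov)], merged[S4Vectors::subjectHits(ov)]))
      bp <- tapply(w, factor(S4Vectors::queryHits(ov),
                             levels = seq_along(win)), sum, default = 0)
      grid[[paste0("prop_", cl)]][rows] <-
        as.numeric(bp) / (grid$end[rows] - grid$start[rows])
    }
  }
  grid
}

# longest-CDS transcript per gene (deterministic representative; ties by
# transcript id)
representative_transcripts <- function(ann) {
  if (!nrow(ann$transcripts)) return(character(0))
  cds_len <- tapply(ann$cds$end - ann$cds$start, ann$cds$transcript_id, sum)
  tx <- ann$transcripts
  tx$cds_len <- ifelse(is.na(cds_len[tx$transcript_id]), 0,
                       cds_len[tx$transcript_id])
  tx <- tx[order(tx$gene_id, -tx$cds_len, tx$transcript_id), , drop = FALSE]
  rep <- tx[!duplicated(tx$gene_id), ]
  setNames(rep$transcript_id, rep$gene_id)
}

#' Per-gene GC3 (third-codon-position GC)
#'
#' For each gene the transcript with the longest total CDS is the
#' representative. Its CDS intervals are concatenated in transcript order
#' (reverse genomic order, reverse-complemented, for minus-strand genes);
#' GC3 is the G+C fraction over non-N third codon positions. A CDS whose
#' length is not a multiple of 3 has its trailing partial codon dropped and
#' the gene is flagged; zero complete codons yields `NA`.
#'
#' @param genome `DNAStringSet`.
#' @param ann An `mhc_annotation`.
#' @return Data frame: `gene_id`, `transcript_id`, `gc3`, `n_codons`,
#'   `partial_codon_dropped`.
#' @export
gene_gc3 <- function(genome, ann) {
  reps <- representative_transcripts(ann)
  out <- data.frame(gene_id = names(reps), transcript_id = unname(reps),
                    gc3 = NA_real_, n_codons = 0L,
                    partial_codon_dropped = FALSE, stringsAsFactors = FALSE)
  strand <- setNames(ann$genes$strand, ann$genes$gene_id)
  scaf <- setNames(ann$genes$scaffold, ann$genes$gene_id)
  for (i in seq_len(nrow(out))) {
    cd <- ann$cds[ann$cds$transcript_id == out$transcript_id[i], ,
                  drop = FALSE]
    if (!nrow(cd)) next
    cd <- cd[order(cd$start), ]
    gid <- out$gene_id[i]
    chunks <- as.character(Biostrings::Views(genome[[scaf[[gid]]]],
                                             start = cd$start + 1L,
                                             end = cd$end))
    cds_seq <- paste(chunks, collapse = "")
    if (strand[[gid]] == "-") cds_seq <- revcomp_chr(cds_seq)
    n <- nchar(cds_seq)
    if (n %% 3 != 0) {
      cds_seq <- substr(cds_seq, 1, n - n %% 3)
      out$partial_codon_dropped[i] <- TRUE
      n <- nchar(cds_seq)
    }
    if (n < 3) next
    third <- strsplit(cds_seq, "")[[1]][seq(3, n, by = 3)]
    third <- third[third != "N"]
    out$n_codons[i] <- as.integer(n %/% 3)
    if (length(third)) out$gc3[i] <- mean(third %in% c("G", "C"))
  }
  out
}

#' Per-gene mean intron length and intergenic distances
#'
#' Introns are the gaps between consecutive exons of the representative
#' (longest-CDS) transcript; the mean is `NA` for intronless genes.
#' Intergenic distances are strand-ignored, between consecutive gene bodies
#' sorted by start on each scaffold: `max(0, next_start - prev_end)`, with
#' overlapping neighbors flagged; scaffold-terminal genes have `NA` on the
#' open side. Output order matches the input gene table regardless of its
#' row order.
#'
#' @param ann An `mhc_annotation`.
#' @return Data frame: `gene_id`, `scaffold`, `start`, `end`,
#'   `mean_intron_length`, `n_introns`, `intergenic_prev`,
#'   `intergenic_next`, `overlaps_prev`, `overlaps_next`.
#' @export
intron_and_intergenic <- function(ann) {
  reps <- representative_transcripts(ann)
  g <- ann$genes[order(ann$genes$gene_id), , drop = FALSE]
  out <- data.frame(gene_id = g$gene_id, scaffold = g$scaffold,
                    start = g$start, end = g$end,
                    mean_intron_length = NA_real_, n_introns = 0L,
                    intergenic_prev = NA_real_, intergenic_next = NA_real_,
                    overlaps_prev = FALSE, overlaps_next = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    tid <- reps[[out$gene_id[i]]]
    if (is.null(tid)) next
    ex <- ann$exons[ann$exons$transcript_id == tid, , drop = FALSE]
    if (nrow(ex) < 2) next
    ex <- ex[order(ex$start), ]
    introns <- ex$start[-1] - ex$end[-nrow(ex)]
    out$n_introns[i] <- length(introns)
    out$mean_intron_length[i] <- mean(introns)
  }
  for (sc in unique(out$scaffold)) {
    rows <- which(out$scaffold == sc)
    rows <- rows[order(out$start[rows])]
    if (length(rows) < 2) next
    prev_end <- out$end[rows[-length(rows)]]
    next_start <- out$start[rows[-1]]
    d <- pmax(0, next_start - prev_end)
    ovl <- next_start < prev_end
    out$intergenic_prev[rows[-1]] <- d
    out$intergenic_next[rows[-length(rows)]] <- d
    out$overlaps_prev[rows[-1]] <- ovl
    out$overlaps_next[rows[-length(rows)]] <- ovl
  }
  out
}

#' Label windows or genes as MHC versus non-MHC
#'
#' A feature is labeled `MHC` iff its midpoint lies inside one of the
#' region spans (midpoint rule: unambiguous for boundary-straddling
#' features).
#'
#' @param features Data frame with `scaffold`, `start`, `end`.
#' @param region A `region_span` from [delineate_and_size()], or a data
#'   frame of spans (`scaffold`, `start`, `end`).
#' @return `features` with a `region_label` column (`"MHC"`/`"nonMHC"`).
#' @export
label_regions <- function(features, region) {
  spans <- if (inherits(region, "region_span")) region$spans else region
  features$region_label <- "nonMHC"
  if (!is.null(spans) && nrow(spans)) {
    mid <- (features$start + features$end) / 2
    for (i in seq_len(nrow(spans))) {
      inside <- features$scaffold == spans$scaffold[i] &
        mid >= spans$start[i] & mid < spans$end[i]
      features$region_label[inside] <- "MHC"
    }
  }
  features
}
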