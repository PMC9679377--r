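#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits
#' @importFrom stats median quantile rbeta rlnorm rnorm rpois runif setNames
#'   kruskal.test pnorm
#' @importFrom utils read.delim write.table head
NULL

# All coordinates inside the package are 0-based half-open [start, end).
# Conversions happen at the file boundary only:
#   GFF3 and RepeatMasker .out are 1-based inclusive -> start-1, end
#   BLAST tabular subject coordinates are 1-based inclusive, strand by order
#   PAF is already 0-based half-open

REPEAT_CLASSES <- c("DNA", "LINE", "SINE", "LTR", "RC", "Satellite",
                    "Simple_repeat", "Low_complexity", "Unknown")

MHC_CLASSES <- c("I", "II", "III", "framework", "extended", "none")

#' Read a genome FASTA file
#'
#' Reads a FASTA file into a [Biostrings::DNAStringSet]. Sequence names are
#' truncated at the first whitespace. Lowercase (soft-masked) input is
#' accepted and normalized to uppercase; all composition operations in the
#' package are case-insensitive by construction.
#'
#' @param path Path to a FASTA file.
#' @return A named `DNAStringSet`, one element per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  if (any(!nzchar(names(seqs)))) stop("empty sequence id in ", path)
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs A named `DNAStringSet` or named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Scaffold lengths of a genome
#'
#' @param seqs A `DNAStringSet` (or named character vector).
#' @return Named integer vector of lengths in bp.
#' @export
scaffold_lengths <- function(seqs) {
  if (is.character(seqs)) return(setNames(nchar(seqs), names(seqs)))
  setNames(Biostrings::width(seqs), names(seqs))
}

# ---- GFF3 ------------------------------------------------------------------

#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/exon/CDS features (via rtracklayer) into a gene
#' annotation: a list of four data frames (`genes`, `transcripts`, `exons`,
#' `cds`) with 0-based half-open coordinates. MHC class labels are taken from
#' the GFF attribute named by `class_attribute` when present, then overridden
#' by the optional `class_map` (symbol -> class) lookup; genes matched by
#' neither get class `"none"`.
#'
#' @param path GFF3 file path.
#' @param class_map Optional named character vector mapping gene symbols to
#'   MHC classes (`I`, `II`, `III`, `framework`, `extended`).
#' @param class_attribute GFF attribute carrying the class (default
#'   `"mhc_class"`).
#' @return An object of class `mhc_annotation`.
#' @export
read_gff3 <- function(path, class_map = NULL, class_attribute = "mhc_class") {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0) return(empty_annotation())
  md <- S4Vectors::mcols(gr)
  typ <- as.character(md$type)
  ids <- if ("ID" %in% colnames(md)) as.character(md$ID) else rep(NA_character_, length(gr))
  parents <- if ("Parent" %in% colnames(md)) {
    vapply(md$Parent, function(p) if (length(p)) p[[1]] else NA_character_, character(1))
  } else rep(NA_character_, length(gr))

  s0 <- BiocGenerics::start(gr) - 1L   # to 0-based half-open
  e0 <- BiocGenerics::end(gr)
  scaf <- as.character(GenomicRanges::seqnames(gr))
  strd <- as.character(BiocGenerics::strand(gr))

  gi <- which(typ == "gene")
  genes <- data.frame(
    gene_id = ids[gi],
    symbol = if ("Name" %in% colnames(md)) as.character(md$Name)[gi] else ids[gi],
    scaffold = scaf[gi], strand = strd[gi],
    start = s0[gi], end = e0[gi],
    mhc_class = "none",
    stringsAsFactors = FALSE
  )
  genes$symbol[is.na(genes$symbol)] <- genes$gene_id[is.na(genes$symbol)]
  if (class_attribute %in% colnames(md)) {
    cls <- as.character(md[[class_attribute]])[gi]
    genes$mhc_class[!is.na(cls)] <- cls[!is.na(cls)]
  }
  if (!is.null(class_map)) {
    hit <- genes$symbol %in% names(class_map)
    genes$mhc_class[hit] <- unname(class_map[genes$symbol[hit]])
  }
  bad <- !genes$mhc_class %in% MHC_CLASSES
  if (any(bad)) stop("unknown MHC class label(s): ",
                     paste(unique(genes$mhc_class[bad]), collapse = ", "))

  ti <- which(typ %in% c("mRNA", "transcript"))
  transcripts <- data.frame(
    transcript_id = ids[ti], gene_id = parents[ti], stringsAsFactors = FALSE
  )

  xi <- which(typ == "exon")
  if (length(xi) && any(is.na(parents[xi]) | !(parents[xi] %in% transcripts$transcript_id)))
    stop("exon without parent transcript in ", path)
  exons <- data.frame(
    transcript_id = parents[xi], start = s0[xi], end = e0[xi],
    stringsAsFactors = FALSE
  )
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  exons$exon_rank <- stats::ave(exons$start, exons$transcript_id,
                                FUN = seq_along)

  ci <- which(typ == "CDS")
  cds <- data.frame(
    transcript_id = parents[ci], start = s0[ci], end = e0[ci],
    frame = if (length(ci)) suppressWarnings(as.integer(as.character(md$phase)[ci])) else integer(0),
    stringsAsFactors = FALSE
  )
  cds$frame[is.na(cds$frame)] <- 0L

  ann <- new_annotation(genes, transcripts, exons, cds)
  flag_cds_outside_exons(ann)
}

empty_annotation <- function() {
  new_annotation(
    data.frame(gene_id = character(0), symbol = character(0),
               scaffold = character(0), strand = character(0),
               start = integer(0), end = integer(0),
               mhc_class = character(0), stringsAsFactors = FALSE),
    data.frame(transcript_id = character(0), gene_id = character(0),
               stringsAsFactors = FALSE),
    data.frame(transcript_id = character(0), start = integer(0),
               end = integer(0), exon_rank = integer(0),
               stringsAsFactors = FALSE),
    data.frame(transcript_id = character(0), start = integer(0),
               end = integer(0), frame = integer(0), stringsAsFactors = FALSE)
  )
}

new_annotation <- function(genes, transcripts, exons, cds) {
  structure(list(genes = genes, transcripts = transcripts,
                 exons = exons, cds = cds),
            class = "mhc_annotation")
}

# warn on CDS intervals not contained in the union of their transcript's exons
flag_cds_outside_exons <- function(ann) {
  if (!nrow(ann$cds)) {
    ann$cds$flagged <- logical(0)
    return(ann)
  }
  flagged <- vapply(seq_len(nrow(ann$cds)), function(i) {
    ex <- ann$exons[ann$exons$transcript_id == ann$cds$transcript_id[i], ]
    if (!nrow(ex)) return(TRUE)
    any(ann$cds$start[i] >= ex$start & ann$cds$end[i] <= ex$end) == FALSE
  }, logical(1))
  if (any(flagged))
    warning(sum(flagged), " CDS interval(s) fall outside their transcript's exons; flagged")
  ann$cds$flagged <- flagged
  ann
}

#' Write a gene annotation to GFF3
#'
#' Inverse of [read_gff3()]: internal 0-based half-open coordinates are
#' converted back to 1-based inclusive GFF3. The MHC class is written as a
#' `mhc_class` attribute on gene features.
#'
#' @param ann An `mhc_annotation`.
#' @param path Output path.
#' @export
write_gff3 <- function(ann, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  tx2gene <- setNames(ann$transcripts$gene_id, ann$transcripts$transcript_id)
  gene_row <- function(i) {
    g <- ann$genes[i, ]
    sprintf("%s\tmhcscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s;mhc_class=%s",
            g$scaffold, g$start + 1L, g$end, g$strand, g$gene_id, g$symbol,
            g$mhc_class)
  }
  lines <- character(0)
  for (i in seq_len(nrow(ann$genes))) {
    g <- ann$genes[i, ]
    lines <- c(lines, gene_row(i))
    txs <- ann$transcripts[ann$transcripts$gene_id == g$gene_id, ]
    for (tid in txs$transcript_id) {
      lines <- c(lines, sprintf(
        "%s\tmhcscan\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
        g$scaffold, g$start + 1L, g$end, g$strand, tid, g$gene_id))
      ex <- ann$exons[ann$exons$transcript_id == tid, ]
      ex <- ex[order(ex$exon_rank), ]
      for (j in seq_len(nrow(ex)))
        lines <- c(lines, sprintf(
          "%s\tmhcscan\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
          g$scaffold, ex$start[j] + 1L, ex$end[j], g$strand, tid))
      cd <- ann$cds[ann$cds$transcript_id == tid, ]
      for (j in seq_len(nrow(cd)))
        lines <- c(lines, sprintf(
          "%s\tmhcscan\tCDS\t%d\t%d\t.\t%s\t%d\tParent=%s",
          g$scaffold, cd$start[j] + 1L, cd$end[j], g$strand, cd$frame[j], tid))
    }
  }
  writeLines(lines, con)
  invisible(path)
}

# ---- BLAST tabular ---------------------------------------------------------

#' Read a BLAST tabular (outfmt 6) homology hit table
#'
#' Expects the standard 12 columns (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore). Subject coordinates are
#' normalized to 0-based half-open with `start < end`; strand is `-` when
#' `sstart > send`. `query_meta` supplies per-query symbol, length (aa) and
#' MHC class, from which hit coverage is computable as
#' `align_length / query_length`.
#'
#' @param path Hit table path.
#' @param query_meta Data frame with columns `query_id`, `symbol`,
#'   `query_length`, `mhc_class`.
#' @param on_unknown `"skip"` (drop rows whose query is absent from
#'   `query_meta`, with a warning) or `"error"`.
#' @return Data frame of homology hits with columns `query_id`, `symbol`,
#'   `query_length`, `mhc_class`, `scaffold`, `start`, `end`, `strand`,
#'   `align_length`, `percent_identity`, `evalue`, `bitscore`, `coverage`.
#' @export
read_blast_tab <- function(path, query_meta, on_unknown = c("skip", "error")) {
  on_unknown <- match.arg(on_unknown)
  stopifnot(all(c("query_id", "symbol", "query_length", "mhc_class") %in%
                  names(query_meta)))
  raw <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("qseqid", "sseqid", "pident", "length",
                                  "mismatch", "gapopen", "qstart", "qend",
                                  "sstart", "send", "evalue", "bitscore"))
  if (!nrow(raw)) return(empty_hits())
  unknown <- !(raw$qseqid %in% query_meta$query_id)
  if (any(unknown)) {
    if (on_unknown == "error")
      stop("unknown query id(s) in ", path, ": ",
           paste(unique(raw$qseqid[unknown]), collapse = ", "))
    warning(sum(unknown), " hit row(s) with unknown query id skipped")
    raw <- raw[!unknown, , drop = FALSE]
  }
  if (!nrow(raw)) return(empty_hits())
  idx <- match(raw$qseqid, query_meta$query_id)
  hits <- data.frame(
    query_id = raw$qseqid,
    symbol = query_meta$symbol[idx],
    query_length = query_meta$query_length[idx],
    mhc_class = query_meta$mhc_class[idx],
    scaffold = raw$sseqid,
    start = pmin(raw$sstart, raw$send) - 1L,
    end = pmax(raw$sstart, raw$send),
    strand = ifelse(raw$sstart <= raw$send, "+", "-"),
    align_length = raw$length,
    percent_identity = raw$pident,
    evalue = raw$evalue,
    bitscore = raw$bitscore,
    stringsAsFactors = FALSE
  )
  hits$coverage <- hits$align_length / hits$query_length
  hits
}

empty_hits <- function() {
  data.frame(query_id = character(0), symbol = character(0),
             query_length = numeric(0), mhc_class = character(0),
             scaffold = character(0), start = integer(0), end = integer(0),
             strand = character(0), align_length = numeric(0),
             percent_identity = numeric(0), evalue = numeric(0),
             bitscore = numeric(0), coverage = numeric(0),
             stringsAsFactors = FALSE)
}

# ---- RepeatMasker ----------------------------------------------------------

#' Map a RepeatMasker class/family string to the nine-way repeat scheme
#'
#' `"LINE/L2"` maps to class `LINE`, family `L2`; classes outside the scheme
#' (e.g. `"Unspecified"`) map to `Unknown`.
#'
#' @param class_family Character vector of `class/family` strings.
#' @return Data frame with columns `repeat_class`, `family`.
#' @export
map_repeat_class <- function(class_family) {
  parts <- strsplit(class_family, "/", fixed = TRUE)
  cls <- vapply(parts, `[`, character(1), 1L)
  fam <- vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_,
                character(1))
  # strip trailing qualifiers like "LINE?" or "DNA?"
  cls <- sub("\\?$", "", cls)
  cls[!cls %in% REPEAT_CLASSES] <- "Unknown"
  data.frame(repeat_class = cls, family = fam, stringsAsFactors = FALSE)
}

#' Read a RepeatMasker .out annotation file
#'
#' Standard layout with three header lines; coordinates (1-based inclusive)
#' are converted to 0-based half-open and the class/family column is mapped
#' into the nine-way repeat classification.
#'
#' @param path Path to a RepeatMasker `.out` file.
#' @return Data frame with columns `scaffold`, `start`, `end`,
#'   `repeat_class`, `family`, `name`.
#' @export
read_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  if (length(lines) > 3) lines <- lines[-(1:3)] else lines <- character(0)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(scaffold = character(0), start = integer(0),
                      end = integer(0), repeat_class = character(0),
                      family = character(0), name = character(0),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(trimws(lines), "\\s+")
  n <- vapply(fields, length, integer(1))
  if (any(n < 11)) stop("malformed RepeatMasker line(s): ",
                        paste(which(n < 11) + 3L, collapse = ", "))
  scaf <- vapply(fields, `[`, character(1), 5L)
  beg <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 6L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 7L)))
  if (anyNA(beg) || anyNA(end))
    stop("malformed coordinate column at RepeatMasker line(s): ",
         paste(which(is.na(beg) | is.na(end)) + 3L, collapse = ", "))
  name <- vapply(fields, `[`, character(1), 10L)
  cf <- map_repeat_class(vapply(fields, `[`, character(1), 11L))
  data.frame(scaffold = scaf, start = beg - 1L, end = end,
             repeat_class = cf$repeat_class, family = cf$family, name = name,
             stringsAsFactors = FALSE)
}

#' Write repeat annotations in RepeatMasker .out layout
#'
#' @param repeats Data frame as returned by [read_repeatmasker_out()].
#' @param path Output path.
#' @export
write_repeatmasker_out <- function(repeats, path) {
  hdr <- c(
    "   SW   perc perc perc  query      position in query           matching       repeat              position in repeat",
    "score   div. del. ins.  sequence   begin    end    (left)      repeat         class/family      begin  end (left)   ID",
    "")
  fam <- ifelse(is.na(repeats$family), repeats$repeat_class,
                paste0(repeats$repeat_class, "/", repeats$family))
  body <- sprintf(" 1000    0.0  0.0  0.0  %s %d %d (0) + %s %s 1 %d (0) %d",
                  repeats$scaffold, repeats$start + 1L, repeats$end,
                  repeats$name, fam, repeats$end - repeats$start,
                  seq_len(nrow(repeats)))
  writeLines(c(hdr, body), path)
  invisible(path)
}

# ---- PAF and link tables ---------------------------------------------------

#' Read alignment blocks from a PAF file
#'
#' The 12 mandatory PAF columns are required; coordinates are already 0-based
#' half-open. The strand column maps to orientation `same` (`+`) or
#' `opposite` (`-`).
#'
#' @param path PAF file path.
#' @return Data frame of alignment blocks with columns `source`,
#'   `source_start`, `source_end`, `target`, `target_start`, `target_end`,
#'   `orientation`, `aligned_length`.
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(source = character(0), source_start = integer(0),
                      source_end = integer(0), target = character(0),
                      target_start = integer(0), target_end = integer(0),
                      orientation = character(0), aligned_length = integer(0),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- vapply(fields, length, integer(1))
  if (any(n < 12)) stop("PAF line(s) with fewer than 12 fields: ",
                        paste(which(n < 12), collapse = ", "))
  getc <- function(i) vapply(fields, `[`, character(1), i)
  geti <- function(i) as.integer(getc(i))
  data.frame(
    source = getc(1), source_start = geti(3), source_end = geti(4),
    target = getc(6), target_start = geti(8), target_end = geti(9),
    orientation = ifelse(getc(5) == "+", "same", "opposite"),
    aligned_length = geti(11),
    stringsAsFactors = FALSE
  )
}

#' Write alignment blocks as PAF
#'
#' @param blocks Data frame as returned by [read_paf()]; needs additionally
#'   `source_length` and `target_length` columns.
#' @param path Output path.
#' @export
write_paf <- function(blocks, path) {
  lines <- sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t60",
                   blocks$source, blocks$source_length, blocks$source_start,
                   blocks$source_end,
                   ifelse(blocks$orientation == "same", "+", "-"),
                   blocks$target, blocks$target_length, blocks$target_start,
                   blocks$target_end, blocks$aligned_length,
                   blocks$aligned_length)
  writeLines(lines, path)
  invisible(path)
}

#' Read paired-end (BAC-end style) links
#'
#' The TSV has one row per clone end with header columns `link_id`, `end`
#' (1 or 2), `scaffold`, `position`, `strand`, `insert_size_max`. Rows are
#' grouped by clone; clones without exactly two ends are dropped with a
#' warning.
#'
#' @param path TSV path.
#' @return Data frame with one row per link: `link_id`, `scaffold1`,
#'   `position1`, `strand1`, `scaffold2`, `position2`, `strand2`,
#'   `insert_size_max`.
#' @export
read_pe_links <- function(path) {
  raw <- read.delim(path, stringsAsFactors = FALSE)
  empty <- data.frame(link_id = character(0), scaffold1 = character(0),
                      position1 = integer(0), strand1 = character(0),
                      scaffold2 = character(0), position2 = integer(0),
                      strand2 = character(0), insert_size_max = integer(0),
                      stringsAsFactors = FALSE)
  if (!nrow(raw)) return(empty)
  counts <- table(raw$link_id)
  bad <- names(counts)[counts != 2]
  if (length(bad)) {
    warning(length(bad), " clone(s) without exactly two ends dropped: ",
            paste(head(bad, 5), collapse = ", "))
    raw <- raw[!raw$link_id %in% bad, , drop = FALSE]
  }
  if (!nrow(raw)) return(empty)
  raw <- raw[order(raw$link_id, raw$end), ]
  e1 <- raw[raw$end == 1, ]
  e2 <- raw[raw$end == 2, ]
  data.frame(link_id = e1$link_id,
             scaffold1 = e1$scaffold, position1 = e1$position,
             strand1 = e1$strand,
             scaffold2 = e2$scaffold, position2 = e2$position,
             strand2 = e2$strand,
             insert_size_max = e1$insert_size_max,
             stringsAsFactors = FALSE)
}

#' Read transcript-to-scaffold links
#'
#' TSV with header columns `transcript_id`, `scaffold`, `start`, `end`,
#' `strand`, `exon_rank` (one row per exon placement). Placements are sorted
#' by exon rank within each transcript. A transcript whose exons fall on two
#' or more distinct scaffolds is a spanning link.
#'
#' @param path TSV path.
#' @return Data frame of exon placements with a logical `spanning` column.
#' @export
read_tx_links <- function(path) {
  raw <- read.delim(path, stringsAsFactors = FALSE)
  if (!nrow(raw)) {
    raw$spanning <- logical(0)
    return(raw)
  }
  raw <- raw[order(raw$transcript_id, raw$exon_rank), ]
  nscaf <- tapply(raw$scaffold, raw$transcript_id,
                  function(s) length(unique(s)))
  raw$spanning <- as.vector(nscaf[raw$transcript_id] >= 2)
  rownames(raw) <- NULL
  raw
}

#' Read PAF, paired-end and transcript link evidence together
#'
#' @param paf_path,pe_path,tx_path File paths; any may be `NULL` to skip.
#' @return List with elements `blocks`, `pe_links`, `tx_links`.
#' @export
read_links <- function(paf_path = NULL, pe_path = NULL, tx_path = NULL) {
  list(
    blocks = if (!is.null(paf_path)) read_paf(paf_path) else NULL,
    pe_links = if (!is.null(pe_path)) read_pe_links(pe_path) else NULL,
    tx_links = if (!is.null(tx_path)) read_tx_links(tx_path) else NULL
  )
}
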