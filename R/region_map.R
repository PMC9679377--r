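# Region delineation and sizing from annotated MHC genes, marker-pair
# sizing, gene presence/duplication matrices, and reciprocal best hits.

#' Delineate the MHC region and estimate its size
#'
#' Per scaffold carrying at least one MHC-classed gene, the span runs from
#' the start of the first to the end of the last such gene; the total size
#' is the sum of the per-scaffold spans.
#'
#' @param genes Gene data frame (`gene_id`, `symbol`, `scaffold`, `start`,
#'   `end`, `mhc_class`); genes with class `"none"` are ignored.
#' @return List of class `region_span`: `spans` (scaffold, start, end,
#'   length, n_genes, first_gene, last_gene), `total_size`.
#' @export
delineate_and_size <- function(genes) {
  g <- genes[genes$mhc_class != "none", , drop = FALSE]
  if (!nrow(g)) {
    return(structure(list(
      spans = data.frame(scaffold = character(0), start = numeric(0),
                         end = numeric(0), length = numeric(0),
                         n_genes = integer(0), first_gene = character(0),
                         last_gene = character(0)),
      total_size = 0), class = "region_span"))
  }
  spans <- do.call(rbind, lapply(split(g, g$scaffold), function(s) {
    i1 <- which.min(s$start); i2 <- which.max(s$end)
    data.frame(scaffold = s$scaffold[1], start = min(s$start),
               end = max(s$end), length = max(s$end) - min(s$start),
               n_genes = nrow(s), first_gene = s$gene_id[i1],
               last_gene = s$gene_id[i2], stringsAsFactors = FALSE)
  }))
  rownames(spans) <- NULL
  structure(list(spans = spans, total_size = sum(spans$length)),
            class = "region_span")
}

#' Marker-pair size of the region
#'
#' Size between two boundary marker genes on one scaffold, measured from
#' the leftmost start to the rightmost end of the two gene bodies
#' (orientation-agnostic: giving the markers in reverse genomic order
#' returns the same value).
#'
#' @param genes Gene data frame with `symbol`, `scaffold`, `start`, `end`.
#' @param start_marker,end_marker Marker gene symbols (e.g. `GABBR1`,
#'   `DAXX`).
#' @return Size in bp.
#' @export
marker_pair_size <- function(genes, start_marker, end_marker) {
  find <- function(sym) {
    hit <- genes[genes$symbol == sym, , drop = FALSE]
    if (!nrow(hit)) {
      sugg <- head(sort(genes$symbol[startsWith(genes$symbol,
                                                substr(sym, 1, 2))]), 5)
      stop("marker not found: ", sym,
           if (length(sugg)) paste0(" (candidates: ",
                                    paste(sugg, collapse = ", "), ")"))
    }
    hit[1, ]
  }
  a <- find(start_marker); b <- find(end_marker)
  if (a$scaffold != b$scaffold)
    stop("markers lie on different scaffolds: ", a$scaffold, " vs ",
         b$scaffold)
  max(a$end, b$end) - min(a$start, b$start)
}

#' Gene presence/duplication matrix across species
#'
#' Counts copies of each reference symbol in each species' delineated
#' region gene list. A symbol is reported missing when absent (count 0)
#' from every species, and duplicated (per species) when its count is >= 2.
#'
#' @param region_gene_lists Named list: species -> character vector of gene
#'   symbols in that species' region (one element per gene copy).
#' @param reference_symbols Character vector of reference (e.g. human MHC)
#'   symbols; must be nonempty.
#' @return List: `matrix` (symbols x species copy counts), `missing`
#'   (symbols with zero copies everywhere), `duplicated` (data frame
#'   species/symbol/count for counts >= 2).
#' @export
gene_presence_matrix <- function(region_gene_lists, reference_symbols) {
  if (!length(reference_symbols)) stop("empty reference symbol set")
  reference_symbols <- unique(reference_symbols)
  m <- vapply(region_gene_lists, function(sym)
    as.integer(table(factor(sym, levels = reference_symbols))),
    integer(length(reference_symbols)))
  m <- matrix(m, nrow = length(reference_symbols),
              dimnames = list(reference_symbols, names(region_gene_lists)))
  missing <- rownames(m)[rowSums(m) == 0]
  dup_idx <- which(m >= 2, arr.ind = TRUE)
  duplicated <- data.frame(
    species = colnames(m)[dup_idx[, "col"]],
    symbol = rownames(m)[dup_idx[, "row"]],
    count = m[dup_idx], stringsAsFactors = FALSE)
  duplicated <- duplicated[order(duplicated$species, duplicated$symbol), ,
                           drop = FALSE]
  rownames(duplicated) <- NULL
  list(matrix = m, missing = missing, duplicated = duplicated)
}

# best hit per query: highest bitscore, ties by lower e-value, then
# lexicographic subject id
best_hit_per_query <- function(tab) {
  tab <- tab[order(tab$query, -tab$bitscore, tab$evalue, tab$subject), ,
             drop = FALSE]
  tab[!duplicated(tab$query), , drop = FALSE]
}

#' Reciprocal best hits between two protein sets
#'
#' A pair (a, b) is retained iff b is a's best hit in the A->B table and a
#' is b's best hit in the B->A table, with ties broken by lower e-value
#' then lexicographic subject id.
#'
#' @param ab,ba Directed hit tables with columns `query`, `subject`,
#'   `bitscore`, `evalue`.
#' @return Data frame of pairs: `gene_a`, `gene_b`, `bitscore_ab`,
#'   `bitscore_ba`.
#' @export
reciprocal_best_hits <- function(ab, ba) {
  empty <- data.frame(gene_a = character(0), gene_b = character(0),
                      bitscore_ab = numeric(0), bitscore_ba = numeric(0))
  if (!nrow(ab) || !nrow(ba)) return(empty)
  ba_best <- best_hit_per_query(ba)
  ab_best <- best_hit_per_query(ab)
  back <- setNames(ba_best$subject, ba_best$query)
  mutual <- !is.na(back[ab_best$subject]) &
    back[ab_best$subject] == ab_best$query
  mutual[is.na(mutual)] <- FALSE
  pairs <- ab_best[mutual, , drop = FALSE]
  if (!nrow(pairs)) return(empty)
  ba_score <- setNames(ba_best$bitscore, ba_best$query)
  out <- data.frame(gene_a = pairs$query, gene_b = pairs$subject,
                    bitscore_ab = pairs$bitscore,
                    bitscore_ba = unname(ba_score[pairs$subject]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' One-way stringent best-hit fallback
#'
#' Supplements reciprocal best hits with one-way best hits passing a
#' bitscore floor, mirroring the use of a stringent one-way search where
#' the reciprocal criterion is not met.
#'
#' @param ab Directed hit table (`query`, `subject`, `bitscore`, `evalue`).
#' @param min_bitscore Bitscore floor (default 200).
#' @return Data frame of retained one-way pairs.
#' @export
one_way_stringent <- function(ab, min_bitscore = 200) {
  best <- best_hit_per_query(ab)
  out <- best[best$bitscore >= min_bitscore, , drop = FALSE]
  rownames(out) <- NULL
  out
}
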