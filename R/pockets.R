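# Cross-referencing per-codon selection classifications with peptide-
# binding-pocket membership maps: readers, the codon-level outer join,
# shared-selection sets, and per-pocket summaries.

CODON_CLASSES <- c("diversifying", "purifying", "neutral", "invariant")
POCKET_LABELS <- c("A", "B", "C", "D", "E", "F", "CDE")

#' Read a per-codon selection classification table
#'
#' Tab-separated with header `species gene codon class source`; lines
#' starting with `#` are skipped. Codon indices are 1-based in the
#' alignment's codon numbering. One class per (species, gene, codon).
#'
#' @param path File path.
#' @return Data frame: `species`, `gene`, `codon`, `class`, `source`.
#' @export
read_codon_classifications <- function(path) {
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("species", "gene", "codon", "class", "source")
  if (!all(need %in% names(d)))
    stop("classification table must have columns: ",
         paste(need, collapse = ", "))
  d <- d[, need]
  bad <- setdiff(unique(d$class), CODON_CLASSES)
  if (length(bad))
    stop("unknown class label(s): ", paste(bad, collapse = ", "))
  if (any(d$codon < 1)) stop("codon indices must be >= 1")
  key <- paste(d$species, d$gene, d$codon)
  if (anyDuplicated(key))
    stop("duplicate (species, gene, codon) classification: ",
         key[duplicated(key)][1])
  d
}

#' Read a pocket membership map
#'
#' Tab-separated with header `structure codon pockets`; `pockets` is a
#' comma-separated nonempty subset of A,B,C,D,E,F,CDE (the chicken
#' structure's pooled CDE label is kept as its own label, not expanded).
#'
#' @param path File path.
#' @return Data frame: `structure`, `codon`, `pockets` (list column of
#'   character vectors).
#' @export
read_pocket_map <- function(path) {
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("structure", "codon", "pockets")
  if (!all(need %in% names(d)))
    stop("pocket map must have columns: ", paste(need, collapse = ", "))
  d <- d[, need]
  d$pockets <- as.character(d$pockets)
  if (anyNA(d$pockets) || any(!nzchar(trimws(d$pockets))))
    stop("every mapped codon needs a nonempty pocket set")
  sets <- strsplit(d$pockets, ",", fixed = TRUE)
  sets <- lapply(sets, trimws)
  if (any(lengths(sets) == 0) || any(vapply(sets, function(s)
    any(!nzchar(s)), logical(1))))
    stop("every mapped codon needs a nonempty pocket set")
  bad <- setdiff(unique(unlist(sets)), POCKET_LABELS)
  if (length(bad))
    stop("unknown pocket label(s): ", paste(bad, collapse = ", "))
  key <- paste(d$structure, d$codon)
  if (anyDuplicated(key))
    stop("duplicate (structure, codon) in pocket map: ",
         key[duplicated(key)][1])
  d$pockets <- sets
  d
}

#' Join selection classifications with pocket membership maps
#'
#' Outer join on the shared alignment codon index: one row per codon in
#' the union of classified and mapped codons, with one class column per
#' species (`class_<species>`, `NA` where unclassified) and one pocket-set
#' column per structure (`pockets_<structure>`, empty where unmapped). An
#' optional remapping table converts structure-native pocket-map numbering
#' to the alignment numbering before joining.
#'
#' @param classifications Data frame from [read_codon_classifications()];
#'   must concern a single gene.
#' @param pocket_map Data frame from [read_pocket_map()].
#' @param remap Optional data frame `structure`, `codon_native`,
#'   `codon_alignment` applied to the pocket map.
#' @return Data frame, one row per codon, ordered by codon; pocket columns
#'   are list columns of character vectors.
#' @export
join_selection_pockets <- function(classifications, pocket_map,
                                   remap = NULL) {
  if (nrow(classifications) && length(unique(classifications$gene)) > 1)
    stop("classifications must concern a single gene; got: ",
         paste(unique(classifications$gene), collapse = ", "))
  key <- paste(classifications$species, classifications$codon)
  if (anyDuplicated(key))
    stop("duplicate (species, codon) classification: ",
         key[duplicated(key)][1])
  if (!is.null(remap)) {
    k <- paste(pocket_map$structure, pocket_map$codon)
    rk <- paste(remap$structure, remap$codon_native)
    hit <- match(k, rk)
    pocket_map$codon[!is.na(hit)] <-
      remap$codon_alignment[hit[!is.na(hit)]]
  }
  codons <- sort(unique(c(classifications$codon, pocket_map$codon)))
  out <- data.frame(codon = codons)
  for (sp in sort(unique(classifications$species))) {
    cl <- classifications[classifications$species == sp, , drop = FALSE]
    out[[paste0("class_", sp)]] <- cl$class[match(codons, cl$codon)]
  }
  for (st in sort(unique(pocket_map$structure))) {
    pm <- pocket_map[pocket_map$structure == st, , drop = FALSE]
    i <- match(codons, pm$codon)
    out[[paste0("pockets_", st)]] <- lapply(seq_along(codons), function(j)
      if (is.na(i[j])) character(0) else pm$pockets[[i[j]]])
  }
  out
}

#' Codon sets under a given selection class, per species and shared
#'
#' @param classifications Data frame from [read_codon_classifications()].
#' @param class_filter One of `diversifying`, `purifying`, `neutral`,
#'   `invariant`.
#' @return List: `per_species` (named list of sorted codon vectors, one per
#'   species present in the input) and `shared` (their intersection; for a
#'   single species, its own set).
#' @export
shared_selection <- function(classifications, class_filter = "diversifying") {
  if (!class_filter %in% CODON_CLASSES)
    stop("unknown class label: ", class_filter)
  species <- sort(unique(classifications$species))
  if (!length(species)) stop("need at least one species")
  per <- lapply(species, function(sp)
    sort(unique(classifications$codon[
      classifications$species == sp &
        classifications$class == class_filter])))
  names(per) <- species
  list(per_species = per, shared = Reduce(intersect, per))
}

#' Per-pocket selection-class counts
#'
#' For every pocket label appearing in the joined table: counts of codons
#' per class per species (a codon in k pockets contributes to all k), and a
#' flag for pockets with zero diversifying codons in every species.
#'
#' @param joined Data frame from [join_selection_pockets()].
#' @return List: `counts` (pocket x species x class long data frame) and
#'   `zero_diversifying` (character vector of flagged pockets).
#' @export
pocket_summary <- function(joined) {
  class_cols <- grep("^class_", names(joined), value = TRUE)
  pocket_cols <- grep("^pockets_", names(joined), value = TRUE)
  pockets_all <- sort(unique(unlist(joined[pocket_cols])))
  species <- sub("^class_", "", class_cols)
  rows <- expand.grid(pocket = pockets_all, species = species,
                      class = CODON_CLASSES, stringsAsFactors = FALSE)
  rows$n <- integer(nrow(rows))
  in_pocket <- function(p) vapply(seq_len(nrow(joined)), function(i)
    any(vapply(pocket_cols, function(cc)
      p %in% joined[[cc]][[i]], logical(1))), logical(1))
  for (p in pockets_all) {
    member <- in_pocket(p)
    for (sp in species) {
      cl <- joined[[paste0("class_", sp)]][member]
      for (cc in CODON_CLASSES) {
        rows$n[rows$pocket == p & rows$species == sp & rows$class == cc] <-
          sum(cl == cc, na.rm = TRUE)
      }
    }
  }
  div <- tapply(rows$n[rows$class == "diversifying"],
                rows$pocket[rows$class == "diversifying"], sum)
  list(counts = rows,
       zero_diversifying = sort(names(div)[div == 0]))
}
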