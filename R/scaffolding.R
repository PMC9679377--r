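# Placement and orientation of unplaced scaffolds within the candidate
# region: alignment blocks drive confident placement; transcript and
# paired-end links corroborate joins; tentative scaffolds are ordered by
# gene-content agreement (LCS) with a reference gene order.

weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1]]
}

#' Place unplaced scaffolds by alignment blocks
#'
#' Per scaffold: the target interval spans the block extremes on the
#' majority target sequence, ordered by the aligned-bp-weighted median of
#' block midpoints; orientation is the majority by aligned bp. A placement
#' is `confident` iff total aligned bp >= `min_aligned_bp` and the majority
#' orientation fraction >= `min_orientation_frac`; otherwise `tentative`.
#' Scaffolds without blocks get a tentative placement with orientation
#' `unknown`.
#'
#' @param blocks Alignment block table from [read_paf()].
#' @param scaffolds Character vector of scaffolds to place.
#' @param min_aligned_bp Confidence floor on summed aligned bp
#'   (default 5000).
#' @param min_orientation_frac Confidence floor on the majority orientation
#'   fraction (default 0.7).
#' @return Data frame: `scaffold`, `target`, `target_start`, `target_end`,
#'   `target_midpoint`, `orientation`, `orientation_frac`, `aligned_bp`,
#'   `n_blocks`, `confidence`.
#' @export
place_by_alignment <- function(blocks, scaffolds, min_aligned_bp = 5000,
                               min_orientation_frac = 0.7) {
  if (min_orientation_frac <= 0 || min_orientation_frac > 1)
    stop("min_orientation_frac must lie in (0, 1]")
  if (!is.character(scaffolds)) scaffolds <- names(scaffolds)
  scaffolds <- sort(unique(scaffolds))
  rows <- lapply(scaffolds, function(sc) {
    b <- blocks[blocks$source == sc, , drop = FALSE]
    if (!nrow(b)) {
      return(data.frame(scaffold = sc, target = NA_character_,
                        target_start = NA_real_, target_end = NA_real_,
                        target_midpoint = NA_real_, orientation = "unknown",
                        orientation_frac = NA_real_, aligned_bp = 0,
                        n_blocks = 0L, confidence = "tentative",
                        stringsAsFactors = FALSE))
    }
    # majority target sequence by aligned bp
    tgt_bp <- tapply(b$aligned_length, b$target, sum)
    tgt <- names(tgt_bp)[which.max(tgt_bp)]
    bt <- b[b$target == tgt, , drop = FALSE]
    ori_bp <- tapply(bt$aligned_length, factor(bt$orientation,
                                               c("same", "opposite")), sum,
                     default = 0)
    maj <- names(ori_bp)[which.max(ori_bp)]
    frac <- max(ori_bp) / sum(ori_bp)
    total_bp <- sum(b$aligned_length)
    conf <- total_bp >= min_aligned_bp & frac >= min_orientation_frac
    mid <- weighted_median((bt$target_start + bt$target_end) / 2,
                           bt$aligned_length)
    data.frame(scaffold = sc, target = tgt,
               target_start = min(bt$target_start),
               target_end = max(bt$target_end),
               target_midpoint = mid,
               orientation = maj,
               orientation_frac = frac, aligned_bp = total_bp,
               n_blocks = nrow(b),
               confidence = if (conf) "confident" else "tentative",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Corroborate adjacent-scaffold joins with link evidence
#'
#' Orders the placed scaffolds by target midpoint (confident placements
#' first, in coordinate order) and, for each adjacent pair, reports whether
#' any transcript places exons on both scaffolds and whether any paired-end
#' link spans both with an implied gap at most its maximum insert size.
#' Links supporting a non-adjacent pairing are returned as conflicts.
#'
#' @param placements Output of [place_by_alignment()] (or any data frame
#'   with `scaffold` and `target_midpoint`).
#' @param tx_links Transcript link table from [read_tx_links()]; may be
#'   `NULL`.
#' @param pe_links Paired-end link table from [read_pe_links()]; may be
#'   `NULL`.
#' @return List: `joins` (scaffold_a, scaffold_b, tx_corroborated,
#'   pe_corroborated, evidence ids) and `conflicts`.
#' @export
corroborate_links <- function(placements, tx_links = NULL, pe_links = NULL) {
  ord <- placements[order(placements$confidence != "confident",
                          placements$target_midpoint), , drop = FALSE]
  scafs <- ord$scaffold
  known_warn <- function(link_scafs, what) {
    unk <- setdiff(unique(link_scafs), scafs)
    if (length(unk))
      warning(what, " link(s) name unknown scaffold(s): ",
              paste(head(unk, 5), collapse = ", "))
  }
  gap_between <- function(a, b) {
    ia <- match(a, ord$scaffold); ib <- match(b, ord$scaffold)
    if (anyNA(c(ord$target_end[ia], ord$target_start[ib]))) return(0)
    lo <- min(ord$target_end[ia], ord$target_end[ib])
    hi <- max(ord$target_start[ia], ord$target_start[ib])
    max(0, hi - lo)
  }
  # collect scaffold pairs supported by each evidence type
  tx_pairs <- list(); pe_pairs <- list()
  if (!is.null(tx_links) && nrow(tx_links)) {
    known_warn(tx_links$scaffold, "transcript")
    for (tid in unique(tx_links$transcript_id)) {
      t <- tx_links[tx_links$transcript_id == tid, , drop = FALSE]
      t <- t[order(t$exon_rank), ]
      consec <- unique(t$scaffold[c(TRUE, diff(match(t$scaffold,
                                                     unique(t$scaffold))) != 0)])
      u <- unique(t$scaffold)
      if (length(u) >= 2)
        for (i in seq_len(length(u) - 1))
          tx_pairs[[length(tx_pairs) + 1]] <-
            list(a = u[i], b = u[i + 1], id = tid)
    }
  }
  if (!is.null(pe_links) && nrow(pe_links)) {
    known_warn(c(pe_links$scaffold1, pe_links$scaffold2), "paired-end")
    for (i in seq_len(nrow(pe_links))) {
      if (pe_links$scaffold1[i] != pe_links$scaffold2[i])
        pe_pairs[[length(pe_pairs) + 1]] <-
          list(a = pe_links$scaffold1[i], b = pe_links$scaffold2[i],
               id = pe_links$link_id[i],
               max_gap = pe_links$insert_size_max[i])
    }
  }
  adjacent <- function(a, b) {
    ia <- match(a, scafs); ib <- match(b, scafs)
    !is.na(ia) && !is.na(ib) && abs(ia - ib) == 1
  }
  joins <- data.frame(scaffold_a = head(scafs, -1), scaffold_b = scafs[-1],
                      tx_corroborated = FALSE, pe_corroborated = FALSE,
                      tx_ids = "", pe_ids = "", stringsAsFactors = FALSE)
  conflicts <- list()
  mark <- function(p, type) {
    i <- which((joins$scaffold_a == p$a & joins$scaffold_b == p$b) |
                 (joins$scaffold_a == p$b & joins$scaffold_b == p$a))
    if (length(i)) {
      col <- paste0(type, "_corroborated")
      joins[[col]][i] <<- TRUE
      idc <- paste0(type, "_ids")
      joins[[idc]][i] <<- paste(c(strsplit(joins[[idc]][i], ",")[[1]], p$id),
                                collapse = ",")
    } else {
      conflicts[[length(conflicts) + 1]] <<-
        data.frame(scaffold_a = p$a, scaffold_b = p$b, evidence = type,
                   id = p$id, stringsAsFactors = FALSE)
    }
  }
  for (p in tx_pairs) mark(p, "tx")
  for (p in pe_pairs) {
    if (adjacent(p$a, p$b) && gap_between(p$a, p$b) > p$max_gap) {
      conflicts[[length(conflicts) + 1]] <-
        data.frame(scaffold_a = p$a, scaffold_b = p$b, evidence = "pe_gap",
                   id = p$id, stringsAsFactors = FALSE)
    } else {
      mark(p, "pe")
    }
  }
  joins$tx_ids <- sub("^,", "", joins$tx_ids)
  joins$pe_ids <- sub("^,", "", joins$pe_ids)
  list(joins = joins,
       conflicts = if (length(conflicts)) do.call(rbind, conflicts) else
         data.frame(scaffold_a = character(0), scaffold_b = character(0),
                    evidence = character(0), id = character(0)))
}

# longest common subsequence length of two symbol vectors
lcs_length <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (!na || !nb) return(0L)
  prev <- integer(nb + 1)
  for (i in seq_len(na)) {
    cur <- integer(nb + 1)
    for (j in seq_len(nb)) {
      cur[j + 1] <- if (a[i] == b[j]) prev[j] + 1L
                    else max(cur[j], prev[j + 1])
    }
    prev <- cur
  }
  prev[nb + 1]
}

#' Compose an ordered, oriented region path
#'
#' Confident scaffolds are ordered by target-interval midpoint. Each
#' tentative scaffold is inserted at the slot (and orientation) maximizing
#' the longest-common-subsequence agreement between the path's concatenated
#' gene symbols and the reference gene order; ties break toward the
#' earliest slot and then lexicographic scaffold id, and an orientation tie
#' yields `unknown`.
#'
#' @param placements Output of [place_by_alignment()].
#' @param reference_gene_order Character vector of gene symbols in
#'   reference order across the region.
#' @param genes_by_scaffold Named list: scaffold -> character vector of its
#'   gene symbols in scaffold coordinate order.
#' @param corroboration Optional output of [corroborate_links()]; join tags
#'   are attached to the path when given.
#' @return Data frame path: `position`, `scaffold`, `orientation`,
#'   `confidence`, plus join corroboration tags (`join_tx`, `join_pe`
#'   with the following scaffold).
#' @export
compose_region_path <- function(placements, reference_gene_order = character(0),
                                genes_by_scaffold = list(),
                                corroboration = NULL) {
  if (!nrow(placements)) {
    return(data.frame(position = integer(0), scaffold = character(0),
                      orientation = character(0), confidence = character(0)))
  }
  conf <- placements[placements$confidence == "confident", , drop = FALSE]
  tent <- placements[placements$confidence != "confident", , drop = FALSE]
  conf <- conf[order(conf$target_midpoint, conf$scaffold), , drop = FALSE]
  path <- data.frame(scaffold = conf$scaffold,
                     orientation = conf$orientation,
                     confidence = "confident", stringsAsFactors = FALSE)
  syms <- function(sc, ori) {
    s <- genes_by_scaffold[[sc]]
    if (is.null(s)) return(character(0))
    if (identical(ori, "opposite")) rev(s) else s
  }
  path_syms <- function(p) {
    unlist(lapply(seq_len(nrow(p)),
                  function(i) syms(p$scaffold[i], p$orientation[i])),
           use.names = FALSE)
  }
  tent <- tent[order(tent$scaffold), , drop = FALSE]
  for (i in seq_len(nrow(tent))) {
    sc <- tent$scaffold[i]
    best <- NULL
    for (slot in seq_len(nrow(path) + 1)) {
      for (ori in c("same", "opposite")) {
        cand <- rbind(
          if (slot > 1) path[seq_len(slot - 1), , drop = FALSE],
          data.frame(scaffold = sc, orientation = ori,
                     confidence = "tentative", stringsAsFactors = FALSE),
          if (slot <= nrow(path)) path[seq(slot, nrow(path)), , drop = FALSE])
        score <- lcs_length(path_syms(cand), reference_gene_order)
        if (is.null(best) || score > best$score) {
          best <- list(score = score, slot = slot, ori = ori, cand = cand,
                       tie_ori = FALSE)
        } else if (score == best$score && slot == best$slot &&
                   ori != best$ori) {
          best$tie_ori <- TRUE
        }
      }
    }
    if (best$tie_ori) best$cand$orientation[best$slot] <- "unknown"
    path <- best$cand
  }
  path$position <- seq_len(nrow(path))
  path <- path[, c("position", "scaffold", "orientation", "confidence")]
  if (!is.null(corroboration)) {
    j <- corroboration$joins
    nxt <- c(path$scaffold[-1], NA)
    key <- paste(path$scaffold, nxt)
    jkey <- paste(j$scaffold_a, j$scaffold_b)
    jkey2 <- paste(j$scaffold_b, j$scaffold_a)
    idx <- match(key, jkey)
    idx2 <- match(key, jkey2)
    idx[is.na(idx)] <- idx2[is.na(idx)]
    path$join_tx <- ifelse(is.na(idx), NA, j$tx_corroborated[idx])
    path$join_pe <- ifelse(is.na(idx), NA, j$pe_corroborated[idx])
  }
  rownames(path) <- NULL
  path
}
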