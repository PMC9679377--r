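# Homology-hit density localization: non-overlapping windows on long
# scaffolds, per-window and per-scaffold hit counting, coverage binning,
# candidate-region calling, unplaced-scaffold reporting filters, and
# canonical k-mer depth profiling.

#' Build non-overlapping window grids
#'
#' Tiles each scaffold strictly longer than `min_scaffold_length` with
#' non-overlapping windows of `window_size` bp; the terminal partial window
#' is kept and flagged. Shorter scaffolds are excluded from windowing but
#' retained (with their lengths) for per-scaffold counting.
#'
#' @param seq_lengths Named vector of scaffold lengths (bp), or a
#'   `DNAStringSet`.
#' @param window_size Window size in bp (default 100 kb).
#' @param min_scaffold_length Only scaffolds strictly longer than this are
#'   windowed (default 1 Mb).
#' @return Data frame with columns `scaffold`, `start`, `end`, `partial`;
#'   attribute `non_windowed` holds the named lengths of excluded scaffolds.
#' @export
build_windows <- function(seq_lengths, window_size = 1e5,
                          min_scaffold_length = 1e6) {
  if (!is.numeric(seq_lengths)) seq_lengths <- scaffold_lengths(seq_lengths)
  if (window_size <= 0) stop("window_size must be positive")
  long <- seq_lengths[seq_lengths > min_scaffold_length]
  out <- lapply(names(long), function(sc) {
    len <- long[[sc]]
    starts <- seq(0, len - 1, by = window_size)
    ends <- pmin(starts + window_size, len)
    data.frame(scaffold = sc, start = starts, end = ends,
               partial = ends - starts < window_size,
               stringsAsFactors = FALSE)
  })
  grid <- if (length(out)) do.call(rbind, out) else
    data.frame(scaffold = character(0), start = numeric(0),
               end = numeric(0), partial = logical(0))
  attr(grid, "non_windowed") <- seq_lengths[seq_lengths <= min_scaffold_length]
  attr(grid, "window_size") <- window_size
  grid
}

# window index of a position on a windowed scaffold (start-coordinate rule
# by default; midpoint rule by option)
assign_window <- function(hits, grid, rule = c("start", "midpoint")) {
  rule <- match.arg(rule)
  pos <- if (rule == "start") hits$start else (hits$start + hits$end) %/% 2
  ws <- attr(grid, "window_size")
  key_grid <- paste(grid$scaffold, grid$start %/% ws)
  key_hit <- paste(hits$scaffold, pos %/% ws)
  match(key_hit, key_grid)
}

#' Count hits per scaffold and per window
#'
#' Every hit is assigned to exactly one window by its start coordinate (a
#' midpoint rule is available); hits on non-windowed scaffolds contribute to
#' scaffold totals only; hits on scaffolds absent from `seq_lengths` are
#' counted in an `"unknown"` bucket with a warning.
#'
#' @param hits Hit table from [read_blast_tab()].
#' @param grid Window grid from [build_windows()].
#' @param seq_lengths Named scaffold lengths (for totals on all scaffolds).
#' @param rule Window assignment rule, `"start"` or `"midpoint"`.
#' @return List with `scaffold_totals` (scaffold, length, n_hits, windowed),
#'   `window_counts` (grid columns + `n_hits` + per-class counts), and
#'   `unknown` (number of hits on unknown scaffolds).
#' @export
count_hits <- function(hits, grid, seq_lengths, rule = "start") {
  if (!is.numeric(seq_lengths)) seq_lengths <- scaffold_lengths(seq_lengths)
  known <- hits$scaffold %in% names(seq_lengths)
  if (any(!known))
    warning(sum(!known), " hit(s) on unknown scaffold(s) counted in the ",
            "'unknown' bucket")
  kh <- hits[known, , drop = FALSE]
  totals <- data.frame(
    scaffold = names(seq_lengths),
    length = as.numeric(seq_lengths),
    n_hits = as.integer(table(factor(kh$scaffold,
                                     levels = names(seq_lengths)))),
    windowed = names(seq_lengths) %in% grid$scaffold,
    stringsAsFactors = FALSE)
  wc <- grid
  wh <- kh[kh$scaffold %in% grid$scaffold, , drop = FALSE]
  idx <- assign_window(wh, grid, rule)
  wc$n_hits <- tabulate(idx, nbins = nrow(grid))
  for (cl in c("I", "II", "III", "framework", "extended")) {
    wc[[paste0("n_", cl)]] <-
      tabulate(idx[wh$mhc_class == cl], nbins = nrow(grid))
  }
  list(scaffold_totals = totals, window_counts = wc,
       unknown = sum(!known))
}

#' Bin hits by query coverage
#'
#' Coverage is `align_length / query_length`, clamped to 1; default bins are
#' the quartile edges `[0,0.25) [0.25,0.5) [0.5,0.75) [0.75,1]`.
#'
#' @param hits Hit table; rows with missing `query_length` are excluded with
#'   a warning.
#' @param bin_edges Increasing numeric vector of edges spanning [0, 1].
#' @param grid Optional window grid; when given, per-window bin counts are
#'   returned as well.
#' @return List with `hits` (input + `coverage_bin` factor) and, when a grid
#'   is supplied, `window_bins` (per-window counts per bin).
#' @export
bin_by_coverage <- function(hits, bin_edges = c(0, 0.25, 0.5, 0.75, 1),
                            grid = NULL) {
  ok <- !is.na(hits$query_length) & hits$query_length > 0
  if (any(!ok)) {
    warning(sum(!ok), " hit(s) without query length excluded from binning")
    hits <- hits[ok, , drop = FALSE]
  }
  cov <- pmin(1, hits$align_length / hits$query_length)
  hits$coverage_bin <- cut(cov, breaks = bin_edges, right = FALSE,
                           include.lowest = TRUE)
  # cut(right=FALSE, include.lowest=TRUE) closes the last bin at 1
  out <- list(hits = hits)
  if (!is.null(grid)) {
    idx <- assign_window(hits, grid)
    wb <- grid
    for (lv in levels(hits$coverage_bin))
      wb[[lv]] <- tabulate(idx[hits$coverage_bin == lv], nbins = nrow(grid))
    out$window_bins <- wb
  }
  out
}

#' Call candidate regions from window hit counts
#'
#' Seed windows are those with `n_hits` at or above the given quantile of
#' all nonzero window counts (across every windowed scaffold); runs of seed
#' windows on a scaffold are merged across at most `max_gap_windows`
#' consecutive sub-threshold windows; candidate regions are ranked by summed
#' hits (rank 1 = densest).
#'
#' @param window_counts `window_counts` from [count_hits()].
#' @param quantile_threshold Seed quantile of nonzero window counts
#'   (default 0.78; on hit profiles like the bundled generator's this sits
#'   above the background window counts but below the in-region counts, so
#'   planted regions are recovered without edge extension).
#' @param max_gap_windows Maximum bridged gap, in windows (default 2).
#' @return Data frame of candidate regions: `scaffold`, `start`, `end`,
#'   `n_windows`, `n_hits`, `rank`.
#' @export
call_candidate_regions <- function(window_counts, quantile_threshold = 0.78,
                                   max_gap_windows = 2L) {
  empty <- data.frame(scaffold = character(0), start = numeric(0),
                      end = numeric(0), n_windows = integer(0),
                      n_hits = numeric(0), rank = integer(0))
  nz <- window_counts$n_hits[window_counts$n_hits > 0]
  if (!length(nz)) return(empty)
  thr <- quantile(nz, quantile_threshold, names = FALSE, type = 7)
  regions <- list()
  for (sc in unique(window_counts$scaffold)) {
    w <- window_counts[window_counts$scaffold == sc, , drop = FALSE]
    w <- w[order(w$start), ]
    seed <- w$n_hits >= thr
    if (!any(seed)) next
    si <- which(seed)
    brk <- c(TRUE, diff(si) > max_gap_windows + 1L)
    run <- cumsum(brk)
    for (r in unique(run)) {
      ii <- si[run == r]
      span <- seq(min(ii), max(ii))
      regions[[length(regions) + 1]] <- data.frame(
        scaffold = sc, start = w$start[min(ii)], end = w$end[max(ii)],
        n_windows = length(span), n_hits = sum(w$n_hits[span]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(regions)) return(empty)
  out <- do.call(rbind, regions)
  out <- out[order(-out$n_hits, out$scaffold, out$start), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Filter unplaced scaffolds for reporting
#'
#' Retains scaffolds with at least `min_hits` total hits AND an average hit
#' density strictly greater than `min_density` hits per 100 bp, mirroring
#' the unplaced-scaffold report filter. A companion filter retains
#' scaffolds with at least `min_links` mapped paired ends.
#'
#' @param scaffold_totals `scaffold_totals` from [count_hits()].
#' @param min_hits Minimum total hits (default 100).
#' @param min_density Density threshold in hits per 100 bp, strict
#'   inequality (default 4).
#' @return The retained subset, with a `density` column.
#' @export
filter_unplaced_for_report <- function(scaffold_totals, min_hits = 100,
                                       min_density = 4) {
  d <- scaffold_totals
  d$density <- d$n_hits / (d$length / 100)
  keep <- d$n_hits >= min_hits & d$density > min_density
  out <- d[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter scaffolds by mapped paired-end (BES) link count
#'
#' @param link_counts Named vector: scaffold -> number of mapped ends.
#' @param min_links Minimum mapped ends (default 5).
#' @return Character vector of retained scaffolds.
#' @export
filter_by_bes_links <- function(link_counts, min_links = 5) {
  names(link_counts)[link_counts >= min_links]
}

# ---- canonical k-mer depth --------------------------------------------------

# canonical form (lexicographic min of k-mer and its reverse complement);
# k-mers containing N return NA
canonical_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  km <- substring(seq, 1:(n - k + 1), k:n)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(km)))
  out <- pmin(km, rc)
  out[grepl("N", km, fixed = TRUE)] <- NA_character_
  out
}

#' Genome-wide canonical k-mer depth across a region
#'
#' Counts canonical k-mers (k odd, default 27) over the whole genome, then
#' reports the depth of the k-mer starting at each position of the query
#' region. Positions whose k-mer contains N get depth `NA`; positions
#' overlapping any repeat annotation are flagged. Intended for genomes of
#' modest size (the counting is an in-memory hash).
#'
#' @param genome `DNAStringSet`.
#' @param scaffold,start,end Query region (0-based half-open).
#' @param k Odd k-mer size, default 27.
#' @param repeats Optional repeat annotation data frame.
#' @return Data frame: `position` (0-based k-mer start), `depth`,
#'   `in_repeat`.
#' @export
kmer_depth_profile <- function(genome, scaffold, start, end, k = 27L,
                               repeats = NULL) {
  if (k %% 2 == 0) stop("k must be odd")
  if (end - start < k) stop("region shorter than k")
  if (!scaffold %in% names(genome)) stop("unknown scaffold: ", scaffold)
  all_km <- unlist(lapply(as.character(genome), canonical_kmers, k = k),
                   use.names = FALSE)
  counts <- table(all_km[!is.na(all_km)])
  s <- substr(as.character(genome[[scaffold]]), start + 1, end)
  qk <- canonical_kmers(s, k)
  depth <- as.integer(counts[qk])
  depth[is.na(qk)] <- NA_integer_
  pos <- start + seq_along(qk) - 1L
  in_rep <- rep(FALSE, length(pos))
  if (!is.null(repeats) && nrow(repeats)) {
    rr <- repeats[repeats$scaffold == scaffold, , drop = FALSE]
    if (nrow(rr)) {
      q <- IRanges::IRanges(start = pos + 1L, width = 1L)
      r <- IRanges::reduce(IRanges::IRanges(start = rr$start + 1L,
                                            end = rr$end))
      in_rep <- IRanges::overlapsAny(q, r)
    }
  }
  data.frame(position = pos, depth = depth, in_repeat = in_rep)
}
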