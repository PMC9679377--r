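# Shared fixtures: one cached synthetic system (expensive to build) plus
# small utilities used across test files.

.shared <- new.env(parent = emptyenv())

shared_sim <- function() {
  if (is.null(.shared$sim)) {
    .shared$cfg <- sim_config(seed = 42L)
    .shared$sim <- simulate_genomes(.shared$cfg)
    .shared$frag <- fragment_and_link(.shared$sim, .shared$cfg)
  }
  list(cfg = .shared$cfg, sim = .shared$sim, frag = .shared$frag)
}

jaccard_interval <- function(a1, a2, b1, b2) {
  inter <- max(0, min(a2, b2) - max(a1, b1))
  inter / (max(a2, b2) - min(a1, b1))
}

# tiny deterministic DNAStringSet builder
dna <- function(...) Biostrings::DNAStringSet(c(...))

# minimal annotation builder: one transcript per gene, exons == CDS
make_ann <- function(genes, exons) {
  tx <- data.frame(transcript_id = paste0("t_", genes$gene_id),
                   gene_id = genes$gene_id, stringsAsFactors = FALSE)
  ex <- exons
  ex$transcript_id <- paste0("t_", ex$gene_id)
  ex <- ex[order(ex$transcript_id, ex$start), ]
  ex$exon_rank <- stats::ave(ex$start, ex$transcript_id, FUN = seq_along)
  cds <- ex[, c("transcript_id", "start", "end")]
  cds$frame <- 0L
  mhcscan:::new_annotation(
    genes, tx, ex[, c("transcript_id", "start", "end", "exon_rank")], cds)
}
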