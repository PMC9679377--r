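# scaffolding: alignment placement, link corroboration, path composition

mk_blocks <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(source = r[[1]], source_start = 0L, source_end = 1000L,
               target = r[[2]], target_start = as.integer(r[[3]]),
               target_end = as.integer(r[[4]]),
               orientation = r[[5]], aligned_length = as.integer(r[[6]]),
               stringsAsFactors = FALSE)))
}

test_that("placement aggregates blocks into interval and majority orientation", {
  b <- mk_blocks(list("f1", "chr", 1000, 2000, "same", 4000),
                 list("f1", "chr", 5000, 9000, "same", 3000),
                 list("f1", "chr", 2500, 3000, "opposite", 500))
  pl <- place_by_alignment(b, "f1")
  expect_identical(pl$target, "chr")
  expect_identical(pl$target_start, 1000L)
  expect_identical(pl$target_end, 9000L)
  expect_identical(pl$orientation, "same")
  expect_equal(pl$orientation_frac, 7000 / 7500)
  expect_identical(pl$confidence, "confident")
  expect_equal(pl$aligned_bp, 7500)
})

test_that("confidence needs >= 5 kb aligned AND >= 0.7 orientation majority", {
  # 4999 bp aligned -> tentative
  b1 <- mk_blocks(list("f1", "chr", 0, 1000, "same", 4999))
  expect_identical(place_by_alignment(b1, "f1")$confidence, "tentative")
  b2 <- mk_blocks(list("f1", "chr", 0, 1000, "same", 5000))
  expect_identical(place_by_alignment(b2, "f1")$confidence, "confident")
  # orientation split 69/31 -> tentative
  b3 <- mk_blocks(list("f1", "chr", 0, 1000, "same", 6900),
                  list("f1", "chr", 2000, 3000, "opposite", 3100))
  expect_identical(place_by_alignment(b3, "f1")$confidence, "tentative")
  b4 <- mk_blocks(list("f1", "chr", 0, 1000, "same", 7000),
                  list("f1", "chr", 2000, 3000, "opposite", 3000))
  expect_identical(place_by_alignment(b4, "f1")$confidence, "confident")
  expect_error(place_by_alignment(b4, "f1", min_orientation_frac = 0),
               "min_orientation_frac")
})

test_that("scaffolds without blocks get tentative unknown placements", {
  b <- mk_blocks(list("f1", "chr", 0, 1000, "same", 6000))
  pl <- place_by_alignment(b, c("f1", "lonely"))
  lo <- pl[pl$scaffold == "lonely", ]
  expect_identical(lo$confidence, "tentative")
  expect_identical(lo$orientation, "unknown")
  expect_identical(lo$n_blocks, 0L)
  expect_true(is.na(lo$target))
})

test_that("the majority target is chosen by aligned bp", {
  b <- mk_blocks(list("f1", "chrA", 0, 1000, "same", 2000),
                 list("f1", "chrB", 0, 1000, "same", 7000))
  expect_identical(place_by_alignment(b, "f1")$target, "chrB")
})

mk_placements <- function(scafs, mids, confidence = "confident") {
  data.frame(scaffold = scafs, target = "chr",
             target_start = mids - 500, target_end = mids + 500,
             target_midpoint = mids, orientation = "same",
             orientation_frac = 1, aligned_bp = 10000, n_blocks = 2L,
             confidence = confidence, stringsAsFactors = FALSE)
}

test_that("link corroboration marks adjacent joins and flags conflicts", {
  pl <- mk_placements(c("f1", "f2", "f3"), c(1000, 5000, 9000))
  tx <- data.frame(transcript_id = c("t1", "t1", "t2", "t2"),
                   scaffold = c("f1", "f2", "f1", "f3"),
                   start = c(0, 0, 0, 0), end = c(10, 10, 10, 10),
                   strand = "+", exon_rank = c(1, 2, 1, 2),
                   stringsAsFactors = FALSE)
  pe <- data.frame(link_id = "c1", scaffold1 = "f2", position1 = 10,
                   strand1 = "+", scaffold2 = "f3", position2 = 20,
                   strand2 = "-", insert_size_max = 100000,
                   stringsAsFactors = FALSE)
  out <- corroborate_links(pl, tx, pe)
  j <- out$joins
  expect_identical(j$scaffold_a, c("f1", "f2"))
  expect_true(j$tx_corroborated[1])
  expect_false(j$tx_corroborated[2])
  expect_true(j$pe_corroborated[2])
  expect_identical(j$tx_ids[1], "t1")
  expect_identical(j$pe_ids[2], "c1")
  # t2 spans non-adjacent scaffolds -> conflict
  expect_identical(out$conflicts$id, "t2")
  expect_identical(out$conflicts$evidence, "tx")
})

test_that("paired-end links violating the insert size become pe_gap conflicts", {
  pl <- mk_placements(c("f1", "f2"), c(1000, 500000))
  pe <- data.frame(link_id = "c1", scaffold1 = "f1", position1 = 10,
                   strand1 = "+", scaffold2 = "f2", position2 = 20,
                   strand2 = "-", insert_size_max = 1000,
                   stringsAsFactors = FALSE)
  out <- corroborate_links(pl, NULL, pe)
  expect_false(out$joins$pe_corroborated)
  expect_identical(out$conflicts$evidence, "pe_gap")
})

test_that("links naming unknown scaffolds warn", {
  pl <- mk_placements(c("f1", "f2"), c(1000, 2000))
  tx <- data.frame(transcript_id = "t1", scaffold = c("f1", "fX"),
                   start = 0, end = 1, strand = "+", exon_rank = 1:2,
                   stringsAsFactors = FALSE)
  expect_warning(corroborate_links(pl, tx, NULL), "unknown scaffold")
})

test_that("lcs_length matches a brute-force subsequence check", {
  expect_identical(mhcscan:::lcs_length(c("a", "b", "c"), c("a", "c")), 2L)
  expect_identical(mhcscan:::lcs_length(letters[1:5], rev(letters[1:5])), 1L)
  expect_identical(mhcscan:::lcs_length(character(0), "a"), 0L)
  expect_identical(mhcscan:::lcs_length(c("x", "a", "y", "b", "z"),
                                        c("a", "b")), 2L)
})

test_that("confident scaffolds are ordered by target midpoint", {
  pl <- mk_placements(c("fB", "fA", "fC"), c(5000, 1000, 9000))
  path <- compose_region_path(pl)
  expect_identical(path$scaffold, c("fA", "fB", "fC"))
  expect_identical(path$position, 1:3)
})

test_that("tentative scaffolds are inserted at the LCS-optimal slot", {
  pl <- rbind(mk_placements(c("f1", "f3"), c(1000, 9000)),
              mk_placements("f2", NA, confidence = "tentative"))
  genes <- list(f1 = c("A", "B"), f2 = c("C", "D"), f3 = c("E", "F"))
  ref <- c("A", "B", "C", "D", "E", "F")
  path <- compose_region_path(pl, ref, genes)
  expect_identical(path$scaffold, c("f1", "f2", "f3"))
  expect_identical(path$orientation[2], "same")
  expect_identical(path$confidence, c("confident", "tentative", "confident"))
  # reversed gene content -> opposite orientation maximizes the LCS
  genes$f2 <- c("D", "C")
  path2 <- compose_region_path(pl, ref, genes)
  expect_identical(path2$scaffold[2], "f2")
  expect_identical(path2$orientation[2], "opposite")
})

test_that("an orientation tie yields unknown; empty placements yield empty path", {
  pl <- rbind(mk_placements("f1", 1000),
              mk_placements("f2", NA, confidence = "tentative"))
  genes <- list(f1 = c("A", "B"), f2 = "C")   # single gene: ori tie
  path <- compose_region_path(pl, c("A", "B", "C"), genes)
  expect_identical(path$orientation[path$scaffold == "f2"], "unknown")
  expect_identical(nrow(compose_region_path(pl[0, ])), 0L)
})

test_that("corroboration tags are attached to path joins", {
  pl <- mk_placements(c("f1", "f2"), c(1000, 5000))
  tx <- data.frame(transcript_id = "t1", scaffold = c("f1", "f2"),
                   start = 0, end = 1, strand = "+", exon_rank = 1:2,
                   stringsAsFactors = FALSE)
  cor <- corroborate_links(pl, tx, NULL)
  path <- compose_region_path(pl, corroboration = cor)
  expect_true(path$join_tx[1])
  expect_false(path$join_pe[1])
  expect_true(is.na(path$join_tx[2]))
})

test_that("alignment placement recovers the planted fragment path", {
  s <- shared_sim()
  frag <- s$frag
  pl <- place_by_alignment(frag$blocks, scaffold_lengths(frag$genome))
  tfr <- frag$truth_fragments[order(frag$truth_fragments$order_index), ]
  pl2 <- pl[match(tfr$fragment, pl$scaffold), ]
  expect_true(all(pl2$confidence == "confident"))
  expect_identical(order(pl2$target_midpoint), seq_len(nrow(pl2)))
  expect_identical(pl2$orientation, tfr$orientation)
  path <- compose_region_path(pl)
  got <- path$scaffold[path$scaffold %in% tfr$fragment]
  expect_identical(got, tfr$fragment)
})
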