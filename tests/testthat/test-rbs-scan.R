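pad_window <- function(core, len = 24) {
  paste0(paste(rep("T", len - nchar(core)), collapse = ""), core)
}

test_that("classify_window applies longest-motif precedence", {
  expect_equal(classify_window(strrep("T", 24))$motif_class, "none")
  hit6 <- classify_window("TTTTTTTTTTAGGAGGTTTTTTTT")
  expect_equal(hit6$motif_class, "6-mer")
  expect_equal(hit6$offset, 10L)
  expect_equal(hit6$motif, "AGGAGG")
  expect_equal(classify_window("TTTTTTTTTTTTTTTTTTTTGGAG")$motif_class, "4-mer")
  # AGGAG contains AGGA and GGAG but is classified by its longest class
  expect_equal(classify_window(pad_window("AGGAG"))$motif_class, "5-mer")
  expect_equal(classify_window(pad_window("GGAGG"))$motif_class, "5-mer")
  # leftmost match of the winning class is reported
  two <- classify_window("AGGATTTTTTTTTTTTTTTTGAGG")
  expect_equal(two$offset, 0L)
  expect_equal(two$motif, "AGGA")
  # matches never straddle the window edge; ambiguity codes never match
  expect_equal(classify_window("TTTTTTTTTTTTTTTTTTTAGGAG")$motif_class, "5-mer")
  expect_equal(classify_window("TTTTTTTTTTTTTTTTTTTTAGGA")$motif_class, "4-mer")
  expect_equal(classify_window(pad_window("AGGNGG"))$motif_class, "none")
})

test_that("filter_segments keeps exactly the segments with a full 5' window", {
  mk <- function(id, start) {
    annotated_segment(id, strrep("C", 200),
                      data.frame(orf_id = paste0(id, "_o1"), start = start,
                                 end = start + 30, strand = "+"),
                      "set")
  }
  kept <- filter_segments(list(mk("s24", 24), mk("s23", 23), mk("s50", 50)))
  expect_setequal(vapply(kept, `[[`, "", "segment_id"), c("s24", "s50"))
  empty <- annotated_segment("s0", strrep("C", 100),
                             data.frame(orf_id = character(0), start = integer(0),
                                        end = integer(0), strand = character(0)),
                             "set")
  expect_warning(out <- filter_segments(list(empty)), "no annotated ORFs")
  expect_length(out, 0L)
})

test_that("extract_upstream returns the 24 bases before the start codon", {
  seqn <- paste0(paste(LETTERS[c(1, 3, 7, 20)][sample.int(4, 24, replace = TRUE)],
                       collapse = ""))
  seg <- annotated_segment("s1", paste0(seqn, "ATGAAATAA"),
                           data.frame(orf_id = "o1", start = 24, end = 33,
                                      strand = "+"), "set")
  w <- extract_upstream(seg, "o1")
  expect_equal(as.character(w), seqn)
  expect_false(attr(w, "truncated"))

  # ORF starting at 1-based 40: bases 16-39
  seg2 <- annotated_segment("s2", strrep("ACGT", 30),
                            data.frame(orf_id = "o1", start = 39, end = 60,
                                       strand = "+"), "set")
  expect_equal(as.character(extract_upstream(seg2, "o1")),
               substr(strrep("ACGT", 30), 16, 39))

  # short upstream region is truncated and flagged
  seg3 <- annotated_segment("s3", strrep("C", 50),
                            data.frame(orf_id = "o1", start = 10, end = 40,
                                       strand = "+"), "set")
  w3 <- extract_upstream(seg3, "o1")
  expect_equal(nchar(w3), 10L)
  expect_true(attr(w3, "truncated"))
  expect_error(extract_upstream(seg3, "nope"), "unknown orf_id")
})

test_that("window extraction matches a direct slice oracle on planted segments", {
  ps <- simulate_segments(25, 100, class_probabilities = c(.3, .2, .2, .3),
                          utr_length = 30, seed = 41)
  for (s in ps$segments) {
    for (i in seq_len(nrow(s$orfs))) {
      w <- extract_upstream(s, s$orfs$orf_id[i])
      st <- s$orfs$start[i]
      expect_identical(as.character(w), substr(s$sequence, st - 23, st))
    }
  }
})

test_that("frequency_table counts are additive and percentages half-up", {
  ps <- simulate_segments(10, 40, class_counts = c(12, 9, 7, 12), seed = 42)
  ft <- frequency_table(ps$segments)
  expect_equal(ft$n_4mer + ft$n_5mer + ft$n_6mer, ft$n_total)
  expect_equal(ft$n_total + sum(attr(ft, "hits")$motif_class == "none"),
               ft$n_orfs)
  expect_equal(ft$n_6mer, 12)
  expect_equal(ft$n_5mer, 9)
  expect_equal(ft$n_4mer, 7)
  expect_equal(ft$pct_total, 70.0)  # 28/40
  # recount oracle straight from the per-ORF table
  hits <- attr(ft, "hits")
  expect_equal(ft$n_total, sum(hits$motif_class != "none"))

  # half-up rounding at a .x5 boundary: 5/8 = 62.5, 1/8 = 12.5
  ps2 <- simulate_segments(4, 8, class_counts = c(5, 1, 0, 2), seed = 43)
  ft2 <- frequency_table(ps2$segments)
  expect_equal(ft2$pct_6mer, 62.5)
  expect_equal(ft2$pct_5mer, 12.5)

  # every window carrying the hexamer: 100% total and 100% 6-mer
  ps3 <- simulate_segments(3, 9, class_probabilities = c(1, 0, 0, 0), seed = 44)
  ft3 <- frequency_table(ps3$segments)
  expect_equal(ft3$pct_total, 100.0)
  expect_equal(ft3$pct_6mer, 100.0)
})

test_that("minus-strand ORFs are reverse-complemented with a warning", {
  # plus-orientation layout: 24-nt window then ORF; store it flipped
  w <- paste0(strrep("T", 10), "AGGAGG", strrep("T", 8))
  plus_seq <- paste0(w, "ATGCCCTAA")
  minus_seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(plus_seq)))
  expect_warning(
    seg <- annotated_segment("m1", minus_seq,
                             data.frame(orf_id = "o1", start = 0, end = 9,
                                        strand = "-"), "set"),
    "reverse-complemented")
  expect_equal(seg$orfs$start, 24)
  expect_equal(classify_window(extract_upstream(seg, "o1"))$motif_class, "6-mer")
})

test_that("segments round-trip through FASTA + GFF3", {
  ps <- simulate_segments(5, 15, class_counts = c(5, 4, 3, 3), seed = 45)
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "segs.fasta"); gf <- file.path(dir, "segs.gff3")
  write_segments(ps$segments, fa, gf)
  back <- read_segments(fa, gf, "roundtrip")
  expect_length(back, 5L)
  orig <- ps$segments[order(vapply(ps$segments, `[[`, "", "segment_id"))]
  back <- back[order(vapply(back, `[[`, "", "segment_id"))]
  for (i in seq_along(orig)) {
    expect_identical(back[[i]]$sequence, orig[[i]]$sequence)
    expect_identical(back[[i]]$orfs$start, orig[[i]]$orfs$start)
    expect_identical(back[[i]]$orfs$end, orig[[i]]$orfs$end)
  }
  ft_a <- frequency_table(ps$segments)
  ft_b <- frequency_table(back)
  expect_equal(ft_a$n_6mer, ft_b$n_6mer)
  expect_equal(ft_a$n_total, ft_b$n_total)
})
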