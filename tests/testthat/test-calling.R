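test_that("explicit all-comparison gap runs are called with exact coordinates", {
  # 16 columns: 4 aligned, a 10-column run gapped in every comparison, 2 aligned
  b <- make_block("ACGTACGTACGTACAC",
                  rep("ACGT----------AC", 5L), focal_start = 100L)
  ins <- call_insertions(b)
  expect_equal(nrow(ins), 1L)
  expect_equal(ins$chrom, "chr1")
  expect_equal(ins$start, 104L)   # 4 focal non-gap chars precede the run
  expect_equal(ins$end, 114L)
  expect_equal(ins$length, 10L)
  expect_equal(ins$sequence, "ACGTACGTAC")
  expect_false(ins$touches_block_edge)
})

test_that("a missing comparison row suppresses all calls in the block", {
  b <- make_block("ACGTACGTACGTACAC",
                  rep("ACGT----------AC", 4L))  # gorGor3 absent
  expect_equal(nrow(call_insertions(b)), 0L)
})

test_that("blocks without gaps, absent focal rows and edge runs behave as specified", {
  expect_equal(nrow(call_insertions(make_block("ACGTAC", rep("ACGTAC", 5L)))), 0L)
  b <- make_block("ACGTAC", rep("ACGTAC", 5L))
  expect_error(call_insertions(b, focal = "mm10"), "focal species")
  # run abutting the last column is called but flagged
  edge <- call_insertions(make_block("ACGTAC", rep("AC----", 5L)))
  expect_equal(edge$start, 102L)
  expect_true(edge$touches_block_edge)
})

test_that("partial gap columns and focal N are not insertion-supporting", {
  # middle columns gapped in only four of five comparisons
  b <- make_block("ACGTACGTACGTACAC",
                  c(rep("ACGT----------AC", 4L), "ACGTACGTACGTACAC"))
  expect_equal(nrow(call_insertions(b)), 0L)
  bn <- make_block("ACNNAC", rep("AC--AC", 5L))
  expect_equal(nrow(call_insertions(bn)), 0L)
  expect_equal(call_insertions(bn, allow_n = TRUE)$sequence, "NN")
})

test_that("minus-strand focal rows are projected onto the plus strand", {
  b <- make_block("AAGGTT", rep("AA--TT", 5L), focal_start = 10L,
                  focal_strand = "-", src_size = 1000)
  ins <- call_insertions(b)
  # minus-strand interval [12,14) maps to plus [986,988); sequence revcomp
  expect_equal(ins$start, 986L)
  expect_equal(ins$end, 988L)
  expect_equal(ins$sequence, "CC")
})

test_that("calling is invariant to comparison row order and soft-masking case", {
  txts <- c("ACGT----------AC", "acgt----------ac", "ACGT----------AC",
            "ACGT----------ac", "acgt----------AC")
  b1 <- make_block("ACGTacgtacGTACAC", txts)
  b2 <- make_block("ACGTacgtacGTACAC", rev(txts))
  i1 <- call_insertions(b1)
  i2 <- call_insertions(b2)
  expect_equal(i1, i2)
  expect_equal(i1$sequence, "ACGTACGTAC")  # uppercased
})

test_that("multiple runs in one block are disjoint and ordered", {
  b <- make_block("AACCGGTTAACCGGTT",
                  rep("AACC----AACC--TT", 5L), focal_start = 0L)
  ins <- call_insertions(b)
  expect_equal(nrow(ins), 2L)
  expect_equal(ins$start, c(4L, 12L))
  expect_equal(ins$end, c(8L, 14L))
  expect_true(all(ins$end[-nrow(ins)] <= ins$start[-1]))  # no overlap
})

test_that("scan_insertions deduplicates identical calls and is order-invariant", {
  b <- make_block("ACGTACGTACGTACAC", rep("ACGT----------AC", 5L))
  b2 <- make_block("AACCGGTTAACCGGTT", rep("AACC----AACCGGTT", 5L))
  ins <- scan_insertions(list(b, b, b2))
  expect_equal(nrow(ins), 2L)
  expect_equal(attr(ins, "n_duplicates"), 1L)
  rev_ins <- scan_insertions(list(b2, b, b))
  expect_setequal(paste(ins$start, ins$end), paste(rev_ins$start, rev_ins$end))
})

test_that("length filter keeps the 10 nt boundary inclusive and conserves counts", {
  ins <- make_insertions(c(0, 100, 200), c(9, 110, 215))  # lengths 9, 10, 15
  f <- filter_by_length(ins)
  expect_equal(f$kept$length, c(10L, 15L))
  expect_equal(f$removed_count, 1L)
  expect_equal(nrow(f$kept) + f$removed_count, nrow(ins))
  empty <- filter_by_length(make_insertions(integer(0), integer(0)))
  expect_equal(nrow(empty$kept), 0L)
  expect_equal(empty$removed_count, 0L)
})

test_that("polymorphic subtraction removes exact matches only and partitions", {
  ins <- make_insertions(c(104, 300), c(114, 330))
  exact <- data.frame(chrom = "chr1", start = 104L, length = 10L)
  s <- subtract_polymorphic(ins, exact)
  expect_equal(s$removed$start, 104L)
  expect_equal(s$fixed$start, 300L)
  expect_equal(nrow(s$fixed) + nrow(s$removed), nrow(ins))

  internal <- data.frame(chrom = "chr1", start = 106L, length = 4L)
  expect_equal(nrow(subtract_polymorphic(ins, internal)$removed), 0L)
  expect_equal(nrow(subtract_polymorphic(ins, NULL)$fixed), 2L)

  # sequence-aware matching distinguishes same-placement alleles
  ins$sequence <- c("ACGTACGTAC", strrep("T", 30))
  seq_known <- data.frame(chrom = "chr1", start = 104L, length = 10L,
                          sequence = "AAAAAAAAAA")
  expect_equal(nrow(subtract_polymorphic(ins, seq_known,
                                         match_sequence = TRUE)$removed), 0L)
  seq_known$sequence <- "ACGTACGTAC"
  expect_equal(nrow(subtract_polymorphic(ins, seq_known,
                                         match_sequence = TRUE)$removed), 1L)
})

test_that("variant counting respects half-open bounds and counts SNPs once", {
  ins <- make_insertions(104, 114)
  snps <- data.frame(chrom = "chr1", pos = c(103L, 104L, 113L, 114L))
  expect_equal(count_variants_in_insertions(ins, snps), 2L)
  expect_equal(count_variants_in_insertions(ins, snps[0, ]), 0L)

  set.seed(42)
  for (rep in 1:5) {
    rins <- random_intervals(50)
    rins <- make_insertions(rins$start, rins$end)
    rsnp <- data.frame(chrom = "chr1", pos = sample.int(100000L, 1000L))
    naive <- sum(vapply(seq_len(nrow(rsnp)), function(i)
      any(rins$start <= rsnp$pos[i] & rsnp$pos[i] < rins$end), logical(1)))
    expect_equal(count_variants_in_insertions(rins, rsnp), naive)
  }
})
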