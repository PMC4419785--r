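test_that("genic classification follows the strand-aware precedence rule", {
  genes <- fixture_transcript("+")
  ins <- make_insertions(c(1050, 1150, 1300, 2500), c(1060, 1160, 1310, 2510))
  calls <- classify_genic(ins, genes)
  expect_equal(calls$category[match(ins$insertion_id, calls$insertion_id)],
               c("UTR5", "CDS_exon", "intron", "intergenic"))
  expect_equal(calls$gene_id[calls$category == "intergenic"], ".")

  minus <- classify_genic(ins[1, ], fixture_transcript("-"))
  expect_equal(minus$category, "UTR3")  # 5' interval flips with the strand
})

test_that("an insertion spanning an exon/intron junction takes the highest precedence", {
  genes <- fixture_transcript("+")
  span <- make_insertions(1190, 1210)   # crosses CDS-exon end into the intron
  expect_equal(classify_genic(span, genes)$category, "CDS_exon")
  utr_span <- make_insertions(1080, 1120)  # crosses UTR5 into CDS
  expect_equal(classify_genic(utr_span, genes)$category, "CDS_exon")
})

test_that("one call per overlapping gene, independent of transcript order", {
  g1 <- fixture_transcript("+")
  g1b <- fixture_transcript("+", tx_id = "GENE1.2")
  g1b$cds_start <- g1b$cds_end <- 1000L   # non-coding isoform
  g2 <- fixture_transcript("+", gene_id = "GENE2", tx_id = "GENE2.1")
  ins <- make_insertions(1150, 1160)
  a <- classify_genic(ins, rbind(g1, g1b, g2))
  b <- classify_genic(ins, rbind(g2, g1b, g1))
  expect_equal(a, b)
  expect_equal(nrow(a), 2L)               # one call per gene
  expect_setequal(a$gene_id, c("GENE1", "GENE2"))
  expect_equal(unique(a$category), "CDS_exon")
})

test_that("non-coding transcripts contribute gene-body evidence only", {
  nc <- fixture_transcript("+")
  nc$cds_start <- nc$cds_end <- 1000L
  calls <- classify_genic(make_insertions(1050, 1060), nc)
  expect_equal(calls$category, "intron")
})

test_that("malformed gene models are rejected by transcript id", {
  bad <- fixture_transcript("+")
  bad$exon_ends <- "1200,2100"   # exon beyond the transcript span
  expect_error(classify_genic(make_insertions(1, 2), bad), "GENE1.1")
})

test_that("repeat summary computes observed, expected and coverage fractions", {
  reps <- data.frame(
    chrom = "chr1",
    start = c(150L, 100L, 170L, 5000L, 6000L),
    end = c(300L, 180L, 200L, 5100L, 6400L),
    repeat_class = c("SINE", "LINE", "LINE", "SINE", "LTR"),
    repeat_name = c("AluY", "L1a", "L1b", "AluSx", "ERV1"))
  ins <- make_insertions(c(100, 400), c(200, 450))
  s <- summarize_repeats(ins, reps)
  # insertion 1: SINE coverage 0.5; LINE union [100,180)+[170,200) = 1.0
  expect_equal(s$any_repeat_fraction, 0.5)
  expect_equal(s$n_repeat_overlapping, 1L)
  expect_equal(s$high_overlap_fraction, 1.0)   # union over classes is 1.0
  expect_equal(s$multi_class_count, 1L)
  ct <- s$class_table
  expect_equal(ct$observed_count[ct$class == "SINE"], 1L)
  expect_equal(ct$observed_count[ct$class == "LINE"], 1L)
  expect_equal(ct$observed_count[ct$class == "LTR"], 0L)
  expect_equal(ct$expected_fraction, c(2, 1, 2) / 5)  # LINE, LTR, SINE sorted
  expect_equal(sum(ct$expected_fraction), 1)
})

test_that("coverage below the threshold is not counted as high overlap", {
  reps <- data.frame(chrom = "chr1", start = 150L, end = 300L,
                     repeat_class = "SINE", repeat_name = "AluY")
  s <- summarize_repeats(make_insertions(100, 200), reps)
  expect_equal(s$any_repeat_fraction, 1.0)
  expect_equal(s$high_overlap_fraction, 0.0)   # 0.5 coverage < 0.8
  expect_equal(summarize_repeats(make_insertions(100, 200), reps,
                                 high_overlap_threshold = 0.5)$high_overlap_fraction, 1.0)
})

test_that("repeat fractions are invariant under splitting an element", {
  set.seed(5)
  ri <- random_intervals(60)
  ins <- make_insertions(ri$start, ri$end)
  reps <- random_intervals(40)
  reps$repeat_class <- sample(c("SINE", "LINE"), 40, replace = TRUE)
  reps$repeat_name <- "r"
  s1 <- summarize_repeats(ins, reps)
  # split every element into two abutting halves of the same class
  mid <- (reps$start + reps$end) %/% 2L
  wide <- reps[reps$end - reps$start >= 2L, ]
  midw <- (wide$start + wide$end) %/% 2L
  split <- rbind(transform(wide, end = midw), transform(wide, start = midw),
                 reps[reps$end - reps$start < 2L, ])
  s2 <- summarize_repeats(ins, split)
  expect_equal(s2$any_repeat_fraction, s1$any_repeat_fraction)
  expect_equal(s2$high_overlap_fraction, s1$high_overlap_fraction)
  expect_equal(s2$class_table$observed_count, s1$class_table$observed_count)
})

test_that("regulatory subset needs DNase, TFBS and gene proximity together", {
  genes <- fixture_transcript("+")
  dnase <- data.frame(chrom = "chr1", start = 1140L, end = 1300L)
  tfbs <- data.frame(chrom = "chr1", start = 1100L, end = 1200L)
  inside <- make_insertions(1150, 1160)
  expect_equal(nrow(regulatory_subset(inside, dnase, tfbs, genes)), 1L)
  # DNase only
  expect_equal(nrow(regulatory_subset(inside, dnase, tfbs[0, ], genes)), 0L)
  # distance boundary: gene span ends at 2000; gaps of 5000 vs 5001
  both <- data.frame(chrom = "chr1", start = 6990L, end = 7020L)
  at_5000 <- make_insertions(7000, 7010)
  at_5001 <- make_insertions(7001, 7011)
  expect_equal(nrow(regulatory_subset(at_5000, both, both, genes)), 1L)
  expect_equal(nrow(regulatory_subset(at_5001, both, both, genes)), 0L)
})

test_that("regulatory subset is idempotent and a subset of its input", {
  set.seed(9)
  ri <- random_intervals(80, max_pos = 20000L)
  ins <- make_insertions(ri$start, ri$end)
  dnase <- random_intervals(30, max_pos = 20000L)
  tfbs <- random_intervals(30, max_pos = 20000L)
  genes <- fixture_transcript("+")
  r1 <- regulatory_subset(ins, dnase, tfbs, genes)
  expect_true(all(r1$insertion_id %in% ins$insertion_id))
  expect_equal(regulatory_subset(r1, dnase, tfbs, genes), r1)
})
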