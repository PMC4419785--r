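test_that("region binomial matches the closed form and handles edge cases", {
  expect_equal(region_binomial(10, 2, 0.1),
               1 - 0.9^10 - 10 * 0.1 * 0.9^9, tolerance = 1e-12)
  expect_equal(region_binomial(10, 0, 0.1), 1.0)
  expect_equal(region_binomial(5, 3, 1.0), 1.0)
  expect_error(region_binomial(10, 11, 0.1), "k_hits")
  expect_error(region_binomial(10, 2, 1.5), "annotated_fraction")
})

test_that("region binomial agrees with exhaustive enumeration for n <= 12", {
  set.seed(2)
  for (rep in 1:15) {
    n <- sample(1:12, 1)
    k <- sample(0:n, 1)
    p <- runif(1)
    expect_equal(region_binomial(n, k, p), oracle_binom_tail(n, k, p),
                 tolerance = 1e-12)
  }
})

test_that("region binomial tail is monotone and telescopes to 1", {
  n <- 30; p <- 0.2
  tails <- vapply(0:n, function(k) region_binomial(n, k, p), numeric(1))
  expect_true(all(diff(tails) <= 0))                       # decreasing in k
  masses <- tails - c(tails[-1], 0)
  expect_true(all(masses >= -1e-12))
  expect_equal(sum(masses), 1, tolerance = 1e-12)
  # non-decreasing in the annotated fraction for fixed k > 0
  ps <- seq(0.05, 0.95, by = 0.05)
  tk <- vapply(ps, function(pp) region_binomial(n, 5, pp), numeric(1))
  expect_true(all(diff(tk) >= 0))
})

test_that("the site-model LRT matches the chi-squared survival closed form", {
  r <- lrt(-100, -97, df = 2)
  expect_equal(r$statistic, 6)
  expect_equal(r$p_value, exp(-3), tolerance = 1e-12)
  expect_equal(lrt(-100, -100)$p_value, 1)
  expect_warning(r0 <- lrt(-97, -100), "clamped")
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
})

test_that("null-simulated LRT p-values are uniform", {
  set.seed(13)
  null_lnl <- -runif(2000, 100, 1000)
  alt_lnl <- null_lnl + rchisq(2000, df = 2) / 2
  p <- lrt(null_lnl, alt_lnl, df = 2)$p_value
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("bonferroni multiplies, clamps and never decreases", {
  expect_equal(bonferroni(1e-4, m = 372), 0.0372)
  expect_equal(bonferroni(0.01, m = 372), 1.0)
  expect_equal(bonferroni(c(0.2, 0.5), m = 1), c(0.2, 0.5))
  set.seed(4)
  p <- runif(50)
  expect_true(all(bonferroni(p, m = 7) >= p))
  expect_equal(bonferroni(p), stats::p.adjust(p, method = "bonferroni"))
  expect_error(bonferroni(c(0.1, 1.2)), "0, 1")
})

test_that("lrt_table runs both model pairs with a shared correction count", {
  lnl <- data.frame(tx_id = c("t1", "t2"), gene_id = c("g1", "g2"),
                    lnL_M1a = c(-100, -200), lnL_M2a = c(-97, -199.9),
                    lnL_M7 = c(-101, -201), lnL_M8 = c(-90, -200.8))
  res <- lrt_table(lnl)
  expect_equal(nrow(res), 4L)
  expect_setequal(unique(res$comparison), c("M1a_vs_M2a", "M7_vs_M8"))
  r12 <- res[res$comparison == "M1a_vs_M2a" & res$tx_id == "t1", ]
  expect_equal(r12$statistic, 6)
  expect_equal(r12$p_adjusted, min(1, r12$p_value * 2))
  resm <- lrt_table(lnl, m = 372)
  expect_equal(resm$p_adjusted, pmin(1, resm$p_value * 372))
})

test_that("basal-plus-extension domains follow the arithmetic and truncation rules", {
  g <- fixture_transcript("+")
  g$tx_start <- 100000L; g$tx_end <- 110000L
  g$cds_start <- 100100L; g$cds_end <- 109000L
  g$exon_starts <- "100000"; g$exon_ends <- "110000"
  d <- build_domains(g, distal = 5000L)
  expect_equal(d$basal_start, 95000)
  expect_equal(d$basal_end, 101000)
  expect_equal(d$start, 90000)
  expect_equal(d$end, 106000)

  d0 <- build_domains(g, distal = 0L)
  expect_equal(c(d0$start, d0$end), c(d0$basal_start, d0$basal_end))

  # neighbor 2 kb downstream of the first basal domain: extensions meet at
  # the neighbor's basal boundary and never invade it
  g2 <- g
  g2$gene_id <- "GENE2"; g2$tx_id <- "GENE2.1"
  shift <- 103000L - 95000L + 2000L   # second basal starts 2 kb after first ends
  g2[, c("tx_start", "tx_end", "cds_start", "cds_end")] <-
    g[, c("tx_start", "tx_end", "cds_start", "cds_end")] + shift
  g2$exon_starts <- as.character(g$tx_start + shift)
  g2$exon_ends <- as.character(g$tx_end + shift)
  dd <- build_domains(rbind(g, g2), basal_up = 5000L, basal_down = 1000L,
                      distal = 5000L)
  b1 <- dd[dd$gene_id == "GENE1", ]; b2 <- dd[dd$gene_id == "GENE2", ]
  expect_equal(b1$end, b2$basal_start)
  expect_equal(b2$start, b1$basal_end)
})

test_that("the canonical transcript is the longest-CDS isoform", {
  short_cds <- fixture_transcript("+")   # exonic CDS length 200, TSS 1000
  short_cds[, c("tx_start", "tx_end", "cds_start", "cds_end")] <-
    short_cds[, c("tx_start", "tx_end", "cds_start", "cds_end")] + 20000L
  short_cds$exon_starts <- "21000,21800"; short_cds$exon_ends <- "21200,22000"
  long_cds <- short_cds; long_cds$tx_id <- "GENE1.2"
  long_cds$tx_start <- 20900L; long_cds$cds_start <- 21000L
  long_cds$cds_end <- 22000L
  long_cds$exon_starts <- "20900"; long_cds$exon_ends <- "22000"  # CDS 1000
  d <- build_domains(rbind(short_cds, long_cds), distal = 0L)
  expect_equal(nrow(d), 1L)
  expect_equal(d$basal_start, 20900 - 5000)   # TSS of the long-CDS isoform
  expect_equal(d$basal_end, 20900 + 1000)
})

test_that("domain-based gene association is gene-order invariant", {
  set.seed(21)
  genes <- do.call(rbind, lapply(1:8, function(i) {
    g <- fixture_transcript("+", gene_id = sprintf("G%d", i),
                            tx_id = sprintf("G%d.1", i))
    off <- as.integer(i * 20000L)
    g[, c("tx_start", "tx_end", "cds_start", "cds_end")] <-
      g[, c("tx_start", "tx_end", "cds_start", "cds_end")] + off
    g$exon_starts <- paste(c(1000L, 1800L) + off, collapse = ",")
    g$exon_ends <- paste(c(1200L, 2000L) + off, collapse = ",")
    g
  }))
  ri <- random_intervals(100, max_pos = 200000L)
  ins <- make_insertions(ri$start, ri$end)
  terms <- data.frame(gene_id = sprintf("G%d", 1:8),
                      term = rep(c("T1", "T2"), 4))
  d1 <- build_domains(genes, distal = 5000L)
  d2 <- build_domains(genes[sample(nrow(genes)), ], distal = 5000L)
  e1 <- region_enrichment(ins, d1, terms, genome_length = 2e5)
  e2 <- region_enrichment(ins, d2, terms, genome_length = 2e5)
  expect_equal(e1, e2)
  expect_true(all(e1$k_hits <= e1$n_regions))
  expect_true(all(e1$p_value >= 0 & e1$p_value <= 1))
})
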