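# Fixture builders and independent brute-force oracles used across tests.

`%||%` <- function(a, b) if (is.null(a)) b else a

PRIMATES <- c("panTro4", "gorGor3", "ponAbe2", "nomLeu3", "rheMac3")

# a block from raw per-species texts; comparison rows share coordinates
make_block <- function(focal_text, comp_texts, focal_start = 100L,
                       focal_strand = "+", chrom = "chr1",
                       src_size = 249250621, comp_species = PRIMATES) {
  nongap <- function(x) nchar(gsub("-", "", x, fixed = TRUE))
  rows <- rbind(
    data.frame(species = "hg19", chrom = chrom, start = focal_start,
               size = nongap(focal_text), strand = focal_strand,
               src_size = src_size, text = focal_text,
               stringsAsFactors = FALSE),
    data.frame(species = comp_species[seq_along(comp_texts)], chrom = chrom,
               start = 100L, size = nongap(comp_texts), strand = "+",
               src_size = src_size, text = comp_texts,
               stringsAsFactors = FALSE))
  maf_block(rows)
}

# insertion data.frame from parallel vectors
make_insertions <- function(start, end, chrom = "chr1") {
  n <- length(start)
  data.frame(chrom = rep(chrom, length.out = n), start = as.integer(start),
             end = as.integer(end), length = as.integer(end - start),
             sequence = strrep("A", end - start),
             touches_block_edge = rep(FALSE, n),
             block_index = rep(NA_integer_, n),
             insertion_id = sprintf("INS%06d", seq_len(n)),
             stringsAsFactors = FALSE)
}

# the worked transcript: '+' chr1 tx [1000,2000), exons [1000,1200)+[1800,2000),
# CDS [1100,1900)
fixture_transcript <- function(strand = "+", gene_id = "GENE1",
                               tx_id = "GENE1.1") {
  data.frame(gene_id = gene_id, tx_id = tx_id, chrom = "chr1",
             strand = strand, tx_start = 1000L, tx_end = 2000L,
             cds_start = 1100L, cds_end = 1900L,
             exon_starts = "1000,1800", exon_ends = "1200,2000",
             stringsAsFactors = FALSE)
}

random_intervals <- function(n, chrom = "chr1", max_pos = 100000L,
                             max_len = 200L) {
  s <- sample.int(max_pos, n, replace = TRUE)
  data.frame(chrom = chrom, start = s,
             end = s + sample.int(max_len, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# ---- brute-force oracles (one explicit loop over queries; the tested path
# is interval-tree based findOverlaps) ---------------------------------

# for each query row: indices of overlapping subject rows
oracle_overlaps <- function(query, subject) {
  lapply(seq_len(nrow(query)), function(i) {
    which(subject$chrom == query$chrom[i] &
            subject$start < query$end[i] & query$start[i] < subject$end)
  })
}

# union coverage fraction of each query under overlapping subject intervals
oracle_coverage <- function(query, subject) {
  hits <- oracle_overlaps(query, subject)
  vapply(seq_len(nrow(query)), function(i) {
    if (!length(hits[[i]])) return(0)
    covered <- rep(FALSE, query$end[i] - query$start[i])
    for (j in hits[[i]]) {
      lo <- max(subject$start[j], query$start[i]) - query$start[i] + 1L
      hi <- min(subject$end[j], query$end[i]) - query$start[i]
      covered[lo:hi] <- TRUE
    }
    mean(covered)
  }, numeric(1))
}

# max subject value over intervals overlapping each query (NA if none)
oracle_max_score <- function(query, subject) {
  hits <- oracle_overlaps(query, subject)
  vapply(hits, function(h)
    if (length(h)) max(subject$value[h]) else NA_real_, numeric(1))
}

# exhaustive-enumeration upper binomial tail, n <= 12
oracle_binom_tail <- function(n, k, p) {
  if (k == 0) return(1)
  total <- 0
  for (bits in 0:(2^n - 1)) {
    ones <- sum(bitwAnd(bits, 2^(0:(n - 1))) > 0)
    if (ones >= k) total <- total + p^ones * (1 - p)^(n - ones)
  }
  total
}

small_sim_config <- function(seed = 7L, n_blocks = 40L, ...) {
  simulation_config(seed = seed, n_blocks = n_blocks,
                    block_length = 10000L, ...)
}
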