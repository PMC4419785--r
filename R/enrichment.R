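#' Upper-tail region binomial probability
#'
#' Probability of observing `k_hits` or more annotated regions out of
#' `n_regions` when each region independently falls in the annotation's
#' regulatory domains with probability `annotated_fraction` (the domains'
#' share of the annotatable genome). This is the region-based enrichment
#' test used with regulatory-domain gene association.
#'
#' @param n_regions number of query regions.
#' @param k_hits number of regions hitting the annotation's domains.
#' @param annotated_fraction domain fraction of the genome, in \[0, 1\].
#' @return `P(X >= k_hits)` for `X ~ Binomial(n_regions, annotated_fraction)`.
#' @export
region_binomial <- function(n_regions, k_hits, annotated_fraction) {
  if (length(n_regions) != 1L || length(k_hits) != 1L ||
      length(annotated_fraction) != 1L ||
      is.na(n_regions) || is.na(k_hits) || is.na(annotated_fraction) ||
      n_regions < 0 || k_hits < 0 || k_hits > n_regions ||
      annotated_fraction < 0 || annotated_fraction > 1)
    stop("region_binomial: need 0 <= k_hits <= n_regions and annotated_fraction in [0, 1]")
  if (k_hits == 0) return(1)
  stats::pbinom(k_hits - 1, n_regions, annotated_fraction, lower.tail = FALSE)
}

#' Likelihood-ratio test between nested site models
#'
#' Compares the log-likelihoods of a null and an alternative codon site
#' model (M1a vs M2a, M7 vs M8). The statistic is `2 * (lnL_alt -
#' lnL_null)`, clamped at 0 with a warning when the alternative fits worse
#' (a sign of optimizer failure); the p-value is the upper chi-squared tail
#' with `df` degrees of freedom (2 for both standard pairs, the number of
#' extra parameters of the selection model).
#'
#' @param lnL_null,lnL_alt log-likelihoods (vectorized).
#' @param df chi-squared degrees of freedom, default 2.
#' @return list with `statistic` and `p_value`.
#' @export
lrt <- function(lnL_null, lnL_alt, df = 2L) {
  stopifnot(df >= 1L)
  stat <- 2 * (lnL_alt - lnL_null)
  if (any(stat < 0))
    warning(sum(stat < 0), " test(s) with lnL_alt < lnL_null; statistic clamped to 0")
  stat <- pmax(0, stat)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Bonferroni correction with an explicit number of tests
#'
#' Multiplies each p-value by `m` and clamps at 1. `m` defaults to the
#' number of p-values supplied but is deliberately an explicit argument:
#' when transcripts of the same gene are tested together, the analyst must
#' choose whether `m` counts genes or transcript-level tests.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @param m number of tests.
#' @return adjusted p-values, order preserved.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  stopifnot(m >= 1L)
  pmin(1, p_values * m)
}

#' Site-model LRTs for a table of log-likelihoods
#'
#' Runs the M1a-vs-M2a and M7-vs-M8 likelihood-ratio tests for every
#' transcript of a log-likelihood table (as produced by an external codeml
#' run) and applies a Bonferroni correction within each model pair.
#'
#' @param lnl data.frame with columns `tx_id`, `lnL_M1a`, `lnL_M2a`,
#'   `lnL_M7`, `lnL_M8` (an optional `gene_id` column is carried through).
#' @param df chi-squared degrees of freedom per test, default 2.
#' @param m number of tests for the Bonferroni correction; defaults to the
#'   number of transcripts.
#' @return long data.frame: `tx_id`, (`gene_id`,) `comparison`, `lnL_null`,
#'   `lnL_alt`, `df`, `statistic`, `p_value`, `p_adjusted`.
#' @export
lrt_table <- function(lnl, df = 2L, m = nrow(lnl)) {
  pairs <- list(M1a_vs_M2a = c("lnL_M1a", "lnL_M2a"),
                M7_vs_M8 = c("lnL_M7", "lnL_M8"))
  out <- lapply(names(pairs), function(nm) {
    cols <- pairs[[nm]]
    r <- lrt(lnl[[cols[1]]], lnl[[cols[2]]], df = df)
    d <- data.frame(tx_id = lnl$tx_id, comparison = nm,
                    lnL_null = lnl[[cols[1]]], lnL_alt = lnl[[cols[2]]],
                    df = df, statistic = r$statistic, p_value = r$p_value,
                    p_adjusted = bonferroni(r$p_value, m),
                    stringsAsFactors = FALSE)
    if (!is.null(lnl$gene_id)) d$gene_id <- lnl$gene_id
    d
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Build basal-plus-extension regulatory domains
#'
#' Each gene gets a basal promoter domain around the TSS of its canonical
#' transcript (`basal_up` bp upstream to `basal_down` bp downstream,
#' strand-aware), extended in both directions by up to `distal` bp but
#' never into a neighboring gene's basal domain. The canonical transcript
#' is the one with the longest total CDS (ties: longest transcript span,
#' then first in the table). Domains are clipped to `[0, chromosome
#' length)` when `chrom_lengths` is given.
#'
#' @param genes gene-model data.frame.
#' @param basal_up,basal_down basal extent upstream/downstream of the TSS
#'   in bp (defaults 5000 / 1000).
#' @param distal maximum extension beyond the basal domain, bp.
#' @param chrom_lengths optional named vector of chromosome lengths.
#' @return data.frame: `gene_id`, `chrom`, `start`, `end`, `basal_start`,
#'   `basal_end` (0-based half-open).
#' @export
build_domains <- function(genes, basal_up = 5000L, basal_down = 1000L,
                          distal = 5000L, chrom_lengths = NULL) {
  stopifnot(basal_up >= 0, basal_down >= 0, distal >= 0)
  validate_gene_models(genes)
  canon <- canonical_transcripts(genes)
  tss <- ifelse(canon$strand == "+", canon$tx_start, canon$tx_end)
  basal_start <- ifelse(canon$strand == "+", tss - basal_up, tss - basal_down)
  basal_end <- ifelse(canon$strand == "+", tss + basal_down, tss + basal_up)
  d <- data.frame(gene_id = canon$gene_id, chrom = canon$chrom,
                  basal_start = pmax(0, basal_start), basal_end = basal_end,
                  stringsAsFactors = FALSE)
  d$start <- NA_real_; d$end <- NA_real_
  for (chr in unique(d$chrom)) {
    i <- which(d$chrom == chr)
    i <- i[order(d$basal_start[i], d$basal_end[i])]
    bs <- d$basal_start[i]; be <- d$basal_end[i]
    n <- length(i)
    left_lim <- c(-Inf, cummax(be)[-n])   # rightmost basal end among genes to the left
    right_lim <- c(bs[-1], Inf)           # nearest basal start among genes to the right
    d$start[i] <- pmax(bs - distal, pmin(left_lim, bs), 0)
    d$end[i] <- pmin(be + distal, pmax(right_lim, be))
  }
  if (!is.null(chrom_lengths)) {
    lim <- chrom_lengths[d$chrom]
    d$end <- pmin(d$end, lim)
    d$basal_end <- pmin(d$basal_end, lim)
  }
  d[, c("gene_id", "chrom", "start", "end", "basal_start", "basal_end")]
}

# one canonical transcript per gene: longest CDS, tie longest span, tie first
canonical_transcripts <- function(genes) {
  cds_len <- vapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    ex <- exon_list(g)
    sum(pmax(0, pmin(ex$end, g$cds_end) - pmax(ex$start, g$cds_start)))
  }, numeric(1))
  span <- genes$tx_end - genes$tx_start
  ord <- order(genes$gene_id, -cds_len, -span, seq_len(nrow(genes)))
  g <- genes[ord, , drop = FALSE]
  g[!duplicated(g$gene_id), , drop = FALSE]
}

#' Regulatory-domain enrichment of an insertion set over a gene-term table
#'
#' Associates insertions to genes through regulatory domains (an insertion
#' hits a gene iff at least one of its bases lies in the gene's domain) and,
#' for every term of a two-column gene-to-term table, computes the
#' upper-tail region binomial p-value: `n_regions` insertions, of which
#' `k_hits` hit the union of domains of the term's genes, against that
#' union's fraction of the annotatable genome.
#'
#' @param insertions insertion data.frame.
#' @param domains regulatory-domain data.frame from [build_domains()].
#' @param gene_terms data.frame with columns `gene_id`, `term`.
#' @param genome_length annotatable genome length in bp (denominator of the
#'   domain fraction).
#' @return data.frame: `annotation_id`, `n_regions`, `k_hits`,
#'   `annotated_fraction`, `p_value`, sorted by `p_value`.
#' @export
region_enrichment <- function(insertions, domains, gene_terms, genome_length) {
  stopifnot(genome_length > 0)
  n <- nrow(insertions)
  ins_gr <- insertions_gr(insertions)
  out <- lapply(sort(unique(gene_terms$term)), function(term) {
    gids <- gene_terms$gene_id[gene_terms$term == term]
    dom <- domains[domains$gene_id %in% gids, , drop = FALSE]
    dom_gr <- GenomicRanges::reduce(intervals_gr(dom))
    frac <- min(1, sum(GenomicRanges::width(dom_gr)) / genome_length)
    k <- sum(GenomicRanges::countOverlaps(ins_gr, dom_gr) > 0L)
    data.frame(annotation_id = term, n_regions = n, k_hits = k,
               annotated_fraction = frac,
               p_value = region_binomial(n, k, frac),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$p_value, out$annotation_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
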