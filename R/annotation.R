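GENIC_CATEGORIES <- c("intergenic", "intron", "UTR3", "UTR5", "CDS_exon")

#' Validate a gene-model table
#'
#' Gene models are transcript-level records: `gene_id`, `tx_id`, `chrom`,
#' `strand`, `tx_start`, `tx_end`, `cds_start`, `cds_end` and comma-separated
#' `exon_starts` / `exon_ends` (0-based half-open, like genePred).
#' `cds_start == cds_end` encodes a non-coding transcript.
#'
#' @param genes gene-model data.frame.
#' @return the validated data.frame, invisibly.
#' @export
validate_gene_models <- function(genes) {
  required <- c("gene_id", "tx_id", "chrom", "strand", "tx_start", "tx_end",
                "cds_start", "cds_end", "exon_starts", "exon_ends")
  missing <- setdiff(required, names(genes))
  if (length(missing))
    stop("gene model table lacks columns: ", paste(missing, collapse = ", "))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    es <- as.integer(strsplit(g$exon_starts, ",")[[1]])
    ee <- as.integer(strsplit(g$exon_ends, ",")[[1]])
    ok <- length(es) == length(ee) && length(es) >= 1L && all(es < ee) &&
      !is.unsorted(es, strictly = TRUE) && all(head(ee, -1) <= tail(es, -1)) &&
      g$tx_start <= g$cds_start && g$cds_start <= g$cds_end &&
      g$cds_end <= g$tx_end && es[1] >= g$tx_start && ee[length(ee)] <= g$tx_end
    if (!ok) stop("malformed gene model for transcript ", g$tx_id)
  }
  invisible(genes)
}

exon_list <- function(g) {
  data.frame(start = as.integer(strsplit(g$exon_starts, ",")[[1]]),
             end = as.integer(strsplit(g$exon_ends, ",")[[1]]))
}

# intersect exon set with one interval [s, e)
clip_intervals <- function(exons, s, e) {
  ns <- pmax(exons$start, s); ne <- pmin(exons$end, e)
  keep <- ns < ne
  data.frame(start = ns[keep], end = ne[keep])
}

# per-transcript categorized sub-intervals with precedence ranks
transcript_regions <- function(g) {
  ex <- exon_list(g)
  pieces <- list(data.frame(start = g$tx_start, end = g$tx_end,
                            rank = 2L))  # gene body: at least intronic
  if (g$cds_start < g$cds_end) {
    cds <- clip_intervals(ex, g$cds_start, g$cds_end)
    if (nrow(cds)) pieces <- c(pieces, list(cbind(cds, rank = 5L)))
    if (identical(g$strand, "+")) {
      u5 <- clip_intervals(ex, g$tx_start, g$cds_start)
      u3 <- clip_intervals(ex, g$cds_end, g$tx_end)
    } else {
      u5 <- clip_intervals(ex, g$cds_end, g$tx_end)
      u3 <- clip_intervals(ex, g$tx_start, g$cds_start)
    }
    if (nrow(u5)) pieces <- c(pieces, list(cbind(u5, rank = 4L)))
    if (nrow(u3)) pieces <- c(pieces, list(cbind(u3, rank = 3L)))
  }
  do.call(rbind, pieces)
}

#' Classify insertions against gene models
#'
#' For each gene whose transcript span overlaps an insertion, emits exactly
#' one call with the highest-precedence category over all of that gene's
#' transcripts: `CDS_exon > UTR5 > UTR3 > intron`. UTR orientation is
#' strand-aware (on `-` transcripts the 5' UTR lies between the CDS end and
#' the transcript end). An insertion overlapping no gene yields a single
#' sentinel call with `gene_id = "."` and category `intergenic`. Non-coding
#' transcripts (`cds_start == cds_end`) contribute gene-body evidence only,
#' i.e. at most an `intron` call.
#'
#' @param insertions insertion data.frame (needs `insertion_id`).
#' @param genes gene-model data.frame (see [validate_gene_models()]).
#' @return data.frame with `insertion_id`, `gene_id`, `category`.
#' @export
classify_genic <- function(insertions, genes) {
  validate_gene_models(genes)
  if (!nrow(insertions))
    return(data.frame(insertion_id = character(0), gene_id = character(0),
                      category = character(0), stringsAsFactors = FALSE))
  regions <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    r <- transcript_regions(genes[i, ])
    r$gene_id <- genes$gene_id[i]
    r$chrom <- genes$chrom[i]
    r
  }))
  reg_gr <- intervals_gr(regions)
  ins_gr <- insertions_gr(insertions)
  hits <- GenomicRanges::findOverlaps(ins_gr, reg_gr)
  cat_names <- c(NA, "intron", "UTR3", "UTR5", "CDS_exon")
  out <- data.frame(insertion_id = insertions$insertion_id[S4Vectors::queryHits(hits)],
                    gene_id = regions$gene_id[S4Vectors::subjectHits(hits)],
                    rank = regions$rank[S4Vectors::subjectHits(hits)],
                    stringsAsFactors = FALSE)
  if (nrow(out)) {
    out <- stats::aggregate(rank ~ insertion_id + gene_id, data = out, FUN = max)
  }
  calls <- data.frame(insertion_id = out$insertion_id, gene_id = out$gene_id,
                      category = cat_names[out$rank], stringsAsFactors = FALSE)
  orphan <- setdiff(insertions$insertion_id, calls$insertion_id)
  if (length(orphan))
    calls <- rbind(calls,
                   data.frame(insertion_id = orphan, gene_id = ".",
                              category = "intergenic", stringsAsFactors = FALSE))
  calls <- calls[order(match(calls$insertion_id, insertions$insertion_id),
                       calls$gene_id), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Summarize repeat-element overlap of an insertion set
#'
#' An insertion is repeat-overlapping if at least one base overlaps any
#' repeat element. Per class, `observed_count` counts insertions touching
#' that class (an insertion overlapping several classes increments each;
#' the number of such multi-class insertions is reported), and
#' `observed_fraction` divides by the number of repeat-overlapping
#' insertions so it is comparable to `expected_fraction`, the share of
#' elements of that class among all annotated elements. Coverage of an
#' insertion is the fraction of its bases under the union of its
#' overlapping elements; `high_overlap_fraction` is the share of
#' repeat-overlapping insertions with coverage at or above the threshold.
#'
#' @param insertions insertion data.frame.
#' @param repeats data.frame with `chrom`, `start`, `end`, `repeat_class`
#'   (and optionally `repeat_name`).
#' @param high_overlap_threshold coverage threshold in (0, 1], default 0.8.
#' @return list with `class_table` (class, observed_count,
#'   observed_fraction, expected_fraction), `any_repeat_fraction`,
#'   `high_overlap_fraction`, `n_insertions`, `n_repeat_overlapping`,
#'   `multi_class_count`.
#' @export
summarize_repeats <- function(insertions, repeats, high_overlap_threshold = 0.8) {
  stopifnot(high_overlap_threshold > 0, high_overlap_threshold <= 1)
  classes <- sort(unique(repeats$repeat_class))
  n_ins <- nrow(insertions)
  ins_gr <- insertions_gr(insertions)
  rep_gr <- intervals_gr(repeats)
  hits <- GenomicRanges::findOverlaps(ins_gr, rep_gr)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)

  overlapping <- sort(unique(qh))
  n_overlap <- length(overlapping)

  obs <- vapply(classes, function(cl) {
    length(unique(qh[repeats$repeat_class[sh] == cl]))
  }, integer(1))
  n_classes_per_ins <- vapply(overlapping, function(i)
    length(unique(repeats$repeat_class[sh[qh == i]])), integer(1))

  # union coverage across all classes, per overlapping insertion
  cov_frac <- vapply(overlapping, function(i) {
    red <- GenomicRanges::reduce(rep_gr[sh[qh == i]])
    inter <- GenomicRanges::pintersect(rep(ins_gr[i], length(red)), red)
    sum(GenomicRanges::width(inter)) / insertions$length[i]
  }, numeric(1))

  class_table <- data.frame(
    class = classes,
    observed_count = obs,
    observed_fraction = if (n_overlap) obs / n_overlap else rep(NA_real_, length(obs)),
    expected_fraction = as.vector(table(factor(repeats$repeat_class,
                                               levels = classes))) / nrow(repeats),
    stringsAsFactors = FALSE)
  list(class_table = class_table,
       any_repeat_fraction = if (n_ins) n_overlap / n_ins else NA_real_,
       high_overlap_fraction = if (n_overlap)
         mean(cov_frac >= high_overlap_threshold) else NA_real_,
       n_insertions = n_ins,
       n_repeat_overlapping = n_overlap,
       multi_class_count = sum(n_classes_per_ins > 1L))
}

#' Restrict insertions to a strict regulatory subset
#'
#' Keeps insertions that overlap (by at least one base) both a DNase
#' hypersensitivity interval and a TF-ChIP interval, and lie within
#' `max_tss_distance` of the nearest gene transcript span (distance 0 for
#' insertions inside a span). Insertions on chromosomes with no gene are
#' excluded. The operation is idempotent and its output is a subset of its
#' input.
#'
#' @param insertions insertion data.frame.
#' @param dnase,tfbs interval data.frames (`chrom`, `start`, `end`).
#' @param genes gene-model data.frame.
#' @param max_tss_distance maximum gap to the nearest transcript span, bp.
#' @return the retained rows of `insertions`.
#' @export
regulatory_subset <- function(insertions, dnase, tfbs, genes,
                              max_tss_distance = 5000L) {
  if (!nrow(insertions)) return(insertions)
  ins_gr <- insertions_gr(insertions)
  has_dnase <- GenomicRanges::countOverlaps(ins_gr, intervals_gr(dnase)) > 0L
  has_tfbs <- GenomicRanges::countOverlaps(ins_gr, intervals_gr(tfbs)) > 0L
  tx_gr <- GenomicRanges::GRanges(genes$chrom,
                                  IRanges::IRanges(genes$tx_start + 1L, genes$tx_end))
  near <- GenomicRanges::distanceToNearest(ins_gr, tx_gr)
  dist <- rep(NA_real_, nrow(insertions))
  dist[S4Vectors::queryHits(near)] <- S4Vectors::mcols(near)$distance
  keep <- has_dnase & has_tfbs & !is.na(dist) & dist <= max_tss_distance
  out <- insertions[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
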