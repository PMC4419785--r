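#' Write insertions as BED6+
#'
#' Columns: chrom, start, end, name (insertion id), score (length), strand
#' (always `+`), sequence, edge flag.
#'
#' @param insertions insertion data.frame.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_insertions_bed <- function(insertions, file) {
  d <- data.table::data.table(
    chrom = insertions$chrom, start = insertions$start, end = insertions$end,
    name = insertions$insertion_id %||% sprintf("INS%06d", seq_len(nrow(insertions))),
    score = insertions$length, strand = "+",
    sequence = insertions$sequence,
    edge = as.integer(insertions$touches_block_edge))
  data.table::fwrite(d, file, sep = "\t", col.names = FALSE, eol = "\n")
  invisible(file)
}

#' Read insertions from BED6+ written by [write_insertions_bed()]
#' @param file path.
#' @return insertion data.frame.
#' @export
read_insertions_bed <- function(file) {
  d <- data.table::fread(file, header = FALSE,
                         col.names = c("chrom", "start", "end", "name",
                                       "score", "strand", "sequence", "edge"))
  data.frame(chrom = d$chrom, start = as.integer(d$start),
             end = as.integer(d$end),
             length = as.integer(d$end - d$start), sequence = d$sequence,
             touches_block_edge = d$edge == 1L,
             block_index = NA_integer_, insertion_id = d$name,
             stringsAsFactors = FALSE)
}

#' Read plain intervals from a BED file
#'
#' Uses `rtracklayer` for the format handling; returns 0-based half-open
#' coordinates.
#'
#' @param file path to a BED file.
#' @return data.frame with `chrom`, `start`, `end`.
#' @export
read_bed_intervals <- function(file) {
  gr <- rtracklayer::import(file, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}

write_bed3 <- function(d, file) {
  data.table::fwrite(data.table::data.table(d$chrom, d$start, d$end),
                     file, sep = "\t", col.names = FALSE, eol = "\n")
  invisible(file)
}

#' Read repeat annotations
#'
#' Accepts RepeatMasker `.out` files (1-based, converted on read) or a
#' 5-column BED-like TSV `chrom start end repeat_class repeat_name`
#' (0-based half-open).
#'
#' @param file path; `.out` triggers RepeatMasker parsing.
#' @return data.frame with `chrom`, `start`, `end`, `repeat_class`,
#'   `repeat_name`.
#' @export
read_repeats <- function(file) {
  if (identical(tolower(tools::file_ext(file)), "out")) {
    lines <- readLines(file)
    lines <- lines[-seq_len(min(3L, length(lines)))]  # banner
    lines <- lines[nzchar(trimws(lines))]
    f <- strsplit(trimws(lines), "[ \t]+")
    return(data.frame(
      chrom = vapply(f, `[`, "", 5L),
      start = as.integer(vapply(f, `[`, "", 6L)) - 1L,
      end = as.integer(vapply(f, `[`, "", 7L)),
      repeat_class = sub("/.*$", "", vapply(f, `[`, "", 11L)),
      repeat_name = vapply(f, `[`, "", 10L), stringsAsFactors = FALSE))
  }
  d <- data.table::fread(file, header = FALSE,
                         col.names = c("chrom", "start", "end",
                                       "repeat_class", "repeat_name"))
  data.frame(chrom = d$chrom, start = as.integer(d$start),
             end = as.integer(d$end), repeat_class = d$repeat_class,
             repeat_name = d$repeat_name, stringsAsFactors = FALSE)
}

write_repeats <- function(repeats, file) {
  data.table::fwrite(data.table::data.table(
    repeats$chrom, repeats$start, repeats$end,
    repeats$repeat_class, repeats$repeat_name),
    file, sep = "\t", col.names = FALSE, eol = "\n")
  invisible(file)
}

#' Read gene models from genePred or BED12
#'
#' genePred may be the 10-column form (`name chrom strand txStart txEnd
#' cdsStart cdsEnd exonCount exonStarts exonEnds`; the transcript name
#' doubles as gene id) or the 15-column extended form whose `name2` column
#' carries the gene id. BED12 uses `thickStart`/`thickEnd` as the CDS and
#' block definitions as exons. All coordinates are already 0-based.
#'
#' @param file path; `.bed` extension triggers BED12 parsing.
#' @return gene-model data.frame (see [validate_gene_models()]).
#' @export
read_gene_models <- function(file) {
  d <- data.table::fread(file, header = FALSE)
  if (identical(tolower(tools::file_ext(file)), "bed")) {
    stopifnot(ncol(d) >= 12L)
    starts <- mapply(function(cs, rel) {
      paste(as.integer(strsplit(rel, ",")[[1]]) + cs, collapse = ",")
    }, d[[2]], d[[12]])
    ends <- mapply(function(cs, rel, sz) {
      r <- as.integer(strsplit(rel, ",")[[1]]) + cs
      paste(r + as.integer(strsplit(sz, ",")[[1]]), collapse = ",")
    }, d[[2]], d[[12]], d[[11]])
    g <- data.frame(gene_id = d[[4]], tx_id = d[[4]], chrom = d[[1]],
                    strand = d[[6]], tx_start = as.integer(d[[2]]),
                    tx_end = as.integer(d[[3]]),
                    cds_start = as.integer(d[[7]]),
                    cds_end = as.integer(d[[8]]),
                    exon_starts = unname(starts), exon_ends = unname(ends),
                    stringsAsFactors = FALSE)
  } else {
    gene_id <- if (ncol(d) >= 12L) d[[12]] else d[[1]]
    g <- data.frame(gene_id = gene_id, tx_id = d[[1]], chrom = d[[2]],
                    strand = d[[3]], tx_start = as.integer(d[[4]]),
                    tx_end = as.integer(d[[5]]),
                    cds_start = as.integer(d[[6]]),
                    cds_end = as.integer(d[[7]]),
                    exon_starts = sub(",$", "", d[[9]]),
                    exon_ends = sub(",$", "", d[[10]]),
                    stringsAsFactors = FALSE)
  }
  validate_gene_models(g)
  g
}

#' Write gene models as 15-column extended genePred
#' @param genes gene-model data.frame.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_gene_models <- function(genes, file) {
  n_exons <- vapply(strsplit(genes$exon_starts, ","), length, integer(1))
  d <- data.table::data.table(
    genes$tx_id, genes$chrom, genes$strand, genes$tx_start, genes$tx_end,
    genes$cds_start, genes$cds_end, n_exons,
    paste0(genes$exon_starts, ","), paste0(genes$exon_ends, ","),
    0L, genes$gene_id, "cmpl", "cmpl", "-1,")
  data.table::fwrite(d, file, sep = "\t", col.names = FALSE, eol = "\n")
  invisible(file)
}

#' Read a known polymorphic-indel set
#'
#' Accepts VCF (insertions are records whose ALT is longer than REF, with
#' the first REF base as the anchor: the inserted sequence starts at POS in
#' 0-based coordinates) or a TSV with columns `chrom`, `start` (0-based),
#' `length` and optionally `sequence`.
#'
#' @param file path; `.vcf` triggers VCF parsing via `VariantAnnotation`.
#' @return data.frame with `chrom`, `start`, `length`, `sequence`.
#' @export
read_polymorphic <- function(file) {
  if (identical(tolower(tools::file_ext(file)), "vcf")) {
    if (!requireNamespace("VariantAnnotation", quietly = TRUE))
      stop("reading VCF requires the VariantAnnotation package")
    v <- VariantAnnotation::readVcf(file)
    ref <- as.character(VariantAnnotation::ref(v))
    alt <- as.character(unlist(VariantAnnotation::alt(v)))
    pos <- GenomicRanges::start(SummarizedExperiment::rowRanges(v))
    chrom <- as.character(GenomicRanges::seqnames(
      SummarizedExperiment::rowRanges(v)))
    is_ins <- nchar(alt) > nchar(ref) &
      substr(alt, 1L, nchar(ref)) == ref
    return(data.frame(
      chrom = chrom[is_ins],
      start = pos[is_ins],  # POS is 1-based anchor; insertion begins at POS 0-based
      length = (nchar(alt) - nchar(ref))[is_ins],
      sequence = substr(alt[is_ins], nchar(ref[is_ins]) + 1L,
                        nchar(alt[is_ins])),
      stringsAsFactors = FALSE))
  }
  d <- data.table::fread(file, header = TRUE)
  stopifnot(all(c("chrom", "start", "length") %in% names(d)))
  data.frame(chrom = d$chrom, start = as.integer(d$start),
             length = as.integer(d$length),
             sequence = if (!is.null(d$sequence)) d$sequence else NA_character_,
             stringsAsFactors = FALSE)
}

write_polymorphic_tsv <- function(known, file) {
  data.table::fwrite(data.table::data.table(
    chrom = known$chrom, start = known$start,
    length = known$length, sequence = known$sequence),
    file, sep = "\t", eol = "\n")
  invisible(file)
}

# Minimal VCF emission of an insertion list: REF is the anchor base before
# the inserted sequence (supplied by the caller), ALT = anchor + sequence.
write_polymorphic_vcf <- function(known, anchors, file) {
  con <- file(file, open = "wb")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                     known$chrom, known$start, anchors,
                     paste0(anchors, known$sequence)), con)
  invisible(file)
}

#' Read a windowed selection-score track
#'
#' Accepts bedGraph (`chrom start end value`, 0-based) via `rtracklayer`,
#' or a 4-column TSV with a header. Statistic and population labels are
#' attached from the arguments.
#'
#' @param file path; `.bedgraph`/`.bg` triggers bedGraph parsing.
#' @param statistic,population labels for the track (e.g. `"CLR"`, `"CEU"`).
#' @return data.frame with `chrom`, `start`, `end`, `value`, `statistic`,
#'   `population`.
#' @export
read_score_track <- function(file, statistic, population) {
  ext <- tolower(tools::file_ext(file))
  if (ext %in% c("bedgraph", "bg")) {
    gr <- rtracklayer::import(file, format = "bedGraph")
    d <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    value = S4Vectors::mcols(gr)$score,
                    stringsAsFactors = FALSE)
  } else {
    x <- data.table::fread(file, header = TRUE)
    d <- data.frame(chrom = x[[1]], start = as.integer(x[[2]]),
                    end = as.integer(x[[3]]), value = as.numeric(x[[4]]),
                    stringsAsFactors = FALSE)
  }
  d$statistic <- statistic
  d$population <- population
  d
}

write_score_track <- function(track, file) {
  data.table::fwrite(data.table::data.table(
    track$chrom, track$start, track$end, track$value),
    file, sep = "\t", col.names = FALSE, eol = "\n")
  invisible(file)
}

#' Read per-SNP iHS scores
#' @param file TSV with header `chrom pos value population` (`pos` 0-based).
#' @return data.frame with those columns.
#' @export
read_snp_scores <- function(file) {
  d <- data.table::fread(file, header = TRUE)
  stopifnot(all(c("chrom", "pos", "value", "population") %in% names(d)))
  data.frame(chrom = d$chrom, pos = as.integer(d$pos),
             value = as.numeric(d$value), population = d$population,
             stringsAsFactors = FALSE)
}

write_snp_scores <- function(snps, file) {
  data.table::fwrite(data.table::as.data.table(
    snps[, c("chrom", "pos", "value", "population")]),
    file, sep = "\t", eol = "\n")
  invisible(file)
}

#' Read a site-model log-likelihood table
#' @param file TSV with header `tx_id lnL_M1a lnL_M2a lnL_M7 lnL_M8`
#'   (optional `gene_id`).
#' @return data.frame.
#' @export
read_lnl_table <- function(file) {
  d <- data.table::fread(file, header = TRUE)
  stopifnot(all(c("tx_id", "lnL_M1a", "lnL_M2a", "lnL_M7", "lnL_M8")
                %in% names(d)))
  data.table::setDF(d)
  d
}

write_lnl_table <- function(lnl, file) {
  data.table::fwrite(data.table::as.data.table(lnl), file, sep = "\t",
                     eol = "\n")
  invisible(file)
}

#' Read / write the synthetic ground-truth manifest
#' @param file TSV path.
#' @return data.frame.
#' @export
read_truth_manifest <- function(file) {
  d <- data.table::fread(file, header = TRUE)
  data.table::setDF(d)
  d
}

write_truth_manifest <- function(truth, file) {
  data.table::fwrite(data.table::as.data.table(truth), file, sep = "\t",
                     eol = "\n")
  invisible(file)
}
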