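empty_insertions <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
              length = integer(0), sequence = character(0),
              touches_block_edge = logical(0), block_index = integer(0),
              stringsAsFactors = FALSE)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Call focal-lineage-specific insertions in one alignment block
#'
#' A column supports an insertion iff the focal character is a base
#' (A/C/G/T, any case; N only when `allow_n = TRUE`) and the character of
#' *every* comparison species is the gap character `-`. Maximal runs of
#' supporting columns become insertion calls. The explicit-evidence rule
#' requires a row for every comparison species: if any is missing from the
#' block, no call is made (absence of a row is never treated as a gap),
#' which guards against unmapped regions in lower-quality assemblies.
#'
#' Calls from a minus-strand focal row are projected onto the plus strand
#' (coordinates flipped against the chromosome length, sequence
#' reverse-complemented). Runs that abut the first or last column are
#' flagged `touches_block_edge`, since an insertion may continue in a
#' neighboring block.
#'
#' @param block a [maf_block].
#' @param focal species label of the focal genome (must be present).
#' @param comparison non-empty character vector of comparison species.
#' @param allow_n logical; treat focal `N` as insertion-supporting.
#' @param block_index integer stored in the output for provenance.
#' @return data.frame with columns `chrom`, `start`, `end`, `length`,
#'   `sequence` (uppercase, plus strand), `touches_block_edge`,
#'   `block_index`. Coordinates are 0-based half-open on the focal genome.
#' @export
call_insertions <- function(block, focal = "hg19",
                            comparison = c("panTro4", "gorGor3", "ponAbe2",
                                           "nomLeu3", "rheMac3"),
                            allow_n = FALSE, block_index = NA_integer_) {
  stopifnot(inherits(block, "maf_block"), length(comparison) >= 1L)
  rows <- block$rows
  fi <- match(focal, rows$species)
  if (is.na(fi))
    stop("focal species '", focal, "' has no row in this block")
  if (!all(comparison %in% rows$species))
    return(empty_insertions())

  fchars <- strsplit(rows$text[fi], "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T", "a", "c", "g", "t")
  if (allow_n) bases <- c(bases, "N", "n")
  comp <- do.call(rbind, strsplit(rows$text[match(comparison, rows$species)],
                                  "", fixed = TRUE))
  supporting <- (fchars %in% bases) & (colSums(comp != "-") == 0L)
  if (!any(supporting)) return(empty_insertions())

  runs <- rle(supporting)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L
  ins_runs <- which(runs$values)

  nongap_before <- cumsum(fchars != "-")
  frow <- rows[fi, ]
  out <- lapply(ins_runs, function(k) {
    cs <- run_start[k]; ce <- run_end[k]
    len <- ce - cs + 1L
    before <- if (cs > 1L) nongap_before[cs - 1L] else 0L
    seq_txt <- toupper(paste(fchars[cs:ce], collapse = ""))
    s <- frow$start + before
    if (identical(frow$strand, "-")) {
      s_plus <- as.integer(frow$src_size - (s + len))
      seq_txt <- revcomp(seq_txt)
      s <- s_plus
    }
    data.frame(chrom = frow$chrom, start = as.integer(s),
               end = as.integer(s + len), length = len, sequence = seq_txt,
               touches_block_edge = cs == 1L || ce == block$ncol,
               block_index = block_index, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Call insertions across a set of alignment blocks
#'
#' Applies [call_insertions()] to every block, assigns serial identifiers
#' and removes duplicate calls with identical `(chrom, start, end)` — which
#' can arise when alignment blocks overlap — keeping the first occurrence.
#' The number of duplicates dropped is stored in the `"n_duplicates"`
#' attribute of the result.
#'
#' @inheritParams call_insertions
#' @param blocks list of [maf_block] objects.
#' @return data.frame of insertions with an `insertion_id` column.
#' @export
scan_insertions <- function(blocks, focal = "hg19",
                            comparison = c("panTro4", "gorGor3", "ponAbe2",
                                           "nomLeu3", "rheMac3"),
                            allow_n = FALSE) {
  calls <- lapply(seq_along(blocks), function(i)
    call_insertions(blocks[[i]], focal = focal, comparison = comparison,
                    allow_n = allow_n, block_index = i))
  ins <- do.call(rbind, c(list(empty_insertions()), calls))
  key <- paste(ins$chrom, ins$start, ins$end)
  dup <- duplicated(key)
  out <- ins[!dup, , drop = FALSE]
  out$insertion_id <- sprintf("INS%06d", seq_len(nrow(out)))
  rownames(out) <- NULL
  attr(out, "n_duplicates") <- sum(dup)
  out
}

#' Remove insertions shorter than a minimum length
#'
#' Short indels are both hard to place precisely in an alignment and
#' unlikely to carry novel regulatory motifs; the default keeps calls of
#' 10 nt and longer.
#'
#' @param insertions insertion data.frame.
#' @param min_length inclusive lower bound on `length` (default 10).
#' @return list with `kept` (order preserved) and `removed_count`.
#' @export
filter_by_length <- function(insertions, min_length = 10L) {
  stopifnot(min_length >= 1L)
  kept <- insertions[insertions$length >= min_length, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, removed_count = nrow(insertions) - nrow(kept))
}

#' Subtract known polymorphic indels
#'
#' An insertion is removed only on an *exact* match to a known polymorphic
#' indel: identical `(chrom, start, length)`, and identical sequence when
#' `match_sequence = TRUE`. Partial overlaps and smaller variants contained
#' inside an insertion — SNPs or internal indels indicative of mutational
#' events postdating the insertion — never cause removal. The survivors are
#' taken as fixed in the focal population.
#'
#' @param insertions insertion data.frame.
#' @param known data.frame of polymorphic indels with columns `chrom`,
#'   `start` (0-based), `length` and optionally `sequence`.
#' @param match_sequence logical; also require identical sequence.
#' @return list with `fixed` and `removed`, a partition of the input.
#' @export
subtract_polymorphic <- function(insertions, known, match_sequence = FALSE) {
  if (is.null(known) || !nrow(known)) {
    return(list(fixed = insertions, removed = insertions[0, , drop = FALSE]))
  }
  key_of <- function(d, with_seq) {
    k <- paste(d$chrom, d$start, d$length)
    if (with_seq) k <- paste(k, toupper(d$sequence))
    k
  }
  use_seq <- match_sequence
  if (use_seq && is.null(known$sequence))
    stop("match_sequence = TRUE but the known indel set has no sequence column")
  removed_mask <- key_of(insertions, use_seq) %in% key_of(known, use_seq)
  fixed <- insertions[!removed_mask, , drop = FALSE]
  removed <- insertions[removed_mask, , drop = FALSE]
  rownames(fixed) <- rownames(removed) <- NULL
  list(fixed = fixed, removed = removed)
}

#' Count variant positions falling inside insertions
#'
#' Counts `(chrom, pos)` pairs with `start <= pos < end` for at least one
#' insertion; a position inside several insertions counts once.
#'
#' @param insertions insertion data.frame.
#' @param snps data.frame with columns `chrom` and `pos` (0-based).
#' @return integer count.
#' @export
count_variants_in_insertions <- function(insertions, snps) {
  if (!nrow(insertions) || is.null(snps) || !nrow(snps)) return(0L)
  snp_gr <- GenomicRanges::GRanges(snps$chrom,
                                   IRanges::IRanges(snps$pos + 1L, width = 1L))
  sum(GenomicRanges::countOverlaps(snp_gr, insertions_gr(insertions)) > 0L)
}

# 0-based half-open data.frame -> GRanges (1-based closed)
insertions_gr <- function(d) {
  GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start + 1L, d$end))
}

intervals_gr <- function(d) {
  GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start + 1L, d$end))
}
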