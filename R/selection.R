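#' Score insertions against a windowed selection-statistic track
#'
#' The track carries one statistic (CLR or Fu's F as -log10 p) for one
#' population. An insertion's score is the maximum value over all windows
#' overlapping it — the conservative choice when an insertion spans several
#' windows (`agg = "mean"` averages instead). Insertions covered by no
#' window are *omitted*: on sparse tracks, absence of data is not evidence
#' against a sweep. An insertion is flagged when its score reaches the
#' threshold (`>=`, matching the -log10 p >= 2 sweep definition).
#'
#' @param insertions insertion data.frame (needs `insertion_id`).
#' @param track data.frame with `chrom`, `start`, `end`, `value` and
#'   constant `statistic` / `population` columns (or pass them as
#'   arguments).
#' @param threshold flagging threshold on the score (default 2).
#' @param statistic,population used when the track lacks those columns.
#' @param agg `"max"` (default) or `"mean"` aggregation over windows.
#' @return data.frame of sweep calls: `insertion_id`, `statistic`,
#'   `population`, `score`, `flagged`.
#' @export
score_insertions <- function(insertions, track, threshold = 2.0,
                             statistic = NULL, population = NULL,
                             agg = c("max", "mean")) {
  agg <- match.arg(agg)
  statistic <- statistic %||% unique(track$statistic)
  population <- population %||% unique(track$population)
  if (length(statistic) != 1L)
    stop("track mixes statistics: ", paste(statistic, collapse = ", "))
  if (length(population) != 1L)
    stop("track mixes populations: ", paste(population, collapse = ", "))
  if (!nrow(insertions) || !nrow(track))
    return(data.frame(insertion_id = character(0), statistic = character(0),
                      population = character(0), score = numeric(0),
                      flagged = logical(0), stringsAsFactors = FALSE))
  hits <- GenomicRanges::findOverlaps(insertions_gr(insertions),
                                      intervals_gr(track))
  qh <- S4Vectors::queryHits(hits)
  if (!length(qh))
    return(data.frame(insertion_id = character(0), statistic = character(0),
                      population = character(0), score = numeric(0),
                      flagged = logical(0), stringsAsFactors = FALSE))
  vals <- track$value[S4Vectors::subjectHits(hits)]
  fun <- if (agg == "max") max else mean
  score <- tapply(vals, qh, fun)
  idx <- as.integer(names(score))
  data.frame(insertion_id = insertions$insertion_id[idx],
             statistic = statistic, population = population,
             score = as.numeric(score),
             flagged = as.numeric(score) >= threshold,
             stringsAsFactors = FALSE)
}

#' Flag insertions by per-SNP |iHS|
#'
#' For every insertion and population with at least one scored SNP inside
#' the insertion (`start <= pos < end`), the score is the maximum absolute
#' iHS over those SNPs; the insertion is flagged when the score *exceeds*
#' the threshold (strict `>`, matching the |iHS| > 2.5 convention).
#' Insertion/population pairs with no SNP yield no call.
#'
#' @param insertions insertion data.frame (needs `insertion_id`).
#' @param snp_scores data.frame with `chrom`, `pos` (0-based), `value`
#'   (signed iHS), `population`.
#' @param threshold strict flagging threshold on |iHS| (default 2.5).
#' @return data.frame of sweep calls as in [score_insertions()], with
#'   `statistic = "iHS"`.
#' @export
ihs_flag <- function(insertions, snp_scores, threshold = 2.5) {
  out <- lapply(sort(unique(snp_scores$population)), function(pop) {
    snps <- snp_scores[snp_scores$population == pop, , drop = FALSE]
    snp_gr <- GenomicRanges::GRanges(snps$chrom,
                                     IRanges::IRanges(snps$pos + 1L, width = 1L))
    hits <- GenomicRanges::findOverlaps(insertions_gr(insertions), snp_gr)
    qh <- S4Vectors::queryHits(hits)
    if (!length(qh)) return(NULL)
    score <- tapply(abs(snps$value[S4Vectors::subjectHits(hits)]), qh, max)
    idx <- as.integer(names(score))
    data.frame(insertion_id = insertions$insertion_id[idx],
               statistic = "iHS", population = pop,
               score = as.numeric(score),
               flagged = as.numeric(score) > threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(insertion_id = character(0), statistic = character(0),
                      population = character(0), score = numeric(0),
                      flagged = logical(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Combine sweep flags across populations
#'
#' @param calls sweep-call data.frame ([score_insertions()] / [ihs_flag()]).
#' @param populations non-empty character vector of population labels.
#' @param mode `"all_of"`: insertions flagged in every named population;
#'   `"any_of"`: flagged in at least one.
#' @return sorted character vector of insertion ids.
#' @export
population_intersection <- function(calls, populations,
                                    mode = c("all_of", "any_of")) {
  mode <- match.arg(mode)
  stopifnot(length(populations) >= 1L)
  flagged <- calls[calls$flagged & calls$population %in% populations, ,
                   drop = FALSE]
  if (mode == "any_of") return(sort(unique(flagged$insertion_id)))
  per_pop <- lapply(populations, function(p)
    unique(flagged$insertion_id[flagged$population == p]))
  sort(Reduce(intersect, per_pop))
}
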