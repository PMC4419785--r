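resolve_input <- function(x, reader, ...) {
  if (is.character(x) && length(x) == 1L) reader(x, ...) else x
}

#' Run the end-to-end insertion funnel
#'
#' Executes the stages in order — insertion calling, length filter,
#' polymorphic subtraction, then (optionally) genic/repeat/regulatory
#' annotation, selective-sweep intersection and site-model LRTs — and
#' returns a funnel report whose conservation identities
#' (`n_total_called = n_removed_short + n_candidates`;
#' `n_candidates = n_polymorphic_removed + n_fixed`) are asserted, not
#' just reported.
#'
#' @param inputs named list. Each element may be an in-memory object or a
#'   file path (read with the matching reader): `maf` (list of blocks or
#'   MAF path; required), `polymorphic`, `genes`, `repeats`, `dnase`,
#'   `tfbs`, `clr` / `fusf` (named lists, one track or bedGraph path per
#'   population), `ihs`, `snps`, `lnl`.
#' @param focal,comparison species labels for calling.
#' @param min_length length-filter cutoff (default 10 nt).
#' @param clr_threshold CLR / Fu's F flagging threshold on -log10 p
#'   (default 2, inclusive).
#' @param ihs_threshold strict |iHS| threshold (default 2.5).
#' @param tss_distance regulatory-subset gene distance, bp (default 5000).
#' @param high_overlap repeat coverage threshold (default 0.8).
#' @param annotate,sweep,lrt_stage logical stage toggles.
#' @param allow_n treat focal `N` as insertion-supporting.
#' @param lrt_m Bonferroni test count for the LRT stage (defaults to the
#'   number of transcripts in the table).
#' @param out_dir optional directory for stage outputs (insertions BED,
#'   sweep-call and LRT TSVs).
#' @return a `funnel_report` list: counts per stage, genic gene counts per
#'   category, the repeat summary, sweep-call and LRT summaries, and the
#'   stage outputs themselves (`insertions`, `fixed`, `genic_calls`,
#'   `sweep_calls`, `lrt_results`).
#' @export
run_pipeline <- function(inputs,
                         focal = "hg19",
                         comparison = c("panTro4", "gorGor3", "ponAbe2",
                                        "nomLeu3", "rheMac3"),
                         min_length = 10L, clr_threshold = 2.0,
                         ihs_threshold = 2.5, tss_distance = 5000L,
                         high_overlap = 0.8,
                         annotate = TRUE, sweep = TRUE, lrt_stage = TRUE,
                         allow_n = FALSE, lrt_m = NULL, out_dir = NULL) {
  collect_paths <- function(x) {
    if (is.character(x)) return(x)
    if (is.list(x) && !is.data.frame(x))
      return(unlist(lapply(unclass(x), collect_paths), use.names = FALSE))
    character(0)
  }
  paths <- collect_paths(inputs)
  if (length(paths)) {
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop("missing input file(s): ", paste(missing, collapse = ", "))
  }
  if (is.null(inputs$maf)) stop("inputs$maf is required")

  blocks <- resolve_input(inputs$maf, read_maf)
  keep <- c(focal, comparison)
  blocks <- lapply(blocks, restrict_species, keep = keep)

  calls <- scan_insertions(blocks, focal = focal, comparison = comparison,
                           allow_n = allow_n)
  n_total_called <- nrow(calls)

  flt <- filter_by_length(calls, min_length = min_length)
  candidates <- flt$kept

  known <- resolve_input(inputs$polymorphic, read_polymorphic)
  sub <- subtract_polymorphic(candidates, known)
  fixed <- sub$fixed

  report <- list(
    n_total_called = n_total_called,
    n_duplicates_removed = attr(calls, "n_duplicates"),
    n_removed_short = flt$removed_count,
    n_candidates = nrow(candidates),
    n_polymorphic_removed = nrow(sub$removed),
    n_fixed = nrow(fixed),
    n_edge_flagged = sum(fixed$touches_block_edge),
    insertions = calls, fixed = fixed)
  stopifnot(report$n_total_called == report$n_removed_short + report$n_candidates,
            report$n_candidates == report$n_polymorphic_removed + report$n_fixed)

  if (!is.null(inputs$snps)) {
    snps <- resolve_input(inputs$snps, function(f)
      data.table::setDF(data.table::fread(f, header = TRUE)))
    report$n_snps_in_insertions <- count_variants_in_insertions(fixed, snps)
  }

  if (annotate && !is.null(inputs$genes)) {
    genes <- resolve_input(inputs$genes, read_gene_models)
    genic <- classify_genic(fixed, genes)
    real <- genic[genic$gene_id != ".", , drop = FALSE]
    per_gene <- if (nrow(real)) {
      rank <- match(real$category, GENIC_CATEGORIES)
      stats::aggregate(rank, by = list(gene_id = real$gene_id), FUN = max)
    } else data.frame(gene_id = character(0), x = integer(0))
    report$n_genes_with_insertions <- nrow(per_gene)
    report$genic_gene_counts <- table(
      factor(GENIC_CATEGORIES[per_gene$x],
             levels = c("CDS_exon", "UTR5", "UTR3", "intron")))
    report$genic_calls <- genic
    if (!is.null(inputs$repeats)) {
      repeats <- resolve_input(inputs$repeats, read_repeats)
      report$repeat_summary <- summarize_repeats(
        fixed, repeats, high_overlap_threshold = high_overlap)
    }
    if (!is.null(inputs$dnase) && !is.null(inputs$tfbs)) {
      dnase <- resolve_input(inputs$dnase, read_bed_intervals)
      tfbs <- resolve_input(inputs$tfbs, read_bed_intervals)
      reg <- regulatory_subset(fixed, dnase, tfbs, genes,
                               max_tss_distance = tss_distance)
      report$n_regulatory_subset <- nrow(reg)
      report$regulatory_subset <- reg
    }
  } else {
    report$genic_gene_counts <- NULL  # stage not run
  }

  if (sweep && (!is.null(inputs$clr) || !is.null(inputs$fusf) ||
                !is.null(inputs$ihs))) {
    sweep_calls <- list()
    for (stat in c("clr", "fusf")) {
      tracks <- inputs[[stat]]
      if (is.null(tracks)) next
      for (pop in names(tracks)) {
        trk <- resolve_input(tracks[[pop]], read_score_track,
                             statistic = toupper(stat), population = pop)
        sweep_calls[[paste(stat, pop)]] <-
          score_insertions(fixed, trk, threshold = clr_threshold)
      }
    }
    if (!is.null(inputs$ihs)) {
      ihs <- resolve_input(inputs$ihs, read_snp_scores)
      sweep_calls[["ihs"]] <- ihs_flag(fixed, ihs, threshold = ihs_threshold)
    }
    sweep_calls <- if (length(sweep_calls))
      do.call(rbind, c(sweep_calls, list(make.row.names = FALSE))) else NULL
    report$sweep_calls <- sweep_calls
    if (!is.null(sweep_calls) && nrow(sweep_calls))
      report$sweep_flag_counts <- stats::aggregate(
        flagged ~ statistic + population, data = sweep_calls, FUN = sum)
  }

  if (lrt_stage && !is.null(inputs$lnl)) {
    lnl <- resolve_input(inputs$lnl, read_lnl_table)
    m <- if (is.null(lrt_m)) nrow(lnl) else lrt_m
    res <- suppressWarnings(lrt_table(lnl, m = m))
    report$lrt_results <- res
    gene_key <- if (!is.null(res$gene_id)) res$gene_id else res$tx_id
    sig <- res$p_value < 0.05
    sig_adj <- res$p_adjusted < 0.05
    report$n_lrt_genes_significant <- length(unique(gene_key[sig]))
    report$n_lrt_genes_bonferroni <- length(unique(gene_key[sig_adj]))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_insertions_bed(fixed, file.path(out_dir, "fixed_insertions.bed"))
    if (!is.null(report$sweep_calls))
      data.table::fwrite(data.table::as.data.table(report$sweep_calls),
                         file.path(out_dir, "sweep_calls.tsv"),
                         sep = "\t", eol = "\n")
    if (!is.null(report$lrt_results))
      data.table::fwrite(data.table::as.data.table(report$lrt_results),
                         file.path(out_dir, "lrt_results.tsv"),
                         sep = "\t", eol = "\n")
  }
  class(report) <- "funnel_report"
  report
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("Insertion funnel\n")
  cat(sprintf("  called:               %d (%d duplicate calls dropped)\n",
              x$n_total_called, x$n_duplicates_removed))
  cat(sprintf("  removed (<min_length): %d\n", x$n_removed_short))
  cat(sprintf("  candidates:           %d\n", x$n_candidates))
  cat(sprintf("  polymorphic removed:  %d\n", x$n_polymorphic_removed))
  cat(sprintf("  fixed:                %d\n", x$n_fixed))
  if (!is.null(x$n_snps_in_insertions))
    cat(sprintf("  SNPs inside fixed insertions: %d\n", x$n_snps_in_insertions))
  if (!is.null(x$n_genes_with_insertions)) {
    cat(sprintf("  genes with insertions: %d\n", x$n_genes_with_insertions))
    print(x$genic_gene_counts)
  } else cat("  annotation stage: not run\n")
  if (!is.null(x$repeat_summary))
    cat(sprintf("  repeat overlap: %.1f%% (>=threshold coverage among those: %.1f%%)\n",
                100 * x$repeat_summary$any_repeat_fraction,
                100 * x$repeat_summary$high_overlap_fraction))
  if (!is.null(x$n_regulatory_subset))
    cat(sprintf("  strict regulatory subset: %d\n", x$n_regulatory_subset))
  if (!is.null(x$n_lrt_genes_significant))
    cat(sprintf("  LRT: %d gene(s) at p<0.05, %d after Bonferroni\n",
                x$n_lrt_genes_significant, x$n_lrt_genes_bonferroni))
  invisible(x)
}

#' Histogram of insertion lengths
#'
#' Half-open bins `[b, b + bin_width)` starting at 0; counts sum to the
#' number of insertions. Empty input yields an empty table.
#'
#' @param insertions insertion data.frame (or a numeric vector of lengths).
#' @param bin_width bin width in nt, default 50.
#' @return data.frame with `bin_start` and `count`.
#' @export
length_histogram <- function(insertions, bin_width = 50L) {
  stopifnot(bin_width >= 1L)
  lens <- if (is.numeric(insertions)) insertions else insertions$length
  if (!length(lens))
    return(data.frame(bin_start = integer(0), count = integer(0)))
  bin <- (lens %/% bin_width) * bin_width
  bins <- seq.int(min(bin), max(bin), by = bin_width)
  counts <- as.integer(table(factor(bin, levels = bins)))
  data.frame(bin_start = as.integer(bins), count = counts)
}
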