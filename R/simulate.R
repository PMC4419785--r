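#' Default insertion-length mixture
#'
#' Three components mirroring the empirical length spectrum of recent
#' human-specific insertions: a short-indel component (discrete power law
#' on 1–50 nt; the exponent 0.4228 places one third of its mass below
#' 10 nt, so with the default weights 30% of all planted lengths fall
#' under the 10-nt calling cutoff and about 86% of retained lengths lie
#' in 10–50 nt), an Alu-like SINE component uniform on 300–350 nt, and a
#' LINE1-like component around 6,000 nt.
#'
#' @return list of component definitions (`name`, `type`, parameters,
#'   `weight`); weights sum to 1.
#' @export
default_length_mixture <- function() {
  list(
    list(name = "short", type = "powerlaw", min = 1L, max = 50L,
         alpha = 0.4228, weight = 0.90),
    list(name = "alu", type = "uniform", min = 300L, max = 350L,
         weight = 0.08),
    list(name = "line", type = "normal", mean = 6000, sd = 150,
         min = 5500L, max = 6500L, weight = 0.02))
}

#' Probability that a mixture draw falls in `[lo, hi]`
#'
#' Exact for the discrete components; the (clipped) normal component is
#' handled through its discretized support.
#'
#' @param mixture a length mixture (see [default_length_mixture()]).
#' @param lo,hi inclusive integer bounds.
#' @return probability.
#' @export
mixture_length_prob <- function(mixture, lo, hi) {
  sum(vapply(mixture, function(cmp) {
    sup <- cmp$min:cmp$max
    w <- switch(cmp$type,
                powerlaw = sup^(-cmp$alpha),
                uniform = rep(1, length(sup)),
                normal = {
                  p <- stats::dnorm(sup, cmp$mean, cmp$sd)
                  # mass clipped onto the bounds
                  p[1] <- p[1] + stats::pnorm(cmp$min - 0.5, cmp$mean, cmp$sd)
                  p[length(p)] <- p[length(p)] +
                    stats::pnorm(cmp$max + 0.5, cmp$mean, cmp$sd,
                                 lower.tail = FALSE)
                  p
                },
                stop("unknown mixture component type: ", cmp$type))
    cmp$weight * sum(w[sup >= lo & sup <= hi]) / sum(w)
  }, numeric(1)))
}

sample_mixture_lengths <- function(n, mixture) {
  weights <- vapply(mixture, `[[`, numeric(1), "weight")
  comp <- sample.int(length(mixture), n, replace = TRUE, prob = weights)
  out <- integer(n)
  for (k in seq_along(mixture)) {
    idx <- which(comp == k)
    if (!length(idx)) next
    cmp <- mixture[[k]]
    out[idx] <- switch(cmp$type,
      powerlaw = {
        sup <- cmp$min:cmp$max
        sample(sup, length(idx), replace = TRUE, prob = sup^(-cmp$alpha))
      },
      uniform = sample(cmp$min:cmp$max, length(idx), replace = TRUE),
      normal = pmin(cmp$max, pmax(cmp$min,
        as.integer(round(stats::rnorm(length(idx), cmp$mean, cmp$sd))))))
  }
  out
}

#' Simulation configuration
#'
#' Declares every knob of the planted-truth generator. Defaults emulate
#' the study conditions: six-species primate alignment blocks with one
#' planted human-specific insertion per block, a Fig.-1-shaped length
#' mixture, 15% of planted insertions polymorphic, 10% of blocks missing
#' one comparison species (making their insertion undetectable under the
#' explicit-evidence rule), repeat/gene/regulatory/selection annotations
#' with known planting probabilities, and a site-model log-likelihood
#' table with a planted positively-selected subset.
#'
#' @param seed integer driving a single RNG stream for all outputs.
#' @param n_blocks number of alignment blocks.
#' @param block_length ancestral length of each block, bp.
#' @param n_insertions number of planted insertions (at most one per
#'   block; defaults to `n_blocks`).
#' @param length_mixture see [default_length_mixture()].
#' @param polymorphic_fraction share of planted insertions emitted into
#'   the known polymorphic-indel file.
#' @param missing_species_fraction share of blocks lacking one comparison
#'   species row.
#' @param substitution_rate per-site substitution rate applied
#'   independently to each comparison lineage.
#' @param focal,comparison,chrom species labels and focal chromosome name.
#' @param repeat_overlap_fraction probability an insertion is planted
#'   inside a repeat element.
#' @param repeat_class_probs named class probabilities (sum to 1) for the
#'   planted element.
#' @param high_coverage_fraction probability a planted repeat element
#'   covers the insertion fully rather than partially.
#' @param gene_context_probs named probabilities over
#'   CDS_exon/UTR5/UTR3/intron/intergenic (sum to 1).
#' @param populations population labels for the selection tracks.
#' @param sweep_prob per-population probability an insertion is planted
#'   inside a swept (high-score) region.
#' @param snp_density per-bp SNP rate inside insertions (and background).
#' @param dnase_prob,tfbs_prob probabilities an insertion is covered by a
#'   planted DNase / TF-ChIP interval.
#' @param selected_fraction share of CDS-insertion transcripts simulated
#'   under positive selection in the log-likelihood table.
#' @param score_window window size of the score tracks, bp.
#' @return a `simulation_config` list, validated.
#' @export
simulation_config <- function(seed = 1L, n_blocks = 500L,
                              block_length = 10000L,
                              n_insertions = n_blocks,
                              length_mixture = default_length_mixture(),
                              polymorphic_fraction = 0.15,
                              missing_species_fraction = 0.10,
                              substitution_rate = 0.01,
                              focal = "hg19",
                              comparison = c("panTro4", "gorGor3", "ponAbe2",
                                             "nomLeu3", "rheMac3"),
                              chrom = "chr1",
                              repeat_overlap_fraction = 0.7,
                              repeat_class_probs = c(SINE = 0.35, LINE = 0.20,
                                                     LTR = 0.10, DNA = 0.07,
                                                     Simple_repeat = 0.20,
                                                     Low_complexity = 0.08),
                              high_coverage_fraction = 0.93,
                              gene_context_probs = c(CDS_exon = 0.05,
                                                     UTR5 = 0.02, UTR3 = 0.03,
                                                     intron = 0.25,
                                                     intergenic = 0.65),
                              populations = c("CEU", "CHB", "YRI"),
                              sweep_prob = 0.05,
                              snp_density = 0.006,
                              dnase_prob = 0.3, tfbs_prob = 0.3,
                              selected_fraction = 0.1,
                              score_window = 2000L) {
  cfg <- as.list(environment())
  w <- sum(vapply(length_mixture, `[[`, numeric(1), "weight"))
  if (abs(w - 1) > 1e-8) stop("length mixture weights must sum to 1")
  fracs <- c(polymorphic_fraction, missing_species_fraction,
             substitution_rate, repeat_overlap_fraction,
             high_coverage_fraction, sweep_prob, dnase_prob, tfbs_prob,
             selected_fraction)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (abs(sum(repeat_class_probs) - 1) > 1e-8)
    stop("repeat_class_probs must sum to 1")
  if (abs(sum(gene_context_probs) - 1) > 1e-8)
    stop("gene_context_probs must sum to 1")
  if (n_insertions > n_blocks)
    stop("at most one planted insertion per block: n_insertions <= n_blocks")
  max_len <- max(vapply(length_mixture, function(cmp) as.numeric(cmp$max),
                        numeric(1)))
  if (max_len > block_length)
    stop("infeasible planting: an insertion of length ", max_len,
         " cannot fit in a block of ", block_length, " bp")
  if (block_length < 2L * sim_margin() + 1L)
    stop("block_length too small to plant away from block edges")
  structure(cfg, class = "simulation_config")
}

sim_margin <- function() 1200L  # clearance (bp) of insertions from block edges

random_dna <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

substitute_sites <- function(chars, rate) {
  hit <- which(stats::runif(length(chars)) < rate)
  if (length(hit)) {
    shift <- sample.int(3L, length(hit), replace = TRUE)
    bases <- c("A", "C", "G", "T")
    chars[hit] <- bases[(match(chars[hit], bases) - 1L + shift) %% 4L + 1L]
  }
  chars
}

# gene constructed around a planted insertion so its genic category is the
# requested one; geometry stays well inside the block (see sim_margin)
make_planted_gene <- function(context, s, e, strand, gene_id) {
  tx <- switch(context,
    CDS_exon = list(tx_start = s - 600L, tx_end = e + 600L,
                    cds_start = s - 300L, cds_end = e + 300L,
                    exon_starts = s - 600L, exon_ends = e + 600L),
    UTR5 = if (strand == "+")
      list(tx_start = s - 200L, tx_end = e + 800L,
           cds_start = e + 100L, cds_end = e + 600L,
           exon_starts = s - 200L, exon_ends = e + 800L)
    else
      list(tx_start = s - 800L, tx_end = e + 200L,
           cds_start = s - 600L, cds_end = s - 100L,
           exon_starts = s - 800L, exon_ends = e + 200L),
    UTR3 = if (strand == "+")
      list(tx_start = s - 800L, tx_end = e + 200L,
           cds_start = s - 600L, cds_end = s - 100L,
           exon_starts = s - 800L, exon_ends = e + 200L)
    else
      list(tx_start = s - 200L, tx_end = e + 800L,
           cds_start = e + 100L, cds_end = e + 600L,
           exon_starts = s - 200L, exon_ends = e + 800L),
    intron = list(tx_start = s - 700L, tx_end = e + 700L,
                  cds_start = s - 650L, cds_end = e + 650L,
                  exon_starts = c(s - 700L, e + 500L),
                  exon_ends = c(s - 500L, e + 700L)),
    return(NULL))
  data.frame(gene_id = gene_id, tx_id = paste0(gene_id, ".1"),
             chrom = NA_character_, strand = strand,
             tx_start = tx$tx_start, tx_end = tx$tx_end,
             cds_start = tx$cds_start, cds_end = tx$cds_end,
             exon_starts = paste(tx$exon_starts, collapse = ","),
             exon_ends = paste(tx$exon_ends, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Generate a planted-truth synthetic data set
#'
#' Produces coordinate-consistent synthetic inputs for every pipeline
#' stage: alignment blocks in which each planted insertion appears as a
#' run of focal bases against explicit gaps in all comparison rows, the
#' polymorphic subset as a known-indel file, gene models realizing each
#' insertion's planted genic context, repeat/DNase/TF-ChIP intervals,
#' windowed CLR and Fu's F tracks and per-SNP iHS values with planted
#' sweep regions, a site-model log-likelihood table, and the ground-truth
#' manifest recording every planted insertion's intended fate. The same
#' seed yields byte-identical files.
#'
#' @param config a [simulation_config()].
#' @param out_dir optional directory; when given, all outputs are written
#'   there (`alignment.maf`, `polymorphic.tsv`, `polymorphic.vcf`,
#'   `genes.genePred`, `repeats.tsv`, `dnase.bed`, `tfbs.bed`,
#'   `clr_<pop>.bedgraph`, `fusf_<pop>.bedgraph`, `ihs.tsv`, `snps.tsv`,
#'   `lnl.tsv`, `truth.tsv`).
#' @param alignment logical; set `FALSE` to skip sequence realization and
#'   return only coordinates, annotations and the manifest (fast mode for
#'   large calibration runs).
#' @return list with elements `blocks`, `truth`, `polymorphic`, `genes`,
#'   `repeats`, `dnase`, `tfbs`, `clr`, `fusf` (named lists of tracks per
#'   population), `ihs`, `snps`, `lnl`, `selection_truth`, `config`,
#'   `files` (when written).
#' @export
simulate_dataset <- function(config, out_dir = NULL, alignment = TRUE) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n_blocks <- config$n_blocks
  L <- config$block_length
  n_ins <- config$n_insertions

  # ---- truth planting -------------------------------------------------
  has_ins <- seq_len(n_blocks) <= n_ins
  lengths <- sample_mixture_lengths(n_ins, config$length_mixture)
  pos_anc <- vapply(seq_len(n_ins), function(i)
    sample(seq.int(sim_margin(), L - sim_margin()), 1L), integer(1))
  missing_species <- stats::runif(n_blocks) < config$missing_species_fraction
  which_missing <- ifelse(missing_species,
                          sample(config$comparison, n_blocks, replace = TRUE),
                          NA_character_)
  is_polymorphic <- stats::runif(n_ins) < config$polymorphic_fraction
  has_repeat <- stats::runif(n_ins) < config$repeat_overlap_fraction
  repeat_class <- ifelse(has_repeat,
                         sample(names(config$repeat_class_probs), n_ins,
                                replace = TRUE,
                                prob = config$repeat_class_probs),
                         NA_character_)
  high_cov <- stats::runif(n_ins) < config$high_coverage_fraction
  gene_context <- sample(names(config$gene_context_probs), n_ins,
                         replace = TRUE, prob = config$gene_context_probs)
  sweep <- matrix(stats::runif(n_ins * length(config$populations)) <
                    config$sweep_prob,
                  nrow = n_ins,
                  dimnames = list(NULL, config$populations))
  has_dnase <- stats::runif(n_ins) < config$dnase_prob
  has_tfbs <- stats::runif(n_ins) < config$tfbs_prob
  sequences <- vapply(lengths, function(l)
    paste(random_dna(l), collapse = ""), character(1))

  # focal-genome coordinates: blocks are laid out consecutively
  ins_len_per_block <- ifelse(has_ins, c(lengths, rep(0L, n_blocks - n_ins)), 0L)
  block_focal_start <- cumsum(c(0, head(L + ins_len_per_block, -1)))
  block_anc_start <- (seq_len(n_blocks) - 1L) * L
  ins_start <- block_focal_start[seq_len(n_ins)] + pos_anc
  ins_end <- ins_start + lengths
  focal_genome_len <- n_blocks * L + sum(lengths)

  truth <- data.frame(
    ins_id = sprintf("T%05d", seq_len(n_ins)),
    chrom = config$chrom, start = as.integer(ins_start),
    end = as.integer(ins_end), length = lengths, sequence = sequences,
    is_polymorphic = is_polymorphic,
    planted_repeat_class = repeat_class,
    planted_high_coverage = has_repeat & high_cov,
    planted_gene_context = gene_context,
    planted_dnase = has_dnase, planted_tfbs = has_tfbs,
    in_block_with_missing_species = missing_species[seq_len(n_ins)],
    detectable = !missing_species[seq_len(n_ins)],
    block_index = seq_len(n_ins), stringsAsFactors = FALSE)
  for (pop in config$populations)
    truth[[paste0("sweep_", pop)]] <- sweep[, pop]

  # ---- annotations ----------------------------------------------------
  gene_strand <- sample(c("+", "-"), n_ins, replace = TRUE)
  genes <- do.call(rbind, lapply(seq_len(n_ins), function(i) {
    g <- make_planted_gene(gene_context[i], truth$start[i], truth$end[i],
                           gene_strand[i], sprintf("G%05d", i))
    if (!is.null(g)) g$chrom <- config$chrom
    g
  }))
  if (is.null(genes)) genes <- make_planted_gene("intron", 2000L, 2010L, "+", "G00000")[0, ]

  repeats <- do.call(rbind, lapply(seq_len(n_ins), function(i) {
    rows <- list()
    s <- truth$start[i]; e <- truth$end[i]; len <- truth$length[i]
    if (has_repeat[i]) {
      if (high_cov[i]) {
        rs <- s - sample(10:80, 1L); re <- e + sample(10:80, 1L)
      } else {
        cov <- max(1L, as.integer(floor(len * stats::runif(1, 0.2, 0.6))))
        rs <- s; re <- s + cov
      }
      rows <- c(rows, list(data.frame(
        chrom = config$chrom, start = rs, end = re,
        repeat_class = repeat_class[i],
        repeat_name = paste0(repeat_class[i], "_p", i),
        stringsAsFactors = FALSE)))
    }
    # background elements, confined to this block and clear of the insertion
    b0 <- block_focal_start[i]
    bg_start <- b0 + sample(50:(sim_margin() - 300L), 2L)
    bg_class <- sample(names(config$repeat_class_probs), 2L, replace = TRUE,
                       prob = config$repeat_class_probs)
    rows <- c(rows, list(data.frame(
      chrom = config$chrom, start = bg_start,
      end = bg_start + sample(80:250, 2L, replace = TRUE),
      repeat_class = bg_class,
      repeat_name = paste0(bg_class, "_b", i), stringsAsFactors = FALSE)))
    do.call(rbind, rows)
  }))

  make_reg <- function(flag) {
    do.call(rbind, lapply(seq_len(n_ins), function(i) {
      s <- truth$start[i]; e <- truth$end[i]
      b0 <- block_focal_start[i]
      bg <- b0 + sample(50:(sim_margin() - 300L), 1L)
      rows <- data.frame(chrom = config$chrom, start = bg, end = bg + 150L,
                         stringsAsFactors = FALSE)
      if (flag[i])
        rows <- rbind(rows, data.frame(chrom = config$chrom,
                                       start = s - 50L, end = e + 50L,
                                       stringsAsFactors = FALSE))
      rows
    }))
  }
  dnase <- make_reg(has_dnase)
  tfbs <- make_reg(has_tfbs)

  # windowed score tracks: background below threshold, swept windows above
  window_track <- function(pop, flagged) {
    do.call(rbind, lapply(seq_len(n_blocks), function(b) {
      b0 <- block_focal_start[b]
      b_end <- b0 + L + ins_len_per_block[b]
      starts <- seq.int(b0, b_end - 1L, by = config$score_window)
      ends <- pmin(starts + config$score_window, b_end)
      value <- stats::runif(length(starts), 0, 1.5)
      if (b <= n_ins && flagged[b]) {
        hit <- starts < truth$end[b] & ends > truth$start[b]
        value[hit] <- stats::runif(sum(hit), 2.2, 4.0)
      }
      data.frame(chrom = config$chrom, start = starts, end = ends,
                 value = value, stringsAsFactors = FALSE)
    }))
  }
  clr <- list(); fusf <- list()
  for (pop in config$populations) {
    t1 <- window_track(pop, sweep[, pop])
    t1$statistic <- "CLR"; t1$population <- pop
    clr[[pop]] <- t1
    t2 <- window_track(pop, sweep[, pop])
    t2$statistic <- "FusF"; t2$population <- pop
    fusf[[pop]] <- t2
  }

  # SNPs: shared positions, per-population iHS values; background values
  # truncated below the flagging threshold, swept insertions get one
  # guaranteed extreme SNP
  snp_rows <- lapply(seq_len(n_ins), function(i) {
    n_snp <- stats::rpois(1L, truth$length[i] * config$snp_density)
    if (any(sweep[i, ])) n_snp <- max(1L, n_snp)
    if (!n_snp) return(NULL)
    support <- seq.int(truth$start[i], truth$end[i] - 1L)
    pos <- sort(support[sample.int(length(support),
                                   min(n_snp, truth$length[i]))])
    data.frame(ins = i, chrom = config$chrom, pos = pos,
               stringsAsFactors = FALSE)
  })
  snp_rows <- do.call(rbind, snp_rows)
  # which insertion (if any) covers a focal position, via the sorted block
  # layout: blocks are consecutive and hold at most one insertion each
  insertion_of <- function(pos) {
    blk <- findInterval(pos, block_focal_start)
    ok <- blk >= 1L & blk <= n_ins
    ok[ok] <- pos[ok] >= ins_start[blk[ok]] & pos[ok] < ins_end[blk[ok]]
    ifelse(ok, blk, NA_integer_)
  }
  bg_pos <- sort(sample.int(focal_genome_len,
                            as.integer(n_blocks * L * config$snp_density / 4)))
  bg_pos <- bg_pos[is.na(insertion_of(bg_pos))]
  snps <- rbind(snp_rows[, c("chrom", "pos")],
                data.frame(chrom = config$chrom, pos = bg_pos,
                           stringsAsFactors = FALSE))
  snps <- snps[order(snps$pos), , drop = FALSE]
  rownames(snps) <- NULL

  trunc_norm <- function(n) pmin(2.4, pmax(-2.4, stats::rnorm(n)))
  snp_ins <- insertion_of(snps$pos)
  ihs <- do.call(rbind, lapply(config$populations, function(pop) {
    d <- data.frame(chrom = snps$chrom, pos = snps$pos,
                    value = trunc_norm(nrow(snps)), population = pop,
                    stringsAsFactors = FALSE)
    swept <- which(sweep[, pop])
    if (length(swept)) {
      pick <- match(swept, snp_ins)  # every swept insertion holds >= 1 SNP
      d$value[pick] <- sample(c(-1, 1), length(pick), replace = TRUE) *
        stats::runif(length(pick), 2.6, 3.5)
    }
    d
  }))

  # site-model log-likelihood table for CDS-insertion transcripts
  cds_idx <- which(gene_context == "CDS_exon")
  sel <- stats::runif(length(cds_idx)) < config$selected_fraction
  base_lnl <- stats::runif(length(cds_idx), -8000, -2000)
  d12 <- ifelse(sel, stats::runif(length(cds_idx), 15, 40),
                stats::rchisq(length(cds_idx), 2L))
  d78 <- ifelse(sel, stats::runif(length(cds_idx), 15, 40),
                stats::rchisq(length(cds_idx), 2L))
  lnl <- data.frame(tx_id = sprintf("G%05d.1", cds_idx),
                    gene_id = sprintf("G%05d", cds_idx),
                    lnL_M1a = base_lnl, lnL_M2a = base_lnl + d12 / 2,
                    lnL_M7 = base_lnl - stats::runif(length(cds_idx), 0, 5),
                    lnL_M8 = rep(NA_real_, length(cds_idx)),
                    stringsAsFactors = FALSE)
  lnl$lnL_M8 <- lnl$lnL_M7 + d78 / 2
  selection_truth <- data.frame(tx_id = lnl$tx_id, gene_id = lnl$gene_id,
                                selected = sel, stringsAsFactors = FALSE)

  polymorphic <- truth[truth$is_polymorphic,
                       c("chrom", "start", "length", "sequence")]
  rownames(polymorphic) <- NULL

  # ---- alignment realization -----------------------------------------
  blocks <- NULL
  if (alignment) {
    comp_src_size <- n_blocks * L
    blocks <- lapply(seq_len(n_blocks), function(b) {
      anc <- random_dna(L)
      if (b <= n_ins) {
        p <- pos_anc[b]
        focal_chars <- c(anc[seq_len(p)],
                         strsplit(sequences[b], "", fixed = TRUE)[[1]],
                         anc[seq.int(p + 1L, L)])
        gap_at <- p
        gap_len <- lengths[b]
      } else {
        focal_chars <- anc
        gap_at <- NULL
      }
      comp_species <- config$comparison
      if (missing_species[b])
        comp_species <- setdiff(comp_species, which_missing[b])
      comp_texts <- vapply(comp_species, function(sp) {
        cc <- substitute_sites(anc, config$substitution_rate)
        if (!is.null(gap_at))
          cc <- c(cc[seq_len(gap_at)], rep("-", gap_len),
                  cc[seq.int(gap_at + 1L, L)])
        paste(cc, collapse = "")
      }, character(1))
      rows <- rbind(
        data.frame(species = config$focal, chrom = config$chrom,
                   start = block_focal_start[b],
                   size = length(focal_chars), strand = "+",
                   src_size = focal_genome_len,
                   text = paste(focal_chars, collapse = ""),
                   stringsAsFactors = FALSE),
        data.frame(species = comp_species, chrom = config$chrom,
                   start = block_anc_start[b], size = L, strand = "+",
                   src_size = comp_src_size, text = unname(comp_texts),
                   stringsAsFactors = FALSE))
      maf_block(rows)
    })
  }

  out <- list(blocks = blocks, truth = truth, polymorphic = polymorphic,
              genes = genes, repeats = repeats, dnase = dnase, tfbs = tfbs,
              clr = clr, fusf = fusf, ihs = ihs, snps = snps, lnl = lnl,
              selection_truth = selection_truth, config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(x) file.path(out_dir, x)
    files <- c(polymorphic = fp("polymorphic.tsv"),
               polymorphic_vcf = fp("polymorphic.vcf"),
               genes = fp("genes.genePred"), repeats = fp("repeats.tsv"),
               dnase = fp("dnase.bed"), tfbs = fp("tfbs.bed"),
               ihs = fp("ihs.tsv"), snps = fp("snps.tsv"),
               lnl = fp("lnl.tsv"), truth = fp("truth.tsv"))
    if (alignment) {
      files["maf"] <- fp("alignment.maf")
      write_maf(blocks, files["maf"])
    }
    write_polymorphic_tsv(polymorphic, files["polymorphic"])
    # anchor base precedes each insertion on the focal genome ('N' in fast
    # mode where no sequence is realized)
    anchors <- rep("N", nrow(polymorphic))
    if (alignment && nrow(polymorphic)) {
      pg <- vapply(seq_len(nrow(polymorphic)), function(j) {
        b <- truth$block_index[truth$is_polymorphic][j]
        frow <- blocks[[b]]$rows
        txt <- frow$text[frow$species == config$focal]
        substr(txt, pos_anc[b], pos_anc[b])
      }, character(1))
      anchors <- pg
    }
    write_polymorphic_vcf(polymorphic, anchors, files["polymorphic_vcf"])
    write_gene_models(genes, files["genes"])
    write_repeats(repeats, files["repeats"])
    write_bed3(dnase, files["dnase"])
    write_bed3(tfbs, files["tfbs"])
    for (pop in config$populations) {
      files[paste0("clr_", pop)] <- fp(paste0("clr_", pop, ".bedgraph"))
      files[paste0("fusf_", pop)] <- fp(paste0("fusf_", pop, ".bedgraph"))
      write_score_track(clr[[pop]], files[paste0("clr_", pop)])
      write_score_track(fusf[[pop]], files[paste0("fusf_", pop)])
    }
    data.table::fwrite(data.table::as.data.table(snps), files["snps"],
                       sep = "\t", eol = "\n")
    write_snp_scores(ihs, files["ihs"])
    write_lnl_table(lnl, files["lnl"])
    write_truth_manifest(truth, files["truth"])
    out$files <- files
  }
  out
}

#' Expected funnel counts from the ground-truth manifest
#'
#' The oracle the pipeline output is compared against: detectable planted
#' insertions (blocks with all comparison species present), those passing
#' the length filter, and those additionally absent from the polymorphic
#' set.
#'
#' @param truth manifest data.frame from [simulate_dataset()].
#' @param min_length length-filter cutoff (default 10).
#' @return list with `n_called`, `n_after_length`, `n_fixed`.
#' @export
expected_funnel <- function(truth, min_length = 10L) {
  det <- truth$detectable
  long_enough <- det & truth$length >= min_length
  list(n_called = sum(det),
       n_after_length = sum(long_enough),
       n_fixed = sum(long_enough & !truth$is_polymorphic))
}
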