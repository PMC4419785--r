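#' Alignment block container
#'
#' A `maf_block` holds one alignment block: a data frame of per-species rows
#' (`species`, `chrom`, `start`, `size`, `strand`, `src_size`, `text`) plus
#' the shared column count. Coordinates follow the MAF convention: `start` is
#' 0-based on the source strand, `size` counts non-gap characters and
#' `src_size` is the chromosome length. Soft-masking case is preserved in
#' `text` but carries no meaning downstream.
#'
#' @param rows data.frame with the columns listed above, one row per species.
#' @return An object of class `maf_block`.
#' @export
maf_block <- function(rows) {
  required <- c("species", "chrom", "start", "size", "strand", "src_size", "text")
  stopifnot(is.data.frame(rows), all(required %in% names(rows)))
  rows <- as.data.frame(rows)[required]
  rows$start <- as.integer(rows$start)
  rows$size <- as.integer(rows$size)
  rows$src_size <- as.double(rows$src_size)
  if (anyDuplicated(rows$species))
    stop("duplicate species in alignment block: ",
         paste(rows$species[duplicated(rows$species)], collapse = ", "))
  ncols <- unique(nchar(rows$text))
  if (length(ncols) > 1)
    stop("rows of one block differ in column count")
  nongap <- nchar(gsub("-", "", rows$text, fixed = TRUE))
  bad <- which(nongap != rows$size)
  if (length(bad))
    stop("size field does not match non-gap character count for species ",
         paste(rows$species[bad], collapse = ", "))
  over <- which(rows$start + rows$size > rows$src_size)
  if (length(over))
    stop("start + size exceeds src_size for species ",
         paste(rows$species[over], collapse = ", "))
  structure(list(rows = rows, ncol = if (length(ncols)) ncols else 0L),
            class = "maf_block")
}

#' @export
print.maf_block <- function(x, ...) {
  cat("maf_block:", nrow(x$rows), "species,", x$ncol, "columns\n")
  invisible(x)
}

parse_s_line <- function(line, lineno) {
  fields <- strsplit(trimws(line), "[ \t]+")[[1]]
  if (length(fields) != 7L)
    stop("malformed s-line at line ", lineno, ": expected 7 fields, found ",
         length(fields), call. = FALSE)
  src <- fields[2]
  dot <- regexpr(".", src, fixed = TRUE)
  if (dot > 0) {
    species <- substr(src, 1L, dot - 1L)
    chrom <- substr(src, dot + 1L, nchar(src))
  } else {
    species <- src
    chrom <- src
  }
  size <- suppressWarnings(as.integer(fields[4]))
  text <- fields[7]
  if (is.na(size) || nchar(gsub("-", "", text, fixed = TRUE)) != size)
    stop("malformed s-line at line ", lineno,
         ": size field does not match non-gap character count", call. = FALSE)
  data.frame(species = species, chrom = chrom,
             start = as.integer(fields[3]), size = size,
             strand = fields[5], src_size = as.double(fields[6]),
             text = text, stringsAsFactors = FALSE)
}

#' Read a MAF alignment file
#'
#' Parses UCSC-dialect MAF: `a`-lines open blocks, `s`-lines carry sequences;
#' `i`/`e`/`q` and comment lines are tolerated and ignored. The species label
#' of a row is the MAF `src` prefix before the first `.` (e.g. `hg19.chr1`
#' gives species `hg19`, chromosome `chr1`).
#'
#' @param file path to a MAF file (or a character vector of lines).
#' @return list of [maf_block] objects, in file order. An empty file yields
#'   an empty list.
#' @export
read_maf <- function(file) {
  lines <- if (length(file) == 1L && file.exists(file)) readLines(file) else file
  blocks <- list()
  cur <- NULL
  flush_block <- function() {
    if (!is.null(cur) && nrow(cur)) blocks[[length(blocks) + 1L]] <<- maf_block(cur)
    cur <<- NULL
  }
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line))) { flush_block(); next }
    first <- substr(trimws(line), 1L, 1L)
    if (first == "a") {
      flush_block()
      cur <- data.frame()
    } else if (first == "s") {
      if (is.null(cur)) stop("s-line outside of a block at line ", i, call. = FALSE)
      cur <- rbind(cur, parse_s_line(line, i))
    }
    # '#', 'i', 'e', 'q', track lines: ignored
  }
  flush_block()
  blocks
}

#' Write alignment blocks as MAF
#'
#' @param blocks list of [maf_block] objects.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_maf <- function(blocks, file) {
  con <- file(file, open = "wb")
  on.exit(close(con))
  writeLines("##maf version=1", con, sep = "\n")
  writeLines("", con)
  for (b in blocks) {
    writeLines("a score=0.000000", con)
    r <- b$rows
    writeLines(sprintf("s %s.%s %d %d %s %.0f %s",
                       r$species, r$chrom, r$start, r$size, r$strand,
                       r$src_size, r$text), con)
    writeLines("", con)
  }
  invisible(file)
}

#' Restrict an alignment block to a set of species
#'
#' Keeps only rows whose species is in `keep` and deletes columns that are
#' gaps in every retained row. Coordinates of retained rows are unchanged
#' (column deletion never removes a non-gap character). Species absent from
#' the block are silently absent from the output.
#'
#' @param block a [maf_block].
#' @param keep non-empty character vector of species labels.
#' @return a [maf_block] with at most `length(keep)` rows.
#' @export
restrict_species <- function(block, keep) {
  stopifnot(inherits(block, "maf_block"), length(keep) >= 1L)
  rows <- block$rows[block$rows$species %in% keep, , drop = FALSE]
  if (!nrow(rows)) {
    rows$text <- character(0)
    return(structure(list(rows = rows, ncol = 0L), class = "maf_block"))
  }
  chars <- do.call(rbind, strsplit(rows$text, "", fixed = TRUE))
  keep_col <- colSums(chars != "-") > 0L
  rows$text <- apply(chars[, keep_col, drop = FALSE], 1L,
                     paste, collapse = "")
  maf_block(rows)
}
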