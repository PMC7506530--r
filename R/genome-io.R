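#' Read a genome from a FASTA file
#'
#' Reads a multi-record FASTA file into a named [Biostrings::DNAStringSet].
#' Sequences are uppercased and any character outside \{A,C,G,T,N\} (IUPAC
#' ambiguity codes, gaps) is mapped to N, so downstream composition scans see
#' a five-letter alphabet only.
#'
#' @param path Path to a FASTA file.
#' @return A `DNAStringSet`, one element per record, named by the first
#'   whitespace-delimited token of each header.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) {
    stop("empty FASTA file (no records): ", path, " at line 1")
  }
  if (!startsWith(first, ">")) {
    stop("malformed FASTA header: ", path, " at line 1 (expected '>')")
  }
  seqs <- Biostrings::readBStringSet(path)
  clean <- toupper(as.character(seqs))
  clean <- gsub("[^ACGTN]", "N", clean)
  out <- Biostrings::DNAStringSet(clean)
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Write a genome to a FASTA file
#'
#' @param genome A named `DNAStringSet` or named character vector.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  genome <- as_genome(genome)
  Biostrings::writeXStringSet(genome, path, width = width)
  invisible(path)
}

# Normalise genome input to a named DNAStringSet.
as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    return(genome)
  }
  if (methods::is(genome, "DNAString")) {
    out <- Biostrings::DNAStringSet(genome)
    names(out) <- "chr"
    return(out)
  }
  if (is.character(genome)) {
    if (is.null(names(genome))) {
      names(genome) <- paste0("chr", seq_along(genome))
    }
    return(Biostrings::DNAStringSet(toupper(genome)))
  }
  stop("cannot interpret object of class ", class(genome)[1L], " as a genome")
}

#' Read genomic intervals from a BED-family file
#'
#' Intervals use the BED convention throughout the package: 0-based start,
#' exclusive end. Output is sorted by (chrom, start); the strand column is
#' `"."` when the dialect does not carry one.
#'
#' @param path Path to a tab-delimited file.
#' @param dialect One of `"BED3"`, `"BED6"`, `"bedGraph"`.
#' @return A data.frame with columns `chrom`, `start`, `end`, `strand`, and
#'   `score` (the bedGraph value or the BED score; `NA` for BED3).
#' @export
read_intervals <- function(path, dialect = c("BED3", "BED6", "bedGraph")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("interval file not found: ", path)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    stop("empty interval file: ", path)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  need <- switch(dialect, BED3 = 3L, bedGraph = 4L, BED6 = 6L)
  nf <- lengths(fields)
  if (any(nf < need)) {
    bad <- which(nf < need)[1L]
    stop("line ", bad, " of ", path, ": expected >= ", need,
         " tab-delimited fields for ", dialect, ", found ", nf[bad])
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- as.integer(vapply(fields, `[[`, "", 2L))
  end <- as.integer(vapply(fields, `[[`, "", 3L))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1L]
    stop("line ", bad, " of ", path, ": non-numeric coordinates")
  }
  if (any(start >= end)) {
    bad <- which(start >= end)[1L]
    stop("line ", bad, " of ", path, ": start >= end (", start[bad], " >= ",
         end[bad], "); BED intervals are half-open and must be non-empty")
  }
  if (any(start < 0L)) {
    bad <- which(start < 0L)[1L]
    stop("line ", bad, " of ", path, ": negative start")
  }
  strand <- rep(".", length(chrom))
  score <- rep(NA_real_, length(chrom))
  if (dialect == "bedGraph") {
    score <- as.numeric(vapply(fields, `[[`, "", 4L))
  } else if (dialect == "BED6") {
    score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
    strand <- vapply(fields, `[[`, "", 6L)
    if (!all(strand %in% c("+", "-", "."))) {
      bad <- which(!strand %in% c("+", "-", "."))[1L]
      stop("line ", bad, " of ", path, ": invalid strand '", strand[bad], "'")
    }
  }
  out <- data.frame(chrom = chrom, start = start, end = end,
                    strand = strand, score = score,
                    stringsAsFactors = FALSE)
  sort_intervals(out)
}

#' Write intervals to a BED-family file
#'
#' Emits tab-delimited, newline-terminated, coordinate-sorted output.
#'
#' @param intervals Interval data.frame (`chrom`, `start`, `end`, optionally
#'   `strand`, `score`, `name`).
#' @param path Output path.
#' @param dialect One of `"BED3"`, `"BED6"`, `"bedGraph"`.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(intervals, path,
                            dialect = c("BED3", "BED6", "bedGraph")) {
  dialect <- match.arg(dialect)
  x <- sort_intervals(intervals)
  lines <- switch(dialect,
    BED3 = paste(x$chrom, x$start, x$end, sep = "\t"),
    bedGraph = paste(x$chrom, x$start, x$end,
                     if (is.null(x$score)) 0 else x$score, sep = "\t"),
    BED6 = {
      nm <- if (is.null(x$name)) "." else x$name
      sc <- if (is.null(x$score)) 0 else ifelse(is.na(x$score), 0, x$score)
      st <- if (is.null(x$strand)) "." else x$strand
      paste(x$chrom, x$start, x$end, nm, sc, st, sep = "\t")
    })
  writeLines(lines, path)
  invisible(path)
}

# Sort an interval data.frame by (chrom, start, end); stable.
sort_intervals <- function(intervals) {
  intervals[order(intervals$chrom, intervals$start, intervals$end), ,
            drop = FALSE] |> `rownames<-`(NULL)
}

# Interval data.frame (BED half-open) -> GRanges (1-based closed).
gr_from_bed <- function(intervals, seqlengths = NULL) {
  strand <- if (is.null(intervals$strand)) "*" else {
    s <- intervals$strand
    s[is.na(s) | s == "."] <- "*"
    s
  }
  GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start + 1L,
                              end = intervals$end),
    strand = strand,
    seqlengths = seqlengths
  )
}

# GRanges -> interval data.frame (BED half-open).
bed_from_gr <- function(gr) {
  s <- as.character(GenomicRanges::strand(gr))
  s[s == "*"] <- "."
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = s,
    stringsAsFactors = FALSE
  )
}

# Read a bedGraph into a coverage data.frame (chrom, start, end, value).
#' Read a coverage track from a bedGraph file
#'
#' @param path Path to a bedGraph file.
#' @return A data.frame `chrom`, `start`, `end`, `value` (piecewise-constant
#'   read density, BED half-open coordinates), sorted.
#' @export
read_coverage <- function(path) {
  x <- read_intervals(path, dialect = "bedGraph")
  data.frame(chrom = x$chrom, start = x$start, end = x$end,
             value = x$score, stringsAsFactors = FALSE)
}

#' Write a coverage track to a bedGraph file
#' @param coverage Coverage data.frame (`chrom`, `start`, `end`, `value`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(coverage, path) {
  cov <- coverage
  cov$score <- cov$value
  write_intervals(cov, path, dialect = "bedGraph")
}
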