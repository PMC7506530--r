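#' Merge overlapping or nearby intervals
#'
#' Merges intervals whose gap is at most `max_gap` base pairs. With the
#' default `max_gap = 0`, book-ended intervals (gap exactly 0, e.g.
#' `[0,100)` and `[100,200)`) are merged, matching the usual interval-merge
#' convention of BED toolchains.
#'
#' @param intervals Interval data.frame (`chrom`, `start`, `end`).
#' @param max_gap Maximum gap in bp between intervals that are still merged.
#' @return A sorted interval data.frame; pairwise gaps in the output exceed
#'   `max_gap`.
#' @export
merge_intervals <- function(intervals, max_gap = 0L) {
  if (nrow(intervals) == 0L) {
    return(empty_intervals())
  }
  gr <- gr_from_bed(intervals)
  GenomicRanges::strand(gr) <- "*"
  merged <- GenomicRanges::reduce(gr, min.gapwidth = max_gap + 1L)
  sort_intervals(bed_from_gr(merged))
}

empty_intervals <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             strand = character(0), stringsAsFactors = FALSE)
}

#' Cluster intervals by proximity
#'
#' Two consecutive intervals on the same chromosome share a cluster id iff
#' the gap between them is at most `max_gap` bp. Ids are dense integers,
#' restarting from 1 on each chromosome.
#'
#' @param intervals Interval data.frame.
#' @param max_gap Maximum gap in bp joining two intervals into one cluster.
#' @return The sorted input with an added integer `cluster_id` column.
#' @export
cluster_intervals <- function(intervals, max_gap) {
  x <- sort_intervals(intervals)
  if (nrow(x) == 0L) {
    x$cluster_id <- integer(0)
    return(x)
  }
  ids <- integer(nrow(x))
  id <- 0L
  prev_chrom <- NA_character_
  prev_end <- -Inf
  for (i in seq_len(nrow(x))) {
    if (!identical(x$chrom[i], prev_chrom)) {
      id <- 1L
      prev_end <- x$end[i]
    } else if ((x$start[i] - prev_end) > max_gap) {
      id <- id + 1L
      prev_end <- x$end[i]
    } else {
      prev_end <- max(prev_end, x$end[i])
    }
    ids[i] <- id
    prev_chrom <- x$chrom[i]
  }
  x$cluster_id <- ids
  x
}

#' Randomly relocate intervals on a genome
#'
#' Places each interval uniformly at random, preserving its length, for
#' shuffle-based null distributions of overlap statistics. By default each
#' interval stays on its own chromosome and placements may not overlap each
#' other. An optional exclusion mask removes regions (e.g. assembly gaps)
#' from consideration.
#'
#' @param intervals Interval data.frame.
#' @param genome Named `DNAStringSet` or a named numeric vector of chromosome
#'   lengths.
#' @param seed Integer seed; equal seeds give byte-identical output.
#' @param same_chrom Keep each interval on its original chromosome.
#' @param no_overlap Disallow overlap among shuffled intervals.
#' @param mask Optional interval data.frame of excluded regions.
#' @param max_tries Retries per interval before giving up.
#' @return A sorted interval data.frame of relocated intervals.
#' @export
shuffle_intervals <- function(intervals, genome, seed,
                              same_chrom = TRUE, no_overlap = TRUE,
                              mask = NULL, max_tries = 1000L) {
  lens <- genome_lengths(genome)
  x <- sort_intervals(intervals)
  if (nrow(x) == 0L) return(empty_intervals())
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    expr
  }
  widths <- x$end - x$start
  place_all <- function() {
    placed_start <- integer(nrow(x))
    placed_chrom <- character(nrow(x))
    occupied <- list()  # per-chrom matrix of placed [start,end)
    for (i in seq_len(nrow(x))) {
      w <- widths[i]
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        # chromosome drawn per attempt, length-proportional, when free
        ch <- if (same_chrom) x$chrom[i] else
          sample(names(lens), 1L, prob = lens / sum(lens))
        hi <- lens[[ch]] - w
        if (hi < 0) stop("interval of width ", w, " does not fit on ", ch)
        s <- sample.int(hi + 1L, 1L) - 1L
        clash <- FALSE
        if (no_overlap && !is.null(occupied[[ch]])) {
          occ <- occupied[[ch]]
          clash <- any(s < occ[, 2L] & (s + w) > occ[, 1L])
        }
        if (!clash && !is.null(mask)) {
          m <- mask[mask$chrom == ch, , drop = FALSE]
          if (nrow(m) > 0L) {
            clash <- any(s < m$end & (s + w) > m$start)
          }
        }
        if (!clash) {
          placed_start[i] <- s
          placed_chrom[i] <- ch
          occupied[[ch]] <- rbind(occupied[[ch]], c(s, s + w))
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop("could not place interval ", i, " without overlap after ",
             max_tries, " tries")
      }
    }
    data.frame(chrom = placed_chrom, start = placed_start,
               end = placed_start + widths, strand = ".",
               stringsAsFactors = FALSE)
  }
  out <- withr_seed(place_all())
  sort_intervals(out)
}

genome_lengths <- function(genome) {
  if (is.numeric(genome)) {
    if (is.null(names(genome))) stop("chromosome lengths must be named")
    return(genome)
  }
  g <- as_genome(genome)
  stats::setNames(Biostrings::width(g), names(g))
}

#' Count query intervals that overlap a subject set
#'
#' An interval in `A` is counted once if it shares at least one base with at
#' least one interval of `B` after extending each `B` interval symmetrically
#' by `slop` bp (e.g. 2 kb when overlap "within +/- 2 kb" is wanted).
#'
#' @param A Query interval data.frame.
#' @param B Subject interval data.frame.
#' @param slop Symmetric extension of `B` in bp before overlap testing.
#' @return Integer count of `A` intervals with at least one hit.
#' @export
overlap_count <- function(A, B, slop = 0L) {
  if (nrow(A) == 0L || nrow(B) == 0L) return(0L)
  b <- B
  b$start <- pmax(0L, b$start - slop)
  b$end <- b$end + slop
  ga <- gr_from_bed(A); GenomicRanges::strand(ga) <- "*"
  gb <- gr_from_bed(b); GenomicRanges::strand(gb) <- "*"
  sum(IRanges::overlapsAny(ga, gb))
}

#' Chi-square goodness-of-fit test for overlap enrichment
#'
#' Compares an observed overlap count against the expected count (typically
#' the mean overlap over shuffled placements) over the two categories
#' \{overlap, no-overlap\}: `chi2 = (O-E)^2/E + ((n-O)-(n-E))^2/(n-E)`, with
#' a p-value from the chi-square distribution with 1 degree of freedom.
#' Depletion (O < E) uses the same statistic.
#'
#' @param observed_overlap Observed count of overlapping regions.
#' @param n_total Total number of regions tested.
#' @param expected_overlap Expected overlap count, strictly between 0 and
#'   `n_total`.
#' @return A list with `chi2` and `p`.
#' @export
chisq_gof_enrichment <- function(observed_overlap, n_total, expected_overlap) {
  if (expected_overlap <= 0 || expected_overlap >= n_total) {
    stop("expected_overlap must lie strictly between 0 and n_total")
  }
  o <- c(observed_overlap, n_total - observed_overlap)
  e <- c(expected_overlap, n_total - expected_overlap)
  chi2 <- sum((o - e)^2 / e)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE))
}

#' Shuffle-based expected overlap and enrichment test
#'
#' Computes the expected overlap of `A` with `B` as the mean overlap count
#' across `n_shuffles` seeded random placements of `A`, then applies
#' [chisq_gof_enrichment()].
#'
#' @inheritParams shuffle_intervals
#' @inheritParams overlap_count
#' @param n_shuffles Number of shuffles used for the expectation.
#' @return A list with `observed`, `expected`, `chi2`, `p`, `n_total`.
#' @export
overlap_enrichment <- function(A, B, genome, seed, slop = 0L,
                               n_shuffles = 100L, same_chrom = TRUE,
                               no_overlap = TRUE) {
  observed <- overlap_count(A, B, slop = slop)
  exp_counts <- vapply(seq_len(n_shuffles), function(i) {
    sh <- shuffle_intervals(A, genome, seed = seed + i - 1L,
                            same_chrom = same_chrom, no_overlap = no_overlap)
    overlap_count(sh, B, slop = slop)
  }, numeric(1))
  expected <- mean(exp_counts)
  test <- chisq_gof_enrichment(observed, nrow(A), expected)
  c(list(observed = observed, expected = expected, n_total = nrow(A)), test)
}

#' Signed distances from oriented points to nearby feature points
#'
#' For each point of `A` (e.g. an oriented origin summit), reports the signed
#' distance to every point of `B` (e.g. pre-RC peak centres) within
#' `max_dist` bp. Sign is strand-aware: upstream of the `A` point is
#' negative, so for a minus-strand summit the sign flips.
#'
#' @param A_points Data.frame `chrom`, `pos`, `strand` ("+" or "-").
#' @param B_points Data.frame `chrom`, `pos`.
#' @param max_dist Maximum absolute distance in bp.
#' @return A data.frame `a_index`, `distance` with one row per (A, nearby B)
#'   pair.
#' @export
nearest_distances <- function(A_points, B_points, max_dist = 10000L) {
  out_idx <- integer(0)
  out_d <- integer(0)
  b_split <- split(B_points$pos, B_points$chrom)
  for (i in seq_len(nrow(A_points))) {
    bp <- b_split[[A_points$chrom[i]]]
    if (is.null(bp)) next
    d <- bp - A_points$pos[i]
    keep <- abs(d) <= max_dist
    if (!any(keep)) next
    d <- d[keep]
    if (A_points$strand[i] == "-") d <- -d
    out_idx <- c(out_idx, rep(i, length(d)))
    out_d <- c(out_d, d)
  }
  data.frame(a_index = out_idx, distance = out_d)
}
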