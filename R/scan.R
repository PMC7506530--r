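#' Hyper-motif scan parameters
#'
#' The genome scan looks for a paired-window G-content architecture ("OGRE"
#' geometry): a G-rich 500-bp window followed by a consecutive, less G-rich
#' 500-bp window. A pair is retained on the forward orientation when the
#' first window holds at least `g1_min` G, the second at least `g2_min` G,
#' the G fraction drops by `drop_min`..`drop_max` (absolute percentage
#' points) from the first to the second window, and neither A nor T exceeds
#' `at_max` over the combined 1-kb pair. The reverse orientation applies the
#' exact C-based mirror of this rule with the window roles exchanged, so the
#' scan is reverse-complement symmetric.
#'
#' @param window Window size in bp.
#' @param step Sliding step in bp; must divide `window`.
#' @param g1_min Minimum G fraction of the first (G-richer) window.
#' @param g2_min Minimum G fraction of the second window.
#' @param drop_min,drop_max Bounds on the absolute G-fraction drop between
#'   the two windows.
#' @param at_max Cap on each of the A and T fractions over the combined pair.
#' @return A list of class `hypermotif_params`.
#' @export
hypermotif_params <- function(window = 500L, step = 100L,
                              g1_min = 0.28, g2_min = 0.25,
                              drop_min = 0.08, drop_max = 0.40,
                              at_max = 0.21) {
  stopifnot(g2_min <= g1_min, g1_min < 1, g2_min > 0,
            drop_min >= 0, drop_min <= drop_max, drop_max < 1,
            window %% step == 0L)
  structure(list(window = as.integer(window), step = as.integer(step),
                 g1_min = g1_min, g2_min = g2_min,
                 drop_min = drop_min, drop_max = drop_max, at_max = at_max),
            class = "hypermotif_params")
}

#' Base composition of paired sliding windows
#'
#' Enumerates every paired-window start position on one chromosome (starts
#' 0, step, 2*step, ... with `start + 2*window <= length`, so each first
#' window has a complete partner) and returns the A/C/G/T counts of both
#' windows. N bases count in the denominator (`window`) but match no
#' nucleotide, so N-rich windows fail composition thresholds.
#'
#' @param chromseq A `DNAString`/`DNAStringSet` element or character scalar.
#' @param window,step Window size and step in bp.
#' @return A list with `start` (0-based pair starts) and integer count
#'   matrices `counts1`, `counts2` (columns A, C, G, T). Empty when the
#'   chromosome is shorter than `2*window`.
#' @export
window_compositions <- function(chromseq, window = 500L, step = 100L) {
  seq1 <- single_sequence(chromseq)
  L <- Biostrings::nchar(seq1)
  if (L < 2L * window) {
    return(list(start = integer(0),
                counts1 = matrix(integer(0), 0, 4,
                                 dimnames = list(NULL, c("A", "C", "G", "T"))),
                counts2 = matrix(integer(0), 0, 4,
                                 dimnames = list(NULL, c("A", "C", "G", "T")))))
  }
  starts0 <- seq.int(0L, L - 2L * window, by = step)
  v1 <- Biostrings::Views(seq1, start = starts0 + 1L, width = window)
  v2 <- Biostrings::Views(seq1, start = starts0 + window + 1L, width = window)
  base_letters <- c("A", "C", "G", "T")
  c1 <- Biostrings::letterFrequency(v1, letters = base_letters)
  c2 <- Biostrings::letterFrequency(v2, letters = base_letters)
  colnames(c1) <- colnames(c2) <- base_letters
  list(start = starts0, counts1 = c1, counts2 = c2)
}

single_sequence <- function(chromseq) {
  if (methods::is(chromseq, "DNAStringSet")) {
    stopifnot(length(chromseq) == 1L)
    return(chromseq[[1L]])
  }
  if (methods::is(chromseq, "DNAString")) return(chromseq)
  Biostrings::DNAString(toupper(as.character(chromseq)))
}

#' Evaluate the hyper-motif rule on window-pair compositions
#'
#' Vectorised over pairs. All threshold comparisons are inclusive.
#'
#' @param counts1,counts2 Integer count matrices (columns A, C, G, T) for the
#'   first and second window of each pair.
#' @param params A [hypermotif_params()] object.
#' @return A list of logical vectors `forward` and `reverse`.
#' @export
hypermotif_filter <- function(counts1, counts2, params = hypermotif_params()) {
  w <- params$window
  g1 <- counts1[, "G"] / w
  g2 <- counts2[, "G"] / w
  c1 <- counts1[, "C"] / w
  c2 <- counts2[, "C"] / w
  a_pair <- (counts1[, "A"] + counts2[, "A"]) / (2 * w)
  t_pair <- (counts1[, "T"] + counts2[, "T"]) / (2 * w)
  at_ok <- a_pair <= params$at_max & t_pair <= params$at_max
  forward <- g1 >= params$g1_min & g2 >= params$g2_min &
    (g1 - g2) >= params$drop_min & (g1 - g2) <= params$drop_max & at_ok
  # mirror rule: on the reverse complement the pair reads second-to-first
  # with G<->C, so C content of window 2 plays the role of G in window 1
  reverse <- c2 >= params$g1_min & c1 >= params$g2_min &
    (c2 - c1) >= params$drop_min & (c2 - c1) <= params$drop_max & at_ok
  list(forward = unname(forward), reverse = unname(reverse))
}

#' Scan a genome for hyper-motif candidate origin regions
#'
#' Runs the paired-window scan on every chromosome, pools retained pairs
#' from both orientations (a position retained by both counts once), projects
#' each retained pair to its `[start, start + 2*window)` footprint, and
#' merges book-ended/overlapping footprints into non-overlapping candidate
#' regions. Each merged region carries the orientation contributing more
#' retained pairs (ties go to forward, "+").
#'
#' @param genome Named `DNAStringSet` or named character vector.
#' @param params A [hypermotif_params()] object.
#' @return A list with:
#'   \describe{
#'     \item{regions}{merged candidate regions (`chrom`, `start`, `end`,
#'       `strand`, `n_pairs`)}
#'     \item{pairs}{retained pair positions (`chrom`, `start`, `forward`,
#'       `reverse`)}
#'     \item{n_pairs}{number of distinct retained pair positions}
#'     \item{n_pairs_forward,n_pairs_reverse}{per-orientation counts}
#'   }
#' @export
scan_genome <- function(genome, params = hypermotif_params()) {
  genome <- as_genome(genome)
  pair_list <- vector("list", length(genome))
  for (i in seq_along(genome)) {
    comp <- window_compositions(genome[[i]], params$window, params$step)
    if (length(comp$start) == 0L) next
    keep <- hypermotif_filter(comp$counts1, comp$counts2, params)
    retained <- keep$forward | keep$reverse
    if (!any(retained)) next
    pair_list[[i]] <- data.frame(
      chrom = names(genome)[i],
      start = comp$start[retained],
      forward = keep$forward[retained],
      reverse = keep$reverse[retained],
      stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, pair_list)
  if (is.null(pairs) || nrow(pairs) == 0L) {
    regions <- empty_intervals()
    regions$n_pairs <- integer(0)
    return(list(regions = regions,
                pairs = data.frame(chrom = character(0), start = integer(0),
                                   forward = logical(0), reverse = logical(0)),
                n_pairs = 0L, n_pairs_forward = 0L, n_pairs_reverse = 0L))
  }
  span <- 2L * params$window
  foot <- data.frame(chrom = pairs$chrom, start = pairs$start,
                     end = pairs$start + span, stringsAsFactors = FALSE)
  regions <- merge_intervals(foot, max_gap = 0L)
  # dominant orientation per merged region
  gr_reg <- gr_from_bed(regions)
  gr_pair <- gr_from_bed(foot)
  GenomicRanges::strand(gr_reg) <- "*"
  GenomicRanges::strand(gr_pair) <- "*"
  hits <- GenomicRanges::findOverlaps(gr_pair, gr_reg)
  fwd <- tabulate_by(S4Vectors::subjectHits(hits),
                     pairs$forward[S4Vectors::queryHits(hits)], nrow(regions))
  rev <- tabulate_by(S4Vectors::subjectHits(hits),
                     pairs$reverse[S4Vectors::queryHits(hits)], nrow(regions))
  regions$strand <- ifelse(fwd >= rev, "+", "-")
  regions$n_pairs <- fwd + rev
  list(regions = regions, pairs = pairs,
       n_pairs = nrow(pairs),
       n_pairs_forward = sum(pairs$forward),
       n_pairs_reverse = sum(pairs$reverse))
}

tabulate_by <- function(group, weight, n) {
  out <- numeric(n)
  agg <- rowsum(as.numeric(weight), group)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

#' Call G-rich regions by simple G density
#'
#' Marks sliding windows whose G fraction strictly exceeds `g_min`
#' (default: more than 37% G per 500-bp window, stepped by 100 bp) and
#' merges the marked window footprints into regions.
#'
#' @param genome Named `DNAStringSet` or named character vector.
#' @param g_min G-fraction threshold (strict).
#' @param window,step Window size and step in bp.
#' @return A sorted interval data.frame of merged G-rich regions.
#' @export
grich_regions <- function(genome, g_min = 0.37, window = 500L, step = 100L) {
  genome <- as_genome(genome)
  out <- vector("list", length(genome))
  for (i in seq_along(genome)) {
    seq1 <- genome[[i]]
    L <- Biostrings::nchar(seq1)
    if (L < window) next
    starts0 <- seq.int(0L, L - window, by = step)
    v <- Biostrings::Views(seq1, start = starts0 + 1L, width = window)
    g <- Biostrings::letterFrequency(v, letters = "G")[, 1L] / window
    keep <- g > g_min
    if (!any(keep)) next
    out[[i]] <- data.frame(chrom = names(genome)[i],
                           start = starts0[keep],
                           end = starts0[keep] + window,
                           stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, out)
  if (is.null(hits)) return(empty_intervals())
  merge_intervals(hits, max_gap = 0L)
}
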