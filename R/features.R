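#' Names of the 22 sequence predictors
#'
#' The feature roster computed by [extract_features()], in fixed column
#' order: upstream/downstream 2-kb base fractions, central G content at 2 kb
#' and 4 kb, the G-content ramp across the 4-kb span, di-/multi-nucleotide
#' and homotrinucleotide densities over the central 1-kb pair, the log10
#' distance to the nearest other candidate, and the maximal A/T fraction of
#' the pair.
#'
#' @return Character vector of 22 feature names.
#' @export
feature_names <- function() {
  c("UP_A_fraction", "UP_C_fraction", "UP_G_fraction", "UP_T_fraction",
    "Down_A_fraction", "Down_C_fraction", "Down_G_fraction", "Down_T_fraction",
    "G_content_2kb", "G_content_4kb", "rampG",
    "CC", "CG", "GG", "GC", "CGCG",
    "AAA", "TTT", "GGG", "CCC",
    "log10_inter_candidate_distance", "at_max_pair")
}

#' Extract the 22 sequence predictors for candidate window pairs
#'
#' Each candidate is a retained window-pair position: the pair spans
#' `[start, start + 2*window)` and its centre is the boundary between the
#' two windows. Features are read in the candidate's orientation over a
#' 4-kb span centred on that boundary (for reverse-orientation candidates
#' the span is read as its reverse complement, so "UP" is always the G-rich
#' side of a true cassette). Spans are truncated at chromosome edges and
#' fractions use the available length.
#' \itemize{
#'   \item `UP_*_fraction`, `Down_*_fraction`: base fractions of the 2-kb
#'     spans up- and downstream of the boundary.
#'   \item `G_content_2kb`, `G_content_4kb`: G fraction of the central 2-kb
#'     and full 4-kb span.
#'   \item `rampG`: least-squares slope (per kb) of the G fraction across
#'     eight 500-bp segments of the 4-kb span.
#'   \item `CC`, `CG`, `GG`, `GC`, `CGCG`, `AAA`, `TTT`, `GGG`, `CCC`:
#'     overlapping k-mer counts per kb over the central 1-kb pair.
#'   \item `log10_inter_candidate_distance`: log10 of the distance (bp,
#'     centre to centre) to the nearest other candidate, capped at 6 (also
#'     used when no other candidate exists).
#'   \item `at_max_pair`: max of the A and T fractions over the 1-kb pair.
#' }
#'
#' Extracting a reverse-orientation candidate is exactly equivalent to
#' extracting the mirrored position of the reverse-complemented chromosome
#' forward: UP and Down swap roles with A<->T and C<->G exchanged, rampG
#' flips sign (as the C-content ramp of the forward strand), and k-mer
#' densities map onto their reverse complements.
#'
#' @param genome Named `DNAStringSet` or named character vector.
#' @param candidates Data.frame `chrom`, `start` of pair positions (as
#'   returned in `scan_genome()$pairs`).
#' @param orientation Character vector, "+" (forward) or "-" per candidate;
#'   a single value is recycled.
#' @param window Window size in bp (pair spans `2*window`).
#' @return A candidates x 22 numeric matrix, columns [feature_names()].
#' @export
extract_features <- function(genome, candidates, orientation = "+",
                             window = 500L) {
  genome <- as_genome(genome)
  lens <- genome_lengths(genome)
  n <- nrow(candidates)
  orientation <- rep_len(orientation, n)
  out <- matrix(NA_real_, n, 22L, dimnames = list(NULL, feature_names()))
  centre <- candidates$start + window
  # inter-candidate distance (centre-to-centre, same chromosome)
  icd <- rep(10^6, n)
  for (ch in unique(candidates$chrom)) {
    idx <- which(candidates$chrom == ch)
    if (length(idx) > 1L) {
      cs <- sort(centre[idx])
      gaps <- diff(cs)
      nearest <- pmin(c(Inf, gaps), c(gaps, Inf))
      icd[idx] <- pmin(nearest[match(centre[idx], cs)], 10^6)
    }
  }
  out[, "log10_inter_candidate_distance"] <- pmin(log10(pmax(icd, 1)), 6)

  base_letters <- c("A", "C", "G", "T")
  kmer_set <- c("CC", "CG", "GG", "GC", "CGCG", "AAA", "TTT", "GGG", "CCC")
  # k-mer identity under reverse complement within the roster
  kmer_rc <- c(CC = "GG", CG = "CG", GG = "CC", GC = "GC", CGCG = "CGCG",
               AAA = "TTT", TTT = "AAA", GGG = "CCC", CCC = "GGG")
  comp <- c(A = "T", C = "G", G = "C", T = "A")

  for (ch in unique(candidates$chrom)) {
    idx <- which(candidates$chrom == ch)
    seq1 <- genome[[ch]]
    L <- lens[[ch]]
    b <- centre[idx]
    if (any(b - 2000L >= L | b + 2000L <= 0L)) {
      stop("candidate 4-kb span fully off chromosome ", ch)
    }
    frac_block <- function(from, to) {
      from <- pmax(0L, as.integer(from)); to <- pmin(L, as.integer(to))
      w <- to - from
      res <- matrix(0, length(from), 4L, dimnames = list(NULL, base_letters))
      ok <- w > 0
      if (any(ok)) {
        v <- Biostrings::Views(seq1, start = from[ok] + 1L, width = w[ok])
        res[ok, ] <- Biostrings::letterFrequency(v, letters = base_letters) /
          w[ok]
      }
      res
    }
    left <- frac_block(b - 2000L, b)    # genome-forward upstream block
    right <- frac_block(b, b + 2000L)   # genome-forward downstream block
    mid2 <- frac_block(b - 1000L, b + 1000L)
    full4 <- frac_block(b - 2000L, b + 2000L)
    # per-segment G and C fractions across the eight 500-bp segments
    seg_g <- matrix(0, length(idx), 8L)
    seg_c <- matrix(0, length(idx), 8L)
    for (k in 0:7) {
      fb <- frac_block(b - 2000L + k * 500L, b - 2000L + (k + 1L) * 500L)
      seg_g[, k + 1L] <- fb[, "G"]
      seg_c[, k + 1L] <- fb[, "C"]
    }
    xk <- seq(-1750, 1750, by = 500) / 1000  # segment midpoints, kb
    xc <- xk - mean(xk)
    ramp_g <- as.numeric(seg_g %*% xc) / sum(xc^2)
    ramp_c <- as.numeric(seg_c %*% xc) / sum(xc^2)
    # k-mer counts over the central 1-kb pair (genome forward)
    pf <- pmax(0L, b - window); pt <- pmin(L, b + window)
    v <- Biostrings::Views(seq1, start = pf + 1L, width = pt - pf)
    pairseq <- Biostrings::DNAStringSet(v)
    kb <- (pt - pf) / 1000
    kcounts <- sapply(kmer_set, function(k) {
      Biostrings::vcountPattern(k, pairseq) / kb
    })
    if (length(idx) == 1L) kcounts <- matrix(kcounts, nrow = 1L,
                                             dimnames = list(NULL, kmer_set))
    pair_frac <- Biostrings::letterFrequency(pairseq, letters = base_letters) /
      (pt - pf)
    fwd <- orientation[idx] == "+"
    for (j in seq_along(idx)) {
      i <- idx[j]
      if (fwd[j]) {
        out[i, paste0("UP_", base_letters, "_fraction")] <- left[j, ]
        out[i, paste0("Down_", base_letters, "_fraction")] <- right[j, ]
        out[i, "G_content_2kb"] <- mid2[j, "G"]
        out[i, "G_content_4kb"] <- full4[j, "G"]
        out[i, "rampG"] <- ramp_g[j]
        out[i, kmer_set] <- kcounts[j, kmer_set]
      } else {
        # reverse orientation: read the span as its reverse complement
        out[i, paste0("UP_", base_letters, "_fraction")] <-
          right[j, comp[base_letters]]
        out[i, paste0("Down_", base_letters, "_fraction")] <-
          left[j, comp[base_letters]]
        out[i, "G_content_2kb"] <- mid2[j, "C"]
        out[i, "G_content_4kb"] <- full4[j, "C"]
        out[i, "rampG"] <- -ramp_c[j]
        out[i, kmer_set] <- kcounts[j, kmer_rc[kmer_set]]
      }
      out[i, "at_max_pair"] <- max(pair_frac[j, "A"], pair_frac[j, "T"])
    }
  }
  out
}

#' Feature matrix with origin-overlap labels
#'
#' Computes [extract_features()] for every candidate and labels a candidate
#' 1 when its 1-kb pair footprint shares at least one base with an origin
#' interval, else 0.
#'
#' @inheritParams extract_features
#' @param origins Interval data.frame of origins (may be empty or `NULL`).
#' @return A list with `features` (candidates x 22 matrix), `labels`
#'   (integer 0/1), and `candidates` (the input positions).
#' @export
feature_matrix <- function(genome, candidates, origins = NULL,
                           orientation = "+", window = 500L) {
  feats <- extract_features(genome, candidates, orientation = orientation,
                            window = window)
  labels <- integer(nrow(candidates))
  if (!is.null(origins) && nrow(origins) > 0L) {
    foot <- data.frame(chrom = candidates$chrom, start = candidates$start,
                       end = candidates$start + 2L * window,
                       stringsAsFactors = FALSE)
    ga <- gr_from_bed(foot); GenomicRanges::strand(ga) <- "*"
    gb <- gr_from_bed(origins); GenomicRanges::strand(gb) <- "*"
    labels <- as.integer(IRanges::overlapsAny(ga, gb))
  }
  list(features = feats, labels = labels, candidates = candidates)
}
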