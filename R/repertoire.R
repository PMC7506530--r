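#' Background-subtracted, TMM-scaled origin activities
#'
#' Subtracts the matched background count matrix from the nascent-strand
#' count matrix (negatives clamped to zero), then scales samples by
#' trimmed-mean-of-M-values (TMM) factors so that samples are comparable.
#' The TMM reference is the sample whose total count is closest to the
#' median total (ties to the first such sample); scale factors are reported
#' relative to that reference, so the reference sample has factor 1.
#' Trim fractions are the standard TMM defaults (30% on M, 5% on A).
#'
#' @param counts Origins x samples matrix of non-negative counts.
#' @param background Matrix of matched background counts, same shape
#'   (optional; zero background if `NULL`).
#' @return A list with `normalized` (origins x samples), `scale_factors`
#'   (per sample, reference = 1), and `mean_activity` (per-origin mean of
#'   the normalized matrix across samples).
#' @export
normalize_activity <- function(counts, background = NULL) {
  counts <- as.matrix(counts)
  if (is.null(background)) background <- matrix(0, nrow(counts), ncol(counts))
  background <- as.matrix(background)
  stopifnot(identical(dim(counts), dim(background)))
  bsub <- pmax(counts - background, 0)
  totals <- colSums(bsub)
  zero_samples <- totals == 0
  if (any(zero_samples)) {
    warning(sum(zero_samples), " sample(s) have zero total signal after ",
            "background subtraction; scale factor set to 1")
  }
  ref <- which.min(abs(totals - stats::median(totals)))
  nf <- rep(1, ncol(bsub))
  usable <- !zero_samples
  if (sum(usable) >= 2 && !zero_samples[ref]) {
    nf[usable] <- edgeR::calcNormFactors(
      bsub[, usable, drop = FALSE],
      method = "TMM",
      refColumn = match(ref, which(usable)))
  }
  eff <- totals * nf
  eff[zero_samples] <- 1
  scale_factors <- eff / eff[ref]
  scale_factors[zero_samples] <- 1
  normalized <- sweep(bsub, 2L, scale_factors, "/")
  list(normalized = normalized,
       scale_factors = scale_factors,
       mean_activity = rowMeans(normalized))
}

#' Classify origins into activity deciles and core/stochastic classes
#'
#' Origins are ranked by decreasing mean activity and cut into
#' `n_quantiles` groups: Q1 holds the most active origins. When the origin
#' count is not divisible by `n_quantiles`, the remainder is distributed to
#' the lowest-activity quantiles, so the top quantiles are exactly
#' `floor(n / n_quantiles)` each (with 320,748 origins and 10 quantiles this
#' gives 32,074 origins in each of Q1 and Q2 and 32,075 in each of Q3-Q10).
#' Q1-Q2 origins are "core", Q3-Q10 "stochastic"; origins with mean activity
#' above `super_threshold` are additionally flagged "super".
#'
#' @param mean_activity Numeric vector of per-origin mean activities.
#' @param n_quantiles Number of activity quantiles (default 10).
#' @param core_quantiles Quantiles defining the core class (default 1:2).
#' @param super_threshold Normalized-count threshold for super origins
#'   (default 50, strict).
#' @param tie_order Optional integer vector; ties in activity across a
#'   quantile boundary are broken by this order (e.g. genomic order). By
#'   default ties break by input position.
#' @return A data.frame with `quantile` (1..n), `klass` ("core" or
#'   "stochastic"), and logical `super`, in input order.
#' @export
classify_quantiles <- function(mean_activity, n_quantiles = 10L,
                               core_quantiles = 1:2, super_threshold = 50,
                               tie_order = seq_along(mean_activity)) {
  n <- length(mean_activity)
  if (n < n_quantiles) stop("need at least ", n_quantiles, " origins")
  base <- n %/% n_quantiles
  r <- n %% n_quantiles
  sizes <- rep(base, n_quantiles)
  if (r > 0) sizes[(n_quantiles - r + 1L):n_quantiles] <- base + 1L
  ranking <- order(-mean_activity, tie_order)
  q_by_rank <- rep.int(seq_len(n_quantiles), sizes)
  quantile <- integer(n)
  quantile[ranking] <- q_by_rank
  data.frame(
    quantile = quantile,
    klass = ifelse(quantile %in% core_quantiles, "core", "stochastic"),
    super = mean_activity > super_threshold,
    stringsAsFactors = FALSE)
}

#' Fraction of initiation signal per origin class
#'
#' For each sample, the fraction of the total normalized signal that falls
#' in each origin group (by default the core/stochastic classes; any
#' grouping vector works, e.g. quantiles).
#'
#' @param normalized Origins x samples normalized activity matrix.
#' @param groups Per-origin grouping vector (character or factor).
#' @return A groups x samples matrix of fractions; columns sum to 1.
#' @export
signal_fraction_by_class <- function(normalized, groups) {
  normalized <- as.matrix(normalized)
  stopifnot(length(groups) == nrow(normalized))
  totals <- colSums(normalized)
  if (any(totals <= 0)) stop("sample with zero total signal: fraction undefined")
  sums <- rowsum(normalized, group = groups)
  sweep(sums, 2L, totals, "/")
}

#' Call origin summits from a coverage track
#'
#' Within each origin interval, read density is evaluated in `bin`-bp bins
#' advanced by `step` bp; the summit is the midpoint of the bin with the
#' highest signal (ties: leftmost bin). Intervals with zero coverage get the
#' interval midpoint and are flagged.
#'
#' @param coverage Coverage data.frame (`chrom`, `start`, `end`, `value`),
#'   piecewise constant, non-overlapping.
#' @param intervals Origin interval data.frame.
#' @param bin Bin width in bp.
#' @param step Bin step in bp.
#' @return A data.frame `summit` (bp) and `no_signal` (logical), one row per
#'   input interval, in input order.
#' @export
call_summits <- function(coverage, intervals, bin = 50L, step = 25L) {
  n <- nrow(intervals)
  summit <- integer(n)
  flag <- logical(n)
  cov_split <- split(coverage, coverage$chrom)
  for (i in seq_len(n)) {
    s <- intervals$start[i]; e <- intervals$end[i]
    cv <- cov_split[[intervals$chrom[i]]]
    bin_starts <- seq.int(s, max(s, e - bin), by = step)
    score <- numeric(length(bin_starts))
    if (!is.null(cv)) {
      cv <- cv[cv$end > s & cv$start < e, , drop = FALSE]
      for (k in seq_along(bin_starts)) {
        bs <- bin_starts[k]; be <- min(bs + bin, e)
        ov <- pmin(cv$end, be) - pmax(cv$start, bs)
        score[k] <- sum(cv$value[ov > 0] * ov[ov > 0])
      }
    }
    if (all(score == 0)) {
      summit[i] <- as.integer((s + e) %/% 2)
      flag[i] <- TRUE
    } else {
      k <- which.max(score)  # which.max takes the leftmost maximum
      summit[i] <- as.integer(bin_starts[k] + bin %/% 2)
    }
  }
  data.frame(summit = summit, no_signal = flag)
}

#' Orient origins by flanking G content
#'
#' Assigns each origin a strand such that the G-richer 500-bp flank lies
#' upstream (left) of the summit: "+" when the G count in
#' `[summit - flank, summit)` is at least the G count in
#' `[summit, summit + flank)` (ties go to "+"); "-" otherwise. Flanks are
#' truncated at chromosome edges.
#'
#' @param genome Named `DNAStringSet` or named character vector.
#' @param summits Data.frame `chrom`, `summit`.
#' @param flank Flank size in bp.
#' @return Character vector of strands ("+"/"-"), one per summit.
#' @export
orient_origins <- function(genome, summits, flank = 500L) {
  genome <- as_genome(genome)
  lens <- genome_lengths(genome)
  strand <- character(nrow(summits))
  for (ch in unique(summits$chrom)) {
    idx <- which(summits$chrom == ch)
    seq1 <- genome[[ch]]
    L <- lens[[ch]]
    s <- summits$summit[idx]
    left_start <- pmax(0L, s - flank)
    right_end <- pmin(L, s + flank)
    gl <- gr_count_G(seq1, left_start, s)
    gr_ <- gr_count_G(seq1, s, right_end)
    strand[idx] <- ifelse(gl >= gr_, "+", "-")
  }
  strand
}

# G counts over half-open [from, to) windows of one sequence (0-based).
gr_count_G <- function(seq1, from, to) {
  w <- to - from
  out <- numeric(length(from))
  ok <- w > 0
  if (any(ok)) {
    v <- Biostrings::Views(seq1, start = from[ok] + 1L, width = w[ok])
    out[ok] <- Biostrings::letterFrequency(v, letters = "G")[, 1L]
  }
  out
}

#' Cluster core origins and classify cluster membership
#'
#' Core origins within `cluster_gap` bp of each other share a cluster.
#' An origin is "tight" when its cluster holds at least `tight_size`
#' members, "isolated" when its nearest core origin lies more than
#' `isolated_gap` bp away, and "loose" otherwise.
#'
#' @param core_origins Interval data.frame of core origins.
#' @param cluster_gap Clustering distance in bp (default 7 kb).
#' @param isolated_gap Isolation distance in bp (default 15 kb).
#' @param tight_size Minimum members of a tight cluster (default 6).
#' @return The sorted input with `cluster_id` and `cluster_class` columns.
#' @export
cluster_origins <- function(core_origins, cluster_gap = 7000L,
                            isolated_gap = 15000L, tight_size = 6L) {
  x <- cluster_intervals(core_origins, max_gap = cluster_gap)
  key <- paste(x$chrom, x$cluster_id)
  csize <- table(key)[key]
  # nearest-neighbour gap on each side, same chromosome
  n <- nrow(x)
  gap_prev <- rep(Inf, n)
  gap_next <- rep(Inf, n)
  if (n > 1L) {
    same_prev <- x$chrom[-1L] == x$chrom[-n]
    g <- x$start[-1L] - x$end[-n]
    gap_prev[-1L][same_prev] <- g[same_prev]
    gap_next[-n][same_prev] <- g[same_prev]
  }
  nearest <- pmin(gap_prev, gap_next)
  cls <- ifelse(csize >= tight_size, "tight",
                ifelse(nearest > isolated_gap, "isolated", "loose"))
  x$cluster_class <- as.character(cls)
  x
}

#' Strand-aware base-composition profile around oriented summits
#'
#' Extracts `[summit - flank, summit + flank)` for each oriented summit
#' (reverse-complemented for minus-strand origins so all origins read
#' G-rich-side upstream), computes per-position base frequencies across
#' origins, and boxcar-smooths each base's profile over `smooth` bp.
#' Positions use the convention offset = position - summit, so offset 0 is
#' the summit. Summits whose window leaves the chromosome are skipped and
#' counted.
#'
#' @param genome Named `DNAStringSet` or named character vector.
#' @param summits Data.frame `chrom`, `summit`, `strand`.
#' @param flank Half-width of the profiled window in bp.
#' @param smooth Boxcar width in bp (1 = no smoothing).
#' @return A list with `profile` (positions x 4 matrix of A/C/G/T
#'   frequencies, rows summing to 1 where no N is present), `offset`
#'   (positions relative to the summit), `n_used`, `n_skipped`.
#' @export
composition_profile <- function(genome, summits, flank = 1500L,
                                smooth = 100L) {
  genome <- as_genome(genome)
  lens <- genome_lengths(genome)
  width <- 2L * flank
  keep <- summits$summit - flank >= 0 &
    summits$summit + flank <= lens[summits$chrom]
  used <- summits[keep, , drop = FALSE]
  if (nrow(used) == 0L) stop("no summit has full flanks inside the genome")
  base_letters <- c("A", "C", "G", "T")
  counts <- matrix(0, nrow = width, ncol = 4,
                   dimnames = list(NULL, base_letters))
  n_counts <- numeric(width)  # non-N coverage per position
  for (ch in unique(used$chrom)) {
    idx <- which(used$chrom == ch)
    v <- Biostrings::Views(genome[[ch]], start = used$summit[idx] - flank + 1L,
                           width = width)
    seqs <- Biostrings::DNAStringSet(v)
    minus <- used$strand[idx] == "-"
    if (any(minus)) {
      seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
    }
    mat <- Biostrings::consensusMatrix(seqs, baseOnly = TRUE)
    counts <- counts + t(mat[base_letters, , drop = FALSE])
    n_counts <- n_counts + colSums(mat[base_letters, , drop = FALSE])
  }
  freq <- counts / pmax(n_counts, 1)
  if (smooth > 1L) {
    freq <- apply(freq, 2L, boxcar_partial, w = smooth)
  }
  list(profile = freq, offset = seq.int(-flank, flank - 1L),
       n_used = nrow(used), n_skipped = sum(!keep))
}

# Boxcar mean with window clipped at the edges (partial windows renormalised).
boxcar_partial <- function(x, w) {
  n <- length(x)
  half <- w %/% 2L
  cs <- c(0, cumsum(x))
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + (w - half - 1L))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Signed-distance profile between oriented summits and feature centres
#'
#' Collects strand-aware signed distances from each oriented summit to all
#' feature centres within `max_dist` bp (upstream negative), and summarises
#' them as a histogram plus the median absolute distance.
#'
#' @param summits Data.frame `chrom`, `summit`, `strand`.
#' @param feature_centers Data.frame `chrom`, `pos`.
#' @param max_dist Maximum absolute distance in bp.
#' @param binwidth Histogram bin width in bp.
#' @return A list with `distances`, `breaks`, `density`, `median_abs`,
#'   `median_signed`.
#' @export
distance_profile <- function(summits, feature_centers, max_dist = 10000L,
                             binwidth = 100L) {
  A <- data.frame(chrom = summits$chrom, pos = summits$summit,
                  strand = summits$strand, stringsAsFactors = FALSE)
  d <- nearest_distances(A, feature_centers, max_dist = max_dist)$distance
  breaks <- seq.int(-max_dist, max_dist, by = binwidth)
  h <- if (length(d) > 0) {
    graphics::hist(d, breaks = breaks, plot = FALSE)$density
  } else {
    rep(0, length(breaks) - 1L)
  }
  list(distances = d, breaks = breaks, density = h,
       median_abs = if (length(d)) stats::median(abs(d)) else NA_real_,
       median_signed = if (length(d)) stats::median(d) else NA_real_)
}
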