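#' Origin-density profile across TADs in 100 bins
#'
#' Divides each TAD into `n_bins` equal bins, assigns each origin to a bin
#' by its summit (or interval midpoint when no `summit` column exists),
#' converts per-bin counts to a density per Mb using that TAD's bin length,
#' and averages the per-bin densities over TADs with equal weight. Bins 1-10
#' and 91-100 are "borders", bins 41-60 "centres".
#'
#' @param origins Interval data.frame (optionally with a `summit` column).
#' @param tads TAD interval data.frame.
#' @param n_bins Number of bins per TAD.
#' @return A list of class `tad_profile` with `bins` (mean density per Mb),
#'   `counts` (total origins per bin), `n_tads`, `n_skipped` (TADs shorter
#'   than `n_bins` bp), `border_bins`, `centre_bins`, and
#'   `border_centre_ratio` (mean border density / mean centre density).
#' @export
tad_density_profile <- function(origins, tads, n_bins = 100L) {
  pts <- origin_points(origins)
  usable <- tads$end - tads$start >= n_bins
  skipped <- sum(!usable)
  tads <- tads[usable, , drop = FALSE]
  if (nrow(tads) == 0L) stop("no TAD is at least ", n_bins, " bp long")
  dens <- matrix(0, nrow(tads), n_bins)
  counts <- numeric(n_bins)
  pts_split <- split(pts$pos, pts$chrom)
  for (i in seq_len(nrow(tads))) {
    s <- tads$start[i]; e <- tads$end[i]
    p <- pts_split[[tads$chrom[i]]]
    p <- p[p >= s & p < e]
    bin_len <- (e - s) / n_bins
    if (length(p) > 0L) {
      idx <- pmin(floor((p - s) / bin_len) + 1L, n_bins)
      tab <- tabulate(idx, nbins = n_bins)
      counts <- counts + tab
      dens[i, ] <- tab / (bin_len / 1e6)
    }
  }
  bins <- colMeans(dens)
  border <- c(1:10, 91:100)
  centre <- 41:60
  structure(list(bins = bins, counts = counts, n_tads = nrow(tads),
                 n_skipped = skipped, border_bins = border,
                 centre_bins = centre,
                 border_centre_ratio = mean(bins[border]) / mean(bins[centre])),
            class = "tad_profile")
}

origin_points <- function(origins) {
  pos <- if (!is.null(origins$summit)) origins$summit else
    (origins$start + origins$end) %/% 2L
  data.frame(chrom = origins$chrom, pos = pos, stringsAsFactors = FALSE)
}

#' Initiation-signal profile across TADs
#'
#' Sums a per-origin signal (e.g. normalized nascent-strand counts) into
#' the TAD bins holding each origin's summit/midpoint, and reports the
#' total border-to-centre signal ratio `sum(border bins) / sum(centre
#' bins)`.
#'
#' @param origins Interval data.frame with a `signal` column (and optional
#'   `summit`).
#' @param tads TAD interval data.frame.
#' @param n_bins Number of bins per TAD.
#' @return A list of class `tad_profile` with `bins` (summed signal),
#'   `n_tads`, `border_bins`, `centre_bins`, `border_centre_sum_ratio`.
#' @export
tad_signal_profile <- function(origins, tads, n_bins = 100L) {
  stopifnot(!is.null(origins$signal))
  pts <- origin_points(origins)
  pts$signal <- origins$signal
  usable <- tads$end - tads$start >= n_bins
  tads <- tads[usable, , drop = FALSE]
  if (nrow(tads) == 0L) stop("no TAD is at least ", n_bins, " bp long")
  bins <- numeric(n_bins)
  pts_split <- split(pts, pts$chrom)
  for (i in seq_len(nrow(tads))) {
    s <- tads$start[i]; e <- tads$end[i]
    p <- pts_split[[tads$chrom[i]]]
    if (is.null(p)) next
    p <- p[p$pos >= s & p$pos < e, , drop = FALSE]
    if (nrow(p) == 0L) next
    bin_len <- (e - s) / n_bins
    idx <- pmin(floor((p$pos - s) / bin_len) + 1L, n_bins)
    agg <- rowsum(p$signal, idx)
    bins[as.integer(rownames(agg))] <- bins[as.integer(rownames(agg))] +
      agg[, 1L]
  }
  border <- c(1:10, 91:100)
  centre <- 41:60
  centre_sum <- sum(bins[centre])
  if (centre_sum <= 0) stop("zero signal in TAD centre bins: ratio undefined")
  structure(list(bins = bins, n_tads = nrow(tads), n_skipped = sum(!usable),
                 border_bins = border, centre_bins = centre,
                 border_centre_sum_ratio = sum(bins[border]) / centre_sum),
            class = "tad_profile")
}

#' Normalise a TAD profile to its centre bins
#'
#' Divides the bin vector by the mean of the centre bins (41-60), so the
#' output's centre mean is 1 and border values read directly as
#' border-over-centre enrichment.
#'
#' @param profile A `tad_profile` or a numeric vector of bins.
#' @param centre_bins Indices of the centre bins.
#' @return Numeric vector of normalised bins.
#' @export
normalize_profile_to_centre <- function(profile, centre_bins = 41:60) {
  bins <- if (inherits(profile, "tad_profile")) profile$bins else profile
  cm <- mean(bins[centre_bins])
  if (!is.finite(cm) || cm <= 0) stop("centre mean is zero: cannot normalise")
  bins / cm
}
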