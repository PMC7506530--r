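#' Specification of a synthetic origin-bearing genome
#'
#' Defaults emulate the statistical structure the repertoire analysis
#' assumes: a background genome of 30% A, 30% T, 20% G, 20% C; planted
#' 1-kb origin cassettes whose paired-window composition satisfies the
#' hyper-motif thresholds (G-rich 500-bp window followed by a less G-rich
#' one, both A/T-poor); log-normal per-origin activity whose top two
#' deciles carry ~80% of the total signal (`sdlog = 1.68` from the
#' log-normal partial-expectation identity); nascent-strand coverage
#' peaking ~300 bp downstream of the cassette boundary; and equal-size TADs
#' with a tunable origin-density border enrichment.
#'
#' @param genome_length Genome length in bp (single chromosome).
#' @param base_probs Background base probabilities, named A/C/G/T.
#' @param n_origins Number of planted origin cassettes.
#' @param cassette List: `up_len`, `down_len` (bp), `up_G`, `down_G` (G
#'   fraction of the two windows), `A_frac`, `T_frac` (shared by both
#'   windows; C takes the remainder).
#' @param min_spacing Minimum gap in bp between planted cassettes.
#' @param n_samples Number of activity samples (the study design used 19).
#' @param activity_meanlog,activity_sdlog Log-normal latent activity
#'   parameters.
#' @param background_rate Poisson mean of per-origin background counts.
#' @param summit_offset Mean summit position downstream of the cassette
#'   boundary, bp.
#' @param summit_sd SD of read positions around the true summit, bp.
#' @param reads_per_origin Reads piled per origin for the coverage track.
#' @param tad_count Number of equal TADs tiling the genome.
#' @param border_factor Relative origin-placement weight of TAD border bins.
#' @param seed Integer seed driving all randomness.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(genome_length = 1e6,
                           base_probs = c(A = 0.30, C = 0.20,
                                          G = 0.20, T = 0.30),
                           n_origins = 50L,
                           cassette = list(up_len = 500L, down_len = 500L,
                                           up_G = 0.45, down_G = 0.30,
                                           A_frac = 0.15, T_frac = 0.15),
                           min_spacing = 2000L,
                           n_samples = 19L,
                           activity_meanlog = 1, activity_sdlog = 1.68,
                           background_rate = 1,
                           summit_offset = 300L, summit_sd = 50,
                           reads_per_origin = 200L,
                           tad_count = 10L, border_factor = 1,
                           seed = 1L) {
  stopifnot(abs(sum(base_probs) - 1) < 1e-8)
  span <- cassette$up_len + cassette$down_len
  if (n_origins * (span + min_spacing) >= genome_length) {
    stop("cannot place ", n_origins, " cassettes of span ", span,
         " with spacing ", min_spacing, " on a ", genome_length, " bp genome")
  }
  structure(as.list(environment()), class = "synthetic_spec")
}

# Derived seeds for the independent generator stages, kept below 2^31.
stage_seed <- function(seed, stage) {
  (as.integer(seed) * 1009L + stage * 7919L) %% 2000000011L
}

random_bases <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

# A permuted window holding the exact base counts implied by `probs`
# (largest-remainder rounding). Cassettes built this way have a
# deterministic composition, so a planted cassette sits exactly on the
# intended side of the scan thresholds; only its internal order is random.
exact_bases <- function(len, probs) {
  counts <- floor(len * probs)
  rem <- len - sum(counts)
  if (rem > 0) {
    frac <- len * probs - counts
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    counts[add] <- counts[add] + 1L
  }
  sample(rep(names(probs), counts))
}

# Composition of the two cassette windows as base-probability vectors.
cassette_probs <- function(cassette) {
  up_C <- 1 - cassette$up_G - cassette$A_frac - cassette$T_frac
  down_C <- 1 - cassette$down_G - cassette$A_frac - cassette$T_frac
  stopifnot(up_C >= 0, down_C >= 0)
  list(up = c(A = cassette$A_frac, C = up_C, G = cassette$up_G,
              T = cassette$T_frac),
       down = c(A = cassette$A_frac, C = down_C, G = cassette$down_G,
                T = cassette$T_frac))
}

#' Generate a synthetic genome with planted origin cassettes
#'
#' Draws an i.i.d. background genome from `base_probs`, then plants
#' `n_origins` cassettes at uniform non-overlapping positions snapped to
#' the 100-bp scan grid (so detection tests probe the thresholds, not
#' window phase), half on each orientation (reverse-complemented on the
#' forward strand for "-"), and records the ground truth.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `genome` (named `DNAStringSet`, one chromosome
#'   `chrS`) and `truth`, a data.frame `chrom`, `start`, `end`, `strand`,
#'   `boundary` (G-rich/less-G-rich window boundary), `summit` (true summit
#'   position).
#' @export
generate_genome <- function(spec) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(stage_seed(spec$seed, 1L))
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  L <- as.integer(spec$genome_length)
  bases <- random_bases(L, spec$base_probs)
  span <- spec$cassette$up_len + spec$cassette$down_len
  n <- spec$n_origins
  truth <- NULL
  if (n > 0L) {
    # uniform non-overlapping placement with spacing: draw sorted starts in
    # the "compressed" genome, then re-expand; snap to the 100-bp grid
    slot <- span + spec$min_spacing
    free <- L - n * slot
    starts <- sort(sample.int(free + 1L, n, replace = TRUE) - 1L) +
      (seq_len(n) - 1L) * slot
    starts <- pmin((starts %/% 100L) * 100L, L - span)
    strand <- sample(rep_len(c("+", "-"), n))
    probs <- cassette_probs(spec$cassette)
    for (i in seq_len(n)) {
      cas <- c(exact_bases(spec$cassette$up_len, probs$up),
               exact_bases(spec$cassette$down_len, probs$down))
      if (strand[i] == "-") {
        cas <- rev(c(A = "T", C = "G", G = "C", T = "A")[cas])
      }
      bases[(starts[i] + 1L):(starts[i] + span)] <- cas
    }
    boundary <- ifelse(strand == "+",
                       starts + spec$cassette$up_len,
                       starts + spec$cassette$down_len)
    summit <- ifelse(strand == "+",
                     boundary + spec$summit_offset,
                     boundary - spec$summit_offset)
    truth <- data.frame(chrom = "chrS", start = starts, end = starts + span,
                        strand = strand, boundary = as.integer(boundary),
                        summit = as.integer(summit),
                        stringsAsFactors = FALSE)
  } else {
    truth <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), strand = character(0),
                        boundary = integer(0), summit = integer(0))
  }
  genome <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(genome) <- "chrS"
  list(genome = genome, truth = truth)
}

#' Simulate per-origin activity and background count matrices
#'
#' Each origin gets a latent activity drawn from a log-normal; per-sample
#' counts are Poisson around the latent value, and background counts are
#' Poisson at `background_rate`.
#'
#' @param truth Truth data.frame from [generate_genome()].
#' @param spec A [synthetic_spec()].
#' @return A list with `counts`, `background` (origins x samples), and
#'   `latent` (true per-origin mean activity).
#' @export
simulate_activity <- function(truth, spec) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(stage_seed(spec$seed, 2L))
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  n <- nrow(truth)
  m <- spec$n_samples
  latent <- stats::rlnorm(n, spec$activity_meanlog, spec$activity_sdlog)
  counts <- matrix(stats::rpois(n * m, rep(latent, m)), n, m)
  background <- matrix(stats::rpois(n * m, spec$background_rate), n, m)
  colnames(counts) <- colnames(background) <- paste0("S", seq_len(m))
  list(counts = counts, background = background, latent = latent)
}

#' Simulate a nascent-strand coverage track
#'
#' Piles `reads_per_origin` read positions per origin, normally distributed
#' around the true summit, and returns the per-bp pileup as a
#' piecewise-constant coverage data.frame (origin-wise sums where piles
#' overlap).
#'
#' @param truth Truth data.frame from [generate_genome()].
#' @param spec A [synthetic_spec()].
#' @return A coverage data.frame `chrom`, `start`, `end`, `value`.
#' @export
simulate_coverage <- function(truth, spec) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(stage_seed(spec$seed, 3L))
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  if (nrow(truth) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), value = numeric(0)))
  }
  L <- as.integer(spec$genome_length)
  reads <- unlist(lapply(seq_len(nrow(truth)), function(i) {
    round(stats::rnorm(spec$reads_per_origin, truth$summit[i],
                       spec$summit_sd))
  }))
  reads <- reads[reads >= 0 & reads < L]
  pile <- table(reads)
  pos <- as.integer(names(pile))
  val <- as.numeric(pile)
  # collapse runs of equal value at consecutive positions
  brk <- c(TRUE, diff(pos) != 1L | diff(val) != 0)
  run <- cumsum(brk)
  start <- tapply(pos, run, min)
  end <- tapply(pos, run, max) + 1L
  value <- tapply(val, run, `[`, 1L)
  data.frame(chrom = truth$chrom[1L], start = as.integer(start),
             end = as.integer(end), value = as.numeric(value),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Simulate TADs and border-enriched origin placements
#'
#' Tiles the genome with `tad_count` equal TADs and places `n_points`
#' origin positions with per-bin placement weight `border_factor` in the
#' border bins (1-10 and 91-100 of 100) and 1 elsewhere.
#'
#' @param spec A [synthetic_spec()].
#' @param n_points Number of origin positions to place.
#' @return A list with `tads` (interval data.frame) and `origins`
#'   (data.frame `chrom`, `start`, `end`, `summit`).
#' @export
simulate_tads <- function(spec, n_points = 10000L) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(stage_seed(spec$seed, 4L))
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  L <- as.integer(spec$genome_length)
  k <- spec$tad_count
  edges <- floor(seq(0, L, length.out = k + 1L))
  tads <- data.frame(chrom = "chrS", start = edges[-(k + 1L)],
                     end = edges[-1L], stringsAsFactors = FALSE)
  n_bins <- 100L
  wts <- rep(1, n_bins)
  wts[c(1:10, 91:100)] <- spec$border_factor
  tad_idx <- sample.int(k, n_points, replace = TRUE)
  bin_idx <- sample.int(n_bins, n_points, replace = TRUE, prob = wts)
  u <- stats::runif(n_points)
  tl <- tads$end[tad_idx] - tads$start[tad_idx]
  pos <- floor(tads$start[tad_idx] + (bin_idx - 1L + u) * tl / n_bins)
  origins <- data.frame(chrom = "chrS", start = pos, end = pos + 1L,
                        summit = pos, stringsAsFactors = FALSE)
  list(tads = tads, origins = sort_intervals(origins))
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper running [generate_genome()], [simulate_activity()],
#' and [simulate_coverage()] from one spec.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `genome`, `truth`, `activity` (counts, background,
#'   latent), `coverage`, and the `spec` echo.
#' @export
simulate_dataset <- function(spec = synthetic_spec()) {
  g <- generate_genome(spec)
  act <- simulate_activity(g$truth, spec)
  cov <- simulate_coverage(g$truth, spec)
  list(genome = g$genome, truth = g$truth, activity = act,
       coverage = cov, spec = spec)
}

#' Plant decoy cassettes into an existing synthetic genome
#'
#' Decoys satisfy the hyper-motif thresholds (so the scanner retains them)
#' but differ from true origin cassettes in composition (default: the C
#' complement of the G-rich window is replaced by A/T within the A/T cap),
#' giving the machine-learning refinement a non-trivial discrimination
#' task. Decoys never receive activity, coverage, or truth summits.
#'
#' @param sim A dataset from [simulate_dataset()].
#' @param n_decoys Number of decoy cassettes.
#' @param decoy_cassette Cassette composition list (as in
#'   [synthetic_spec()]); the default keeps the true G architecture but
#'   moves C mass to A/T.
#' @return `sim` with modified `genome` and an added `decoys` truth
#'   data.frame.
#' @export
add_decoy_cassettes <- function(sim, n_decoys = 50L,
                                decoy_cassette = list(up_len = 500L,
                                                      down_len = 500L,
                                                      up_G = 0.45,
                                                      down_G = 0.30,
                                                      A_frac = 0.20,
                                                      T_frac = 0.20)) {
  spec <- sim$spec
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(stage_seed(spec$seed, 5L))
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  L <- as.integer(spec$genome_length)
  span <- decoy_cassette$up_len + decoy_cassette$down_len
  bases <- strsplit(as.character(sim$genome[[1L]]), "")[[1L]]
  # candidate grid positions far enough from true cassettes and each other
  grid <- seq.int(0L, L - span, by = 100L)
  occ <- rep(FALSE, length(grid))
  for (i in seq_len(nrow(sim$truth))) {
    bad <- grid < sim$truth$end[i] + spec$min_spacing &
      grid + span > sim$truth$start[i] - spec$min_spacing
    occ <- occ | bad
  }
  probs <- cassette_probs(decoy_cassette)
  placed <- integer(0)
  strand <- character(0)
  avail <- grid[!occ]
  for (i in seq_len(n_decoys)) {
    if (length(avail) == 0L) stop("no room for decoy ", i)
    p <- avail[sample.int(length(avail), 1L)]
    st <- sample(c("+", "-"), 1L)
    cas <- c(exact_bases(decoy_cassette$up_len, probs$up),
             exact_bases(decoy_cassette$down_len, probs$down))
    if (st == "-") cas <- rev(c(A = "T", C = "G", G = "C", T = "A")[cas])
    bases[(p + 1L):(p + span)] <- cas
    placed <- c(placed, p)
    strand <- c(strand, st)
    avail <- avail[avail >= p + span + spec$min_spacing |
                     avail + span <= p - spec$min_spacing]
  }
  genome <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(genome) <- names(sim$genome)
  sim$genome <- genome
  sim$decoys <- sort_intervals(
    data.frame(chrom = names(genome)[1L], start = placed,
               end = placed + span, strand = strand, stringsAsFactors = FALSE))
  sim
}
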