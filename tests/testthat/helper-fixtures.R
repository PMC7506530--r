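# Fixture builders and independent oracles, all generated in code.

# Random genome as a plain character string (independent of the package's
# generator) with given base probabilities.
random_genome_string <- function(length, probs = c(A = 0.30, C = 0.20,
                                                   G = 0.20, T = 0.30),
                                 seed = 1) {
  set.seed(seed)
  paste(sample(names(probs), length, replace = TRUE, prob = probs),
        collapse = "")
}

# Deterministic sequence with exact per-window base counts: each element of
# `counts` is a named vector c(A=,C=,G=,T=) summing to the window size; the
# bases are laid down in blocks (composition is all the scan measures).
blockseq <- function(counts_list) {
  paste(vapply(counts_list, function(ct) {
    paste(rep(names(ct), ct), collapse = "")
  }, ""), collapse = "")
}

# Brute-force hyper-motif scan oracle: character-level counting, a double
# loop over pair positions, thresholds applied literally. Independent of
# the package's Views/letterFrequency path.
brute_scan_pairs <- function(seqstr, window = 500, step = 100,
                             g1_min = 0.28, g2_min = 0.25,
                             drop_min = 0.08, drop_max = 0.40,
                             at_max = 0.21) {
  chars <- strsplit(seqstr, "")[[1]]
  L <- length(chars)
  starts <- integer(0); fwd <- logical(0); rev <- logical(0)
  p <- 0
  while (p + 2 * window <= L) {
    w1 <- chars[(p + 1):(p + window)]
    w2 <- chars[(p + window + 1):(p + 2 * window)]
    cnt <- function(w, b) sum(w == b)
    g1 <- cnt(w1, "G") / window; g2 <- cnt(w2, "G") / window
    c1 <- cnt(w1, "C") / window; c2 <- cnt(w2, "C") / window
    a <- (cnt(w1, "A") + cnt(w2, "A")) / (2 * window)
    t <- (cnt(w1, "T") + cnt(w2, "T")) / (2 * window)
    at_ok <- a <= at_max && t <= at_max
    f <- g1 >= g1_min && g2 >= g2_min &&
      (g1 - g2) >= drop_min && (g1 - g2) <= drop_max && at_ok
    r <- c2 >= g1_min && c1 >= g2_min &&
      (c2 - c1) >= drop_min && (c2 - c1) <= drop_max && at_ok
    if (f || r) {
      starts <- c(starts, p); fwd <- c(fwd, f); rev <- c(rev, r)
    }
    p <- p + step
  }
  data.frame(start = as.integer(starts), forward = fwd, reverse = rev)
}

# Reverse complement of a plain character string.
revcomp_string <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# A small deterministic coverage track: one rectangular stack.
stack_coverage <- function(chrom, start, end, value = 10) {
  data.frame(chrom = chrom, start = start, end = end, value = value,
             stringsAsFactors = FALSE)
}
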