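#!/usr/bin/env Rscript

# Stage 2: hyper-motif genome scan.
#
# Slides paired 500-bp windows (step 100 bp) over both orientations of the
# simulated genome and retains pairs with >= 28% G in the first window,
# >= 25% G in the second, an 8-40 percentage-point G drop, and at most 21%
# A and T over the pair; retained pairs are merged into candidate origin
# regions. Also calls simple G-rich regions (> 37% G per 500-bp window)
# for comparison.

library(oriscan)

genome <- read_genome_fasta("results/sim/genome.fa")
truth <- read_intervals("results/sim/truth.bed", "BED6")
decoys <- read_intervals("results/sim/decoys.bed", "BED6")

scan <- scan_genome(genome)
reg <- scan$regions
message("retained window pairs: ", scan$n_pairs,
        " (forward ", scan$n_pairs_forward,
        ", reverse ", scan$n_pairs_reverse, ")")
message("merged candidate regions: ", nrow(reg),
        "; mean length ", round(mean(reg$end - reg$start)), " bp")

sens <- overlap_count(truth, reg) / nrow(truth)
dec <- overlap_count(decoys, reg) / nrow(decoys)
message("planted-cassette sensitivity: ", round(sens, 4),
        "; decoy retention: ", round(dec, 4))

grich <- grich_regions(genome)
message("simple G-rich regions (>37% G / 500 bp): ", nrow(grich))

dir.create("results", showWarnings = FALSE)
reg$name <- "."
reg$score <- reg$n_pairs
write_intervals(reg, "results/candidates.bed", dialect = "BED6")
write.table(scan$pairs, "results/retained_pairs.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write_intervals(grich, "results/grich_regions.bed", dialect = "BED3")

# shuffle-based enrichment of candidates over planted origins
enr <- overlap_enrichment(truth, reg, genome, seed = 1, n_shuffles = 50)
message("candidate/origin overlap: observed ", enr$observed,
        ", expected ", round(enr$expected, 1),
        ", chi2 ", round(enr$chi2, 1), ", p ", signif(enr$p, 3))
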