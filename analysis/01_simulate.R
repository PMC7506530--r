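#!/usr/bin/env Rscript

# Stage 1: build the synthetic study dataset.
#
# A 2-Mb genome (30% A, 30% T, 20% G, 20% C) with 200 planted origin
# cassettes (G-rich 500-bp window followed by a less G-rich one, half on
# each strand), 19 samples of log-normal origin activity with Poisson
# background, and a nascent-strand coverage track peaking ~300 bp
# downstream of each cassette boundary. Everything is seeded; rerunning
# reproduces identical files.

library(oriscan)

outdir <- "results/sim"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

spec <- synthetic_spec(genome_length = 2e6, n_origins = 200, seed = 1)
sim <- simulate_dataset(spec)
sim <- add_decoy_cassettes(sim, n_decoys = 200)

write_genome_fasta(sim$genome, file.path(outdir, "genome.fa"))
write_intervals(cbind(sim$truth, name = "."),
                file.path(outdir, "truth.bed"), dialect = "BED6")
write_intervals(cbind(sim$decoys, name = "."),
                file.path(outdir, "decoys.bed"), dialect = "BED6")
write.table(data.frame(sim$truth[, c("chrom", "start", "end")],
                       summit = sim$truth$summit),
            file.path(outdir, "truth_summits.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sim$activity$counts, file.path(outdir, "counts.tsv"),
            sep = "\t", quote = FALSE)
write.table(sim$activity$background, file.path(outdir, "background.tsv"),
            sep = "\t", quote = FALSE)
write_coverage(sim$coverage, file.path(outdir, "coverage.bedGraph"))

message("genome: ", sum(Biostrings::width(sim$genome)), " bp; ",
        nrow(sim$truth), " true origins; ", nrow(sim$decoys),
        " decoy cassettes; ", ncol(sim$activity$counts), " samples")
message("wrote ", outdir, "/{genome.fa,truth.bed,decoys.bed,counts.tsv,",
        "background.tsv,coverage.bedGraph}")
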