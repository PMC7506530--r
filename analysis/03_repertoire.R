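#!/usr/bin/env Rscript

# Stage 3: origin repertoire analytics.
#
# Background-subtracts and TMM-scales the activity matrix, ranks origins
# into deciles (Q1 = most active; Q1-Q2 = core, Q3-Q10 = stochastic,
# > 50 normalized counts = super), calls coverage summits (50-bp bins,
# 25-bp steps), orients origins by flanking G content, clusters core
# origins (7-kb gap; tight >= 6 members, isolated > 15 kb), and profiles
# base composition and upstream-feature distances around oriented summits.

library(oriscan)

genome <- read_genome_fasta("results/sim/genome.fa")
truth <- read_intervals("results/sim/truth.bed", "BED6")
counts <- as.matrix(read.delim("results/sim/counts.tsv"))
background <- as.matrix(read.delim("results/sim/background.tsv"))
coverage <- read_coverage("results/sim/coverage.bedGraph")

norm <- normalize_activity(counts, background)
q <- classify_quantiles(norm$mean_activity)
message("origins: ", nrow(truth), "; core ", sum(q$klass == "core"),
        ", stochastic ", sum(q$klass == "stochastic"),
        ", super ", sum(q$super))

fr <- signal_fraction_by_class(norm$normalized, q$klass)
message("core origins host ",
        round(100 * mean(fr["core", ]), 1),
        "% of total initiation signal (per-sample range ",
        round(100 * min(fr["core", ]), 1), "-",
        round(100 * max(fr["core", ]), 1), "%)")

summits <- call_summits(coverage, truth)
strand <- orient_origins(genome, data.frame(chrom = truth$chrom,
                                            summit = summits$summit))
repertoire <- data.frame(truth[, c("chrom", "start", "end")],
                         summit = summits$summit, strand = strand,
                         mean_activity = norm$mean_activity,
                         quantile = q$quantile, klass = q$klass,
                         super = q$super)

core <- repertoire[repertoire$klass == "core", ]
cc <- cluster_origins(core)
message("core-origin cluster classes: ",
        paste(names(table(cc$cluster_class)),
              table(cc$cluster_class), collapse = ", "))

write.table(repertoire, "results/repertoire.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

# oriented base-composition profile around summits
prof <- composition_profile(genome,
                            data.frame(chrom = repertoire$chrom,
                                       summit = repertoire$summit,
                                       strand = repertoire$strand))
write.table(data.frame(offset = prof$offset, prof$profile),
            "results/composition_profile.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
up_g <- mean(prof$profile[prof$offset < -300 & prof$offset >= -800, "G"])
down_g <- mean(prof$profile[prof$offset >= 0 & prof$offset < 500, "G"])
message("mean G frequency upstream (-800..-300): ", round(up_g, 3),
        " vs downstream (0..500): ", round(down_g, 3))

# distance from the oriented summit to the planted cassette boundary
boundary <- data.frame(chrom = truth$chrom,
                       pos = ifelse(strand == "+",
                                    truth$start + 500L, truth$end - 500L))
dp <- distance_profile(data.frame(chrom = repertoire$chrom,
                                  summit = repertoire$summit,
                                  strand = repertoire$strand),
                       boundary, max_dist = 2000L)
message("median |summit - cassette boundary| distance: ", dp$median_abs,
        " bp (signed median ", dp$median_signed, ")")
write.table(data.frame(mid = head(dp$breaks, -1) + 50, density = dp$density),
            "results/boundary_distance_profile.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
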