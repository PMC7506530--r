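#!/usr/bin/env Rscript

# Stage 5: origin density across TADs.
#
# Simulates TAD-partitioned genomes with origins placed uniformly
# (border_factor 1) and with a 3-fold border enrichment, profiles origin
# density in 100 bins per TAD (bins 1-10 and 91-100 = borders, 41-60 =
# centres), normalises profiles to the centre bins, and reports the
# border/centre ratios.

library(oriscan)

profiles <- list()
for (bf in c(1, 3)) {
  spec <- synthetic_spec(genome_length = 1e7, tad_count = 20,
                         border_factor = bf, seed = 1)
  ts <- simulate_tads(spec, n_points = 10000)
  prof <- tad_density_profile(ts$origins, ts$tads)
  message("border_factor ", bf, ": border/centre density ratio ",
          round(prof$border_centre_ratio, 3),
          " over ", prof$n_tads, " TADs")
  profiles[[paste0("bf", bf)]] <- normalize_profile_to_centre(prof)
}

# signal-weighted profile with a 1.53-fold planted border weighting
spec <- synthetic_spec(genome_length = 1e7, tad_count = 20,
                       border_factor = 1, seed = 2)
ts <- simulate_tads(spec, n_points = 10000)
rel <- (ts$origins$start %% 500000) / 500000
sig <- ts$origins
sig$signal <- ifelse(rel < 0.10 | rel >= 0.90, 1.53, 1)
sp <- tad_signal_profile(sig, ts$tads)
message("planted 1.53-fold border signal: recovered sum ratio ",
        round(sp$border_centre_sum_ratio, 3))

dir.create("results", showWarnings = FALSE)
write.table(data.frame(bin = 1:100,
                       uniform = profiles$bf1,
                       border3x = profiles$bf3),
            "results/tad_profiles.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
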