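test_that("generation is byte-identical under a fixed seed", {
  spec <- synthetic_spec(genome_length = 50000, n_origins = 5, seed = 101)
  a <- generate_genome(spec)
  b <- generate_genome(spec)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$truth, b$truth)
  expect_false(identical(
    as.character(generate_genome(synthetic_spec(genome_length = 50000,
                                                n_origins = 5,
                                                seed = 102))$genome),
    as.character(a$genome)))
})

test_that("background composition matches the base probabilities", {
  spec <- synthetic_spec(genome_length = 100000, n_origins = 0, seed = 103)
  g <- generate_genome(spec)$genome
  gfrac <- Biostrings::letterFrequency(g[[1]], "G")[[1]] / 100000
  # binomial: sd = sqrt(0.2 * 0.8 / 1e5) ~ 0.00126
  expect_lt(abs(gfrac - 0.20), 3 * sqrt(0.2 * 0.8 / 100000))
  afrac <- Biostrings::letterFrequency(g[[1]], "A")[[1]] / 100000
  expect_lt(abs(afrac - 0.30), 3 * sqrt(0.3 * 0.7 / 100000))
})

test_that("planted cassettes satisfy the hyper-motif thresholds in place", {
  spec <- synthetic_spec(genome_length = 200000, n_origins = 10, seed = 104)
  sim <- generate_genome(spec)
  comp <- window_compositions(sim$genome[[1]])
  keep <- hypermotif_filter(comp$counts1, comp$counts2)
  retained <- comp$start[keep$forward | keep$reverse]
  expect_true(all(sim$truth$start %in% retained))
  # orientation of retention matches the planted strand
  fwd_starts <- comp$start[keep$forward]
  plus <- sim$truth[sim$truth$strand == "+", ]
  expect_true(all(plus$start %in% fwd_starts))
  # spacing and non-overlap of the truth set
  expect_true(all(diff(sim$truth$start) >= 1000 + spec$min_spacing))
})

test_that("out-of-threshold cassettes are rejected by the scan", {
  # drop exactly 0.05 (below drop_min 0.08) on both the G and the mirrored
  # C reading; A/T exactly at the 0.21 cap so background-mixed edge windows
  # exceed it and cannot leak in
  spec <- synthetic_spec(genome_length = 200000, n_origins = 10, seed = 105,
                         cassette = list(up_len = 500L, down_len = 500L,
                                         up_G = 0.30, down_G = 0.25,
                                         A_frac = 0.21, T_frac = 0.21))
  sim <- generate_genome(spec)
  sc <- scan_genome(sim$genome)
  # exact-count cassettes sit deterministically below the drop threshold;
  # only a rare background/cassette mixture window could graze a region
  expect_lte(overlap_count(sim$truth, sc$regions), 1L)
  comp <- window_compositions(sim$genome[[1]])
  keep <- hypermotif_filter(comp$counts1, comp$counts2)
  retained <- comp$start[keep$forward | keep$reverse]
  expect_false(any(sim$truth$start %in% retained))
})

test_that("activity simulation follows the latent log-normal structure", {
  spec <- synthetic_spec(genome_length = 100000, n_origins = 20, seed = 106,
                         activity_sdlog = 0, n_samples = 5)
  sim <- generate_genome(spec)
  act <- simulate_activity(sim$truth, spec)
  expect_true(all(act$latent == act$latent[1]))  # sdlog 0: equal means
  expect_equal(dim(act$counts), c(20L, 5L))

  spec0 <- synthetic_spec(genome_length = 100000, n_origins = 20, seed = 107,
                          background_rate = 0)
  act0 <- simulate_activity(generate_genome(spec0)$truth, spec0)
  expect_true(all(act0$background == 0))
})

test_that("large activity dispersion concentrates signal in the top deciles", {
  # at sdlog = 1.68 the top two deciles of a log-normal carry ~80% of the
  # mass: share = Phi(sdlog - qnorm(0.8))
  spec <- synthetic_spec(genome_length = 2e6, n_origins = 500, seed = 108,
                         min_spacing = 1000L)
  sim <- generate_genome(spec)
  act <- simulate_activity(sim$truth, spec)
  norm <- normalize_activity(act$counts, act$background)
  q <- classify_quantiles(norm$mean_activity)
  fr <- signal_fraction_by_class(norm$normalized, q$klass)
  # partial-expectation share Phi(sdlog - z_0.8) ~ 0.799; Monte-Carlo of
  # the top-quintile share at n = 500 gives SD ~ 0.029 (heavy tail), so a
  # 4-SD band is ~ +/- 0.12
  expected_share <- pnorm(1.68 - qnorm(0.8))
  expect_lt(abs(mean(fr["core", ]) - expected_share), 0.12)
})

test_that("coverage piles recover the planted summits", {
  spec <- synthetic_spec(genome_length = 200000, n_origins = 10, seed = 109)
  sim <- generate_genome(spec)
  cov <- simulate_coverage(sim$truth, spec)
  expect_true(all(cov$value > 0))
  called <- call_summits(cov, sim$truth)
  expect_true(all(abs(called$summit - sim$truth$summit) <= 50))

  # no origins -> empty track
  spec0 <- synthetic_spec(genome_length = 50000, n_origins = 0, seed = 110)
  sim0 <- generate_genome(spec0)
  expect_equal(nrow(simulate_coverage(sim0$truth, spec0)), 0L)
})

test_that("TAD simulation tiles the genome and honours the border factor", {
  spec <- synthetic_spec(genome_length = 1e6, tad_count = 10, seed = 111,
                         border_factor = 1)
  ts <- simulate_tads(spec, n_points = 20000)
  expect_equal(ts$tads$start[1], 0L)
  expect_equal(ts$tads$end[nrow(ts$tads)], 1000000)
  expect_true(all(ts$tads$start[-1] == ts$tads$end[-nrow(ts$tads)]))
  prof <- tad_density_profile(ts$origins, ts$tads)
  # uniform placement: ratio within Monte-Carlo noise of 1
  se <- sqrt(1 / (20000 * 0.2) + 1 / (20000 * 0.2))
  expect_lt(abs(prof$border_centre_ratio - 1), 3 * se)
})

test_that("decoy cassettes pass the scan but never overlap true origins", {
  spec <- synthetic_spec(genome_length = 500000, n_origins = 20, seed = 112)
  sim <- simulate_dataset(spec)
  sim <- add_decoy_cassettes(sim, n_decoys = 20,
                             decoy_cassette = list(up_len = 500L,
                                                   down_len = 500L,
                                                   up_G = 0.45, down_G = 0.30,
                                                   A_frac = 0.18,
                                                   T_frac = 0.18))
  expect_equal(overlap_count(sim$decoys, sim$truth), 0L)
  sc <- scan_genome(sim$genome)
  expect_gte(overlap_count(sim$decoys, sc$regions) / nrow(sim$decoys), 0.9)
  # true cassettes still detected
  expect_equal(overlap_count(sim$truth, sc$regions), nrow(sim$truth))
})
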