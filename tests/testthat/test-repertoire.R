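test_that("background subtraction and TMM scaling behave at fixed points", {
  cts <- matrix(rpois(200, 20), 50, 4)
  # background equal to counts -> all zeros (and a zero-total warning)
  expect_warning(res <- normalize_activity(cts, cts), "zero total")
  expect_true(all(res$normalized == 0))

  # identical samples -> all scale factors 1
  same <- matrix(rep(rpois(50, 30), 4), 50, 4)
  res <- normalize_activity(same)
  expect_equal(unname(res$scale_factors), rep(1, 4), tolerance = 1e-8)

  # one sample exactly 2x the other -> factors {1, 2} within 1%
  set.seed(2)
  base <- rpois(200, 50) + 1
  two <- cbind(S1 = base, S2 = 2L * base)
  res <- normalize_activity(two)
  expect_equal(unname(res$scale_factors), c(1, 2), tolerance = 0.01)
  # after scaling the two samples agree
  expect_equal(res$normalized[, 1], res$normalized[, 2], tolerance = 1e-6)

  # invariance to a common rescaling of all samples (up to that factor)
  res3 <- normalize_activity(two * 3)
  expect_equal(res3$mean_activity, res$mean_activity * 3, tolerance = 1e-6)
  expect_equal(res3$scale_factors, res$scale_factors, tolerance = 1e-6)
})

test_that("negative background-subtracted values clamp to zero", {
  cts <- matrix(c(5, 0), 1, 2)
  bg <- matrix(c(10, 0), 1, 2)
  expect_warning(res <- normalize_activity(cts, bg))
  expect_true(all(res$normalized >= 0))
})

test_that("decile classification follows the rank and remainder rules", {
  # 20 origins with distinct activities: Q1 = top 2, core = top 4
  act <- seq(200, 10, by = -10)
  q <- classify_quantiles(act)
  expect_equal(which(q$quantile == 1), 1:2)
  expect_equal(which(q$klass == "core"), 1:4)
  expect_equal(q$klass[5:20], rep("stochastic", 16))

  # super origins flagged above 50 normalized counts
  expect_equal(q$super, act > 50)

  # remainder goes to the lowest-activity quantiles
  q2 <- classify_quantiles(seq_len(105))
  expect_equal(as.vector(table(q2$quantile)),
               c(rep(10L, 5), rep(11L, 5)))

  # all activities equal: partition survives on the tie-break alone
  q3 <- classify_quantiles(rep(1, 30))
  expect_equal(as.vector(table(q3$quantile)), rep(3L, 10))
  expect_equal(q3$quantile, rep(1:10, each = 3))
})

test_that("quantile labels always partition with near-equal sizes", {
  set.seed(11)
  for (n in c(50, 123, 9999)) {
    q <- classify_quantiles(rlnorm(n))
    tab <- table(q$quantile)
    expect_length(tab, 10L)
    expect_lte(diff(range(tab)), 1L)
    expect_equal(sum(tab), n)
    # klass is a function of quantile
    expect_true(all((q$quantile <= 2) == (q$klass == "core")))
  }
})

test_that("signal fractions per class sum to one and match direct sums", {
  norm <- matrix(runif(300), 100, 3)
  klass <- rep(c("core", "stochastic"), c(20, 80))
  fr <- signal_fraction_by_class(norm, klass)
  expect_equal(unname(colSums(fr)), rep(1, 3))
  expect_equal(unname(fr["core", 1]), sum(norm[1:20, 1]) / sum(norm[, 1]))

  # all signal on one core origin
  one <- matrix(0, 10, 2); one[1, ] <- 5
  fr1 <- signal_fraction_by_class(one, rep(c("core", "stochastic"), c(2, 8)))
  expect_equal(unname(fr1["core", ]), c(1, 1))

  # uniform signal -> core fraction equals the core share of origins
  unif <- matrix(1, 100, 2)
  fr2 <- signal_fraction_by_class(unif, rep(c("core", "stochastic"), c(20, 80)))
  expect_equal(unname(fr2["core", ]), c(0.2, 0.2))

  expect_error(signal_fraction_by_class(matrix(0, 5, 1), rep("a", 5)),
               "zero total")
})

test_that("summit calling finds the maximal bin with leftmost ties", {
  iv <- data.frame(chrom = "c1", start = 0L, end = 500L)
  # single 50-bp stack at [100,150) -> summit 125
  s <- call_summits(stack_coverage("c1", 100L, 150L), iv)
  expect_equal(s$summit, 125L)
  expect_false(s$no_signal)

  # two equal stacks -> leftmost midpoint
  cov2 <- rbind(stack_coverage("c1", 100L, 150L),
                stack_coverage("c1", 300L, 350L))
  expect_equal(call_summits(cov2, iv)$summit, 125L)

  # triangular coverage peaking at 400 -> summit within one bin of the peak
  tri <- data.frame(chrom = "c1", start = 350:449, end = 351:450,
                    value = c(1:50, 50:1))
  iv2 <- data.frame(chrom = "c1", start = 0L, end = 800L)
  s3 <- call_summits(tri, iv2)$summit
  expect_lte(abs(s3 - 400L), 25L)

  # zero coverage -> interval midpoint, flagged
  s4 <- call_summits(stack_coverage("c2", 0L, 10L), iv)
  expect_equal(s4$summit, 250L)
  expect_true(s4$no_signal)
})

test_that("orientation puts the G-richer flank upstream", {
  left_rich <- paste0(paste(rep("G", 500), collapse = ""),
                      paste(rep("A", 500), collapse = ""))
  g <- c(c1 = left_rich)
  expect_equal(orient_origins(g, data.frame(chrom = "c1", summit = 500L)), "+")
  mirror <- c(c1 = paste(rev(strsplit(left_rich, "")[[1]]), collapse = ""))
  expect_equal(orient_origins(mirror, data.frame(chrom = "c1", summit = 500L)),
               "-")
  # equal counts tie to "+"
  even <- c(c1 = paste(rep("GA", 500), collapse = ""))
  expect_equal(orient_origins(even, data.frame(chrom = "c1", summit = 500L)),
               "+")
})

test_that("core-origin clustering assigns tight, loose, and isolated classes", {
  # six origins each 5 kb apart -> one tight cluster
  six <- data.frame(chrom = "c1", start = seq(0, by = 6000, length.out = 6),
                    end = seq(0, by = 6000, length.out = 6) + 1000L)
  cc <- cluster_origins(six)
  expect_equal(unique(cc$cluster_id), 1L)
  expect_equal(cc$cluster_class, rep("tight", 6))

  # pair 10 kb apart -> each loose; singleton 20 kb away -> isolated
  mix <- data.frame(chrom = "c1",
                    start = c(0L, 11000L, 40000L),
                    end = c(1000L, 12000L, 41000L))
  cm <- cluster_origins(mix)
  expect_equal(cm$cluster_class, c("loose", "loose", "isolated"))
})

test_that("composition profile is strand-aware and sums to one", {
  # identical planted sequence at every summit -> frequency 1 at each offset
  word <- random_genome_string(200, seed = 30)
  g <- c(c1 = paste0(word, word, word))
  summits <- data.frame(chrom = "c1", summit = c(100L, 300L, 500L),
                        strand = "+")
  cp <- composition_profile(g, summits, flank = 100L, smooth = 1L)
  expect_true(all(apply(cp$profile, 1, max) == 1))
  expect_equal(rowSums(cp$profile), rep(1, 200), tolerance = 1e-12)

  # a minus-strand origin contributes its reverse complement
  s <- paste0(paste(rep("A", 100), collapse = ""),
              paste(rep("G", 100), collapse = ""))
  g2 <- c(c1 = s)
  plus <- composition_profile(g2, data.frame(chrom = "c1", summit = 100L,
                                             strand = "+"),
                              flank = 50L, smooth = 1L)
  minus <- composition_profile(g2, data.frame(chrom = "c1", summit = 100L,
                                              strand = "-"),
                               flank = 50L, smooth = 1L)
  expect_equal(unname(plus$profile[1, "A"]), 1)
  expect_equal(unname(minus$profile[1, "C"]), 1)

  # random background genome -> profile flat near the base probabilities
  bg <- c(c1 = random_genome_string(60000, seed = 31))
  sm <- data.frame(chrom = "c1",
                   summit = as.integer(seq(2000, 58000, length.out = 40)),
                   strand = "+")
  cpf <- composition_profile(bg, sm, flank = 1000L, smooth = 100L)
  expect_lt(max(abs(colMeans(cpf$profile) -
                      c(A = 0.3, C = 0.2, G = 0.2, T = 0.3))), 0.02)

  # summits too close to the edge are skipped and counted
  cpe <- composition_profile(bg, rbind(sm, data.frame(chrom = "c1",
                                                      summit = 10L,
                                                      strand = "+")),
                             flank = 1000L)
  expect_equal(cpe$n_skipped, 1L)
  expect_equal(cpe$n_used, 40L)
})

test_that("distance profiles recover planted upstream offsets", {
  # spacing beyond 2*max_dist so each summit sees only its own feature
  summits <- data.frame(chrom = "c1",
                        summit = seq(5000L, 230000L, by = 25000L),
                        strand = "+")
  feats <- data.frame(chrom = "c1", pos = summits$summit - 300L)
  dp <- distance_profile(summits, feats)
  expect_equal(dp$median_signed, -300)
  expect_equal(dp$median_abs, 300)

  # on the minus strand the same geometry flips sign
  summits$strand <- "-"
  expect_equal(distance_profile(summits, feats)$median_signed, 300)

  # features beyond the window give an empty profile
  far <- data.frame(chrom = "c1", pos = summits$summit + 12000L)
  dpf <- distance_profile(summits, far)
  expect_length(dpf$distances, 0L)
  expect_true(all(dpf$density == 0))
})
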