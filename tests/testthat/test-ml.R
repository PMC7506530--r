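test_that("balanced accuracy matches exact length arithmetic", {
  span <- c(c1 = 1000)
  truth <- data.frame(chrom = "c1", start = 0L, end = 100L)
  # pred == truth -> 1
  expect_equal(balanced_accuracy(truth, truth, span)$ba, 1)
  # pred = whole genome -> 0.5 * (1 + 0)
  whole <- data.frame(chrom = "c1", start = 0L, end = 1000L)
  expect_equal(balanced_accuracy(whole, truth, span)$ba, 0.5)
  # worked case: truth [0,100), pred [50,150)
  pred <- data.frame(chrom = "c1", start = 50L, end = 150L)
  res <- balanced_accuracy(pred, truth, span)
  expect_equal(res$TP, 50)
  expect_equal(res$FP, 50)
  expect_equal(res$FN, 50)
  expect_equal(res$TN, 850)
  expect_equal(res$ba, 0.5 * (50 / 100 + 850 / 900))
})

test_that("balanced accuracy is symmetric under complementation", {
  set.seed(7)
  span <- c(c1 = 5000)
  mk <- function() {
    s <- sort(sample.int(4800, 6))
    merge_intervals(data.frame(chrom = "c1", start = s, end = s + 150L))
  }
  complement <- function(x) {
    edges <- c(0L, as.vector(t(cbind(x$start, x$end))), 5000L)
    m <- matrix(edges, ncol = 2, byrow = TRUE)
    keep <- m[, 2] > m[, 1]
    data.frame(chrom = "c1", start = m[keep, 1], end = m[keep, 2])
  }
  for (i in 1:5) {
    pred <- mk(); truth <- mk()
    a <- balanced_accuracy(pred, truth, span)$ba
    b <- balanced_accuracy(complement(pred), complement(truth), span)$ba
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("k-fold splits are disjoint, balanced, and seed-stable", {
  f <- kfold_split(100, 10, seed = 3)
  expect_equal(as.vector(table(f)), rep(10L, 10))
  expect_identical(f, kfold_split(100, 10, seed = 3))
  expect_false(identical(f, kfold_split(100, 10, seed = 4)))
  f2 <- kfold_split(23, 5, seed = 1)
  expect_lte(diff(range(table(f2))), 1L)
  expect_equal(sum(table(f2)), 23L)
})

# Synthetic candidate geometry: widely spaced window pairs so merging is
# the identity and region scoring reduces to per-pair scoring.
spaced_candidates <- function(n) {
  data.frame(chrom = "c1", start = seq(0L, by = 10000L, length.out = n))
}

test_that("greedy selection recovers a single generating feature with its sign", {
  set.seed(5)
  n <- 300
  X <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(NULL, c("UP_G_fraction", paste0("noise", 1:5))))
  # labels depend only on UP_G_fraction through a steep logistic curve
  y <- rbinom(n, 1, plogis(6 * X[, "UP_G_fraction"]))
  m <- greedy_lr_select(X, y, spaced_candidates(n), seed = 2)
  expect_equal(m$selected_features[1], "UP_G_fraction")
  expect_gt(unname(m$coefficients["UP_G_fraction"]), 0)
  expect_gt(m$cv_balanced_accuracy, 0.8)
  # trajectory of accepted balanced accuracies is non-decreasing
  expect_true(all(diff(m$cv_trajectory) >= 0))
})

test_that("perfect separation by one feature yields near-perfect CV accuracy", {
  n <- 200
  set.seed(6)
  X <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(NULL, c("sep", paste0("noise", 1:3))))
  y <- as.integer(X[, "sep"] > 0)
  m <- greedy_lr_select(X, y, spaced_candidates(n), seed = 8)
  expect_equal(m$selected_features[1], "sep")
  expect_gt(m$cv_balanced_accuracy, 0.95)
})

test_that("uninformative features stop selection near the null accuracy", {
  set.seed(9)
  n <- 300
  X <- matrix(rnorm(n * 8), n, 8,
              dimnames = list(NULL, paste0("f", 1:8)))
  y <- rbinom(n, 1, 0.5)
  m <- greedy_lr_select(X, y, spaced_candidates(n), seed = 10)
  # the greedy CV maximum carries selection noise; it must stay near 0.5
  expect_lt(abs(m$cv_balanced_accuracy - 0.5), 0.1)
  expect_lte(length(m$selected_features), 2L)
})

test_that("greedy selection with a fixed seed is bit-reproducible", {
  set.seed(12)
  n <- 150
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- as.integer(X[, 1] + 0.5 * rnorm(n) > 0)
  m1 <- greedy_lr_select(X, y, spaced_candidates(n), seed = 77)
  m2 <- greedy_lr_select(X, y, spaced_candidates(n), seed = 77)
  expect_identical(m1$selected_features, m2$selected_features)
  expect_identical(m1$coefficients, m2$coefficients)
  expect_identical(m1$cv_balanced_accuracy, m2$cv_balanced_accuracy)
})

test_that("sparse SVM selects the informative feature and prunes noise", {
  set.seed(13)
  n <- 300
  X <- matrix(rnorm(n * 22), n, 22,
              dimnames = list(NULL, paste0("f", 1:22)))
  y <- as.integer(X[, "f1"] > 0)
  m <- sparse_svm_train(X, y, spaced_candidates(n), seed = 14)
  expect_true("f1" %in% m$selected_features)
  expect_gt(abs(m$coefficients["f1"]),
            max(abs(m$coefficients[-1]), 1e-12))
  expect_gt(m$cv_balanced_accuracy, 0.9)
  # most noise weights vanish at the selected penalty
  expect_gte(sum(m$coefficients[-1] == 0), 15L)
  # same seed and grid -> identical choice
  m2 <- sparse_svm_train(X, y, spaced_candidates(n), seed = 14)
  expect_identical(m$penalty, m2$penalty)
  expect_identical(m$coefficients, m2$coefficients)
})

test_that("an overwhelming SVM penalty zeroes all weights and scores 0.5", {
  set.seed(15)
  n <- 100
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- as.integer(X[, 1] > 0)
  fit <- oriscan:::svm_l1_fit(X, y, lambda = 1e6)
  expect_true(all(fit$w == 0))
  pred <- oriscan:::svm_l1_predict(fit, X)
  expect_equal(length(unique(pred)), 1L)
  ba <- oriscan:::pair_region_ba(spaced_candidates(n), pred == 1, y == 1)
  expect_equal(ba, 0.5)
})

test_that("prediction merges positive windows into sorted disjoint regions", {
  g <- c(c1 = random_genome_string(30000, seed = 50))
  cand <- data.frame(chrom = "c1", start = c(2000L, 2100L, 9000L))
  X <- matrix(1, 3, 1, dimnames = list(NULL, "f"))
  model <- structure(list(method = "greedy_lr", selected_features = "f",
                          coefficients = c(f = 10), intercept = -5),
                     class = "trained_model")
  pr <- predict_genome(model, X, cand)
  expect_equal(pr$regions$start, c(2000L, 9000L))
  expect_equal(pr$regions$end, c(3100L, 10000L))

  none <- structure(list(method = "greedy_lr",
                         selected_features = character(0),
                         coefficients = numeric(0), intercept = 0),
                    class = "trained_model")
  expect_equal(nrow(predict_genome(none, X, cand)$regions), 0L)
})

test_that("prediction evaluation reports per-quantile sensitivity and FPR", {
  origins <- data.frame(chrom = "c1",
                        start = seq(0L, 9000L, by = 1000L),
                        end = seq(0L, 9000L, by = 1000L) + 500L,
                        quantile = rep(1:2, each = 5))
  # predictions identical to origins
  ev <- evaluate_predictions(origins[, 1:3], origins)
  expect_equal(unname(ev$sensitivity["all"]), 1)
  expect_equal(unname(ev$fpr), 0)
  # disjoint predictions
  far <- data.frame(chrom = "c1", start = 20000L, end = 21000L)
  ev2 <- evaluate_predictions(far, origins)
  expect_equal(unname(ev2$sensitivity["all"]), 0)
  expect_equal(ev2$fpr, 1)
  # half of predictions overlap truth -> FPR 0.5 by direct counting
  half <- rbind(origins[1:5, 1:3],
                data.frame(chrom = "c1", start = seq(30000L, 34000L, 1000L),
                           end = seq(30000L, 34000L, 1000L) + 500L))
  ev3 <- evaluate_predictions(half, origins)
  expect_equal(ev3$fpr, 0.5)
  expect_equal(unname(ev3$sensitivity["Q1"]), 1)
  expect_equal(unname(ev3$sensitivity["Q2"]), 0)
})
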