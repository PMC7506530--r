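#' Length-weighted balanced accuracy of region predictions
#'
#' Computes the confusion categories as base-pair lengths by interval set
#' algebra over an evaluated span: TP = |pred intersect truth|, FP = |pred
#' minus truth|, FN = |truth minus pred|, TN = span minus the rest, and
#' returns `0.5 * (TP/(TP+FN) + TN/(TN+FP))`. A class with zero total
#' length contributes 0 to the average.
#'
#' @param pred Predicted interval data.frame.
#' @param truth True interval data.frame.
#' @param genome_span Evaluated span: an interval data.frame, or a named
#'   numeric vector of chromosome lengths (whole chromosomes), or a genome.
#' @return A list with `ba` and the bp lengths `TP`, `TN`, `FP`, `FN`.
#' @export
balanced_accuracy <- function(pred, truth, genome_span) {
  span <- span_intervals(genome_span)
  gs <- gr_from_bed(span); GenomicRanges::strand(gs) <- "*"
  clip <- function(x) {
    if (nrow(x) == 0L) return(GenomicRanges::GRanges())
    g <- gr_from_bed(x); GenomicRanges::strand(g) <- "*"
    GenomicRanges::reduce(GenomicRanges::intersect(g, gs))
  }
  gp <- clip(pred)
  gt <- clip(truth)
  total <- sum(GenomicRanges::width(gs))
  tp <- sum(GenomicRanges::width(GenomicRanges::intersect(gp, gt)))
  fp <- sum(GenomicRanges::width(gp)) - tp
  fn <- sum(GenomicRanges::width(gt)) - tp
  tn <- total - tp - fp - fn
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  spec <- if (tn + fp > 0) tn / (tn + fp) else 0
  list(ba = 0.5 * (sens + spec), TP = tp, TN = tn, FP = fp, FN = fn)
}

span_intervals <- function(genome_span) {
  if (is.data.frame(genome_span)) {
    return(merge_intervals(genome_span))
  }
  lens <- genome_lengths(genome_span)
  data.frame(chrom = names(lens), start = 0L, end = as.integer(lens),
             stringsAsFactors = FALSE)
}

#' Seeded k-fold assignment
#'
#' Random, disjoint folds covering all items with sizes differing by at
#' most one; reproducible under the seed.
#'
#' @param n Number of items.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold labels in 1..k.
#' @export
kfold_split <- function(n, k = 10L, seed = 1L) {
  stopifnot(n >= k)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  sample(rep_len(seq_len(k), n))
}

# Total covered length of a set of intervals (chrom/start/end vectors).
union_length <- function(chrom, start, end) {
  if (length(start) == 0L) return(0)
  o <- order(chrom, start)
  chrom <- chrom[o]; start <- start[o]; end <- end[o]
  new_chrom <- c(TRUE, chrom[-1L] != chrom[-length(chrom)])
  hi <- end
  for (grp in split(seq_along(end), cumsum(new_chrom))) {
    hi[grp] <- cummax(end[grp])
  }
  prev_hi <- c(0, hi[-length(hi)])
  covered <- pmax(end - pmax(start, ifelse(new_chrom, start, prev_hi)), 0)
  sum(as.numeric(covered))
}

# Length-weighted BA over a fold's window pairs: positives are merged into
# regions on each side; the evaluated span is the merged footprint of all
# the fold's pairs. Pure integer interval arithmetic for speed inside CV.
pair_region_ba <- function(candidates, pred_pos, truth_pos, window = 500L) {
  ch <- candidates$chrom
  s <- candidates$start
  e <- s + 2L * window
  total <- union_length(ch, s, e)
  lp <- union_length(ch[pred_pos], s[pred_pos], e[pred_pos])
  lt <- union_length(ch[truth_pos], s[truth_pos], e[truth_pos])
  both <- pred_pos | truth_pos
  lu <- union_length(ch[both], s[both], e[both])
  tp <- lp + lt - lu
  fp <- lp - tp
  fn <- lt - tp
  tn <- total - tp - fp - fn
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  spec <- if (tn + fp > 0) tn / (tn + fp) else 0
  0.5 * (sens + spec)
}

# Logistic fit without formula overhead; returns coefficients
# (intercept first). Perfect separation is tolerated: the decision rule
# only needs the sign of the linear predictor.
fit_lr <- function(X, y) {
  fit <- suppressWarnings(stats::glm.fit(
    cbind(`(Intercept)` = 1, X), y, family = stats::binomial(),
    control = list(epsilon = 1e-8, maxit = 100)))
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  cf
}

predict_lr <- function(coefs, X) {
  as.numeric(cbind(1, X) %*% coefs >= 0)
}

#' Greedy forward feature selection with logistic regression
#'
#' Starts from the empty model and, at each round, adds the feature that
#' maximises the mean cross-validated length-weighted balanced accuracy of
#' the logistic classifier (positive windows merged into regions before
#' scoring). Selection stops when the best improvement falls below `tol`.
#' The returned model is refit on all data with the selected features.
#'
#' @param features Candidates x features numeric matrix.
#' @param labels 0/1 labels per candidate.
#' @param candidates Data.frame `chrom`, `start` of the window pairs (used
#'   for the length-weighted, merged-region scoring).
#' @param k Number of CV folds.
#' @param seed Seed for the fold split.
#' @param tol Minimum CV improvement to accept another feature.
#' @param window Window size in bp.
#' @return An object of class `trained_model` with elements `method`,
#'   `selected_features`, `coefficients`, `intercept`,
#'   `cv_balanced_accuracy`, `cv_trajectory`, `folds`, `seed`.
#' @export
greedy_lr_select <- function(features, labels, candidates, k = 10L,
                             seed = 1L, tol = 1e-3, window = 500L) {
  folds <- kfold_split(nrow(features), k = k, seed = seed)
  for (f in seq_len(k)) {
    if (length(unique(labels[folds != f])) < 2L) {
      stop("training fold ", f, " contains a single class")
    }
  }
  all_feats <- colnames(features)
  selected <- character(0)
  best_ba <- 0.5  # empty model: predict the majority structure, BA 0.5
  trajectory <- numeric(0)
  repeat {
    remaining <- setdiff(all_feats, selected)
    if (length(remaining) == 0L) break
    cand_ba <- vapply(remaining, function(fname) {
      cols <- c(selected, fname)
      mean(vapply(seq_len(k), function(f) {
        tr <- folds != f
        cf <- fit_lr(features[tr, cols, drop = FALSE], labels[tr])
        pred <- predict_lr(cf, features[!tr, cols, drop = FALSE])
        pair_region_ba(candidates[!tr, , drop = FALSE],
                       pred == 1, labels[!tr] == 1, window = window)
      }, numeric(1)))
    }, numeric(1))
    best <- which.max(cand_ba)
    if (cand_ba[best] - best_ba < tol) break
    selected <- c(selected, remaining[best])
    best_ba <- cand_ba[best]
    trajectory <- c(trajectory, best_ba)
  }
  coefs <- numeric(0); intercept <- 0
  if (length(selected) > 0L) {
    cf <- fit_lr(features[, selected, drop = FALSE], labels)
    intercept <- unname(cf[1L])
    coefs <- stats::setNames(unname(cf[-1L]), selected)
  }
  structure(list(method = "greedy_lr", selected_features = selected,
                 coefficients = coefs, intercept = intercept,
                 cv_balanced_accuracy = best_ba, cv_trajectory = trajectory,
                 folds = folds, seed = seed),
            class = "trained_model")
}

#' Lasso-regularised linear support vector machine
#'
#' Trains an L1-penalised linear SVM (squared hinge loss, proximal-gradient
#' optimisation on standardised features) over a penalty grid and keeps the
#' penalty with the highest mean cross-validated length-weighted balanced
#' accuracy. Features with zero weight at the optimum are reported as
#' unselected.
#'
#' @inheritParams greedy_lr_select
#' @param penalties Decreasing-or-any-order numeric grid of L1 penalties.
#' @param max_iter Proximal-gradient iterations per fit.
#' @return A `trained_model` with additional elements `penalty`,
#'   `penalty_grid`, `penalty_cv`.
#' @export
sparse_svm_train <- function(features, labels, candidates, k = 10L,
                             seed = 1L,
                             penalties = 10^seq(-4, 0, length.out = 9),
                             max_iter = 500L, window = 500L) {
  folds <- kfold_split(nrow(features), k = k, seed = seed)
  for (f in seq_len(k)) {
    if (length(unique(labels[folds != f])) < 2L) {
      stop("training fold ", f, " contains a single class")
    }
  }
  # decreasing penalties: CV ties resolve to the sparser model
  penalties <- sort(penalties, decreasing = TRUE)
  cv_ba <- vapply(penalties, function(lam) {
    mean(vapply(seq_len(k), function(f) {
      tr <- folds != f
      fit <- svm_l1_fit(features[tr, , drop = FALSE], labels[tr], lam,
                        max_iter = max_iter)
      pred <- svm_l1_predict(fit, features[!tr, , drop = FALSE])
      pair_region_ba(candidates[!tr, , drop = FALSE],
                     pred == 1, labels[!tr] == 1, window = window)
    }, numeric(1)))
  }, numeric(1))
  best <- which.max(cv_ba)
  fit <- svm_l1_fit(features, labels, penalties[best], max_iter = max_iter)
  sel <- names(fit$w)[fit$w != 0]
  structure(list(method = "sparse_svm", selected_features = sel,
                 coefficients = fit$w, intercept = fit$b,
                 scaling = fit$scaling,
                 cv_balanced_accuracy = cv_ba[best],
                 penalty = penalties[best], penalty_grid = penalties,
                 penalty_cv = cv_ba, folds = folds, seed = seed),
            class = "trained_model")
}

# L1-penalised squared-hinge linear SVM by ISTA (proximal gradient).
# Objective: (1/n) sum_i max(0, 1 - y_i (x_i w + b))^2 + lambda * ||w||_1,
# y in {-1, +1}; features standardised internally (constant columns kept
# at zero weight).
svm_l1_fit <- function(X, labels, lambda, max_iter = 500L) {
  X <- as.matrix(X)
  y <- ifelse(labels == 1, 1, -1)
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")
  n <- nrow(Z); p <- ncol(Z)
  # Lipschitz constant of the smooth part: 2/n * ||[Z 1]||_2^2
  Zb <- cbind(Z, 1)
  Lc <- 2 / n * (norm(Zb, "2"))^2
  step <- 1 / Lc
  w <- numeric(p); b <- 0
  soft <- function(v, t) sign(v) * pmax(abs(v) - t, 0)
  for (it in seq_len(max_iter)) {
    m <- 1 - y * (Z %*% w + b)
    act <- m > 0
    grad_w <- -(2 / n) * crossprod(Z[act, , drop = FALSE],
                                   (y * m)[act])
    grad_b <- -(2 / n) * sum((y * m)[act])
    w_new <- soft(w - step * as.numeric(grad_w), step * lambda)
    b_new <- b - step * grad_b
    delta <- max(abs(c(w_new - w, b_new - b)))
    w <- w_new; b <- b_new
    if (delta < 1e-8) break
  }
  list(w = stats::setNames(w, colnames(X)), b = b,
       scaling = list(center = mu, scale = sdv), lambda = lambda)
}

svm_l1_predict <- function(fit, X) {
  Z <- sweep(sweep(as.matrix(X), 2L, fit$scaling$center), 2L,
             fit$scaling$scale, "/")
  as.numeric(Z %*% fit$w + fit$b >= 0)
}

#' Predict positive candidates and merge them into origin regions
#'
#' Applies a trained model to a feature matrix and merges the footprints of
#' positive window pairs into non-overlapping predicted regions
#' (book-ended merge).
#'
#' @param model A `trained_model` from [greedy_lr_select()] or
#'   [sparse_svm_train()].
#' @param features Candidates x features matrix.
#' @param candidates Data.frame `chrom`, `start`.
#' @param window Window size in bp.
#' @return A list with `regions` (merged predictions) and `positive`
#'   (logical per candidate).
#' @export
predict_genome <- function(model, features, candidates, window = 500L) {
  pos <- if (model$method == "greedy_lr") {
    if (length(model$selected_features) == 0L) {
      rep(FALSE, nrow(candidates))
    } else {
      eta <- model$intercept +
        as.numeric(features[, model$selected_features, drop = FALSE] %*%
                     model$coefficients)
      eta >= 0  # logistic probability >= 0.5
    }
  } else {
    fit <- list(w = model$coefficients, b = model$intercept,
                scaling = model$scaling)
    svm_l1_predict(fit, features) == 1
  }
  regions <- if (any(pos)) {
    merge_intervals(data.frame(chrom = candidates$chrom[pos],
                               start = candidates$start[pos],
                               end = candidates$start[pos] + 2L * window,
                               stringsAsFactors = FALSE))
  } else {
    empty_intervals()
  }
  list(regions = regions, positive = pos)
}

#' Per-quantile sensitivity and false-positive rate of predicted regions
#'
#' Sensitivity of quantile k is the fraction of quantile-k origins that
#' overlap at least one predicted region. The FPR is the fraction of
#' predicted regions that overlap no origin; by default on region counts,
#' optionally weighted by region length ("normalised to average fragment
#' length").
#'
#' @param pred Predicted interval data.frame.
#' @param origins Interval data.frame with a `quantile` column (optional;
#'   overall sensitivity is always reported).
#' @return A list with `sensitivity` (named by quantile, plus `all` and,
#'   when a `klass` column is present, `core`/`stochastic`), `fpr`
#'   (region-count basis), `fpr_length` (bp-weighted), `n_pred`.
#' @export
evaluate_predictions <- function(pred, origins) {
  sens_of <- function(o) {
    if (nrow(o) == 0L) return(NA_real_)
    overlap_count(o, pred) / nrow(o)
  }
  sens <- c(all = sens_of(origins))
  if (!is.null(origins$quantile)) {
    qs <- sort(unique(origins$quantile))
    sq <- vapply(qs, function(q) {
      sens_of(origins[origins$quantile == q, , drop = FALSE])
    }, numeric(1))
    names(sq) <- paste0("Q", qs)
    sens <- c(sens, sq)
  }
  if (!is.null(origins$klass)) {
    for (kl in unique(origins$klass)) {
      sens[kl] <- sens_of(origins[origins$klass == kl, , drop = FALSE])
    }
  }
  if (nrow(pred) == 0L) {
    return(list(sensitivity = sens, fpr = NA_real_, fpr_length = NA_real_,
                n_pred = 0L))
  }
  ga <- gr_from_bed(pred); GenomicRanges::strand(ga) <- "*"
  gb <- gr_from_bed(origins); GenomicRanges::strand(gb) <- "*"
  hit <- IRanges::overlapsAny(ga, gb)
  w <- pred$end - pred$start
  list(sensitivity = sens,
       fpr = mean(!hit),
       fpr_length = sum(w[!hit]) / sum(w),
       n_pred = nrow(pred))
}
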