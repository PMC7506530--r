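#' Pipeline run configuration
#'
#' Collects every tunable parameter of the workflow with defaults at the
#' values the analysis is built around: the hyper-motif thresholds, the
#' 10-quantile split with core = Q1-Q2, the 7/15-kb cluster gaps with
#' tight clusters of 6+ members, the super-origin threshold of 50
#' normalized counts, the ML method/fold/tolerance settings, 100 TAD bins,
#' and 100 shuffles for enrichment expectations.
#'
#' @param ... Overrides for any default element.
#' @return A list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    params = hypermotif_params(),
    n_quantiles = 10L,
    core_quantiles = 1:2,
    super_threshold = 50,
    cluster_gap = 7000L,
    isolated_gap = 15000L,
    tight_size = 6L,
    ml_method = "greedy_lr",
    ml_k = 10L,
    ml_tol = 1e-3,
    tad_bins = 100L,
    n_shuffles = 100L,
    n_decoys = 0L,
    seed = 1L,
    spec = synthetic_spec()
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  structure(cfg, class = "run_config")
}

#' Run the full synthetic-genome analysis pipeline
#'
#' Executes simulate -> scan -> features -> train -> predict -> classify ->
#' tads on a synthetic dataset, writes every stage's artifact into
#' `outdir` (FASTA, BED, TSV, bedGraph), and records a machine-readable
#' manifest (parameter echo, seeds, per-file MD5 checksums). Rerunning the
#' same configuration reproduces identical checksums.
#'
#' @param config A [run_config()].
#' @param outdir Output directory (created if missing).
#' @return The manifest list, invisibly; artifacts and `manifest.json` are
#'   written under `outdir`.
#' @export
run_pipeline <- function(config = run_config(), outdir = tempfile("orirun")) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- character(0)
  t0 <- Sys.time()
  msg <- function(stage) {
    message(sprintf("[%s] %s", format(Sys.time() - t0, digits = 3), stage))
    stages <<- c(stages, stage)
  }

  msg("simulate")
  spec <- config$spec
  spec$seed <- config$seed
  sim <- simulate_dataset(spec)
  if (config$n_decoys > 0L) sim <- add_decoy_cassettes(sim, config$n_decoys)
  write_genome_fasta(sim$genome, file.path(outdir, "genome.fa"))
  write_intervals(cbind(sim$truth, name = "."), file.path(outdir, "truth.bed"),
                  dialect = "BED6")
  utils::write.table(sim$activity$counts, file.path(outdir, "counts.tsv"),
                     sep = "\t", quote = FALSE)
  utils::write.table(sim$activity$background,
                     file.path(outdir, "background.tsv"),
                     sep = "\t", quote = FALSE)
  write_coverage(sim$coverage, file.path(outdir, "coverage.bedGraph"))

  msg("scan")
  scan <- scan_genome(sim$genome, config$params)
  reg <- scan$regions
  reg$name <- "."
  reg$score <- reg$n_pairs
  write_intervals(reg, file.path(outdir, "candidates.bed"), dialect = "BED6")

  msg("features")
  orient <- ifelse(scan$pairs$forward, "+", "-")
  fm <- feature_matrix(sim$genome, scan$pairs, origins = sim$truth,
                       orientation = orient, window = config$params$window)
  utils::write.table(
    data.frame(fm$candidates, fm$features, label = fm$labels),
    file.path(outdir, "features.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  msg("train")
  if (length(unique(fm$labels)) < 2L) {
    warning("all candidates share one label; training a null model")
  }
  model <- if (length(unique(fm$labels)) < 2L) {
    structure(list(method = "greedy_lr", selected_features = character(0),
                   coefficients = numeric(0), intercept = 0,
                   cv_balanced_accuracy = 0.5, cv_trajectory = numeric(0),
                   seed = config$seed),
              class = "trained_model")
  } else if (config$ml_method == "greedy_lr") {
    greedy_lr_select(fm$features, fm$labels, fm$candidates,
                     k = config$ml_k, seed = config$seed,
                     tol = config$ml_tol, window = config$params$window)
  } else {
    sparse_svm_train(fm$features, fm$labels, fm$candidates,
                     k = config$ml_k, seed = config$seed,
                     window = config$params$window)
  }
  jsonlite::write_json(
    list(method = model$method, selected_features = model$selected_features,
         coefficients = as.list(model$coefficients),
         intercept = model$intercept,
         cv_balanced_accuracy = model$cv_balanced_accuracy,
         seed = model$seed),
    file.path(outdir, "model.json"), auto_unbox = TRUE, digits = NA)

  msg("predict")
  pred <- predict_genome(model, fm$features, fm$candidates,
                         window = config$params$window)
  if (nrow(pred$regions) > 0L) {
    write_intervals(pred$regions, file.path(outdir, "predicted.bed"),
                    dialect = "BED3")
  } else {
    writeLines(character(0), file.path(outdir, "predicted.bed"))
  }

  msg("classify")
  norm <- normalize_activity(sim$activity$counts, sim$activity$background)
  qk <- classify_quantiles(norm$mean_activity,
                           n_quantiles = config$n_quantiles,
                           core_quantiles = config$core_quantiles,
                           super_threshold = config$super_threshold)
  summits <- call_summits(sim$coverage, sim$truth)
  strands <- orient_origins(sim$genome,
                            data.frame(chrom = sim$truth$chrom,
                                       summit = summits$summit))
  repertoire <- data.frame(
    chrom = sim$truth$chrom, start = sim$truth$start, end = sim$truth$end,
    summit = summits$summit, strand = strands,
    mean_activity = norm$mean_activity,
    quantile = qk$quantile, klass = qk$klass,
    stringsAsFactors = FALSE)
  core <- repertoire[repertoire$klass == "core", , drop = FALSE]
  if (nrow(core) > 0L) {
    cc <- cluster_origins(core, cluster_gap = config$cluster_gap,
                          isolated_gap = config$isolated_gap,
                          tight_size = config$tight_size)
    repertoire$cluster_id <- NA_integer_
    repertoire$cluster_class <- NA_character_
    key_all <- paste(repertoire$chrom, repertoire$start)
    key_cc <- paste(cc$chrom, cc$start)
    m <- match(key_all, key_cc)
    repertoire$cluster_id <- cc$cluster_id[m]
    repertoire$cluster_class <- cc$cluster_class[m]
  }
  utils::write.table(repertoire, file.path(outdir, "repertoire.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  msg("tads")
  tadsim <- simulate_tads(spec)
  prof <- tad_density_profile(tadsim$origins, tadsim$tads,
                              n_bins = config$tad_bins)
  utils::write.table(
    data.frame(bin = seq_along(prof$bins), density_per_mb = prof$bins),
    file.path(outdir, "tad_profile.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  files <- list.files(outdir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    package = "oriscan",
    version = as.character(utils::packageVersion("oriscan")),
    seed = config$seed,
    stages = stages,
    parameters = list(
      hypermotif = unclass(config$params),
      n_quantiles = config$n_quantiles,
      super_threshold = config$super_threshold,
      cluster_gap = config$cluster_gap,
      isolated_gap = config$isolated_gap,
      tight_size = config$tight_size,
      ml_method = config$ml_method,
      ml_k = config$ml_k,
      ml_tol = config$ml_tol,
      tad_bins = config$tad_bins
    ),
    checksums = as.list(tools::md5sum(files))
  )
  names(manifest$checksums) <- basename(files)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
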