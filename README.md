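# oriscan

Sequence-based prediction and repertoire analysis of DNA replication
origins.

## What this is for

Mammalian DNA replication initiates from thousands of initiation sites
(IS) mapped by short nascent strand sequencing (SNS-seq). Their activity
is heavily skewed: the top two deciles of mean normalized activity
("core origins", Q1–Q2 of Q1–Q10) host ~80% of initiation events in
every cell type and carry an asymmetric G-rich sequence element upstream
of the IS summit. `oriscan` is an R package plus a small analysis
workflow for people who want to

* classify an origin repertoire from count matrices — background
  subtraction, TMM scaling, decile classes (core / stochastic / super,
  the last defined by mean activity > 50 normalized counts), coverage
  summits, G-content orientation, 7-kb clustering, composition and
  distance profiles, TAD-bin density profiles; and
* predict origin positions from genome sequence alone — a hyper-motif
  scan over paired 500-bp windows (step 100 bp) retaining pairs with

  G₁ ≥ 0.28, G₂ ≥ 0.25, (G₁ − G₂) ∈ [0.08, 0.40], max(A, T) ≤ 0.21,

  run on both strand orientations and merged into candidate regions,
  followed by machine-learning refinement on 22 sequence predictors:
  logistic regression with greedy forward selection, and an L1-penalised
  linear SVM, both scored by length-weighted balanced accuracy

  BA = ½ · (TP/(TP+FN) + TN/(TN+FP))

  computed on the base-pair lengths of merged prediction/truth regions
  under 10-fold cross-validation.

A seeded synthetic-genome generator plants origin cassettes, log-normal
activities, coverage summits, decoy cassettes, and border-enriched TADs,
so the full analysis runs and is tested end-to-end with known ground
truth and no external downloads.

## Worked example

The analysis workflow is five numbered drivers:

```sh
Rscript analysis/01_simulate.R     # 2-Mb genome, 200 origins, 200 decoys, 19 samples
Rscript analysis/02_scan.R         # hyper-motif scan + G-rich caller + enrichment
Rscript analysis/03_repertoire.R   # quantiles, summits, orientation, clusters, profiles
Rscript analysis/04_features_ml.R  # 22 features, greedy LR, sparse SVM, FPR table
Rscript analysis/05_tads.R         # TAD border/centre density and signal ratios
```

which print, on the packaged synthetic dataset (seed 1):

```
retained window pairs: 971 (forward 638, reverse 649)
merged candidate regions: 400; mean length 1144 bp
planted-cassette sensitivity: 1; decoy retention: 1
candidate/origin overlap: observed 200, expected 87.4, chi2 257.7, p 5.54e-58

origins: 200; core 40, stochastic 160, super 9
core origins host 80.7% of total initiation signal (per-sample range 78.8-82.3%)
mean G frequency upstream (-800..-300): 0.437 vs downstream (0..500): 0.242
median |summit - cassette boundary| distance: 300 bp (signed median -300)

raw scan: 400 regions, sensitivity 1, FPR 50%
greedy LR selected: CC (CV balanced accuracy 1)
GS+LR: 200 regions, sensitivity 1, FPR 0%
GS+SVM (penalty 0.316, 4 nonzero features): 200 regions, sensitivity 1, FPR 0%

border_factor 1: border/centre density ratio 1.012 over 20 TADs
border_factor 3: border/centre density ratio 3.114 over 20 TADs
planted 1.53-fold border signal: recovered sum ratio 1.552
```

Read: the scan finds every planted cassette but, by design, also every
G-rich decoy (FPR 50%); the ML layer separates them on composition
features and removes the decoys at full sensitivity; the repertoire
statistics (80% core signal share, summit 300 bp downstream of the
G-rich element, border-enriched TADs) match the structure the generator
plants. Tables land under `results/`.

The same stages are available as library calls (`scan_genome()`,
`classify_quantiles()`, `greedy_lr_select()`, `tad_density_profile()`,
...) and as one call, `run_pipeline(run_config(...))`, which writes all
artifacts plus a checksummed run manifest. The methods vignette
(`vignettes/origin-prediction.Rmd`) documents the model, parameter
choices, and the generator's scope.

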