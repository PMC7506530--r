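---
title: "Predicting replication origins from DNA sequence: methods and design"
author: "oriscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting replication origins from DNA sequence: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oriscan)
```

## The problem

Metazoan DNA replication starts from thousands of initiation sites (IS)
whose specification is not explained by a consensus motif. Short nascent
strand sequencing (SNS-seq) maps these sites genome-wide and shows a
strongly skewed activity distribution: a minority of "core" origins — the
top two deciles of mean normalized activity — host the large majority of
initiation events in every cell type, and core origins carry an
asymmetric, G-rich sequence signature (an OGRE-like element upstream of
the IS summit). `oriscan` implements the two halves of that observation
as a reusable toolkit:

1. **Repertoire analytics** — turning origin intervals plus per-sample
   count matrices into normalized activities, decile classes
   (core/stochastic/super), summits, orientations, clusters, composition
   and distance profiles, and TAD density profiles.
2. **Sequence-only prediction** — a hyper-motif genome scan for the
   paired-window G-content architecture, followed by machine-learning
   refinement on 22 sequence predictors.

Because the package is exercised end-to-end on synthetic genomes with
planted ground truth, every stage is testable without any external data.

## The hyper-motif genome scan

A hyper-motif is a discriminatory composition pattern longer than a
transcription-factor motif. The scan slides paired 500-bp windows (step
100 bp) along each chromosome and retains a pair on the forward
orientation when

* window 1 has G fraction ≥ 0.28,
* window 2 has G fraction ≥ 0.25,
* the drop (window 1 − window 2) lies in [0.08, 0.40] (absolute
  percentage points), and
* both the A and the T fraction over the combined 1-kb pair are ≤ 0.21.

The reverse orientation applies the exact C-based mirror of the rule with
the window roles exchanged. Two interpretation choices deserve comment,
since the thresholds admit more than one reading:

* **The drop is absolute**, on the same scale as the 28%/25% minima. A
  relative reading (8–40% of window 1's G content) would make the window-2
  minimum almost never binding; the absolute reading keeps all four
  thresholds on one scale. Both remain available through
  `hypermotif_params()`.
* **The A/T cap applies to each base separately** over the combined pair.
  Requiring A+T ≤ 0.21 jointly would force ≥ 79% G+C over 1 kb, which
  essentially never occurs outside CpG islands and is incompatible with a
  mammalian-genome-scale retained set.
* **The mirrored rule is the exact reverse complement** of the forward
  rule. This is forced by a symmetry argument: scanning the reverse
  complement of a chromosome must give the mirror image of scanning the
  chromosome, which the test suite asserts exactly.

All threshold comparisons are inclusive, except the simple G-rich caller
(`grich_regions()`), which is documented as a strict "> 37% G". N bases
count in window denominators and match nothing, so N-rich windows fail.

Retained pairs from both orientations are pooled (a position retained
twice counts once), projected to their 1-kb footprints, and merged
book-ended into candidate regions; a merged region takes the orientation
contributing more retained pairs, ties going to forward.

## The 22 sequence predictors

Each retained pair is described by 22 features over a 4-kb span centred
on the boundary between its two windows, read in the candidate's
orientation (reverse candidates read the reverse complement, so "UP" is
always the putatively G-rich side):

| family | features |
|---|---|
| upstream 2-kb fractions | `UP_A/C/G/T_fraction` |
| downstream 2-kb fractions | `Down_A/C/G/T_fraction` |
| central G content | `G_content_2kb`, `G_content_4kb` |
| composition gradient | `rampG` — least-squares slope (per kb) of G fraction across eight 500-bp segments |
| dinucleotide/multinucleotide densities | `CC`, `CG`, `GG`, `GC`, `CGCG` per kb of the central 1-kb pair (overlapping counts) |
| homotrinucleotide densities | `AAA`, `TTT`, `GGG`, `CCC` |
| context | `log10_inter_candidate_distance` (centre-to-centre, capped at 6), `at_max_pair` |

The roster is a reconstruction from the named best-model features and
the described feature families; it is one config-visible table
(`feature_names()`), so alternates can be swapped in, and it should not
be read as anyone's verbatim supplementary list. `rampG` is defined here
as a regression slope because only the name is fixed; a slope is the
simplest orientation-covariant statistic of a composition ramp. Feature
extraction is exactly reverse-complement covariant (UP and Down swap with
A–T and C–G exchanged, `rampG` flips sign, k-mers map to their reverse
complements), which the tests assert to machine precision.

## Length-weighted balanced accuracy and the classifiers

Because there are no synthetic negative instances, classifier quality is
scored on *region lengths*: positive windows are merged into regions,
and TP/TN/FP/FN are the base-pair lengths of the set algebra between
predicted and true regions over the evaluated span. Balanced accuracy is
`0.5 * (TP/(TP+FN) + TN/(TN+FP))`, with a zero-length class contributing
0. This metric is symmetric under jointly complementing predictions and
truth.

Two refinement models are provided:

* `greedy_lr_select()` — forward feature selection for logistic
  regression: at each round the feature maximising mean 10-fold CV
  balanced accuracy is added; selection stops when the best improvement
  falls below `tol = 1e-3`; the final model is refit on all data. The
  decision threshold is a predicted probability of 0.5, and the logistic
  fits use a fixed convergence tolerance of 1e-8. Perfectly separated
  fits are tolerated (only the sign of the linear predictor matters).
* `sparse_svm_train()` — an L1-penalised linear SVM (squared hinge loss)
  written in-package and optimised by proximal gradient descent on
  standardised features; the penalty grid is scored by the same CV metric
  and evaluated from the largest penalty down, so ties resolve to the
  sparser model. Zero-weight features are reported as unselected.

The repeated-CV majority-vote protocol used at the original study's
scale is collapsed to a single seeded CV here: with the study-scale data
replaced by desk-scale simulations, one seeded partition preserves the
selection semantics at a fraction of the cost, and both fold assignment
and the full selection path are bit-reproducible under the seed.

## Repertoire analytics

* **Normalization** (`normalize_activity()`): background counts are
  subtracted element-wise with negatives clamped to zero (sign handling
  is a package choice; the clamp keeps the activity scale interpretable
  as counts), then samples are TMM-scaled with the standard trims (30%
  on M, 5% on A). The reference sample is the one whose total count is
  closest to the median total, and reported scale factors are relative to
  it.
* **Quantiles** (`classify_quantiles()`): origins are ranked by
  decreasing mean activity and cut into 10 groups; any remainder goes to
  the *lowest-activity* quantiles. This is the only remainder convention
  under which 320,748 origins split into exactly 64,148 core (2 × 32,074)
  and 256,600 stochastic (8 × 32,075) origins. Ties across a boundary
  break by a caller-supplied order (genomic order in the pipeline). Core
  = Q1–Q2, stochastic = Q3–Q10, and a mean activity above 50 normalized
  counts flags a super origin.
* **Summits** (`call_summits()`): the midpoint of the maximal 50-bp bin
  on a 25-bp grid, leftmost on ties; zero-coverage intervals fall back to
  the interval midpoint with a flag.
* **Orientation** (`orient_origins()`): "+" iff the 500-bp flank to the
  left of the summit has at least as many G as the right flank, so the
  G-rich element reads upstream.
* **Clusters** (`cluster_origins()`): 7-kb single-linkage clusters;
  "tight" = cluster of ≥ 6 core origins, "isolated" = nearest core origin
  beyond 15 kb, "loose" otherwise.
* **TAD profiles** (`tad_density_profile()`, `tad_signal_profile()`):
  each TAD is split into 100 equal bins; origins are assigned by summit
  point; densities are per Mb and averaged with equal weight per TAD
  (length-weighted averaging is a one-line change but would let a few
  giant TADs dominate). Bins 1–10 and 91–100 are borders and bins 41–60
  centres — the 20-bin reading is used because the alternative "40–60"
  names 21 bins. Profiles can be normalised to the centre bins so border
  values read directly as enrichment.

## The synthetic-data generator

`synthetic_spec()` fixes the study conditions the tests probe:

* background genome: i.i.d. bases at 30% A, 30% T, 20% G, 20% C (no
  isochore or repeat structure — a documented simplification; the
  generator validates thresholds and estimators, not genome realism);
* cassettes: 500 + 500 bp with G fractions 0.45/0.30 and A = T = 0.15,
  comfortably inside the scan thresholds; composition is planted as
  *exact* base counts (largest-remainder rounding, order permuted) so a
  cassette sits deterministically on the intended side of every
  threshold — per-position sampling would give window compositions a 2–3
  percentage-point standard deviation and make near-threshold cassettes
  ambiguous by construction;
* placement: uniform non-overlapping positions with 2-kb minimum spacing,
  snapped to the 100-bp scan grid so that detection tests probe the
  thresholds rather than window phase; half the cassettes are planted
  reverse-complemented;
* activity: per-origin latent means are log-normal with `meanlog = 1`,
  `sdlog = 1.68`; the sdlog comes from the partial-expectation identity
  (the top-quintile share of a log-normal is Φ(σ − z₀.₈)), which puts
  ~80% of total signal in the top two deciles — the core-origin share the
  repertoire analysis is built around. Per-sample counts are Poisson
  around the latent mean over 19 samples, with Poisson background;
* coverage: 200 reads per origin, normal around a true summit placed
  300 bp downstream of the cassette boundary with SD 50 bp — the
  OGRE-upstream/IS-downstream geometry at the few-hundred-bp distance
  scale seen for pre-RC components;
* decoys (`add_decoy_cassettes()`): cassettes that pass the scan but
  split their non-G mass differently between C and A/T (A = T = 0.18
  instead of 0.15), giving the ML layer a genuine discrimination task —
  G-richness alone cannot separate them;
* TADs: equal-width domains with origin placement weighted by
  `border_factor` in the border bins.

All randomness derives from one integer seed through fixed per-stage
offsets, so every artifact is byte-reproducible.

What passing tests on this generator do *not* show: performance on real
genomes, where isochores, repeats, CpG islands, and assembly gaps make
both the background composition and the decoy structure far richer. The
scan machinery runs unchanged on any FASTA, but the reported recovery
rates are properties of the simulation.

## Numerical choices and degenerate inputs

* Coordinates are BED-style 0-based half-open everywhere; merging with
  `max_gap = 0` joins book-ended intervals.
* Orientation ties go to "+", summit ties to the leftmost bin, merged
  region orientation ties to forward, and equidistant up/downstream
  features are both reported by `nearest_distances()`.
* Shuffle-based expected overlaps default to the mean over 100 seeded
  shuffles; placement ignores assembly gaps unless an exclusion mask is
  given.
* Zero-signal samples get scale factor 1 with a warning; zero-coverage
  summits are flagged; a zero-length confusion class contributes 0 to
  balanced accuracy; TADs shorter than 100 bp are skipped and counted.
* The SVM optimiser stops at a coefficient change below 1e-8 or 500
  iterations; its step size is set by the Lipschitz constant of the
  squared-hinge term.

## Problem sizes

The test suite and the acceptance script use a 10-Mb genome with 500
planted cassettes for recovery rates, 200-kb sequences for exact
brute-force scanner comparisons, a 2-Mb genome with 80 true and 80 decoy
cassettes for the ML comparison, 320,748 synthetic activities for the
decile bookkeeping, and 10,000 placements over 20 TADs for the border
profiles. These sizes were chosen so each property is measured with
comfortable statistical margin while the whole analysis reruns in
minutes on one core.

## Known limitations

* The generator's background has no positional structure, so
  inter-candidate distance is uninformative in simulations even though it
  is a plausible signal on real genomes.
* The FPR of merged predictions is reported on region counts by default;
  a base-pair-weighted variant is also emitted because the two differ
  when predicted regions have very unequal lengths.
* `evaluate_predictions()` treats any ≥ 1 bp overlap as a hit; no
  reciprocal-overlap criterion is implemented.
* The pipeline is single-chromosome in its simulated form; all interval
  operations are multi-chromosome, but the generator plants one
  chromosome per run.
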