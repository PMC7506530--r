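#!/usr/bin/env Rscript

# Stage 4: machine-learning refinement of the genome scan.
#
# Extracts the 22 sequence predictors for every retained window pair,
# labels pairs by overlap with true origins, and trains (i) a logistic
# regression with greedy forward feature selection and (ii) a
# lasso-regularised linear SVM, both scored by 10-fold cross-validated
# length-weighted balanced accuracy with positive windows merged into
# regions. Reports the FPR reduction relative to the raw scan.

library(oriscan)

genome <- read_genome_fasta("results/sim/genome.fa")
truth <- read_intervals("results/sim/truth.bed", "BED6")
scan <- scan_genome(genome)

gs_eval <- evaluate_predictions(scan$regions, truth)
message("raw scan: ", gs_eval$n_pred, " regions, sensitivity ",
        round(gs_eval$sensitivity["all"], 3), ", FPR ",
        round(100 * gs_eval$fpr, 1), "%")

orient <- ifelse(scan$pairs$forward, "+", "-")
fm <- feature_matrix(genome, scan$pairs, origins = truth,
                     orientation = orient)
write.table(data.frame(fm$candidates, fm$features, label = fm$labels),
            "results/features.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

lr <- greedy_lr_select(fm$features, fm$labels, fm$candidates, seed = 1)
message("greedy LR selected: ",
        paste(lr$selected_features, collapse = ", "),
        " (CV balanced accuracy ", round(lr$cv_balanced_accuracy, 3), ")")
lr_pred <- predict_genome(lr, fm$features, fm$candidates)
lr_eval <- evaluate_predictions(lr_pred$regions, truth)
message("GS+LR: ", lr_eval$n_pred, " regions, sensitivity ",
        round(lr_eval$sensitivity["all"], 3), ", FPR ",
        round(100 * lr_eval$fpr, 1), "%")

svm <- sparse_svm_train(fm$features, fm$labels, fm$candidates, seed = 1)
svm_pred <- predict_genome(svm, fm$features, fm$candidates)
svm_eval <- evaluate_predictions(svm_pred$regions, truth)
message("GS+SVM (penalty ", signif(svm$penalty, 3), ", ",
        length(svm$selected_features), " nonzero features): ",
        svm_eval$n_pred, " regions, sensitivity ",
        round(svm_eval$sensitivity["all"], 3), ", FPR ",
        round(100 * svm_eval$fpr, 1), "%")

summary <- data.frame(
  method = c("GS", "GS+LR", "GS+SVM"),
  n_regions = c(gs_eval$n_pred, lr_eval$n_pred, svm_eval$n_pred),
  sensitivity = c(gs_eval$sensitivity["all"], lr_eval$sensitivity["all"],
                  svm_eval$sensitivity["all"]),
  fpr = c(gs_eval$fpr, lr_eval$fpr, svm_eval$fpr),
  fpr_length = c(gs_eval$fpr_length, lr_eval$fpr_length,
                 svm_eval$fpr_length))
write.table(summary, "results/prediction_summary.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write_intervals(lr_pred$regions, "results/predicted_lr.bed",
                dialect = "BED3")
write_intervals(svm_pred$regions, "results/predicted_svm.bed",
                dialect = "BED3")
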