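#!/usr/bin/env Rscript
# Stage 4: rank the unlabeled genes with the median-AUC model.
#
# The run whose AUC sits at the median of the 101 resampling runs is
# regenerated from its recorded seed, its model (trained on all seeds +
# that run's pseudo-negatives) scores every unlabeled gene, and genes
# with posterior > 0.9 become candidates.

suppressPackageStartupMessages(library(netprio))

feats <- read.delim("results/features.tsv", colClasses = c(gene = "character"))
manifest <- read.delim("results/run_manifest.tsv")
best_idx <- as.integer(readLines("results/best_run_index.txt"))
seed <- manifest$seed[manifest$run_index == best_idx]

n_pos <- sum(feats$label == "positive")
negs <- sample_negatives(feats, n_pos, seed = seed)
run <- cv_evaluate(feats, negs, seed = seed)
stopifnot(abs(run$auc - manifest$auc[manifest$run_index == best_idx]) < 1e-12)

preds <- predict_unlabeled(run$model, feats, threshold = 0.9)
write.table(preds, "results/predictions.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("scored", nrow(preds), "unlabeled genes;",
    sum(preds$candidate), "candidates at posterior > 0.9\n")
cat("top 10 predictions:\n")
print(head(preds, 10), digits = 4)
cat("wrote results/predictions.tsv\n")
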