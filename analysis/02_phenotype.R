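#!/usr/bin/env Rscript
# Behavioral phenotyping: k-means (k = 2) on (failures, latency), a refit
# linear discriminant, comparison against the frozen reference equations,
# and the LH/NLH/Ctrl group statistics (one-way ANOVA + Bonferroni).

suppressPackageStartupMessages(library(lhcoex))

beh <- read.csv("results/synthetic/behavior.csv", stringsAsFactors = FALSE)
truth <- read.delim("results/synthetic/behavior_truth.tsv",
                    stringsAsFactors = FALSE)
dir.create("results/phenotype", showWarnings = FALSE, recursive = TRUE)

tested <- beh[beh$group != "Ctrl", ]
cl <- cluster_mice(tested, seed = 20260925L)
model <- fit_discriminant(tested, cl$labels)
pred <- classify_mice(model, tested$failures, tested$latency_s)
agree_truth <- mean(cl$labels[truth$mouse_id] == truth$true_class)

ref <- reference_discriminant()
ref_pred <- classify_mice(ref, tested$failures, tested$latency_s)

out <- data.frame(mouse_id = tested$mouse_id,
                  failures = tested$failures,
                  latency_s = tested$latency_s,
                  kmeans_label = unname(cl$labels[tested$mouse_id]),
                  lda_label = pred$class,
                  reference_label = ref_pred$class,
                  true_class = truth$true_class[match(tested$mouse_id,
                                                      truth$mouse_id)])
write.table(out, "results/phenotype/labels.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

stats <- compare_groups(beh, ifelse(beh$group == "Ctrl", "Ctrl",
                                    out$kmeans_label[match(beh$mouse_id,
                                                           out$mouse_id)]))
for (metric in names(stats)) {
  write.table(stats[[metric]]$pairwise,
              file.path("results/phenotype",
                        paste0("pairwise_", metric, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

cat("Phenotyping results (results/phenotype/):\n")
cat(sprintf("  k-means agreement with planted truth: %.0f%%\n",
            100 * agree_truth))
cat(sprintf("  refit LDA agrees with k-means on %.0f%% of mice\n",
            100 * mean(pred$class == unname(cl$labels[tested$mouse_id]))))
cat(sprintf("  reference equations agree with k-means on %.0f%% of mice\n",
            100 * mean(ref_pred$class ==
                         unname(cl$labels[tested$mouse_id]))))
cat(sprintf("  centroids: LH (%.1f, %.1f), NLH (%.1f, %.1f)\n",
            cl$centroids["LH", 1], cl$centroids["LH", 2],
            cl$centroids["NLH", 1], cl$centroids["NLH", 2]))
cat(sprintf("  failures ANOVA: F = %.1f, p = %.3g\n",
            stats$failures$F, stats$failures$p))
cat(sprintf("  latency  ANOVA: F = %.1f, p = %.3g\n",
            stats$latency$F, stats$latency$p))
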