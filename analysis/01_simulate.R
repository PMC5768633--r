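#!/usr/bin/env Rscript
# Generates the synthetic study: shuttle-box behavior for two phenotype
# clusters, a four-group FPKM matrix with planted DE transcripts and
# lncRNA-mRNA pairs, a mixed-biotype annotation, a gene-set collection
# enriched for the planted DE genes, and a qPCR plate with planted folds.
# All downstream drivers read from results/synthetic/.

suppressPackageStartupMessages(library(lhcoex))

out <- "results/synthetic"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20260925L

beh <- simulate_behavior(n_lh = 14, n_nlh = 17, n_ctrl = 10, seed = seed)
write.csv(beh$behavior, file.path(out, "behavior.csv"), row.names = FALSE)
write.table(beh$truth, file.path(out, "behavior_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cfg <- sim_config(n_per_group = 4, n_transcripts = 2000, n_de = 150,
                  n_pairs = 30, de_effect = 3, noise_sd = 0.5,
                  pair_r = 0.98, seed = seed)
sim <- simulate_expression(cfg)
write_expression(sim$matrix, file.path(out, "expression_fpkm.tsv"))
write_annotation_tsv(sim$annotation, file.path(out, "annotation.tsv"))
write_annotation_gtf(sim$annotation, file.path(out, "annotation.gtf"))
write.table(sim$design, file.path(out, "metadata.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sim$truth, file.path(out, "expression_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

sets <- simulate_gene_sets(sim$annotation, sim$truth, n_terms = 30,
                           enriched_terms = 5, term_size = 15, seed = seed)
write_gmt(sets, file.path(out, "gene_sets.gmt"))

plate <- simulate_qpcr(c(Gene1 = 2, Gene2 = 0.5, Gene3 = 1.5, Gene4 = 1),
                       n_per_group = 10, ct_noise_sd = 0.1, seed = seed)
write.csv(plate, file.path(out, "qpcr_ct.csv"), row.names = FALSE)

cat("Synthetic study written to", out, "\n")
cat(sprintf("  %d mice (%d LH / %d NLH / %d Ctrl)\n",
            nrow(beh$behavior), sum(beh$behavior$group == "LH"),
            sum(beh$behavior$group == "NLH"),
            sum(beh$behavior$group == "Ctrl")))
cat(sprintf("  %d transcripts x %d samples; %d planted DE, %d planted pairs\n",
            nrow(sim$matrix), ncol(sim$matrix), cfg$n_de, cfg$n_pairs))
cat(sprintf("  %d gene-set terms (%d DE-enriched); qPCR plate: %d genes\n",
            length(sets), 5, 4))
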