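#!/usr/bin/env Rscript
# Characterize the classifier-selected edges: weighted degrees per region,
# intra/inter-network standardized percentages, and correlations with the
# clinical variables in patients.

source("analysis/00_config.R")

atlas <- build_default_atlas()
subjects <- read_subject_table(file.path(COHORT_DIR, "subjects.csv"))
edge_mat <- load_edge_matrix()
sel <- read.delim(file.path(RESULTS_DIR, "selected_edges.tsv"))

deg <- weighted_degree(sel, atlas)
cat(sprintf("Regions above mean+2SD positive weighted degree: %s\n",
            paste(deg$label[deg$pos_gt_2sd], collapse = ", ")))
cat(sprintf("Regions below mean-2SD negative weighted degree: %s\n",
            paste(deg$label[deg$neg_lt_2sd], collapse = ", ")))
write.table(deg, file.path(RESULTS_DIR, "weighted_degrees.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

ns <- network_summary(sel, atlas)
cat(sprintf("\n%d intra-network and %d inter-network selected edges\n",
            ns$totals$n_intra, ns$totals$n_inter))
cat(sprintf("Mean standardized percentage: intra %.2f%%, inter %.2f%%\n",
            ns$totals$mean_intra_pct, ns$totals$mean_inter_pct))
cat("Standardized percentage per network pair:\n")
print(round(ns$percent_matrix, 2))
write.table(ns$table, file.path(RESULTS_DIR, "network_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

pat <- subjects$group == "OSA"
cc <- clinical_correlation(sel, edge_mat[pat, , drop = FALSE],
                           subjects[pat, , drop = FALSE], atlas = atlas)
sig <- cc[cc$significant, ]
cat(sprintf("\n%d edge-clinical correlations at p < 0.005 (of %d tested):\n",
            nrow(sig), nrow(cc)))
if (nrow(sig)) print(sig[, c("edge_label", "variable", "r", "p")],
                     digits = 3, row.names = FALSE)
write.table(cc, file.path(RESULTS_DIR, "clinical_correlations.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("Wrote characterization tables under", RESULTS_DIR, "\n")
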