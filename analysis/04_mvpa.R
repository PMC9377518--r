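#!/usr/bin/env Rscript
# Leave-one-subject-out linear SVM over the 10%..100% feature-selection
# grid, plus (optionally) the max-over-grid permutation test. The
# permutation test reruns the complete nested procedure per permutation, so
# at full cohort scale it costs roughly n_perm x the LOOCV runtime; pass a
# permutation count as the first argument to enable it, e.g.
#   Rscript analysis/04_mvpa.R 100

source("analysis/00_config.R")

n_perm <- if (length(commandArgs(TRUE)))
  as.integer(commandArgs(TRUE)[1]) else 0L

subjects <- read_subject_table(file.path(COHORT_DIR, "subjects.csv"))
edge_mat <- load_edge_matrix()

res <- loocv_classify(edge_mat, subjects$group)
metrics <- data.frame(percentage = res$percentages, res$metrics)
cat("Per-percentage held-out performance:\n")
print(metrics, digits = 3, row.names = FALSE)
cat(sprintf("\nFinal accuracy %.2f%% at the top %d%% of edges; AUC = %.3f\n",
            100 * res$final_accuracy, res$best_percentage, res$auc))

if (n_perm >= 100) {
  pt <- mvpa_permutation_test(edge_mat, subjects$group, n_perm = n_perm,
                              seed = SEED + 2, observed = res)
  metrics$fwe_p <- pt$fwe_p
  cat(sprintf("FWE-corrected p of the final accuracy: %.4g (%d permutations)\n",
              pt$fwe_p_final, n_perm))
} else {
  cat("Permutation test skipped (pass a count >= 100 to enable)\n")
}

write.table(metrics, file.path(RESULTS_DIR, "mvpa_metrics.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(res$roc, file.path(RESULTS_DIR, "roc_points.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

sel <- aggregate_selected_edges(res)
atlas <- build_default_atlas()
sel_out <- cbind(sel[1], edge_label = edge_labels(atlas, sel$edge), sel[-1])
write.table(sel_out, file.path(RESULTS_DIR, "selected_edges.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("Selected-edge set at %d%%: %d edges (%d positive, %d negative weights)\n",
            res$best_percentage, nrow(sel), sum(sel$weight > 0),
            sum(sel$weight < 0)))

eff <- demo_spec()$effect_edges
cat(sprintf("Implanted-edge recovery: %d of %d in the selected set\n",
            length(intersect(sel$edge, eff)), length(eff)))
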