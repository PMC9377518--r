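#!/usr/bin/env Rscript
# Read the cohort back through the real-data input path and compute each
# subject's Fisher-z edge vector (4005 canonical edges).

source("analysis/00_config.R")

atlas <- build_default_atlas()
subjects <- read_subject_table(file.path(COHORT_DIR, "subjects.csv"))
ts <- lapply(subjects$id, function(id) {
  read_timeseries(file.path(COHORT_DIR, paste0(id, "_timeseries.tsv")), atlas)
})
names(ts) <- subjects$id

edge_mat <- cohort_edge_matrix(ts)
cat(sprintf("Edge matrix: %d subjects x %d edges\n",
            nrow(edge_mat), ncol(edge_mat)))
cat(sprintf("Fisher-z range: %.2f to %.2f\n",
            min(edge_mat), max(edge_mat)))

write.table(cbind(id = rownames(edge_mat), as.data.frame(edge_mat)),
            edge_matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
cat("Wrote", edge_matrix_path, "\n")
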