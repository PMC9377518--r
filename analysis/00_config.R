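# Shared settings for the analysis scripts. Each numbered script can be run
# on its own (later stages read what earlier ones wrote under results/).
#
# The demonstration cohort mirrors a single-site case-control resting-state
# study: 21 subjects per group, 170 retained volumes, 90 regions, with a
# group effect of +0.5 correlation implanted on the 400 edges of a
# 29-region subnetwork and two clinical variables tied to specific edges.

library(fcmvpa)

SEED <- 20260924 %% 2147483647
RESULTS_DIR <- "results"
COHORT_DIR <- file.path(RESULTS_DIR, "cohort")

demo_spec <- function(seed = SEED) {
  eff <- subnetwork_effect_edges(90, 400)
  cohort_spec(
    n_per_group = 21, n_timepoints = 170,
    effect_edges = eff, effect_delta = 0.5,
    clinical_links = list(
      list(edge = eff[1], variable = "AHI", r = -0.607),
      list(edge = eff[2], variable = "pct_tst_below_90", r = 0.705)
    ),
    seed = seed
  )
}

edge_matrix_path <- file.path(RESULTS_DIR, "edge_matrix.tsv")

load_edge_matrix <- function() {
  d <- read.delim(edge_matrix_path, check.names = FALSE)
  m <- as.matrix(d[, -1])
  rownames(m) <- d$id
  colnames(m) <- NULL
  m
}
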