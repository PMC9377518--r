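# Shared fixture builders.

# A small cohort, cached per parameter set within the session.
tiny_cohort <- local({
  cache <- list()
  function(n_per_group = 6, n_regions = 10, n_timepoints = 40, seed = 101,
           ...) {
    key <- paste(n_per_group, n_regions, n_timepoints, seed,
                 deparse(list(...)), collapse = "|")
    if (is.null(cache[[key]])) {
      spec <- cohort_spec(n_per_group = n_per_group, n_regions = n_regions,
                          n_timepoints = n_timepoints, seed = seed, ...)
      co <- sample_cohort(spec)
      co$edge_matrix <- cohort_edge_matrix(co$timeseries)
      cache[[key]] <<- co
    }
    cache[[key]]
  }
})

# Build an edge set with prescribed intra-network counts per network and a
# prescribed total number of inter-network edges, drawn deterministically
# from the canonical edge order.
fixture_edge_set <- function(atlas, intra_counts, n_inter) {
  E <- n_edges(nrow(atlas))
  p <- pair_of_edge(seq_len(E), nrow(atlas))
  neta <- atlas$network[p[, "i"]]
  netb <- atlas$network[p[, "j"]]
  chosen <- integer(0)
  for (nw in names(intra_counts)) {
    pool <- which(neta == nw & netb == nw)
    k <- intra_counts[[nw]]
    stopifnot(length(pool) >= k)
    chosen <- c(chosen, pool[seq_len(k)])
  }
  pool_inter <- which(as.character(neta) != as.character(netb))
  chosen <- c(chosen, pool_inter[seq_len(n_inter)])
  sort(chosen)
}
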