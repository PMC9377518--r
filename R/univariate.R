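#' Vectorised pooled-variance two-sample t statistics
#'
#' Student (pooled-variance) two-sample t per column, with the sign
#' convention t > 0 when group A has the larger mean. Pooled variance
#' matches equal-variance group comparison software conventions for
#' edgewise tests; group sizes in case-control FC designs are typically
#' equal, where Student and Welch coincide in the balanced-variance case.
#'
#' @param xa,xb Numeric matrices (subjects x features) for groups A and B;
#'   vectors are treated as single-feature matrices.
#' @return List with `t`, two-tailed `p`, `df`, and `degenerate` (logical,
#'   TRUE where the pooled variance is zero so t is undefined; t and p are
#'   NA there).
#' @export
pooled_ttest <- function(xa, xb) {
  if (is.vector(xa)) xa <- matrix(xa, ncol = 1)
  if (is.vector(xb)) xb <- matrix(xb, ncol = 1)
  na <- nrow(xa); nb <- nrow(xb)
  stopifnot(na >= 2, nb >= 2, ncol(xa) == ncol(xb))
  ma <- colMeans(xa); mb <- colMeans(xb)
  ssa <- colSums(sweep(xa, 2, ma)^2)
  ssb <- colSums(sweep(xb, 2, mb)^2)
  df <- na + nb - 2
  sp2 <- (ssa + ssb) / df
  degenerate <- sp2 <= 0
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t <- (ma - mb) / se
  t[degenerate] <- NA_real_
  p <- 2 * pt(-abs(t), df)
  list(t = t, p = p, df = df, degenerate = degenerate)
}

#' Edgewise two-sample t-tests with multiple-comparison masks
#'
#' Compares every Fisher-z edge between two groups with a pooled-variance
#' two-sample t-test and reports significance masks under Bonferroni
#' (corrected p < `alpha`) and Benjamini-Hochberg FDR (q < `q`) control.
#' By convention group A is the control group, so t > 0 marks edges with
#' larger connectivity in controls.
#'
#' @param xa,xb Subjects x edges Fisher-z matrices for groups A (controls)
#'   and B (patients).
#' @param alpha Bonferroni family-wise level.
#' @param q FDR level.
#' @return A list of class `univariate_result`: data.frame `edges` (edge,
#'   t, p, bonferroni, fdr), plus `df`, `alpha`, `q`, `n_degenerate`.
#' @export
edgewise_ttest <- function(xa, xb, alpha = 0.05, q = 0.05) {
  tt <- pooled_ttest(xa, xb)
  res <- data.frame(edge = seq_along(tt$t), t = tt$t, p = tt$p,
                    bonferroni = bonferroni_mask(tt$p, alpha),
                    fdr = bh_fdr_mask(tt$p, q))
  out <- list(edges = res, df = tt$df, alpha = alpha, q = q,
              n_degenerate = sum(tt$degenerate))
  class(out) <- "univariate_result"
  out
}

#' Bonferroni and Benjamini-Hochberg significance masks
#'
#' `bonferroni_mask` flags p-values with p * m < alpha (m = number of
#' finite p-values). `bh_fdr_mask` applies the Benjamini-Hochberg step-up
#' procedure at level q (via [stats::p.adjust()]). NA p-values (degenerate
#' edges) are never flagged.
#'
#' @param p Vector of p-values (NAs allowed, excluded from m).
#' @param alpha,q Levels.
#' @return Logical mask the length of `p`.
#' @export
bonferroni_mask <- function(p, alpha = 0.05) {
  m <- sum(!is.na(p))
  mask <- p * m < alpha
  mask[is.na(mask)] <- FALSE
  mask
}

#' @rdname bonferroni_mask
#' @export
bh_fdr_mask <- function(p, q = 0.05) {
  mask <- p.adjust(p, method = "BH") <= q
  mask[is.na(mask)] <- FALSE
  mask
}

# Suprathreshold component extents for one direction. tvals over edges;
# returns list(components = list of integer edge vectors, extents).
nbs_components <- function(tvals, t_crit, n_regions) {
  sup <- which(!is.na(tvals) & tvals > t_crit)
  if (!length(sup))
    return(list(components = list(), extents = integer(0)))
  p <- pair_of_edge(sup, n_regions)
  g <- igraph::graph_from_edgelist(p, directed = FALSE)
  memb <- igraph::components(g)$membership
  comp_of_edge <- memb[p[, "i"]]  # both endpoints share a component
  comps <- split(sup, comp_of_edge)
  extents <- lengths(comps)
  ord <- order(-extents)
  list(components = unname(comps[ord]), extents = unname(extents[ord]))
}

nbs_max_extent <- function(tvals, t_crit, n_regions) {
  max_pos <- if (any(!is.na(tvals) & tvals > t_crit))
    max(nbs_components(tvals, t_crit, n_regions)$extents) else 0L
  max_neg <- if (any(!is.na(tvals) & -tvals > t_crit))
    max(nbs_components(-tvals, t_crit, n_regions)$extents) else 0L
  max(max_pos, max_neg)
}

#' Network-based statistic (NBS)
#'
#' Cluster-level inference on the edge graph. Edgewise pooled t statistics
#' are thresholded at the cluster-defining level `cdt_p` (two-sided,
#' applied per direction: edges with |t| above the two-sided critical value
#' and the direction's sign), connected components of the suprathreshold
#' graph are found per direction, and each component's extent (edge count)
#' is compared against a permutation null of the maximal extent over both
#' directions under random relabelling of subjects.
#'
#' @param xa,xb Subjects x edges Fisher-z matrices (A = controls).
#' @param n_regions Number of regions (edges must equal n(n-1)/2).
#' @param cdt_p Cluster-defining two-sided p threshold (default 0.001).
#' @param n_perm Number of label permutations (default 10000), or
#'   `exhaustive = TRUE` to enumerate every assignment of subjects to
#'   groups (feasible for small n).
#' @param seed RNG seed for the permutation stream.
#' @param exhaustive Enumerate all label assignments instead of sampling.
#' @return A list of class `nbs_result`: `components` — data.frame
#'   (component id, direction `"A>B"`/`"B>A"`, extent, corrected p) —
#'   `component_edges` (list of edge-index vectors), `t_crit`, `cdt_p`,
#'   `null_max` (the permutation maxima), `n_perm`, `seed`. Corrected p is
#'   the proportion of null maxima >= the extent, floored at 1/n_perm for
#'   sampled permutations.
#' @export
nbs <- function(xa, xb, n_regions, cdt_p = 0.001, n_perm = 10000L,
                seed = 1L, exhaustive = FALSE) {
  stopifnot(ncol(xa) == n_edges(n_regions))
  if (!exhaustive && n_perm < 100) stop("n_perm must be >= 100")
  na <- nrow(xa); nb <- nrow(xb)
  df <- na + nb - 2
  t_crit <- qt(1 - cdt_p / 2, df)
  obs <- pooled_ttest(xa, xb)

  res_pos <- nbs_components(obs$t, t_crit, n_regions)
  res_neg <- nbs_components(-obs$t, t_crit, n_regions)
  directions <- c(rep("A>B", length(res_pos$extents)),
                  rep("B>A", length(res_neg$extents)))
  extents <- c(res_pos$extents, res_neg$extents)
  comp_edges <- c(res_pos$components, res_neg$components)

  x <- rbind(xa, xb)
  if (exhaustive) {
    splits <- combn(na + nb, na)
    null_max <- apply(splits, 2, function(ia) {
      perm <- pooled_ttest(x[ia, , drop = FALSE], x[-ia, , drop = FALSE])
      nbs_max_extent(perm$t, t_crit, n_regions)
    })
    n_perm <- ncol(splits)
    floor_p <- 0
  } else {
    set.seed(seed)
    null_max <- vapply(seq_len(n_perm), function(b) {
      ia <- sample(na + nb, na)
      perm <- pooled_ttest(x[ia, , drop = FALSE], x[-ia, , drop = FALSE])
      nbs_max_extent(perm$t, t_crit, n_regions)
    }, 0L)
    floor_p <- 1 / n_perm
  }

  corrected_p <- vapply(extents, function(e) {
    max(mean(null_max >= e), floor_p)
  }, 0)
  ord <- order(-extents)
  components <- data.frame(
    component = seq_along(ord),
    direction = directions[ord],
    extent = as.integer(extents[ord]),
    corrected_p = corrected_p[ord]
  )
  out <- list(components = components, component_edges = comp_edges[ord],
              t_crit = t_crit, cdt_p = cdt_p, null_max = null_max,
              n_perm = n_perm, seed = if (exhaustive) NA_integer_ else seed,
              exhaustive = exhaustive)
  class(out) <- "nbs_result"
  out
}

#' Group comparison table for demographic and clinical variables
#'
#' Per-variable group means, SDs and pooled-variance two-sample t-tests
#' (two-tailed), the standard "Table of demographics" of a case-control
#' study. Missing values are excluded pairwise and counted.
#'
#' @param subjects Subject table with columns `group` (two levels) and the
#'   clinical variables.
#' @param variables Variables to compare (default: all of
#'   [clinical_variables()] present in the table).
#' @param group_a Label of the first group (its mean enters t with positive
#'   sign); default `"HC"`.
#' @return Data.frame: variable, per-group mean/sd/n, n_missing, t, p.
#' @export
demographics_table <- function(subjects,
                               variables = intersect(clinical_variables(),
                                                     names(subjects)),
                               group_a = "HC") {
  stopifnot("group" %in% names(subjects), length(variables) > 0)
  gl <- unique(subjects$group)
  stopifnot(length(gl) == 2, group_a %in% gl)
  group_b <- setdiff(gl, group_a)
  rows <- lapply(variables, function(v) {
    va <- subjects[[v]][subjects$group == group_a]
    vb <- subjects[[v]][subjects$group == group_b]
    n_missing <- sum(is.na(va)) + sum(is.na(vb))
    va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
    tt <- pooled_ttest(va, vb)
    data.frame(variable = v,
               mean_a = mean(va), sd_a = sd(va), n_a = length(va),
               mean_b = mean(vb), sd_b = sd(vb), n_b = length(vb),
               n_missing = n_missing, t = tt$t, p = tt$p)
  })
  out <- do.call(rbind, rows)
  names(out) <- sub("_a$", paste0("_", group_a), names(out))
  names(out) <- sub("_b$", paste0("_", group_b), names(out))
  rownames(out) <- NULL
  out
}
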