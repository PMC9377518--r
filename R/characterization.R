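#' Signed weighted degrees of the selected edges
#'
#' For every region, sums the positive weights and (separately) the
#' negative weights of the selected edges incident to it — the region's
#' positive and negative weighted degree. Regions whose degree exceeds the
#' across-region mean by 1 or 2 SDs (for positive degrees; falls below
#' mean - k SD for negative degrees) are flagged; the mean and SD are taken
#' over all regions, zeros included.
#'
#' @param edges A `selected_edge_set` (data.frame with `edge`, `weight`).
#' @param atlas The region atlas.
#' @param use_abs If TRUE, thresholds for the negative degrees are applied
#'   on absolute values (equivalent flags, provided for plotting parity).
#' @return Data.frame: region `index`, `label`, `network`, `pos_degree`,
#'   `neg_degree`, flags `pos_gt_1sd`, `pos_gt_2sd`, `neg_lt_1sd`,
#'   `neg_lt_2sd`; attributes `pos_mean`, `pos_sd`, `neg_mean`, `neg_sd`.
#' @export
weighted_degree <- function(edges, atlas, use_abs = FALSE) {
  n <- nrow(atlas)
  p <- pair_of_edge(edges$edge, n)
  w <- edges$weight
  pos <- pmax(w, 0)
  neg <- pmin(w, 0)
  pos_deg <- neg_deg <- numeric(n)
  for (side in c("i", "j")) {
    pos_deg <- pos_deg + as.numeric(tapply(pos, factor(p[, side], levels = 1:n),
                                           sum, default = 0))
    neg_deg <- neg_deg + as.numeric(tapply(neg, factor(p[, side], levels = 1:n),
                                           sum, default = 0))
  }
  pm <- mean(pos_deg); ps <- sd(pos_deg)
  nd <- if (use_abs) abs(neg_deg) else neg_deg
  nm <- mean(nd); ns <- sd(nd)
  out <- data.frame(
    index = atlas$index, label = atlas$label, network = atlas$network,
    pos_degree = pos_deg, neg_degree = neg_deg,
    pos_gt_1sd = pos_deg > pm + ps,
    pos_gt_2sd = pos_deg > pm + 2 * ps,
    neg_lt_1sd = if (use_abs) nd > nm + ns else nd < nm - ns,
    neg_lt_2sd = if (use_abs) nd > nm + 2 * ns else nd < nm - 2 * ns
  )
  attr(out, "pos_mean") <- pm; attr(out, "pos_sd") <- ps
  attr(out, "neg_mean") <- nm; attr(out, "neg_sd") <- ns
  out
}

#' Intra-/inter-network summary of the selected edges
#'
#' Classifies each selected edge by the functional networks of its two
#' endpoint regions and standardizes the per-network-pair counts by the
#' number of possible edges of that pair (from [possible_edge_counts()]),
#' expressed as percentages. The diagonal holds intra-network figures.
#'
#' @param edges A `selected_edge_set` (only `edge` is used) or integer
#'   vector of edge indices.
#' @param atlas The region atlas.
#' @return List of class `network_fc_summary`: `table` (data.frame
#'   network_a, network_b, type, n_selected, n_possible, percent),
#'   `count_matrix` / `percent_matrix` (6 x 6 symmetric), and `totals`
#'   (n_intra, n_inter, possible_intra, possible_inter, mean_intra_pct,
#'   mean_inter_pct — the means are pooled: 100 * total count / total
#'   possible).
#' @export
network_summary <- function(edges, atlas) {
  if (is.data.frame(edges)) edges <- edges$edge
  validate_atlas(atlas)
  lv <- levels(atlas$network)
  poss <- possible_edge_counts(atlas)
  p <- pair_of_edge(edges, nrow(atlas))
  na_ <- as.integer(atlas$network[p[, "i"]])
  nb_ <- as.integer(atlas$network[p[, "j"]])
  a <- pmin(na_, nb_); b <- pmax(na_, nb_)
  key <- paste(lv[a], lv[b])
  cnt <- table(factor(key, levels = paste(poss$network_a, poss$network_b)))
  tab <- poss
  tab$n_selected <- as.integer(cnt)
  tab$percent <- 100 * tab$n_selected / tab$n_possible
  tab <- tab[, c("network_a", "network_b", "type", "n_selected",
                 "n_possible", "percent")]
  cm <- pm <- matrix(0, length(lv), length(lv), dimnames = list(lv, lv))
  ia <- as.integer(tab$network_a); ib <- as.integer(tab$network_b)
  cm[cbind(ia, ib)] <- tab$n_selected; cm[cbind(ib, ia)] <- tab$n_selected
  pm[cbind(ia, ib)] <- tab$percent;    pm[cbind(ib, ia)] <- tab$percent
  intra <- tab$type == "intra"
  totals <- list(
    n_intra = sum(tab$n_selected[intra]),
    n_inter = sum(tab$n_selected[!intra]),
    possible_intra = sum(tab$n_possible[intra]),
    possible_inter = sum(tab$n_possible[!intra]),
    mean_intra_pct = 100 * sum(tab$n_selected[intra]) /
      sum(tab$n_possible[intra]),
    mean_inter_pct = 100 * sum(tab$n_selected[!intra]) /
      sum(tab$n_possible[!intra])
  )
  out <- list(table = tab, count_matrix = cm, percent_matrix = pm,
              totals = totals)
  class(out) <- "network_fc_summary"
  out
}

#' Correlations between selected edges and clinical variables
#'
#' Pearson correlation (two-tailed) of each selected edge's Fisher-z values
#' against each requested clinical variable, computed within the patient
#' group only. Pairs with p below `alpha` (default 0.005, uncorrected) are
#' flagged; Benjamini-Hochberg q-values over all tested pairs are included
#' as a supplementary column for users who prefer corrected inference.
#'
#' @param edges A `selected_edge_set` or integer vector of edge indices.
#' @param edge_matrix Patients x edges Fisher-z matrix (patients only).
#' @param subjects Patient rows of the subject table (same order as
#'   `edge_matrix` rows).
#' @param variables Clinical variable names (default: AHI and the
#'   percentage of sleep time below 90% oxygen saturation).
#' @param alpha Uncorrected significance level (default 0.005).
#' @param atlas Optional atlas for human-readable edge labels.
#' @return Data.frame: `edge`, (`edge_label`,) `variable`, `r`, `p`, `n`,
#'   `q`, `significant`. Constant variables or edges give NA r and are
#'   never flagged.
#' @export
clinical_correlation <- function(edges, edge_matrix, subjects,
                                 variables = c("AHI", "pct_tst_below_90"),
                                 alpha = 0.005, atlas = NULL) {
  if (is.data.frame(edges)) edges <- edges$edge
  stopifnot(nrow(edge_matrix) == nrow(subjects), nrow(subjects) >= 4)
  missing_vars <- setdiff(variables, names(subjects))
  if (length(missing_vars))
    stop("clinical variable(s) not in subject table: ",
         paste(missing_vars, collapse = ", "))
  grid <- expand.grid(edge = edges, variable = variables,
                      stringsAsFactors = FALSE)
  stats_list <- mapply(function(e, v) {
    x <- edge_matrix[, e]
    yv <- subjects[[v]]
    ok <- complete.cases(x, yv)
    nn <- sum(ok)
    if (nn < 4 || sd(x[ok]) == 0 || sd(yv[ok]) == 0)
      return(c(r = NA_real_, p = NA_real_, n = nn))
    ct <- stats::cor.test(x[ok], yv[ok], method = "pearson")
    c(r = unname(ct$estimate), p = ct$p.value, n = nn)
  }, grid$edge, grid$variable)
  out <- data.frame(edge = grid$edge, variable = grid$variable,
                    r = stats_list["r", ], p = stats_list["p", ],
                    n = as.integer(stats_list["n", ]))
  if (!is.null(atlas))
    out <- cbind(out[1], edge_label = edge_labels(atlas, out$edge),
                 out[-1])
  out$q <- p.adjust(out$p, method = "BH")
  out$significant <- !is.na(out$p) & out$p < alpha
  rownames(out) <- NULL
  out
}
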