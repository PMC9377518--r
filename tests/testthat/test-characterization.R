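atlas90 <- build_default_atlas()

test_that("weighted degrees honour the conservation identity", {
  # single positive edge: both endpoints carry its weight
  one <- data.frame(edge = edge_index(3, 17, 90), weight = 0.5,
                    frequency = 1)
  deg <- weighted_degree(one, atlas90)
  expect_equal(deg$pos_degree[c(3, 17)], c(0.5, 0.5))
  expect_equal(sum(deg$pos_degree), 1)
  expect_equal(sum(deg$neg_degree), 0)

  # random edge sets: sum of degrees is twice the sum of weights, per sign
  set.seed(91)
  for (rep in 1:5) {
    ed <- data.frame(edge = sample(4005, 150),
                     weight = rnorm(150), frequency = 1)
    deg <- weighted_degree(ed, atlas90)
    expect_equal(sum(deg$pos_degree), 2 * sum(pmax(ed$weight, 0)))
    expect_equal(sum(deg$neg_degree), 2 * sum(pmin(ed$weight, 0)))
  }
})

test_that("degree thresholds single out a concentrated hub region", {
  # all weight on edges incident to region 7
  others <- setdiff(1:20, 7)
  ed <- data.frame(edge = edge_index(rep(7, 19), others, 90),
                   weight = 0.4, frequency = 1)
  deg <- weighted_degree(ed, atlas90)
  expect_true(deg$pos_gt_2sd[7])
  expect_equal(sum(deg$pos_gt_2sd), 1)
  neg <- ed; neg$weight <- -0.4
  degn <- weighted_degree(neg, atlas90)
  expect_true(degn$neg_lt_2sd[7])
  degn_abs <- weighted_degree(neg, atlas90, use_abs = TRUE)
  expect_equal(degn_abs$neg_lt_2sd, degn$neg_lt_2sd)
})

test_that("network summary reproduces the standardized percentages", {
  intra_counts <- c(VN = 9, SMN = 4, AN = 8, FPN = 4, DMN = 30, LS = 10)
  edges <- fixture_edge_set(atlas90, intra_counts, n_inter = 335)
  ns <- network_summary(edges, atlas90)
  tab <- ns$table
  intra <- tab[tab$type == "intra", ]
  got <- setNames(round(intra$percent, 2), as.character(intra$network_a))
  expect_equal(got[c("VN", "SMN", "AN", "FPN", "DMN", "LS")],
               c(VN = 9.89, SMN = 6.06, AN = 7.62, FPN = 8.89,
                 DMN = 11.86, LS = 8.33))
  expect_equal(ns$totals$n_intra, 65)
  expect_equal(ns$totals$n_inter, 335)
  expect_equal(round(ns$totals$mean_intra_pct, 2), 9.56)
  expect_equal(round(ns$totals$mean_inter_pct, 2), 10.08)
  expect_equal(sum(tab$n_selected), length(edges))
  # symmetric matrices agree with the table
  expect_equal(ns$count_matrix["DMN", "DMN"], 30)
  expect_true(isSymmetric(ns$count_matrix))
  expect_true(isSymmetric(ns$percent_matrix))
})

test_that("network summary totals hold for arbitrary edge sets", {
  set.seed(92)
  for (rep in 1:5) {
    edges <- sample(4005, sample(50:500, 1))
    ns <- network_summary(edges, atlas90)
    expect_equal(sum(ns$table$n_selected), length(edges))
    expect_equal(ns$totals$n_intra + ns$totals$n_inter, length(edges))
    expect_equal(ns$totals$possible_intra, 680L)
    expect_equal(ns$totals$possible_inter, 3325L)
    expect_equal(ns$totals$mean_intra_pct,
                 100 * ns$totals$n_intra / 680)
  }
})

test_that("clinical correlations match the textbook formula", {
  co <- tiny_cohort(n_per_group = 8, n_regions = 8, n_timepoints = 30,
                    seed = 93)
  pat <- co$subjects$group == "OSA"
  em <- cohort_edge_matrix(co$timeseries[pat])
  subj <- co$subjects[pat, ]
  edges <- c(1, 4, 9)
  cc <- clinical_correlation(edges, em, subj,
                             variables = c("AHI", "pct_tst_below_90"))
  expect_equal(nrow(cc), 6)
  for (k in seq_len(nrow(cc))) {
    expect_equal(cc$r[k],
                 oracle_pearson(em[, cc$edge[k]], subj[[cc$variable[k]]]),
                 tolerance = 1e-12)
    ref <- stats::cor.test(em[, cc$edge[k]], subj[[cc$variable[k]]])
    expect_equal(cc$p[k], ref$p.value, tolerance = 1e-12)
  }
  expect_true(all(abs(cc$r) <= 1))
  # a variable equal to an edge's values correlates perfectly
  subj$AHI <- em[, 4]
  cc1 <- clinical_correlation(4, em, subj, variables = "AHI")
  expect_equal(cc1$r, 1)
  expect_true(cc1$significant)
  # a constant variable is flagged, not crashed on
  subj$AHI <- 5
  cc0 <- clinical_correlation(4, em, subj, variables = "AHI")
  expect_true(is.na(cc0$r))
  expect_false(cc0$significant)
  expect_error(clinical_correlation(4, em, subj, variables = "nope"),
               "not in subject table")
})

test_that("generator clinical links are recovered through the full path", {
  spec <- cohort_spec(n_per_group = 60, n_regions = 8, n_timepoints = 50,
                      seed = 94,
                      clinical_links = list(list(edge = 3, variable = "AHI",
                                                 r = 0.7)))
  co <- sample_cohort(spec)
  pat <- co$subjects$group == "OSA"
  em <- cohort_edge_matrix(co$timeseries[pat])
  cc <- clinical_correlation(3, em, co$subjects[pat, ], variables = "AHI")
  expect_lt(abs(cc$r - 0.7), 0.2)
})
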