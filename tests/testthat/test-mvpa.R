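test_that("F scores obey the F = t-squared identity and ranking rules", {
  co <- tiny_cohort()
  em <- cohort_edge_matrix(co$timeseries)
  y <- co$subjects$group
  fs <- f_score_rank(em, y)
  tt <- pooled_ttest(em[y == "HC", ], em[y == "OSA", ])
  expect_equal(fs$f, tt$t^2, tolerance = 1e-10)
  # subject order is irrelevant
  perm <- sample(nrow(em))
  expect_equal(f_score_rank(em[perm, ], y[perm])$f, fs$f)
  # identical group means give F = 0
  x0 <- rbind(matrix(1:6, 3, 2), matrix(1:6, 3, 2) + 0.0)
  x0[, 2] <- c(1, 2, 3, 3, 2, 1)
  f0 <- f_score_rank(x0, c(1, 1, 1, -1, -1, -1))
  expect_equal(f0$f[2], 0)
  # zero within-group variance with distinct means ranks first, flagged
  xd <- cbind(c(0, 0, 0, 1, 1, 1), rnorm(6))
  fd <- f_score_rank(xd, c(1, 1, 1, -1, -1, -1))
  expect_equal(fd$f[1], Inf)
  expect_true(fd$degenerate[1])
  expect_equal(fd$ranking[1], 1L)
  # ties break by ascending feature index
  xt <- cbind(a = c(0, 0, 1, 1), b = c(0, 0, 1, 1), c = c(0, 1, 0, 1))
  expect_equal(f_score_rank(xt, c(1, 1, -1, -1))$ranking, c(1L, 2L, 3L))
})

test_that("top-fraction selection floors the feature count", {
  expect_length(select_top_fraction(1:4005, 10), 400)
  expect_length(select_top_fraction(1:4005, 100), 4005)
  expect_equal(select_top_fraction(1:10, 10), 1L)
  expect_equal(select_top_fraction(c(7L, 2L, 9L), 100, 3), c(7L, 2L, 9L))
  expect_error(select_top_fraction(1:100, 0.5), "no features")
})

test_that("linear SVM matches an independent quadratic-programming solve", {
  set.seed(41)
  # separable toy, symmetric about the origin
  x1 <- rbind(c(1, 1), c(2, 1), c(-1, -1), c(-2, -1))
  y1 <- c(1, 1, -1, -1)
  m1 <- train_linear_svm(x1, y1, C = 10)
  expect_equal(sign(svm_decision(m1, x1)), y1)
  o1 <- oracle_svm_qp(x1, y1, C = 10)
  expect_equal(m1$w, o1$w, tolerance = 1e-4, ignore_attr = TRUE)
  expect_equal(m1$b, o1$b, tolerance = 1e-4)

  # soft-margin, non-separable case
  x2 <- matrix(rnorm(40), 20, 2)
  y2 <- ifelse(x2[, 1] + 0.5 * rnorm(20) > 0, 1, -1)
  if (length(unique(y2)) == 2) {
    m2 <- train_linear_svm(x2, y2, C = 1)
    o2 <- oracle_svm_qp(x2, y2, C = 1)
    expect_equal(m2$w, o2$w, tolerance = 1e-4, ignore_attr = TRUE)
    expect_equal(m2$b, o2$b, tolerance = 1e-3)
  }

  # duplicated feature columns share the weight equally, as the QP does
  x3 <- cbind(x2[, 1], x2[, 1], x2[, 2])
  m3 <- train_linear_svm(x3, y2, C = 1)
  o3 <- oracle_svm_qp(x3, y2, C = 1)
  expect_equal(m3$w[1], m3$w[2], tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(m3$w, o3$w, tolerance = 1e-4, ignore_attr = TRUE)

  # with a hard margin, rescaling features leaves the boundary in place:
  # w scales inversely, the margin location x where w.x + b = 0 doubles
  m4 <- train_linear_svm(2 * x1, y1, C = 1e4)
  expect_equal(m4$w, m1$w / 2, tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(m4$b, m1$b, tolerance = 1e-3)

  expect_error(train_linear_svm(x1, rep(1, 4)), "both classes")
})

test_that("decision orientation is fixed regardless of label order", {
  x <- rbind(c(2, 0), c(3, 1), c(-2, 0), c(-3, -1))
  for (ord in list(1:4, 4:1, c(3, 1, 4, 2))) {
    m <- train_linear_svm(x[ord, ], c(1, 1, -1, -1)[ord])
    expect_gt(svm_decision(m, c(2.5, 0.5)), 0)   # control side
    expect_lt(svm_decision(m, c(-2.5, -0.5)), 0) # patient side
  }
})

test_that("LOOCV separates strong effects and never leaks the test subject", {
  co <- tiny_cohort(n_per_group = 5, n_regions = 8, n_timepoints = 30,
                    seed = 505,
                    effect_edges = subnetwork_effect_edges(8, 10),
                    effect_delta = 0.8, rho_in = 0, rho_out = 0)
  em <- cohort_edge_matrix(co$timeseries)
  y <- co$subjects$group
  res <- loocv_classify(em, y, percentages = c(50, 100))
  expect_equal(unname(res$metrics[, "accuracy"]), c(1, 1))
  expect_equal(res$final_accuracy, 1)
  expect_equal(res$best_percentage, 50)  # smallest percentage wins ties
  expect_equal(res$auc, 1)

  # leakage guard: each fold's selected set must equal the ranking
  # computed without the held-out subject (and the leaky ranking differs
  # on constructed data with an outlier held-out subject)
  set.seed(66)
  xl <- matrix(rnorm(10 * 6, sd = 0.1), 10, 6)
  yl <- rep(c(1, -1), 5)
  xl[, 3] <- yl * 0.1 + rnorm(10, sd = 0.01)   # weaker informative edge
  xl[, 5] <- yl * 0.3 + rnorm(10, sd = 0.01)   # strongest without subject 1
  xl[1, 5] <- 50                               # outlier in held-out subject
  resl <- loocv_classify(xl, yl, percentages = c(20, 100))
  sel_fold1 <- resl$folds[[1]]$selected[[1]]
  nonleaky <- select_top_fraction(f_score_rank(xl[-1, ], yl[-1])$ranking,
                                  20, 6)
  leaky <- select_top_fraction(f_score_rank(xl, yl)$ranking, 20, 6)
  expect_equal(sel_fold1, nonleaky)
  expect_false(identical(nonleaky, leaky))
})

test_that("LOOCV accuracy sits at chance for label-independent data", {
  accs <- vapply(1:8, function(run) {
    set.seed(600 + run)
    x <- matrix(rnorm(16 * 30), 16, 30)
    y <- rep(c(1, -1), 8)[sample(16)]
    loocv_classify(x, y, percentages = c(50, 100))$metrics[1, "accuracy"]
  }, 0)
  expect_lt(abs(mean(accs) - 0.5), 0.2)
})

test_that("ROC/AUC equal brute-force pair counting, including ties", {
  expect_equal(roc_auc(c(5, 4, 1, 2, 0.5, 0), c(-1, -1, -1, 1, 1, 1))$auc,
               8 / 9)
  perfect <- roc_auc(c(3, 2, 1, -1, -2, -3), rep(c(-1, 1), each = 3))
  expect_equal(perfect$auc, 1)
  set.seed(71)
  for (rep in 1:10) {
    scores <- sample(c(rnorm(3), round(rnorm(3), 0)))  # induce ties
    labels <- c(rep(-1, 3), rep(1, 3))[sample(6)]
    ra <- roc_auc(scores, labels)
    expect_equal(ra$auc, oracle_auc(scores, labels))
    expect_equal(ra$curve$fpr[1], 0)
    expect_equal(ra$curve$tpr[nrow(ra$curve)], 1)
    expect_true(all(diff(ra$curve$fpr) >= 0) && all(diff(ra$curve$tpr) >= 0))
  }
  # label-independent scores: AUC near one half
  set.seed(72)
  big <- roc_auc(rnorm(2000), rep(c(1, -1), 1000))
  expect_lt(abs(big$auc - 0.5), 0.05)
})

test_that("max-over-grid permutation p-values behave and are reproducible", {
  co <- tiny_cohort(n_per_group = 5, n_regions = 8, n_timepoints = 30,
                    seed = 505,
                    effect_edges = subnetwork_effect_edges(8, 10),
                    effect_delta = 0.8, rho_in = 0, rho_out = 0)
  em <- cohort_edge_matrix(co$timeseries)
  y <- co$subjects$group
  obs <- loocv_classify(em, y, percentages = c(50, 100))
  pt <- mvpa_permutation_test(em, y, percentages = c(50, 100),
                              n_perm = 100, seed = 5, observed = obs)
  # perfectly separable truth: no permutation max can exceed it, so the
  # floor 1/n_perm applies
  expect_equal(pt$fwe_p_final, 1 / 100)
  expect_true(all(pt$fwe_p >= 1 / 100 & pt$fwe_p <= 1))
  pt2 <- mvpa_permutation_test(em, y, percentages = c(50, 100),
                               n_perm = 100, seed = 5, observed = obs)
  expect_identical(pt$null_max, pt2$null_max)
  # the global-shuffle variant is also exposed; with 10 subjects a global
  # shuffle occasionally reproduces the true labelling, so only the p-value
  # bounds are guaranteed
  ptg <- mvpa_permutation_test(em, y, percentages = c(50, 100),
                               n_perm = 100, seed = 5, mode = "global",
                               observed = obs)
  expect_true(all(ptg$fwe_p >= 1 / 100 & ptg$fwe_p <= 1))
})

test_that("selected-edge aggregation pools folds correctly", {
  co <- tiny_cohort(n_per_group = 5, n_regions = 8, n_timepoints = 30,
                    seed = 505,
                    effect_edges = subnetwork_effect_edges(8, 10),
                    effect_delta = 0.8, rho_in = 0, rho_out = 0)
  em <- cohort_edge_matrix(co$timeseries)
  res <- loocv_classify(em, co$subjects$group, percentages = c(50, 100))
  sel100 <- aggregate_selected_edges(res, 100)
  # identical selection in every fold at 100%: exactly E edges, freq 1
  expect_equal(sel100$edge, seq_len(n_edges(8)))
  expect_equal(sel100$frequency, rep(1, n_edges(8)))
  sel <- aggregate_selected_edges(res)
  expect_gte(nrow(sel), floor(0.5 * n_edges(8)))
  expect_true(all(sel$frequency >= 1 / 10 & sel$frequency <= 1))
  # per-edge weight is the mean over selecting folds
  e1 <- sel$edge[1]
  k <- which(res$percentages == res$best_percentage)
  w <- unlist(lapply(res$folds, function(f) {
    hit <- match(e1, f$selected[[k]])
    if (!is.na(hit)) f$w[[k]][hit]
  }))
  expect_equal(sel$weight[1], mean(w))
  # implanted edges are enriched among the selected (rank-enrichment)
  eff <- subnetwork_effect_edges(8, 10)
  ov <- length(intersect(sel$edge, eff))
  expect_lt(stats::phyper(ov - 1, 10, n_edges(8) - 10, nrow(sel),
                          lower.tail = FALSE), 0.05)
})
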