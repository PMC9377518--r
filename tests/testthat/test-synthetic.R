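test_that("group covariance construction honours the null and analytic cases", {
  spec0 <- cohort_spec(n_per_group = 4, n_regions = 8, n_timepoints = 20,
                       effect_delta = 0, seed = 1)
  cv0 <- make_group_covariances(spec0)
  expect_identical(cv0$control, cv0$patient)

  # uncorrelated background, one shifted edge: analytic, no repair needed
  spec1 <- cohort_spec(n_per_group = 4, n_regions = 8, n_timepoints = 20,
                       rho_in = 0, rho_out = 0, effect_edges = 3L,
                       effect_delta = 0.3, seed = 1)
  cv1 <- make_group_covariances(spec1)
  expect_false(cv1$repaired)
  expected <- diag(8)
  p <- pair_of_edge(3L, 8)
  expected[p] <- 0.3
  expected[p[, c(2, 1), drop = FALSE]] <- 0.3
  expect_equal(cv1$patient, expected)
  expect_equal(cv1$achieved_delta, 0.3)
})

test_that("both population matrices are valid correlation matrices", {
  specs <- list(
    cohort_spec(n_per_group = 4, seed = 1),
    cohort_spec(n_per_group = 4, effect_edges = subnetwork_effect_edges(90, 50),
                effect_delta = 0.4, seed = 1),
    cohort_spec(n_per_group = 4, n_regions = 12, n_timepoints = 30,
                rho_in = 0.5, rho_out = 0.2, effect_edges = 1:6,
                effect_delta = -0.3, seed = 1)
  )
  for (spec in specs) {
    cv <- make_group_covariances(spec)
    for (m in list(cv$control, cv$patient)) {
      expect_equal(m, t(m))
      expect_equal(unname(diag(m)), rep(1, nrow(m)))
      expect_true(all(abs(m) <= 1 + 1e-12))
      expect_gt(min(eigen(m, symmetric = TRUE, only.values = TRUE)$values),
                1e-10)
    }
  }
})

test_that("irreparable effect patterns are rejected, not silently shrunk", {
  # compound shift of every edge of a 5-region block to -0.8: the nearest
  # correlation matrix is bounded below at -1/4 pairwise, so achieved
  # deltas must fall short by more than half the request
  spec <- cohort_spec(n_per_group = 4, n_regions = 5, n_timepoints = 20,
                      rho_in = 0, rho_out = 0, effect_edges = 1:10,
                      effect_delta = -0.8, seed = 1)
  expect_error(make_group_covariances(spec), "repair moved")
})

test_that("cohorts are bit-identical under a fixed seed", {
  spec <- cohort_spec(n_per_group = 3, n_regions = 8, n_timepoints = 25,
                      seed = 77,
                      clinical_links = list(list(edge = 2, variable = "AHI",
                                                 r = 0.5)))
  c1 <- sample_cohort(spec)
  c2 <- sample_cohort(spec)
  expect_identical(c1$timeseries, c2$timeseries)
  expect_identical(c1$subjects, c2$subjects)
})

test_that("sampled connectivity converges to the population effect", {
  # long series: the sample FC difference on the shifted edge approaches
  # the implanted population delta
  spec <- cohort_spec(n_per_group = 2, n_regions = 6, n_timepoints = 20000,
                      rho_in = 0, rho_out = 0, effect_edges = 4L,
                      effect_delta = 0.3, ar1 = 0, seed = 5)
  co <- sample_cohort(spec)
  r_of <- function(ids) {
    mean(vapply(ids, function(s) {
      p <- pair_of_edge(4L, 6)
      cor(co$timeseries[[s]][, p[1, "i"]], co$timeseries[[s]][, p[1, "j"]])
    }, 0))
  }
  hc <- co$subjects$id[co$subjects$group == "HC"]
  pat <- co$subjects$id[co$subjects$group == "OSA"]
  expect_lt(abs((r_of(pat) - r_of(hc)) - 0.3), 0.05)
})

test_that("AR(1) filtering keeps the spatial correlation structure", {
  spec <- cohort_spec(n_per_group = 2, n_regions = 6, n_timepoints = 8000,
                      rho_in = 0.4, rho_out = 0.1, ar1 = 0.6, seed = 9)
  co <- sample_cohort(spec)
  x <- co$timeseries[[1]]
  # temporal smoothness: lag-1 autocorrelation near the AR coefficient
  ac1 <- mean(apply(x, 2, function(col) cor(col[-1], col[-length(col)])))
  expect_lt(abs(ac1 - 0.6), 0.07)
  # spatial structure: sample correlations near the population block values
  fc <- compute_fc(x)
  memb <- fcmvpa:::block_membership(6)
  same <- outer(memb, memb, "==") & upper.tri(fc)
  expect_lt(abs(mean(fc[same]) - 0.4), 0.07)
  expect_lt(abs(mean(fc[!same & upper.tri(fc)]) - 0.1), 0.07)
})

test_that("clinical links attain their target correlation", {
  spec <- cohort_spec(n_per_group = 200, n_regions = 8, n_timepoints = 60,
                      seed = 13,
                      clinical_links = list(
                        list(edge = 5, variable = "AHI", r = 0.7),
                        list(edge = 9, variable = "pct_tst_below_90", r = 0.7)
                      ))
  co <- sample_cohort(spec)
  pat <- co$subjects$group == "OSA"
  em <- cohort_edge_matrix(co$timeseries[pat])
  expect_lt(abs(cor(em[, 5], co$subjects$AHI[pat]) - 0.7), 0.1)
  expect_lt(abs(cor(em[, 9], co$subjects$pct_tst_below_90[pat]) - 0.7), 0.1)
  # unlinked group marginals stay in their physiological ranges
  expect_true(all(co$subjects$MMSE <= 30))
  expect_true(all(co$subjects$ESS >= 0 & co$subjects$ESS <= 24))
  expect_true(all(co$subjects$AHI >= 0))
  expect_true(all(co$subjects$pct_tst_below_90 >= 0 &
                    co$subjects$pct_tst_below_90 <= 100))
})
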