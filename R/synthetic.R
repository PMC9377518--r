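#' Specification of a synthetic two-group cohort
#'
#' Describes a synthetic case-control cohort of post-preprocessed ROI time
#' series. Control subjects are drawn from a block-structured population
#' correlation matrix (correlation `rho_in` between regions of the same
#' functional network, `rho_out` otherwise); patients share that structure
#' except on a designated edge subset where the population correlation is
#' shifted by `effect_delta` (and the shifted matrix is repaired to the
#' nearest valid correlation matrix). Clinical variables can be tied to
#' designated edges with a target Pearson correlation via a Gaussian copula.
#'
#' @param n_per_group Subjects per group (default 21, a typical single-site
#'   patient-control cohort).
#' @param n_regions Number of regions (default 90; atlas networks are used
#'   for the block structure when 90, contiguous pseudo-blocks otherwise).
#' @param n_timepoints Retained fMRI volumes per subject (default 170).
#' @param rho_in,rho_out Within- and between-network block correlations.
#' @param effect_edges Integer canonical edge indices carrying the group
#'   effect.
#' @param effect_delta Correlation shift added to `effect_edges` in the
#'   patient group.
#' @param ar1 Temporal AR(1) coefficient in [0, 1); default 0.3 mimics the
#'   smoothness of band-passed BOLD series.
#' @param clinical_links List of lists with fields `edge` (canonical edge
#'   index), `variable` (clinical variable name) and `r` (target Pearson
#'   correlation between the patients' Fisher-z edge values and the
#'   variable).
#' @param seed Integer RNG seed; the whole cohort is reproducible from it.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 21L, n_regions = 90L,
                        n_timepoints = 170L, rho_in = 0.3, rho_out = 0.1,
                        effect_edges = integer(0), effect_delta = 0,
                        ar1 = 0.3, clinical_links = list(), seed = 1L) {
  spec <- list(n_per_group = as.integer(n_per_group),
               n_regions = as.integer(n_regions),
               n_timepoints = as.integer(n_timepoints),
               rho_in = rho_in, rho_out = rho_out,
               effect_edges = as.integer(effect_edges),
               effect_delta = effect_delta, ar1 = ar1,
               clinical_links = clinical_links, seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

#' @rdname cohort_spec
#' @param spec A `cohort_spec`.
#' @export
validate_cohort_spec <- function(spec) {
  stopifnot(spec$n_per_group >= 2, spec$n_regions >= 3,
            spec$n_timepoints >= 3,
            spec$ar1 >= 0, spec$ar1 < 1,
            abs(spec$rho_in) < 1, abs(spec$rho_out) < 1)
  E <- n_edges(spec$n_regions)
  if (length(spec$effect_edges) &&
      (min(spec$effect_edges) < 1 || max(spec$effect_edges) > E))
    stop("effect_edges out of range 1..", E)
  for (lk in spec$clinical_links) {
    stopifnot(all(c("edge", "variable", "r") %in% names(lk)))
    if (abs(lk$r) > 1) stop("clinical link target |r| must be <= 1")
  }
  invisible(spec)
}

# Network membership used for the block correlation structure: the default
# atlas when n_regions == 90, otherwise up-to-six contiguous pseudo-blocks.
block_membership <- function(n_regions) {
  if (n_regions == 90L) {
    as.integer(build_default_atlas()$network)
  } else {
    # contiguous pseudo-networks of at least two regions each
    n_blocks <- max(1L, min(6L, n_regions %/% 2L))
    sort(rep_len(seq_len(n_blocks), n_regions))
  }
}

#' Population correlation matrices for the two groups
#'
#' Builds the control-group block correlation matrix and the patient-group
#' matrix obtained by adding `effect_delta` on `effect_edges`. If the
#' shifted matrix is not positive definite it is repaired to the nearest
#' correlation matrix (Higham alternating projections, via
#' [Matrix::nearPD()]); the achieved shifts on the effect edges are then
#' verified against the requested one.
#'
#' @param spec A [cohort_spec()].
#' @return List with `control` and `patient` correlation matrices,
#'   `achieved_delta` (numeric vector over `effect_edges`) and `repaired`
#'   (logical).
#' @export
make_group_covariances <- function(spec) {
  validate_cohort_spec(spec)
  R <- spec$n_regions
  memb <- block_membership(R)
  control <- matrix(spec$rho_out, R, R)
  same <- outer(memb, memb, "==")
  control[same] <- spec$rho_in
  diag(control) <- 1
  if (min(eigen(control, symmetric = TRUE, only.values = TRUE)$values) <= 1e-10)
    stop("block correlation matrix is not positive definite; ",
         "reduce |rho_out| or |rho_in|")

  patient <- control
  repaired <- FALSE
  if (length(spec$effect_edges) && spec$effect_delta != 0) {
    p <- pair_of_edge(spec$effect_edges, R)
    patient[p] <- patient[p] + spec$effect_delta
    patient[p[, c(2, 1), drop = FALSE]] <- patient[p]
    patient[patient > 1] <- 1
    patient[patient < -1] <- -1
    diag(patient) <- 1
    ev <- eigen(patient, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-8) {
      repaired <- TRUE
      patient <- as.matrix(Matrix::nearPD(patient, corr = TRUE,
                                          maxit = 400)$mat)
      patient <- (patient + t(patient)) / 2
      diag(patient) <- 1
    }
    achieved <- patient[p] - control[p]
    if (any(abs(achieved - spec$effect_delta) > abs(spec$effect_delta) / 2))
      stop("correlation-matrix repair moved an effect edge by more than ",
           "half the requested delta; reduce effect_delta or the number ",
           "of effect edges")
  } else {
    achieved <- numeric(0)
  }
  list(control = control, patient = patient,
       achieved_delta = achieved, repaired = repaired)
}

# Stationary AR(1) series with unit marginal variance, one column per region.
ar1_noise <- function(n_timepoints, n_regions, phi) {
  z <- matrix(rnorm(n_timepoints * n_regions), n_timepoints, n_regions)
  if (phi == 0) return(z)
  innov <- z * sqrt(1 - phi^2)
  init <- rnorm(n_regions)  # stationary start
  apply(rbind(init, innov), 2, function(col) {
    stats::filter(col[-1], phi, method = "recursive", init = col[1])
  })
}

# mean/sd marginals of the clinical variables per group, following typical
# moderate-to-severe sleep-apnea cohorts. Shapes: "lnorm" = log-normal
# (positive, right-skewed), "norm" = normal clamped to [lo, hi].
.clinical_marginals <- list(
  OSA = list(
    age = list(shape = "norm", mean = 44.05, sd = 7.277, lo = 25, hi = 70),
    education = list(shape = "norm", mean = 13.48, sd = 3.092, lo = 0, hi = 25),
    BMI = list(shape = "norm", mean = 29.52, sd = 4.231, lo = 15, hi = 60),
    MMSE = list(shape = "norm", mean = 29.48, sd = 0.814, lo = 24, hi = 30),
    AHI = list(shape = "lnorm", mean = 54.35, sd = 19.97),
    pct_tst_below_90 = list(shape = "lnorm", mean = 18.66, sd = 21.10,
                            hi = 100),
    ESS = list(shape = "norm", mean = 14.67, sd = 7.262, lo = 0, hi = 24)
  ),
  HC = list(
    age = list(shape = "norm", mean = 40.62, sd = 11.404, lo = 25, hi = 70),
    education = list(shape = "norm", mean = 14.76, sd = 2.914, lo = 0, hi = 25),
    BMI = list(shape = "norm", mean = 24.95, sd = 3.173, lo = 15, hi = 60),
    MMSE = list(shape = "norm", mean = 29.86, sd = 0.359, lo = 24, hi = 30),
    AHI = list(shape = "lnorm", mean = 2.52, sd = 1.401),
    pct_tst_below_90 = list(shape = "lnorm", mean = 0.979, sd = 2.654,
                            hi = 100),
    ESS = list(shape = "norm", mean = 1.10, sd = 1.136, lo = 0, hi = 24)
  )
)

#' Clinical variable names of a subject record
#' @return Character vector of the clinical columns generated by
#'   [sample_cohort()].
#' @export
clinical_variables <- function() names(.clinical_marginals$OSA)

# Transform a standard-normal latent to the marginal of one variable.
# Returns the value and, as attribute, the Pearson attenuation factor of a
# monotone transform (1 for normal shapes; s/sqrt(e^s2 - 1) for log-normal).
marginal_transform <- function(latent, marg) {
  if (marg$shape == "lnorm") {
    s2 <- log(1 + (marg$sd / marg$mean)^2)
    s <- sqrt(s2)
    mu <- log(marg$mean) - s2 / 2
    v <- exp(mu + s * latent)
    if (!is.null(marg$hi)) v <- pmin(v, marg$hi)  # physiological ceiling
    v
  } else {
    pmin(pmax(marg$mean + marg$sd * latent, marg$lo), marg$hi)
  }
}

marginal_attenuation <- function(marg) {
  if (marg$shape == "lnorm") {
    s <- sqrt(log(1 + (marg$sd / marg$mean)^2))
    s / sqrt(exp(s^2) - 1)
  } else 1
}

#' Sample a synthetic cohort
#'
#' Draws per-subject ROI time series from the group population correlation
#' matrices (multivariate normal with AR(1) temporal autocorrelation; the
#' spatial mixing is applied after temporal filtering so the population
#' correlation structure is preserved exactly) and generates a clinical
#' table. Patient clinical variables named in `spec$clinical_links` are
#' generated from a Gaussian copula on the subject's observed Fisher-z edge
#' value; the latent correlation is attenuation-corrected for log-normal
#' marginals so the target Pearson correlation is attained in expectation on
#' the observed scale. Fully deterministic given `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return List of class `fc_cohort` with elements `timeseries` (list of
#'   T x R matrices, atlas labels as column names for 90 regions),
#'   `subjects` (data.frame: id, group, clinical variables), `covariances`
#'   (the [make_group_covariances()] output) and `spec`.
#' @export
sample_cohort <- function(spec) {
  validate_cohort_spec(spec)
  covs <- make_group_covariances(spec)
  set.seed(spec$seed)
  n <- spec$n_per_group
  groups <- rep(c("HC", "OSA"), each = n)
  ids <- sprintf("S%03d", seq_along(groups))
  chol_by_group <- list(HC = chol(covs$control), OSA = chol(covs$patient))
  labels <- if (spec$n_regions == 90L) build_default_atlas()$label else
    sprintf("R%02d", seq_len(spec$n_regions))

  ts_list <- vector("list", length(ids))
  names(ts_list) <- ids
  for (s in seq_along(ids)) {
    z <- ar1_noise(spec$n_timepoints, spec$n_regions, spec$ar1)
    x <- z %*% chol_by_group[[groups[s]]]
    colnames(x) <- labels
    ts_list[[s]] <- x
  }

  subjects <- data.frame(id = ids, group = groups, stringsAsFactors = FALSE)
  linked_vars <- vapply(spec$clinical_links, `[[`, "", "variable")
  for (v in clinical_variables()) {
    vals <- numeric(length(ids))
    for (g in c("HC", "OSA")) {
      idx <- which(groups == g)
      vals[idx] <- marginal_transform(rnorm(length(idx)),
                                      .clinical_marginals[[g]][[v]])
    }
    subjects[[v]] <- vals
  }
  # overwrite patient values for edge-linked variables using the copula
  if (length(spec$clinical_links)) {
    pat <- which(groups == "OSA")
    for (lk in spec$clinical_links) {
      marg <- .clinical_marginals$OSA[[lk$variable]]
      if (is.null(marg)) stop("unknown clinical variable: ", lk$variable)
      zedge <- vapply(ts_list[pat], function(x) {
        vectorize_fc(compute_fc(x), clip = TRUE)[lk$edge]
      }, 0)
      zstd <- as.numeric(scale(zedge))
      r_lat <- lk$r / marginal_attenuation(marg)
      if (abs(r_lat) > 0.99) {
        warning("clinical link target r = ", lk$r, " for ", lk$variable,
                " requires latent correlation beyond 0.99 after marginal ",
                "attenuation; capped")
        r_lat <- sign(r_lat) * 0.99
      }
      latent <- r_lat * zstd + sqrt(1 - r_lat^2) * rnorm(length(pat))
      subjects[[lk$variable]][pat] <- marginal_transform(latent, marg)
    }
  }
  subjects$MMSE <- round(subjects$MMSE, 0)
  subjects$ESS <- round(subjects$ESS, 0)

  out <- list(timeseries = ts_list, subjects = subjects,
              covariances = covs, spec = spec)
  class(out) <- "fc_cohort"
  out
}

#' Effect edges forming a coherent subnetwork
#'
#' Returns the first `k` canonical edge indices among all pairs of a region
#' subset. Concentrating the group effect on the pairs of a subnetwork
#' keeps the shifted correlation matrix close to positive definite (the
#' shift acts like an extra latent factor shared by those regions), whereas
#' the same number of randomly scattered shifted edges usually cannot form
#' a valid correlation matrix at comparable effect sizes.
#'
#' @param n_regions Total regions.
#' @param k Number of effect edges wanted.
#' @param regions Region subset (default: the smallest prefix of 1..n with
#'   at least `k` pairs).
#' @return Integer vector of `k` canonical edge indices.
#' @export
subnetwork_effect_edges <- function(n_regions, k, regions = NULL) {
  if (is.null(regions)) {
    m <- which(choose(seq_len(n_regions), 2) >= k)[1]
    if (is.na(m)) stop("not enough region pairs for ", k, " edges")
    regions <- seq_len(m)
  }
  pairs <- t(combn(regions, 2))
  if (nrow(pairs) < k) stop("region subset has fewer than ", k, " pairs")
  edge_index(pairs[, 1], pairs[, 2], n_regions)[seq_len(k)]
}

#' Write a cohort to disk in the real-data input formats
#'
#' Writes one TSV time-series file per subject (T rows x R columns, header =
#' region labels) plus a `subjects.csv` table — the same formats the
#' real-data path reads back with [read_timeseries()] and
#' [read_subject_table()].
#'
#' @param cohort A cohort from [sample_cohort()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$timeseries)) {
    write.table(cohort$timeseries[[id]],
                file.path(dir, paste0(id, "_timeseries.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.csv(cohort$subjects, file.path(dir, "subjects.csv"),
            row.names = FALSE)
  invisible(dir)
}
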