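#' Read a subject table
#'
#' Reads the subjects CSV (columns `id`, `group`, plus clinical variables)
#' with validation: duplicate ids and unknown group labels are rejected.
#'
#' @param path CSV path.
#' @return Data.frame of subject records.
#' @export
read_subject_table <- function(path) {
  if (!file.exists(path)) stop("subject table not found: ", path)
  subjects <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("id", "group")
  miss <- setdiff(required, names(subjects))
  if (length(miss))
    stop("subject table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(subjects$id))
    stop("duplicate subject ids: ",
         paste(unique(subjects$id[duplicated(subjects$id)]), collapse = ", "))
  bad <- setdiff(unique(subjects$group), c("OSA", "HC"))
  if (length(bad))
    stop("unknown group value(s): ", paste(bad, collapse = ", "),
         "; allowed: OSA, HC")
  subjects
}

#' Read a per-subject ROI time-series TSV
#'
#' Reads a T x R time-series matrix (header row = region labels) and
#' validates the column labels against the atlas.
#'
#' @param path TSV path.
#' @param atlas Atlas whose labels the header must match (in order).
#' @return Numeric T x R matrix.
#' @export
read_timeseries <- function(path, atlas = build_default_atlas()) {
  if (!file.exists(path)) stop("time-series file not found: ", path)
  d <- read.delim(path, check.names = FALSE)
  if (ncol(d) != nrow(atlas))
    stop("time-series file ", path, " has ", ncol(d),
         " columns; expected ", nrow(atlas))
  if (!identical(names(d), atlas$label))
    stop("time-series header of ", path,
         " does not match the atlas region labels")
  m <- as.matrix(d)
  if (!is.numeric(m)) stop("non-numeric cells in ", path)
  m
}

#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end analysis. Exactly one of
#' `synthetic` (a [cohort_spec()]) or `input_dir` (a directory holding
#' `subjects.csv` and `<id>_timeseries.tsv` files, as written by
#' [write_cohort()]) must be given.
#'
#' @param synthetic A [cohort_spec()], or NULL.
#' @param input_dir Directory of real input files, or NULL.
#' @param percentages Feature-selection grid.
#' @param C SVM cost.
#' @param n_perm_mvpa,n_perm_nbs Permutation counts for the classifier FWE
#'   test and for NBS.
#' @param alpha,q,cdt_p Bonferroni level, FDR level, NBS cluster-defining
#'   two-sided p.
#' @param clinical_vars Variables for the edge-clinical correlations.
#' @param clinical_alpha Uncorrected significance level for those.
#' @param run_mvpa_permutation Whether to run the (expensive) classifier
#'   permutation test.
#' @param seed Global seed; expanded into independent per-stage seeds so
#'   stages are reproducible in isolation.
#' @param out_dir Output directory.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL, input_dir = NULL,
                            percentages = seq(10, 100, 10), C = 1,
                            n_perm_mvpa = 200L, n_perm_nbs = 1000L,
                            alpha = 0.05, q = 0.05, cdt_p = 0.001,
                            clinical_vars = c("AHI", "pct_tst_below_90"),
                            clinical_alpha = 0.005,
                            run_mvpa_permutation = TRUE,
                            seed = 1L, out_dir) {
  if (is.null(synthetic) == is.null(input_dir))
    stop("provide exactly one of 'synthetic' or 'input_dir'")
  stopifnot(alpha > 0, alpha < 1, q > 0, q < 1, cdt_p > 0, cdt_p < 1,
            length(percentages) >= 1, seed < 2^31 - 10)
  cfg <- list(synthetic = synthetic, input_dir = input_dir,
              percentages = percentages, C = C,
              n_perm_mvpa = as.integer(n_perm_mvpa),
              n_perm_nbs = as.integer(n_perm_nbs),
              alpha = alpha, q = q, cdt_p = cdt_p,
              clinical_vars = clinical_vars,
              clinical_alpha = clinical_alpha,
              run_mvpa_permutation = isTRUE(run_mvpa_permutation),
              seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

# Independent per-stage seeds derived from the global one (kept < 2^31).
stage_seeds <- function(seed) {
  base <- as.integer(seed)
  list(cohort = base, nbs = (base + 1001L) %% .Machine$integer.max,
       mvpa = (base + 2002L) %% .Machine$integer.max)
}

write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Orchestrates cohort input (synthetic or from disk), connectivity,
#' univariate statistics (edgewise tests, NBS, demographics), the LOOCV
#' classifier with optional permutation FWE test, and characterization of
#' the selected edges. All module outputs are written as TSV/JSON under
#' `config$out_dir` together with a run manifest (config echo, seed,
#' package version, per-stage wall time). Rerunning with the same config
#' and seed reproduces every result file byte-identically.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- stage_seeds(config$seed)
  manifest <- list(seed = config$seed,
                   package_version = as.character(utils::packageVersion("fcmvpa")),
                   stages = list())
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      writeLines(paste("FAILED at stage:", name),
                 file.path(config$out_dir, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
    manifest$stages[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  atlas <- build_default_atlas()

  cohort <- stage("input", {
    if (!is.null(config$synthetic)) {
      spec <- config$synthetic
      spec$seed <- seeds$cohort
      sample_cohort(spec)
    } else {
      subjects <- read_subject_table(file.path(config$input_dir,
                                               "subjects.csv"))
      ts <- lapply(subjects$id, function(id) {
        read_timeseries(file.path(config$input_dir,
                                  paste0(id, "_timeseries.tsv")), atlas)
      })
      names(ts) <- subjects$id
      list(timeseries = ts, subjects = subjects)
    }
  })
  subjects <- cohort$subjects
  n_regions <- ncol(cohort$timeseries[[1]])
  if (n_regions != 90L) atlas <- NULL  # reduced synthetic parcellations

  edge_mat <- stage("connectivity", {
    cohort_edge_matrix(cohort$timeseries,
                       clip = !is.null(config$synthetic))
  })
  is_hc <- subjects$group == "HC"
  xa <- edge_mat[is_hc, , drop = FALSE]
  xb <- edge_mat[!is_hc, , drop = FALSE]

  univariate <- stage("univariate", {
    uni <- edgewise_ttest(xa, xb, alpha = config$alpha, q = config$q)
    nbs_res <- nbs(xa, xb, n_regions = n_regions, cdt_p = config$cdt_p,
                   n_perm = config$n_perm_nbs, seed = seeds$nbs)
    demo <- if (length(intersect(clinical_variables(), names(subjects))))
      demographics_table(subjects) else NULL
    edges_out <- uni$edges
    if (!is.null(atlas))
      edges_out <- cbind(edges_out[1],
                         edge_label = edge_labels(atlas, edges_out$edge),
                         edges_out[-1])
    write_tsv(edges_out, file.path(config$out_dir, "edgewise_tests.tsv"))
    if (!is.null(demo))
      write_tsv(demo, file.path(config$out_dir, "demographics.tsv"))
    jsonlite::write_json(
      list(cdt_p = nbs_res$cdt_p, t_crit = nbs_res$t_crit,
           n_perm = nbs_res$n_perm, seed = nbs_res$seed,
           components = nbs_res$components),
      file.path(config$out_dir, "nbs_summary.json"),
      auto_unbox = TRUE, digits = NA)
    list(edgewise = uni, nbs = nbs_res, demographics = demo)
  })

  mvpa_res <- stage("mvpa", {
    res <- loocv_classify(edge_mat, subjects$group,
                          percentages = config$percentages, C = config$C)
    perm <- NULL
    if (config$run_mvpa_permutation)
      perm <- mvpa_permutation_test(edge_mat, subjects$group,
                                    percentages = config$percentages,
                                    C = config$C,
                                    n_perm = config$n_perm_mvpa,
                                    seed = seeds$mvpa, observed = res)
    metrics_out <- data.frame(percentage = config$percentages,
                              res$metrics)
    if (!is.null(perm)) metrics_out$fwe_p <- perm$fwe_p
    write_tsv(metrics_out, file.path(config$out_dir, "mvpa_metrics.tsv"))
    write_tsv(res$roc, file.path(config$out_dir, "roc_points.tsv"))
    jsonlite::write_json(
      list(best_percentage = res$best_percentage,
           final_accuracy = res$final_accuracy, auc = res$auc,
           fwe_p_final = if (!is.null(perm)) perm$fwe_p_final else NULL,
           n_perm = if (!is.null(perm)) perm$n_perm else NULL),
      file.path(config$out_dir, "mvpa_summary.json"),
      auto_unbox = TRUE, digits = NA)
    list(result = res, permutation = perm)
  })

  characterization <- stage("characterization", {
    sel <- aggregate_selected_edges(mvpa_res$result)
    sel_out <- sel
    corr <- NULL
    net <- NULL
    if (!is.null(atlas)) {
      sel_out <- cbind(sel[1], edge_label = edge_labels(atlas, sel$edge),
                       sel[-1])
      deg <- weighted_degree(sel, atlas)
      net <- network_summary(sel, atlas)
      write_tsv(deg, file.path(config$out_dir, "weighted_degrees.tsv"))
      write_tsv(net$table, file.path(config$out_dir, "network_summary.tsv"))
    }
    pat <- !is_hc
    vars_ok <- intersect(config$clinical_vars, names(subjects))
    if (length(vars_ok) && sum(pat) >= 4) {
      corr <- clinical_correlation(sel, edge_mat[pat, , drop = FALSE],
                                   subjects[pat, , drop = FALSE],
                                   variables = vars_ok,
                                   alpha = config$clinical_alpha,
                                   atlas = atlas)
      write_tsv(corr, file.path(config$out_dir, "clinical_correlations.tsv"))
    }
    write_tsv(sel_out, file.path(config$out_dir, "selected_edges.tsv"))
    list(selected = sel, network = net, clinical = corr)
  })

  cfg_echo <- config
  cfg_echo$synthetic <- if (!is.null(config$synthetic))
    unclass(config$synthetic) else NULL
  manifest$config <- unclass(cfg_echo)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(cohort = cohort, edge_matrix = edge_mat,
                 univariate = univariate, mvpa = mvpa_res,
                 characterization = characterization,
                 manifest = manifest))
}
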