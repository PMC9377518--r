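# Label coding convention used throughout the classifier stack:
# controls (HC) are coded +1 and patients (OSA) -1, so a positive SVM
# weight marks a feature whose larger value pushes the decision toward HC
# (i.e. connectivity that is LOWER in patients). Sensitivity/specificity
# treat patients as the positive class.

#' Coerce labels to the +1 (control) / -1 (patient) coding
#'
#' @param y Labels: numeric +/-1, or character/factor with values
#'   `"HC"`/`"OSA"`.
#' @return Numeric vector of +1 / -1.
#' @export
code_labels <- function(y) {
  if (is.numeric(y)) {
    if (!all(y %in% c(-1, 1))) stop("numeric labels must be +1/-1")
    return(as.numeric(y))
  }
  y <- as.character(y)
  if (!all(y %in% c("HC", "OSA")))
    stop("labels must be 'HC'/'OSA' (or +1/-1)")
  ifelse(y == "HC", 1, -1)
}

#' Two-group F scores and feature ranking
#'
#' One-way two-group ANOVA F score per feature (between-group mean square
#' over within-group mean square), the classical filter criterion for
#' feature selection; for two groups F equals the square of the pooled
#' two-sample t statistic. Features are ranked by descending F with ties
#' broken by ascending feature index, so rankings are deterministic across
#' platforms.
#'
#' @param x Subjects x features training matrix.
#' @param y Training labels (see [code_labels()]); both classes required.
#' @return List: `f` (per-feature F; +Inf where the within-group variance
#'   is zero but the means differ, 0 where the feature is constant),
#'   `ranking` (feature indices, best first), `degenerate` (logical flags
#'   for zero within-group variance).
#' @export
f_score_rank <- function(x, y) {
  y <- code_labels(y)
  if (length(unique(y)) != 2) stop("both classes must be present")
  xa <- x[y > 0, , drop = FALSE]
  xb <- x[y < 0, , drop = FALSE]
  na <- nrow(xa); nb <- nrow(xb); n <- na + nb
  ma <- colMeans(xa); mb <- colMeans(xb); m <- colMeans(x)
  ss_between <- na * (ma - m)^2 + nb * (mb - m)^2
  ss_within <- colSums(sweep(xa, 2, ma)^2) + colSums(sweep(xb, 2, mb)^2)
  degenerate <- ss_within <= 0
  f <- (ss_between / 1) / (ss_within / (n - 2))
  f[degenerate & ss_between > 0] <- Inf
  f[degenerate & ss_between <= 0] <- 0
  list(f = f, ranking = order(-f, seq_along(f)), degenerate = degenerate)
}

#' Select the top fraction of a feature ranking
#'
#' Keeps the first floor(percent/100 * E) features of a ranking. Floor
#' rounding means a 10% selection over 4005 edges yields exactly 400.
#'
#' @param ranking Feature indices, best first.
#' @param percent Percentage in (0, 100].
#' @param n_features Total number of features E (default: ranking length).
#' @return Integer vector of selected feature indices.
#' @export
select_top_fraction <- function(ranking, percent, n_features = length(ranking)) {
  stopifnot(percent > 0, percent <= 100)
  k <- floor(percent / 100 * n_features)
  if (k < 1) stop("selection fraction keeps no features")
  ranking[seq_len(k)]
}

#' Train a soft-margin linear SVM
#'
#' Fits a linear support vector machine (via libsvm) and extracts the
#' primal hyperplane: weight vector w and bias b with decision value
#' d(x) = w.x + b, oriented so that d > 0 predicts the +1 (control) class.
#' No internal feature standardization is applied.
#'
#' @param x Subjects x features training matrix.
#' @param y Labels (see [code_labels()]); both classes required.
#' @param C Soft-margin cost (default 1).
#' @param tolerance Termination tolerance of the underlying optimizer;
#'   tight by default so the solution agrees with a direct quadratic
#'   program to high precision.
#' @return List of class `linear_svm`: `w`, `b`, `C`.
#' @export
train_linear_svm <- function(x, y, C = 1, tolerance = 1e-6) {
  y <- code_labels(y)
  if (length(unique(y)) != 2) stop("training set must contain both classes")
  stopifnot(C > 0)
  yf <- factor(y, levels = c(1, -1))
  fit <- e1071::svm(x, yf, kernel = "linear", cost = C, scale = FALSE,
                    tolerance = tolerance)
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  # libsvm orients its decision values toward the first training label;
  # re-orient deterministically toward the +1 class.
  if (y[1] < 0) { w <- -w; b <- -b }
  structure(list(w = w, b = b, C = C), class = "linear_svm")
}

#' Decision values of a linear SVM
#' @param model A `linear_svm`.
#' @param x Matrix (or vector) of observations over the model's features.
#' @return Numeric decision values w.x + b.
#' @export
svm_decision <- function(model, x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  drop(x %*% model$w + model$b)
}

# Accuracy / sensitivity / specificity from +/-1 truth and predictions,
# patients (-1) as the positive class.
classification_metrics <- function(truth, predicted) {
  tp <- sum(truth < 0 & predicted < 0)
  tn <- sum(truth > 0 & predicted > 0)
  fn <- sum(truth < 0 & predicted > 0)
  fp <- sum(truth > 0 & predicted < 0)
  c(accuracy = (tp + tn) / length(truth),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp))
}

# Core LOOCV engine shared by the true analysis and the permutation null.
# shuffle: NULL, or a function(train_labels, fold) returning the labels the
# fold actually trains on (used by the permutation modes).
loocv_core <- function(x, y, percentages, C, shuffle = NULL,
                       keep_folds = TRUE) {
  n <- nrow(x)
  n_feat <- ncol(x)
  np <- length(percentages)
  decision <- matrix(NA_real_, n, np,
                     dimnames = list(rownames(x), paste0("p", percentages)))
  folds <- if (keep_folds) vector("list", n) else NULL
  for (i in seq_len(n)) {
    xtr <- x[-i, , drop = FALSE]
    ytr <- y[-i]
    if (!is.null(shuffle)) ytr <- shuffle(ytr, i)
    rk <- f_score_rank(xtr, ytr)$ranking
    fold <- if (keep_folds)
      list(held_out = i, selected = vector("list", np),
           w = vector("list", np), b = numeric(np)) else NULL
    for (k in seq_len(np)) {
      sel <- select_top_fraction(rk, percentages[k], n_feat)
      model <- train_linear_svm(xtr[, sel, drop = FALSE], ytr, C)
      decision[i, k] <- svm_decision(model, x[i, sel])
      if (keep_folds) {
        fold$selected[[k]] <- sel
        fold$w[[k]] <- model$w
        fold$b[k] <- model$b
      }
    }
    if (keep_folds) folds[[i]] <- fold
  }
  predicted <- ifelse(decision >= 0, 1, -1)
  metrics <- t(apply(predicted, 2, function(pr) classification_metrics(y, pr)))
  list(decision = decision, metrics = metrics, folds = folds)
}

#' Leave-one-subject-out SVM classification with nested feature selection
#'
#' For each left-out subject, features are ranked by F score on the
#' remaining subjects only (so feature selection never sees the test
#' subject), the top N% are selected for each percentage on the grid, a
#' linear SVM is trained and the held-out subject scored. Accuracy,
#' sensitivity and specificity per percentage are computed from the pooled
#' held-out predictions; the final accuracy is the maximum over the grid
#' (smallest percentage on ties).
#'
#' @param x Subjects x features matrix (e.g. the Fisher-z edge matrix).
#' @param y Labels (see [code_labels()]).
#' @param percentages Feature-selection grid (default 10..100 by 10).
#' @param C SVM cost.
#' @return List of class `mvpa_result`: `metrics` (per-percentage accuracy
#'   / sensitivity / specificity), `percentages`, `best_percentage`,
#'   `final_accuracy`, `decision` (subjects x percentages held-out decision
#'   values), `roc` + `auc` at the best percentage, `folds` (per-fold
#'   selected sets, weights, bias).
#' @export
loocv_classify <- function(x, y, percentages = seq(10, 100, 10), C = 1) {
  y <- code_labels(y)
  stopifnot(nrow(x) >= 4, sum(y > 0) >= 2, sum(y < 0) >= 2,
            length(percentages) >= 1)
  res <- loocv_core(x, y, percentages, C)
  acc <- res$metrics[, "accuracy"]
  best <- which.max(acc)  # first (= smallest percentage) on ties
  roc <- roc_auc(-res$decision[, best], y)  # patient-ness score = -d
  out <- list(metrics = res$metrics, percentages = percentages,
              best_percentage = percentages[best],
              final_accuracy = unname(acc[best]),
              decision = res$decision, roc = roc$curve, auc = roc$auc,
              folds = res$folds, C = C)
  class(out) <- "mvpa_result"
  out
}

#' ROC curve and AUC from decision scores
#'
#' Sweeps a threshold over the pooled held-out scores to trace the ROC
#' curve, grouping tied scores at a single threshold (diagonal segments).
#' The AUC is computed by the rank / Mann-Whitney formula with average
#' ranks for ties, which equals the trapezoidal area under the tie-grouped
#' curve.
#'
#' @param scores Scores where larger means more patient-like.
#' @param labels Labels (see [code_labels()]); patients (-1) are the
#'   positive class.
#' @return List: `curve` (data.frame threshold, fpr, tpr) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  y <- code_labels(labels)
  pos <- y < 0
  n1 <- sum(pos); n0 <- sum(!pos)
  stopifnot(n1 > 0, n0 > 0)
  rk <- rank(scores)  # average ranks on ties
  auc <- (sum(rk[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), 0)
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), 0)
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                      tpr = c(0, tpr))
  list(curve = curve, auc = auc)
}

#' Max-over-grid permutation test for LOOCV accuracies
#'
#' Family-wise-error corrected significance for the per-percentage
#' accuracies: each permutation reruns the complete nested LOOCV procedure
#' (F-score ranking, selection at every grid percentage, SVM training)
#' with shuffled class labels, and the highest accuracy across the grid is
#' recorded as that permutation's statistic. The corrected p-value of each
#' true accuracy is the proportion of permutation maxima greater than or
#' equal to it, floored at 1/n_perm.
#'
#' @param x,y,percentages,C As in [loocv_classify()].
#' @param n_perm Number of permutations (>= 100).
#' @param seed RNG seed for the permutation stream.
#' @param mode `"within_fold"` shuffles each fold's training labels
#'   independently (the default); `"global"` draws one shuffled label
#'   vector per permutation and uses its training part in every fold.
#' @param observed Optionally, a precomputed [loocv_classify()] result for
#'   (x, y) to avoid refitting the true model.
#' @return List of class `mvpa_permutation`: `null_max` (n_perm maxima),
#'   `fwe_p` (per percentage), `fwe_p_final` (at the best percentage),
#'   `observed` (the true `mvpa_result`), `n_perm`, `seed`, `mode`.
#' @export
mvpa_permutation_test <- function(x, y, percentages = seq(10, 100, 10),
                                  C = 1, n_perm = 10000L, seed = 1L,
                                  mode = c("within_fold", "global"),
                                  observed = NULL) {
  mode <- match.arg(mode)
  y <- code_labels(y)
  stopifnot(n_perm >= 100)
  if (is.null(observed)) observed <- loocv_classify(x, y, percentages, C)
  set.seed(seed)
  n <- nrow(x)
  null_max <- vapply(seq_len(n_perm), function(b) {
    shuffle <- if (mode == "within_fold") {
      function(ytr, i) sample(ytr)
    } else {
      yperm <- sample(y)
      function(ytr, i) yperm[-i]
    }
    perm <- loocv_core(x, y, percentages, C, shuffle = shuffle,
                       keep_folds = FALSE)
    max(perm$metrics[, "accuracy"])
  }, 0)
  acc <- observed$metrics[, "accuracy"]
  fwe_p <- vapply(acc, function(a) max(mean(null_max >= a), 1 / n_perm), 0)
  best <- which(percentages == observed$best_percentage)[1]
  out <- list(null_max = null_max, fwe_p = fwe_p,
              fwe_p_final = unname(fwe_p[best]), observed = observed,
              n_perm = n_perm, seed = seed, mode = mode)
  class(out) <- "mvpa_permutation"
  out
}

#' Aggregate the edges selected across cross-validation folds
#'
#' Collects every feature selected in at least one fold at the chosen grid
#' percentage, with its mean SVM weight over the folds where it was
#' selected and its selection frequency. Under the label coding of
#' [code_labels()], a positive aggregated weight marks an edge whose larger
#' Fisher-z value pushes the classifier toward the control class (i.e.
#' connectivity lower in patients), and vice versa.
#'
#' @param result An `mvpa_result` from [loocv_classify()].
#' @param percentage Grid percentage to aggregate at (default: the best).
#' @return Data.frame of class `selected_edge_set`: `edge`, `weight` (mean
#'   over selecting folds), `frequency` (selecting folds / total folds),
#'   sorted by edge index.
#' @export
aggregate_selected_edges <- function(result,
                                     percentage = result$best_percentage) {
  k <- which(result$percentages == percentage)
  if (!length(k)) stop("percentage ", percentage, " not on the grid")
  n_folds <- length(result$folds)
  sel_all <- lapply(result$folds, function(f) f$selected[[k]])
  w_all <- lapply(result$folds, function(f) f$w[[k]])
  edges <- sort(unique(unlist(sel_all)))
  wmat <- matrix(NA_real_, length(edges), n_folds)
  idx <- match(unlist(sel_all), edges)
  split_at <- rep(seq_len(n_folds), times = lengths(sel_all))
  for (fold in seq_len(n_folds)) {
    rows <- idx[split_at == fold]
    wmat[rows, fold] <- w_all[[fold]]
  }
  out <- data.frame(
    edge = edges,
    weight = rowMeans(wmat, na.rm = TRUE),
    frequency = rowMeans(!is.na(wmat))
  )
  class(out) <- c("selected_edge_set", "data.frame")
  attr(out, "percentage") <- percentage
  attr(out, "n_folds") <- n_folds
  out
}
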