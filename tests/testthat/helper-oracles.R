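# Independent oracles used by the test-suite. These deliberately avoid the
# package's own code paths: components via hand-rolled BFS, AUC via pair
# counting, SVM via a direct quadratic-programming solve of the dual.

# Pooled two-sample t via stats::t.test, one feature at a time.
oracle_t <- function(a, b) {
  unname(stats::t.test(a, b, var.equal = TRUE)$statistic)
}

# Connected-component extents of an edge set (pairs matrix, i/j columns)
# by breadth-first search over an adjacency list.
oracle_component_extents <- function(pairs, n_nodes) {
  if (nrow(pairs) == 0) return(integer(0))
  adj <- vector("list", n_nodes)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  comp <- integer(n_nodes)
  cur <- 0L
  for (s in unique(as.vector(pairs))) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (comp[w] == 0) {
        comp[w] <- cur
        queue <- c(queue, w)
      }
    }
  }
  # extent = number of edges whose endpoints share a component
  as.integer(table(comp[pairs[, 1]]))
}

# Exhaustive NBS oracle: corrected p of each observed component extent by
# enumerating the distinct splits of n subjects into two equal groups
# (complement-invariant, so each unordered split is counted once).
oracle_nbs_exhaustive <- function(x, na, n_regions, t_crit) {
  n <- nrow(x)
  splits <- combn(n, na)
  keep <- splits[1, ] == 1  # fix subject 1 in group A: distinct splits
  splits <- splits[, keep, drop = FALSE]
  maxima <- apply(splits, 2, function(ia) {
    tv <- vapply(seq_len(ncol(x)), function(e) {
      oracle_t(x[ia, e], x[-ia, e])
    }, 0)
    ext <- 0L
    for (sgn in c(1, -1)) {
      sup <- which(sgn * tv > t_crit)
      if (length(sup)) {
        p <- pair_of_edge(sup, n_regions)
        ext <- max(ext, oracle_component_extents(p, n_regions))
      }
    }
    ext
  })
  maxima
}

# AUC by exhaustive pair counting (ties count one half).
oracle_auc <- function(scores, labels) {
  y <- code_labels(labels)
  pos <- scores[y < 0]
  neg <- scores[y > 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Linear soft-margin SVM via the dual QP, solved with kernlab::ipop:
#   min 1/2 a' Q a - 1'a   s.t.  y'a = 0,  0 <= a <= C,   Q = (y y') * (X X')
oracle_svm_qp <- function(x, y, C = 1) {
  y <- code_labels(y)
  K <- tcrossprod(x)
  Q <- (y %o% y) * K
  n <- length(y)
  sol <- kernlab::ipop(c = rep(-1, n), H = Q,
                       A = matrix(y, 1), b = 0, r = 0,
                       l = rep(0, n), u = rep(C, n), sigf = 9)
  a <- kernlab::primal(sol)
  w <- drop(crossprod(x, a * y))
  margin <- which(a > 1e-6 * C & a < C * (1 - 1e-6))
  if (!length(margin)) margin <- which(a > 1e-6 * C)
  b <- mean(y[margin] - x[margin, , drop = FALSE] %*% w)
  list(w = w, b = b)
}

# Textbook Pearson correlation.
oracle_pearson <- function(x, y) {
  n <- length(x)
  (sum(x * y) - n * mean(x) * mean(y)) /
    sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
}
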