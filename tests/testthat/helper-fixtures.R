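# shared fixtures, all generated in code

# two well separated 1-D clusters
two_cluster_1d <- function(n_per = 20, gap = 100, sd = 1, seed = 1) {
  set.seed(seed)
  matrix(c(rnorm(n_per, 0, sd), rnorm(n_per, gap, sd)), ncol = 1)
}

# a fuzzy partition with prescribed memberships (for AMD unit tests)
partition_from_membership <- function(u) {
  structure(list(centres = matrix(0, ncol(u), 1), membership = u,
                 objective = 0, trace = 0, iterations = 1L, converged = TRUE,
                 m = 2, seed = 1L),
            class = "fuzzy_partition")
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

# small world shared by several test files (generated once per test run)
small_world <- local({
  w <- NULL
  function() {
    if (is.null(w)) w <<- trophoscape::generate_world(n_cells = 1200, seed = 99)
    w
  }
})

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# exhaustive enumeration of all depth<=2 trees over midpoint thresholds,
# the independent global-optimum oracle for tiny instances
enumerate_best_fitness <- function(X, y, alpha = 0.01, min_bucket = 1) {
  classes <- sort(unique(y))
  yi <- match(y, classes)
  err_leaf <- function(idx) length(idx) - max(tabulate(yi[idx], length(classes)))
  cands <- lapply(seq_len(ncol(X)), function(j) {
    u <- sort(unique(X[, j]))
    if (length(u) < 2) numeric(0) else (u[-1] + u[-length(u)]) / 2
  })
  n <- nrow(X)
  best <- err_leaf(seq_len(n)) / n + alpha       # single leaf
  splits <- do.call(rbind, lapply(seq_along(cands), function(j)
    if (length(cands[[j]])) cbind(j, cands[[j]])))
  child_best <- function(idx) {
    # best (error, leaves) for a subtree of depth <= 1 on idx
    b <- c(err = err_leaf(idx), leaves = 1)
    for (r in seq_len(nrow(splits))) {
      left <- idx[X[idx, splits[r, 1]] < splits[r, 2]]
      right <- setdiff(idx, left)
      if (length(left) < min_bucket || length(right) < min_bucket) next
      e <- err_leaf(left) + err_leaf(right)
      if (e / n + 2 * alpha < b["err"] / n + b["leaves"] * alpha)
        b <- c(err = e, leaves = 2)
    }
    b
  }
  for (r in seq_len(nrow(splits))) {
    left <- which(X[, splits[r, 1]] < splits[r, 2])
    right <- setdiff(seq_len(n), left)
    if (length(left) < min_bucket || length(right) < min_bucket) next
    bl <- child_best(left); br <- child_best(right)
    f <- (bl["err"] + br["err"]) / n + (bl["leaves"] + br["leaves"]) * alpha
    if (f < best) best <- f
  }
  unname(best)
}

checkerboard <- function(n = 120, seed = 1) {
  set.seed(seed)
  X <- cbind(x1 = runif(n, 0, 4), x2 = runif(n, 0, 4))
  y <- ifelse(xor(X[, 1] < 2, X[, 2] < 2), "a", "b")
  list(X = X, y = y)
}
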