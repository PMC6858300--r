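test_that("c-means recovers perfectly separated points with crisp membership", {
  x <- matrix(c(0, 10), ncol = 1)
  p <- fit_cmeans(x, c = 2, seed = 1)
  expect_equal(sort(as.numeric(p$centres)), c(0, 10), tolerance = 1e-6)
  # coincident-point convention: sample at a centre gets membership 1
  expect_equal(max(p$membership[1, ]), 1)
  expect_equal(max(p$membership[2, ]), 1)
})

test_that("c = 1 gives the feature-wise mean and AMD 0", {
  x <- matrix(rnorm(40), 20, 2)
  p <- fit_cmeans(x, c = 1, seed = 1)
  expect_equal(as.numeric(p$centres), colMeans(x))
  expect_true(all(p$membership == 1))
  expect_equal(compute_amd(p)$amd, 0)
})

test_that("fitted centres land near planted centres on the Gaussian benchmark", {
  b <- generate_cluster_benchmark(n = 2400, d = 11, k = 6, sd = 1, seed = 3)
  best <- NULL
  for (r in 1:10) {
    p <- fit_cmeans(b$samples, 6, seed = r)
    a <- compute_amd(p)$amd
    if (is.null(best) || a > attr(best, "amd")) {
      best <- p; attr(best, "amd") <- a
    }
  }
  tol <- 3 * b$sd / sqrt(nrow(b$samples) / 6)
  for (k in seq_len(6)) {
    d <- sqrt(rowSums((b$centres -
                         matrix(best$centres[k, ], 6, 11, byrow = TRUE))^2))
    expect_lt(min(d), max(tol, 0.5))
  }
})

test_that("invalid arguments are rejected", {
  x <- matrix(rnorm(10), 5, 2)
  expect_error(fit_cmeans(x, c = 6, seed = 1), "c")
  expect_error(fit_cmeans(x, c = 2, m = 1, seed = 1), "m")
  expect_error(amd_scan(x, c_min = 1, c_max = 3), "range")
  expect_error(amd_scan(x, c_min = 4, c_max = 2), "range")
})

test_that("all-identical samples with c > 1 return a flagged partition", {
  x <- matrix(1, 10, 3)
  p <- fit_cmeans(x, c = 2, seed = 1)
  expect_false(p$converged)
  expect_equal(unname(rowSums(p$membership)), rep(1, 10))
})

test_that("AMD matches its formula on hand-built partitions", {
  # crisp partition, c = 6
  u <- diag(6)[rep(1:6, 5), ]
  expect_equal(compute_amd(partition_from_membership(u))$amd, 1 - 1 / 6)
  # uniform partition, c = 4
  u <- matrix(1 / 4, 12, 4)
  expect_equal(compute_amd(partition_from_membership(u))$amd, 0)
  # non-normalised rows rejected
  u_bad <- matrix(c(0.6, 0.6), 1, 2)
  expect_error(compute_amd(partition_from_membership(u_bad)), "normalised")
})

test_that("membership rows stay normalised and AMD stays within its bounds", {
  set.seed(42)
  for (i in 1:8) {
    n <- sample(20:60, 1); d <- sample(1:5, 1); c <- sample(2:5, 1)
    x <- matrix(rnorm(n * d, sd = sample(1:5, 1)), n, d)
    p <- fit_cmeans(x, c, seed = i)
    expect_equal(unname(rowSums(p$membership)), rep(1, n), tolerance = 1e-9)
    a <- compute_amd(p)
    expect_gte(a$amd, -1e-12)
    expect_lte(a$amd, 1 - 1 / c + 1e-12)
  }
})

test_that("the c-means objective is monotone non-increasing over iterations", {
  set.seed(5)
  for (i in 1:5) {
    x <- matrix(rnorm(200), 100, 2)
    p <- fit_cmeans(x, 3, seed = i)
    expect_true(all(diff(p$trace) <= 1e-8 * max(1, p$trace[1])))
  }
})

test_that("AMD is invariant to label permutation, rotation and translation", {
  set.seed(9)
  x <- rbind(matrix(rnorm(60), 30, 2), matrix(rnorm(60, 5), 30, 2))
  p <- fit_cmeans(x, 2, seed = 2)
  a0 <- compute_amd(p)$amd
  # permuting cluster columns
  pp <- p; pp$membership <- p$membership[, 2:1]; pp$centres <- p$centres[2:1, ]
  expect_equal(compute_amd(pp)$amd, a0)
  # rigid rotation + translation of the samples
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  xr <- sweep(x %*% R, 2, c(3, -8), `+`)
  ar <- compute_amd(fit_cmeans(xr, 2, seed = 2))$amd
  expect_equal(ar, a0, tolerance = 1e-6)
})

test_that("best-of-replicates matches an independent reference fit on a toy", {
  # cross-check against e1071's c-means from several starts on 6 points
  skip_if_not_installed("e1071")
  x <- matrix(c(0, 0.5, 1, 9, 9.5, 10), ncol = 1)
  p <- fit_cmeans(x, 2, seed = 1)
  ref_best <- Inf
  for (s in 1:10) {
    set.seed(s)
    ref <- e1071::cmeans(x, 2, m = 2, iter.max = 300)
    d2 <- outer(as.numeric(x), as.numeric(ref$centers),
                function(a, b) (a - b)^2)
    ref_best <- min(ref_best, sum(ref$membership^2 * d2))
  }
  expect_equal(p$objective, ref_best, tolerance = 1e-4)
  expect_equal(sort(as.numeric(p$centres)), c(0.5, 9.5), tolerance = 1e-3)
  # hard labels agree with exhaustive best 2-part split of the line
  expect_equal(sort(table(hard_labels(p))), sort(c(3, 3)), ignore_attr = TRUE)
})

test_that("amd_scan recovers two well separated planted clusters", {
  b <- generate_cluster_benchmark(n = 400, d = 11, k = 2, sd = 1, seed = 4)
  s <- amd_scan(b$samples, c_min = 2, c_max = 5, replicates = 10, seed = 1)
  expect_equal(s$selected_c, 2)
  expect_equal(nrow(s$curve), 4)
  expect_equal(max(s$curve$best_amd), s$curve$best_amd[s$curve$c == 2])
  # in 1-D the two planted clusters are maximally crisp at c = 2: the AMD
  # at c = 2 approaches its upper bound 1 - 1/2
  x <- two_cluster_1d(n_per = 30, gap = 100, sd = 1, seed = 4)
  s1 <- amd_scan(x, c_min = 2, c_max = 2, replicates = 10, seed = 1)
  expect_gt(s1$curve$best_amd[1], 0.5 - 0.01)
})

test_that("selected AMD decreases as planted clusters blur", {
  peaks <- sapply(c(0.5, 1, 1.7, 3), function(s) {
    b <- generate_cluster_benchmark(n = 1200, d = 11, k = 6, sd = s, seed = 11)
    max(sapply(1:8, function(r)
      compute_amd(fit_cmeans(b$samples, 6, seed = r))$amd))
  })
  expect_true(all(diff(peaks) < 0))
})
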