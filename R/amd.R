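#' Average membership degree (AMD) cluster validity statistic
#'
#' For a fuzzy partition of `n` samples into `c` clusters, the AMD statistic is
#' the mean over samples of the membership degree to the nearest cluster (the
#' row maximum of the membership matrix), minus `1/c`:
#' \deqn{AMD = \frac{1}{n} \sum_{j=1}^{n} MD_j - \frac{1}{c}.}
#' For structureless (randomly distributed) data memberships approach the
#' uniform `1/c`, so AMD is close to 0; for perfectly crisp clusters it
#' approaches `1 - 1/c`.  Tracking AMD across increasing `c` locates the
#' number of well-defined clusters in the data.
#'
#' @param partition A `fuzzy_partition` from [fit_cmeans()].
#' @return Object of class `amd_result`: list with `amd`, `mean_nearest_md`,
#'   `n`, `c`.
#' @export
compute_amd <- function(partition) {
  if (!inherits(partition, "fuzzy_partition"))
    stop("'partition' must be a fuzzy_partition", call. = FALSE)
  u <- partition$membership
  rs <- rowSums(u)
  if (any(abs(rs - 1) > 1e-6))
    stop("membership rows are not normalised to 1", call. = FALSE)
  if (any(u < -1e-12) || any(u > 1 + 1e-12))
    stop("memberships outside [0, 1]", call. = FALSE)
  n <- nrow(u); c <- ncol(u)
  md <- apply(u, 1L, max)
  res <- list(amd = mean(md) - 1 / c, mean_nearest_md = mean(md),
              n = n, c = c)
  class(res) <- "amd_result"
  res
}

#' @export
print.amd_result <- function(x, ...) {
  cat(sprintf("AMD = %.4f (mean nearest membership %.4f, n = %d, c = %d)\n",
              x$amd, x$mean_nearest_md, x$n, x$c))
  invisible(x)
}

#' Scan cluster numbers with replicated c-means and the AMD statistic
#'
#' For each candidate number of clusters runs `replicates` independently
#' seeded c-means fits (replicate `r` uses seed `seed + r`), keeps the
#' partition with the highest AMD, and selects the cluster number whose best
#' AMD is maximal.  Ties (within 1e-12) are broken toward the smallest `c`,
#' i.e. toward parsimony.  The full AMD-versus-c curve is returned so
#' secondary peaks can be inspected.
#'
#' @inheritParams fit_cmeans
#' @param c_min,c_max Scan range, `2 <= c_min <= c_max <= n`.
#' @param replicates Number of random restarts per cluster number.
#' @param seed Base seed; replicate seeds are `seed + 1, ..., seed + replicates`.
#' @return Object of class `amd_scan`: list with `curve` (data frame with
#'   columns `c`, `best_amd`, `replicates`), `selected_c`, `best_partition`
#'   (for `selected_c`), and `partitions` (best partition per `c`).
#' @examples
#' b <- generate_cluster_benchmark(n = 300, d = 2, k = 3, sd = 0.5, seed = 1)
#' s <- amd_scan(b$samples, c_min = 2, c_max = 5, replicates = 5, seed = 1)
#' s$selected_c
#' @export
amd_scan <- function(samples, c_min = 2L, c_max, replicates = 200L, m = 2,
                     tol = 1e-9, max_iter = 300L, seed = 1L) {
  x <- as_sample_matrix(samples)
  n <- nrow(x)
  if (c_min < 2L || c_min > c_max || c_max > n)
    stop("scan range must satisfy 2 <= c_min <= c_max <= n", call. = FALSE)
  if (replicates < 1L) stop("'replicates' must be >= 1", call. = FALSE)
  cs <- seq.int(c_min, c_max)
  best <- vector("list", length(cs))
  best_amd <- rep(-Inf, length(cs))
  for (i in seq_along(cs)) {
    for (r in seq_len(replicates)) {
      p <- fit_cmeans(x, cs[i], m = m, tol = tol, max_iter = max_iter,
                      seed = seed + r)
      a <- compute_amd(p)$amd
      if (a > best_amd[i]) { best_amd[i] <- a; best[[i]] <- p }
    }
  }
  sel <- which(best_amd >= max(best_amd) - 1e-12)[1L]
  res <- list(curve = data.frame(c = cs, best_amd = best_amd,
                                 replicates = replicates),
              selected_c = cs[sel], best_partition = best[[sel]],
              partitions = best, m = m, seed = seed)
  class(res) <- "amd_scan"
  res
}

#' @export
print.amd_scan <- function(x, ...) {
  cat(sprintf("AMD scan over c = %d..%d (%d replicates each)\n",
              min(x$curve$c), max(x$curve$c), x$curve$replicates[1L]))
  cat(sprintf("selected c = %d (best AMD %.4f)\n", x$selected_c,
              max(x$curve$best_amd)))
  invisible(x)
}

#' Write an AMD curve to CSV
#'
#' @param scan An `amd_scan` object.
#' @param path Output CSV path.
#' @export
write_amd_curve <- function(scan, path) {
  stopifnot(inherits(scan, "amd_scan"))
  utils::write.csv(scan$curve, path, row.names = FALSE)
  invisible(path)
}
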