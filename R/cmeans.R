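#' Coerce input to a sample matrix
#'
#' A sample matrix is a plain numeric matrix with samples as rows, features as
#' columns, and row names as sample identifiers.  It is the common currency of
#' the clustering functions: species-by-resource diet percentages, cell-by-guild
#' species counts, and artificial benchmark points all travel in this form.
#'
#' @param x A numeric matrix or data frame (an id column named `id` or row
#'   names supply sample identifiers).
#' @return A numeric matrix with row names.
#' @export
as_sample_matrix <- function(x) {
  if (is.data.frame(x)) {
    idcol <- which(names(x) == "id")
    if (length(idcol) == 1L) {
      ids <- as.character(x[[idcol]])
      x <- x[, -idcol, drop = FALSE]
    } else {
      ids <- rownames(x)
    }
    x <- as.matrix(x)
    rownames(x) <- ids
  }
  if (!is.matrix(x) || !is.numeric(x))
    stop("samples must be a numeric matrix or data frame", call. = FALSE)
  if (anyNA(x)) stop("samples contain missing values", call. = FALSE)
  if (nrow(x) < 1L || ncol(x) < 1L)
    stop("samples must have at least one row and one column", call. = FALSE)
  if (is.null(rownames(x))) rownames(x) <- paste0("s", seq_len(nrow(x)))
  x
}

#' Read / write a sample matrix as CSV
#'
#' First column holds the sample id, remaining columns the features.
#'
#' @param path Path to a CSV file.
#' @rdname sample_matrix_io
#' @export
read_sample_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  names(df)[1L] <- "id"
  as_sample_matrix(df)
}

#' @param x Sample matrix.
#' @rdname sample_matrix_io
#' @export
write_sample_matrix <- function(x, path) {
  x <- as_sample_matrix(x)
  df <- data.frame(id = rownames(x), x, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Fuzzy c-means clustering
#'
#' Alternating optimisation of the fuzzy c-means objective
#' \eqn{J = \sum_{j,k} u_{jk}^m \, \|x_j - v_k\|^2} with the standard
#' inverse-squared-distance membership update.  Centres are initialised as
#' `c` distinct rows drawn at random from the data, so every run is fully
#' reproducible from `seed`.  A sample coincident with a centre receives
#' membership 1 to (the first) such centre and 0 elsewhere.
#'
#' @param samples Sample matrix (see [as_sample_matrix()]).
#' @param c Number of clusters, `1 <= c <= nrow(samples)`.
#' @param m Fuzzifier exponent, `> 1`.  `m = 2` is the conventional default.
#' @param tol Convergence tolerance on the relative change of the objective.
#' @param max_iter Iteration cap.
#' @param seed Integer seed for the centre initialisation.
#' @return An object of class `fuzzy_partition`: list with `centres`
#'   (`c x d`), `membership` (`n x c`, rows summing to 1), `objective`,
#'   `trace` (objective per iteration), `converged`, `m`, and `seed`.
#' @examples
#' x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 6), 20))
#' p <- fit_cmeans(x, c = 2, seed = 1)
#' compute_amd(p)
#' @export
fit_cmeans <- function(samples, c, m = 2, tol = 1e-9, max_iter = 300L,
                       seed = 1L) {
  x <- as_sample_matrix(samples)
  n <- nrow(x)
  if (!is.numeric(c) || length(c) != 1L || c < 1L || c > n)
    stop("'c' must be a single integer in [1, nrow(samples)]", call. = FALSE)
  if (m <= 1) stop("fuzzifier 'm' must be > 1", call. = FALSE)
  c <- as.integer(c)

  if (c == 1L) {
    centre <- matrix(colMeans(x), 1L, ncol(x),
                     dimnames = list(NULL, colnames(x)))
    d2 <- rowSums((x - centre[rep(1L, n), , drop = FALSE])^2)
    part <- list(centres = centre,
                 membership = matrix(1, n, 1L, dimnames = list(rownames(x), NULL)),
                 objective = sum(d2), trace = sum(d2), iterations = 1L,
                 converged = TRUE, m = m, seed = seed)
    class(part) <- "fuzzy_partition"
    return(part)
  }

  uniq <- unique(x)
  degenerate <- nrow(uniq) < c
  init <- local({
    set.seed(seed)
    if (degenerate) {
      idx <- sample.int(nrow(x), c, replace = TRUE)
      x[idx, , drop = FALSE]
    } else {
      uniq[sample.int(nrow(uniq), c), , drop = FALSE]
    }
  })

  fit <- .cmeans_core(x, init, m, tol, as.integer(max_iter))
  membership <- fit$membership
  rownames(membership) <- rownames(x)
  colnames(fit$centres) <- colnames(x)
  part <- list(centres = fit$centres, membership = membership,
               objective = fit$objective, trace = fit$trace,
               iterations = fit$iterations,
               converged = fit$converged && !degenerate,
               m = m, seed = seed)
  class(part) <- "fuzzy_partition"
  part
}

#' @export
print.fuzzy_partition <- function(x, ...) {
  cat(sprintf("fuzzy c-means partition: n = %d, c = %d, m = %g\n",
              nrow(x$membership), ncol(x$membership), x$m))
  cat(sprintf("objective %.6g after %d iterations (%s)\n", x$objective,
              x$iterations, if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Hard cluster labels of a fuzzy partition
#'
#' @param partition A `fuzzy_partition`.
#' @return Integer vector of maximum-membership cluster indices.
#' @export
hard_labels <- function(partition) {
  stopifnot(inherits(partition, "fuzzy_partition"))
  max.col(partition$membership, ties.method = "first")
}
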