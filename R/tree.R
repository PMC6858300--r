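## Axis-aligned classification trees fitted by an evolutionary algorithm.
##
## Genotypes are nested lists: internal nodes carry a split variable (column
## index) and threshold, leaves carry nothing.  Leaf labels are not part of
## the genotype: they are always the majority class of the training samples
## reaching the leaf, so the search space is the space of split structures.
## Routing convention: value < threshold goes left, value >= threshold right.

#' Evolution settings for globally optimised classification trees
#'
#' Fitness is minimised and equals the training misclassification rate plus
#' `alpha` per leaf, so with the default `alpha = 0.01` an extra leaf must
#' buy at least one percentage point of accuracy.  Candidate split thresholds
#' are the midpoints of consecutive sorted unique values of each variable.
#'
#' @param population Number of trees per generation.
#' @param generations Maximum number of generations.
#' @param patience Stop early after this many generations without improvement
#'   of the best fitness.
#' @param tournament Tournament size for parent selection.
#' @param p_crossover Probability that an offspring is produced by subtree
#'   crossover (otherwise a mutated clone of one parent).
#' @param p_threshold,p_variable,p_prune,p_grow Per-offspring probabilities of
#'   the four mutation operators (threshold jitter, split-variable swap,
#'   subtree pruning, leaf growing).
#' @param restarts Number of independent evolutionary runs (seeded
#'   `seed, seed + 1000, ...`); the best-fitness tree is kept.
#' @param alpha Complexity penalty per leaf.
#' @param max_depth Maximum tree depth (root = depth 0).
#' @param min_bucket Minimum number of training samples per leaf; splits that
#'   would violate it are collapsed.
#' @param seed Integer seed.
#' @return A list of class `evolution_config`.
#' @export
evolution_config <- function(population = 200L, generations = 500L,
                             patience = 100L, tournament = 4L,
                             p_crossover = 0.7, p_threshold = 0.3,
                             p_variable = 0.15, p_prune = 0.15, p_grow = 0.2,
                             restarts = 1L, alpha = 0.01, max_depth = 6L,
                             min_bucket = 7L, seed = 1L) {
  cfg <- list(population = as.integer(population),
              generations = as.integer(generations),
              patience = as.integer(patience),
              tournament = as.integer(tournament),
              restarts = as.integer(restarts),
              p_crossover = p_crossover, p_threshold = p_threshold,
              p_variable = p_variable, p_prune = p_prune, p_grow = p_grow,
              alpha = alpha, max_depth = as.integer(max_depth),
              min_bucket = as.integer(min_bucket), seed = as.integer(seed))
  probs <- unlist(cfg[c("p_crossover", "p_threshold", "p_variable",
                        "p_prune", "p_grow")])
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (cfg$max_depth < 1L) stop("max_depth must be >= 1")
  class(cfg) <- "evolution_config"
  cfg
}

## ---- genotype helpers -----------------------------------------------------

.leaf <- function() list(leaf = TRUE)
.split <- function(var, thr, left, right)
  list(leaf = FALSE, var = var, thr = thr, left = left, right = right)

.node_paths <- function(node, path = character(0), internal_only = FALSE) {
  if (node$leaf)
    return(if (internal_only) list() else list(path))
  c(list(path),
    .node_paths(node$left, c(path, "left"), internal_only),
    .node_paths(node$right, c(path, "right"), internal_only))
}

.get_node <- function(tree, path) if (length(path)) tree[[path]] else tree
.set_node <- function(tree, path, value) {
  if (!length(path)) return(value)
  tree[[path]] <- value
  tree
}

.random_split <- function(cands) {
  ok <- which(lengths(cands) > 0L)
  v <- ok[sample.int(length(ok), 1L)]
  list(var = v, thr = cands[[v]][sample.int(length(cands[[v]]), 1L)])
}

.random_tree <- function(cands, max_depth, p_split = 0.7, depth = 0L) {
  if (depth >= max_depth || stats::runif(1) > p_split) return(.leaf())
  s <- .random_split(cands)
  .split(s$var, s$thr,
         .random_tree(cands, max_depth, p_split * 0.8, depth + 1L),
         .random_tree(cands, max_depth, p_split * 0.8, depth + 1L))
}

## training samples reaching the node at `path` (left = strictly below)
.idx_at_path <- function(g, X, path) {
  idx <- seq_len(nrow(X))
  node <- g
  for (step in path) {
    go_left <- X[idx, node$var] < node$thr
    idx <- if (step == "left") idx[go_left] else idx[!go_left]
    node <- node[[step]]
  }
  idx
}

## best single split of idx by Gini impurity gain (the CART induction
## criterion; unlike misclassification gain it rewards purifying one child
## even when the majority class is unchanged), evaluated with one sorted
## sweep of cumulative class counts per variable
.best_split <- function(X, y_int, nclass, idx, min_bucket,
                        variables = seq_len(ncol(X))) {
  n <- length(idx)
  cnt <- tabulate(y_int[idx], nclass)
  if (max(cnt) == n || n < 2L * min_bucket) return(NULL)
  parent_cost <- n - sum(cnt^2) / n          # n * gini
  best <- list(gain = 1e-9)
  for (v in variables) {
    xv <- X[idx, v]
    ord <- order(xv)
    xs <- xv[ord]
    ys <- y_int[idx][ord]
    cum <- vapply(seq_len(nclass), function(k) cumsum(ys == k), numeric(n))
    pos <- seq_len(n - 1L)
    valid <- xs[pos] < xs[pos + 1L] & pos >= min_bucket &
      (n - pos) >= min_bucket
    if (!any(valid)) next
    cl <- cum[pos, , drop = FALSE]
    cr <- matrix(cnt, n - 1L, nclass, byrow = TRUE) - cl
    cost <- (pos - rowSums(cl^2) / pos) +
      ((n - pos) - rowSums(cr^2) / (n - pos))
    cost[!valid] <- Inf
    i <- which.min(cost)
    gain <- parent_cost - cost[i]
    if (gain > best$gain)
      best <- list(gain = gain, var = v, thr = (xs[i] + xs[i + 1L]) / 2)
  }
  if (best$gain > 1e-9) best else NULL
}

## Fast fitness evaluation: returns misclassification count and number of
## leaves of the *effective* tree (depth-trimmed, min_bucket-collapsed).
.eval_node <- function(node, X, y_int, idx, nclass, depth, max_depth,
                       min_bucket) {
  as_leaf <- function() {
    cnt <- tabulate(y_int[idx], nclass)
    list(err = length(idx) - max(cnt), leaves = 1L)
  }
  if (node$leaf || depth >= max_depth) return(as_leaf())
  go_left <- X[idx, node$var] < node$thr
  nl <- sum(go_left)
  if (nl < min_bucket || (length(idx) - nl) < min_bucket) return(as_leaf())
  l <- .eval_node(node$left, X, y_int, idx[go_left], nclass, depth + 1L,
                  max_depth, min_bucket)
  r <- .eval_node(node$right, X, y_int, idx[!go_left], nclass, depth + 1L,
                  max_depth, min_bucket)
  list(err = l$err + r$err, leaves = l$leaves + r$leaves)
}

## Annotated (phenotype) tree for the final model: trims exactly like
## .eval_node and stores per-node sample counts, class ratios and majority
## labels.
.annotate_node <- function(node, X, y_int, idx, classes, depth, max_depth,
                           min_bucket) {
  cnt <- tabulate(y_int[idx], length(classes))
  base <- list(n = length(idx), class_counts = stats::setNames(cnt, classes),
               ratio = if (length(idx)) cnt / length(idx) else cnt,
               label = classes[which.max(cnt)], depth = depth)
  as_leaf <- function() c(list(leaf = TRUE), base)
  if (node$leaf || depth >= max_depth) return(as_leaf())
  go_left <- X[idx, node$var] < node$thr
  nl <- sum(go_left)
  if (nl < min_bucket || (length(idx) - nl) < min_bucket) return(as_leaf())
  c(list(leaf = FALSE, var = node$var, thr = node$thr,
         left = .annotate_node(node$left, X, y_int, idx[go_left], classes,
                               depth + 1L, max_depth, min_bucket),
         right = .annotate_node(node$right, X, y_int, idx[!go_left], classes,
                                depth + 1L, max_depth, min_bucket)),
    base)
}

.tree_depth <- function(node) {
  if (node$leaf) return(0L)
  1L + max(.tree_depth(node$left), .tree_depth(node$right))
}
.tree_leaves <- function(node) {
  if (node$leaf) return(1L)
  .tree_leaves(node$left) + .tree_leaves(node$right)
}

.finalise_model <- function(genotype, X, y, classes, cfg, method,
                            history = NULL) {
  y_int <- match(y, classes)
  root <- .annotate_node(genotype, X, y_int, seq_len(nrow(X)), classes, 0L,
                         cfg$max_depth, cfg$min_bucket)
  ev <- .eval_node(genotype, X, y_int, seq_len(nrow(X)), length(classes), 0L,
                   cfg$max_depth, cfg$min_bucket)
  misclass <- ev$err / nrow(X)
  model <- list(root = root, var_names = colnames(X), classes = classes,
                depth = .tree_depth(root), n_leaves = .tree_leaves(root),
                misclass = misclass,
                fitness = misclass + cfg$alpha * ev$leaves,
                config = cfg, method = method, history = history,
                n_train = nrow(X))
  class(model) <- "tree_model"
  model
}

.check_features <- function(features) {
  X <- if (is.data.frame(features)) as.matrix(features) else features
  if (!is.matrix(X) || !is.numeric(X))
    stop("features must be a numeric matrix or data frame", call. = FALSE)
  if (anyNA(X)) stop("features contain missing values", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  X
}

.threshold_candidates <- function(X) {
  lapply(seq_len(ncol(X)), function(j) {
    u <- sort(unique(X[, j]))
    if (length(u) < 2L) numeric(0) else (u[-1L] + u[-length(u)]) / 2
  })
}

## ---- fitting --------------------------------------------------------------

#' Fit a globally optimised classification tree by evolutionary search
#'
#' A population of axis-aligned decision trees is evolved by tournament
#' selection, subtree crossover and four mutation operators, minimising
#' `misclassification rate + alpha * n_leaves`.  Unlike greedy recursive
#' partitioning, split thresholds are optimised jointly, so structures such
#' as checkerboard (XOR) class layouts, where no single split helps, can
#' still be found.  The best individual ever seen is returned; the run is
#' deterministic given `config$seed`.
#'
#' @param features Numeric matrix or data frame of predictor variables.
#' @param labels Vector of class labels (character or factor), one per row.
#' @param config An [evolution_config()].
#' @return A `tree_model`: annotated tree (`root`), `depth`, `n_leaves`,
#'   training `misclass` and `fitness`, and the per-generation best-fitness
#'   `history`.
#' @seealso [greedy_tree()] for the recursive-partitioning baseline,
#'   [predict.tree_model()], [extract_thresholds()].
#' @export
evolve_tree <- function(features, labels, config = evolution_config()) {
  X <- .check_features(features)
  labels <- as.character(labels)
  if (length(labels) != nrow(X)) stop("labels must match rows of features")
  classes <- sort(unique(labels))
  if (length(classes) < 1L) stop("no labels supplied")
  if (config$min_bucket * 2L > nrow(X) && length(classes) > 1L)
    stop("min_bucket too large for the number of samples", call. = FALSE)
  y_int <- match(labels, classes)
  nclass <- length(classes)

  if (nclass == 1L)
    return(.finalise_model(.leaf(), X, labels, classes, config, "evolved"))

  cands <- .threshold_candidates(X)
  if (all(lengths(cands) == 0L))
    return(.finalise_model(.leaf(), X, labels, classes, config, "evolved"))

  idx_all <- seq_len(nrow(X))
  fitness_of <- function(g) {
    ev <- .eval_node(g, X, y_int, idx_all, nclass, 0L, config$max_depth,
                     config$min_bucket)
    ev$err / nrow(X) + config$alpha * ev$leaves
  }

  run_once <- function(run_seed) {
  set.seed(run_seed)
  pop <- lapply(seq_len(config$population), function(i)
    .random_tree(cands, config$max_depth))
  ## seed the population with the greedy solution plus greedy completions
  ## under every candidate root variable: evolution then refines and
  ## recombines locally optimal trees instead of starting from scratch
  seeds <- c(list(.greedy_genotype(X, y_int, nclass, config)),
             lapply(which(lengths(cands) > 0L), function(v)
               .greedy_genotype(X, y_int, nclass, config, root_var = v)))
  seeds <- seeds[seq_len(min(length(seeds), config$population %/% 2L))]
  pop[seq.int(config$population - length(seeds) + 1L, config$population)] <-
    seeds
  fit <- vapply(pop, fitness_of, numeric(1))
  best_g <- pop[[which.min(fit)]]
  best_f <- min(fit)
  history <- numeric(config$generations)
  stale <- 0L

  mutate <- function(g) {
    if (stats::runif(1) < config$p_threshold) {
      ip <- .node_paths(g, internal_only = TRUE)
      if (length(ip)) {
        p <- ip[[sample.int(length(ip), 1L)]]
        nd <- .get_node(g, p)
        cc <- cands[[nd$var]]
        u <- stats::runif(1)
        if (u < 0.34) {
          # locally optimal threshold for this node's variable
          idx <- .idx_at_path(g, X, p)
          bs <- .best_split(X, y_int, nclass, idx, config$min_bucket,
                            variables = nd$var)
          if (!is.null(bs)) nd$thr <- bs$thr
        } else if (u < 0.67 && length(cc) > 1L) {
          i <- which.min(abs(cc - nd$thr))
          nd$thr <- cc[min(max(i + sample(c(-1L, 1L), 1L), 1L), length(cc))]
        } else if (length(cc)) {
          nd$thr <- cc[sample.int(length(cc), 1L)]
        }
        g <- .set_node(g, p, nd)
      }
    }
    if (stats::runif(1) < config$p_variable) {
      ip <- .node_paths(g, internal_only = TRUE)
      if (length(ip)) {
        p <- ip[[sample.int(length(ip), 1L)]]
        nd <- .get_node(g, p)
        s <- .random_split(cands)
        nd$var <- s$var; nd$thr <- s$thr
        # pair the new variable with its locally best threshold, so variable
        # swaps are viable moves rather than near-certain regressions
        idx <- .idx_at_path(g, X, p)
        bs <- .best_split(X, y_int, nclass, idx, config$min_bucket,
                          variables = s$var)
        if (!is.null(bs)) nd$thr <- bs$thr
        g <- .set_node(g, p, nd)
      }
    }
    if (stats::runif(1) < config$p_prune) {
      ip <- .node_paths(g, internal_only = TRUE)
      if (length(ip)) {
        p <- ip[[sample.int(length(ip), 1L)]]
        g <- .set_node(g, p, .leaf())
      }
    }
    if (stats::runif(1) < config$p_grow) {
      ap <- .node_paths(g)
      lp <- Filter(function(p) .get_node(g, p)$leaf, ap)
      lp <- Filter(function(p) length(p) < config$max_depth, lp)
      if (length(lp)) {
        p <- lp[[sample.int(length(lp), 1L)]]
        s <- if (stats::runif(1) < 0.5) {
          # greedy extension: the best single split of this leaf's samples
          idx <- .idx_at_path(g, X, p)
          .best_split(X, y_int, nclass, idx, config$min_bucket)
        }
        if (is.null(s)) s <- .random_split(cands)
        g <- .set_node(g, p, .split(s$var, s$thr, .leaf(), .leaf()))
      }
    }
    g
  }
  pick <- function() {
    ids <- sample.int(config$population, config$tournament, replace = TRUE)
    pop[[ids[which.min(fit[ids])]]]
  }

  for (gen in seq_len(config$generations)) {
    newpop <- vector("list", config$population)
    newpop[[1L]] <- best_g                     # elitism
    for (i in 2:config$population) {
      child <- pick()
      if (stats::runif(1) < config$p_crossover) {
        donor <- pick()
        dp <- .node_paths(donor)
        rp <- .node_paths(child)
        sub <- .get_node(donor, dp[[sample.int(length(dp), 1L)]])
        child <- .set_node(child, rp[[sample.int(length(rp), 1L)]], sub)
      }
      newpop[[i]] <- mutate(child)
    }
    pop <- newpop
    fit <- vapply(pop, fitness_of, numeric(1))
    if (min(fit) < best_f - 1e-15) {
      best_f <- min(fit)
      best_g <- pop[[which.min(fit)]]
      stale <- 0L
    } else stale <- stale + 1L
    history[gen] <- best_f
    if (stale >= config$patience) { history <- history[seq_len(gen)]; break }
  }
  list(genotype = best_g, fitness = best_f, history = history)
  }

  runs <- lapply(seq_len(max(1L, config$restarts)) - 1L, function(r)
    run_once(config$seed + 1000L * r))
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "fitness"))]]
  .finalise_model(best$genotype, X, labels, classes, config, "evolved",
                  best$history)
}

#' Greedy (CART-style) classification tree baseline
#'
#' Recursive partitioning under the same depth and leaf-size constraints as
#' [evolve_tree()], choosing at each node the split with the largest Gini
#' impurity gain (the CART convention) and stopping when no split improves
#' it.  This is the locally optimal benchmark the evolutionary learner is
#' compared against: greedy split choice ignores the nodes further down the
#' tree, so it fails on problems (e.g. checkerboards) where the first split
#' has no marginal gain, and it cannot trade local purity against the
#' complexity penalty the way the global search can.
#'
#' @inheritParams evolve_tree
#' @return A `tree_model` with `method = "greedy"`.
#' @export
greedy_tree <- function(features, labels, config = evolution_config()) {
  X <- .check_features(features)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  y_int <- match(labels, classes)
  nclass <- length(classes)
  cands <- .threshold_candidates(X)
  g <- if (nclass > 1L) .greedy_genotype(X, y_int, nclass, config)
       else .leaf()
  .finalise_model(g, X, labels, classes, config, "greedy")
}

.greedy_genotype <- function(X, y_int, nclass, config, root_var = NULL) {
  build <- function(idx, depth) {
    if (depth >= config$max_depth) return(.leaf())
    best <- .best_split(X, y_int, nclass, idx, config$min_bucket)
    if (is.null(best)) return(.leaf())
    go_left <- X[idx, best$var] < best$thr
    .split(best$var, best$thr, build(idx[go_left], depth + 1L),
           build(idx[!go_left], depth + 1L))
  }
  if (is.null(root_var)) return(build(seq_len(nrow(X)), 0L))
  ## greedy completion under a forced root variable (locally best threshold)
  idx <- seq_len(nrow(X))
  bs <- .best_split(X, y_int, nclass, idx, config$min_bucket,
                    variables = root_var)
  if (is.null(bs)) return(build(idx, 0L))
  go_left <- X[idx, bs$var] < bs$thr
  .split(bs$var, bs$thr, build(idx[go_left], 1L), build(idx[!go_left], 1L))
}

## ---- prediction and reporting ---------------------------------------------

#' Predict class labels from a fitted tree
#'
#' Samples are routed deterministically: a value strictly below the node
#' threshold goes left, a value greater than or equal to it goes right.
#'
#' @param object A `tree_model`.
#' @param newdata Numeric matrix or data frame containing (at least) the
#'   variables used by the tree, with matching column names.
#' @param ... Unused.
#' @return Character vector of predicted labels.
#' @export
predict.tree_model <- function(object, newdata, ...) {
  X <- if (is.data.frame(newdata)) newdata else as.data.frame(newdata)
  used <- unique(vapply(.internal_nodes(object$root), function(nd)
    object$var_names[nd$var], character(1)))
  missing_vars <- setdiff(used, names(X))
  if (length(missing_vars))
    stop("unknown variables in model: ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  out <- character(nrow(X))
  route <- function(node, idx) {
    if (!length(idx)) return(invisible())
    if (node$leaf) { out[idx] <<- node$label; return(invisible()) }
    v <- X[[object$var_names[node$var]]][idx]
    go_left <- v < node$thr
    route(node$left, idx[go_left])
    route(node$right, idx[!go_left])
  }
  route(object$root, seq_len(nrow(X)))
  out
}

.internal_nodes <- function(node) {
  if (node$leaf) return(list())
  c(list(node), .internal_nodes(node$left), .internal_nodes(node$right))
}

#' Threshold report of a fitted tree
#'
#' Pre-order traversal of the internal nodes, one row per split: the variable
#' and threshold, the node depth, and the majority label of each child.  For
#' a binary tree the report has `n_leaves - 1` rows.
#'
#' @param model A `tree_model`.
#' @return Data frame with columns `variable`, `threshold`, `depth`,
#'   `left_label`, `right_label`, `n`.
#' @export
extract_thresholds <- function(model) {
  stopifnot(inherits(model, "tree_model"))
  rows <- list()
  walk <- function(node) {
    if (node$leaf) return(invisible())
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = model$var_names[node$var], threshold = node$thr,
      depth = node$depth, left_label = node$left$label,
      right_label = node$right$label, n = node$n,
      stringsAsFactors = FALSE)
    walk(node$left); walk(node$right)
  }
  walk(model$root)
  if (!length(rows))
    return(data.frame(variable = character(0), threshold = numeric(0),
                      depth = integer(0), left_label = character(0),
                      right_label = character(0), n = integer(0)))
  do.call(rbind, rows)
}

#' @export
print.tree_model <- function(x, ...) {
  cat(sprintf("%s classification tree: %d leaves, depth %d\n",
              x$method, x$n_leaves, x$depth))
  cat(sprintf("training misclassification %.4f, fitness %.4f (n = %d)\n",
              x$misclass, x$fitness, x$n_train))
  walk <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$leaf) {
      cat(sprintf("%s* %s (n = %d)\n", pad, node$label, node$n))
    } else {
      cat(sprintf("%s%s < %g\n", pad, x$var_names[node$var], node$thr))
      walk(node$left, indent + 1L)
      walk(node$right, indent + 1L)
    }
  }
  walk(x$root, 0L)
  invisible(x)
}

#' Serialise / restore a tree model as JSON
#'
#' @param model A `tree_model`.
#' @param path File path.
#' @rdname tree_model_io
#' @export
write_tree_model <- function(model, path) {
  stopifnot(inherits(model, "tree_model"))
  out <- model
  out$config <- unclass(out$config)
  jsonlite::write_json(unclass(out), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname tree_model_io
#' @export
read_tree_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  fix <- function(node) {
    node$class_counts <- unlist(node$class_counts)
    node$ratio <- unlist(node$ratio)
    if (!isTRUE(node$leaf)) {
      node$left <- fix(node$left); node$right <- fix(node$right)
    }
    node
  }
  raw$root <- fix(raw$root)
  raw$var_names <- unlist(raw$var_names)
  raw$classes <- unlist(raw$classes)
  raw$history <- unlist(raw$history)
  if (!is.null(raw$config)) class(raw$config) <- "evolution_config"
  class(raw) <- "tree_model"
  raw
}

## Hand-built tree from explicit rules (used for planted climate rules and
## available to users who want to encode a known threshold logic).
#' Build a tree model from explicit split rules
#'
#' Constructs a `tree_model` directly from a nested rule description instead
#' of fitting one.  A rule node is `list(var =, threshold =, left =, right =)`
#' where children are either further rule nodes or a character class label.
#' Useful for encoding published threshold logic or planting rules in
#' synthetic data.
#'
#' @param rules Nested rule list (see details above).
#' @param var_names Character vector of all feature names the tree may
#'   reference.
#' @return A `tree_model` with `method = "specified"`.
#' @export
rule_tree <- function(rules, var_names) {
  classes <- character(0)
  convert <- function(r, depth) {
    if (is.character(r)) {
      classes <<- union(classes, r)
      return(list(leaf = TRUE, label = r, n = NA_integer_,
                  class_counts = NULL, ratio = NULL, depth = depth))
    }
    v <- match(r$var, var_names)
    if (is.na(v)) stop("unknown variable in rules: ", r$var, call. = FALSE)
    list(leaf = FALSE, var = v, thr = r$threshold,
         left = convert(r$left, depth + 1L),
         right = convert(r$right, depth + 1L),
         label = NA_character_, n = NA_integer_, depth = depth)
  }
  root <- convert(rules, 0L)
  model <- list(root = root, var_names = var_names, classes = sort(classes),
                depth = .tree_depth(root), n_leaves = .tree_leaves(root),
                misclass = NA_real_, fitness = NA_real_, config = NULL,
                method = "specified", history = NULL, n_train = NA_integer_)
  class(model) <- "tree_model"
  model
}
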