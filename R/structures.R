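## From species presences to community trophic structures: build the
## cell x guild count matrix, filter low-human-impact cells, classify them by
## fuzzy clustering, interpolate the rest with a random forest, and relate
## the structure space to species richness by PCA.

#' Build the cell x guild trophic space
#'
#' Counts, for every grid cell, the number of present species belonging to
#' each guild.  Each cell becomes a point in a guild-count space whose
#' dimension equals the number of guilds; the row sum is the cell's species
#' richness.  Cells without species are retained as zero rows.
#'
#' @param grid Presence data: either a binary cell x species matrix (cells as
#'   row names, species as column names) or a long data frame with columns
#'   `cell` and `species`.
#' @param guilds A `guild_assignment`, or a named character vector of guild
#'   labels per species.
#' @return Object of class `trophic_space`: `counts` (cell x guild integer
#'   matrix), `richness` (per-cell row sums), `guild_names`.
#' @export
build_trophic_space <- function(grid, guilds) {
  labels <- if (inherits(guilds, "guild_assignment")) guild_labels(guilds)
            else guilds
  if (is.null(names(labels)))
    stop("guild labels must be named by species", call. = FALSE)
  if (is.data.frame(grid) && all(c("cell", "species") %in% names(grid))) {
    cells <- unique(as.character(grid$cell))
    species <- unique(as.character(grid$species))
    m <- matrix(0L, length(cells), length(species),
                dimnames = list(cells, species))
    m[cbind(match(grid$cell, cells), match(grid$species, species))] <- 1L
    grid <- m
  }
  if (!is.matrix(grid)) stop("grid must be a matrix or long data frame")
  if (!all(grid %in% c(0L, 1L)))
    stop("presence grid must be binary", call. = FALSE)
  unknown <- setdiff(colnames(grid), names(labels))
  if (length(unknown))
    stop("species without guild label: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  glev <- unique(labels[colnames(grid)])
  ind <- outer(labels[colnames(grid)], glev, `==`) + 0L
  counts <- grid %*% ind
  colnames(counts) <- glev
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, richness = rowSums(counts),
                 guild_names = glev),
            class = "trophic_space")
}

#' @export
print.trophic_space <- function(x, ...) {
  cat(sprintf("trophic space: %d cells x %d guilds, richness %d-%d\n",
              nrow(x$counts), ncol(x$counts), min(x$richness),
              max(x$richness)))
  invisible(x)
}

#' Select cells with low human impact
#'
#' Keeps cells satisfying all three criteria: primary vegetation cover at
#' least `primary_min` percent, urban cover below `urban_max` percent, and
#' population density below `pop_max` inhabitants per km2.  Per-criterion
#' exclusion counts are reported as a message and attached as an attribute.
#'
#' @param impacts Data frame with columns `cell`, `primary`, `urban`,
#'   `pop_density` (a `synthetic_world$cells` table works directly).
#' @param cells Optional subset of cell ids to consider (default all).
#' @param primary_min,urban_max,pop_max Filter thresholds; the defaults are
#'   25 percent primary vegetation, 0.003 percent urban cover and 26
#'   inhabitants per km2.
#' @param quiet Suppress the exclusion-count message.
#' @return Character vector of retained cell ids, with attribute
#'   `exclusions` (named counts per criterion).
#' @export
filter_low_impact <- function(impacts, cells = NULL, primary_min = 25,
                              urban_max = 0.003, pop_max = 26,
                              quiet = FALSE) {
  need <- c("cell", "primary", "urban", "pop_density")
  if (!all(need %in% names(impacts)))
    stop("impacts must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!is.null(cells)) {
    miss <- setdiff(cells, impacts$cell)
    if (length(miss))
      stop("no impact record for cell(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    impacts <- impacts[match(cells, impacts$cell), , drop = FALSE]
  }
  fail_primary <- impacts$primary < primary_min
  fail_urban <- impacts$urban >= urban_max
  fail_pop <- impacts$pop_density >= pop_max
  keep <- !(fail_primary | fail_urban | fail_pop)
  excl <- c(primary = sum(fail_primary), urban = sum(fail_urban),
            population = sum(fail_pop))
  if (!quiet)
    message(sprintf(
      "low-impact filter: kept %d of %d cells (excluded: primary %d, urban %d, population %d)",
      sum(keep), nrow(impacts), excl[1L], excl[2L], excl[3L]))
  structure(impacts$cell[keep], exclusions = excl)
}

#' Classify cells into trophic structures by fuzzy clustering
#'
#' Clusters the guild-count vectors of the given cells with fuzzy c-means.
#' With `c = "auto"` an AMD scan over `scan_range` first determines how many
#' well-defined structures the data support.  Each cell receives the label of
#' its maximum-membership cluster and that membership degree (the colour
#' intensity of a map would be proportional to it).
#'
#' @param space A `trophic_space` or a plain cell x guild count matrix.
#' @param cells Cell ids to classify (e.g. the low-impact subset); default
#'   all rows.
#' @param c Number of structures, or `"auto"`.
#' @param scan_range Range scanned when `c = "auto"`.
#' @param replicates Random restarts (per candidate c when scanning).
#' @param m Fuzzifier.
#' @param seed Integer seed.
#' @return Object of class `structure_classification`: `cells` (data frame
#'   with `cell`, `label`, `membership`, `provenance = "clustered"`),
#'   `centres` (structure x guild), `scan` (the `amd_scan`, if run), and
#'   `labels` (the label vocabulary, `S1..Sk` until renamed with
#'   [name_structures()]).
#' @export
classify_structures <- function(space, cells = NULL, c = "auto",
                                scan_range = c(2L, 10L), replicates = 50L,
                                m = 2, seed = 1L) {
  counts <- if (inherits(space, "trophic_space")) space$counts else space
  counts <- as_sample_matrix(counts)
  if (!is.null(cells)) {
    miss <- setdiff(cells, rownames(counts))
    if (length(miss))
      stop("cells absent from the trophic space: ",
           paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
    counts <- counts[cells, , drop = FALSE]
  }
  scan <- NULL
  if (identical(c, "auto")) {
    scan <- amd_scan(counts, c_min = scan_range[1L],
                     c_max = min(scan_range[2L], nrow(counts)),
                     replicates = replicates, m = m, seed = seed)
    part <- scan$best_partition
  } else {
    if (c > nrow(counts))
      stop("fewer cells than requested structures", call. = FALSE)
    best <- NULL
    for (r in seq_len(replicates)) {
      p <- fit_cmeans(counts, c, m = m, seed = seed + r)
      a <- compute_amd(p)$amd
      if (is.null(best) || a > best_a) { best <- p; best_a <- a }
    }
    part <- best
  }
  lab <- hard_labels(part)
  k <- ncol(part$membership)
  labels <- paste0("S", seq_len(k))
  res <- list(cells = data.frame(
                cell = rownames(counts), label = labels[lab],
                membership = part$membership[cbind(seq_along(lab), lab)],
                provenance = "clustered", stringsAsFactors = FALSE),
              centres = part$centres, labels = labels, scan = scan,
              partition = part)
  rownames(res$centres) <- labels
  class(res) <- "structure_classification"
  res
}

#' @export
print.structure_classification <- function(x, ...) {
  cat(sprintf("structure classification: %d cells, %d structures\n",
              nrow(x$cells), length(x$labels)))
  print(table(label = x$cells$label, provenance = x$cells$provenance))
  invisible(x)
}

#' Rename structure clusters by matching centres to archetype profiles
#'
#' Finds the one-to-one assignment of cluster centres to archetype rows that
#' minimises the total Euclidean distance (exhaustive over permutations for
#' up to 8 clusters, greedy beyond) and renames the classification
#' accordingly.  With fewer clusters than archetypes the best-matching subset
#' of archetype names is used.
#'
#' @param classification A `structure_classification`.
#' @param archetypes Structure x guild reference matrix, default
#'   [default_structure_archetypes()].
#' @return The classification with labels replaced by archetype names.
#' @export
name_structures <- function(classification,
                            archetypes = default_structure_archetypes()) {
  stopifnot(inherits(classification, "structure_classification"))
  shared <- intersect(colnames(classification$centres), colnames(archetypes))
  if (!length(shared))
    stop("centres and archetypes share no guild columns", call. = FALSE)
  cen <- classification$centres[, shared, drop = FALSE]
  arc <- archetypes[, shared, drop = FALSE]
  k <- nrow(cen)
  d <- outer(seq_len(k), seq_len(nrow(arc)),
             Vectorize(function(i, j) sqrt(sum((cen[i, ] - arc[j, ])^2))))
  if (k <= 8L && nrow(arc) >= k) {
    perms <- .permutations(seq_len(nrow(arc)), k)
    tot <- vapply(perms, function(p) sum(d[cbind(seq_len(k), p)]), numeric(1))
    match_idx <- perms[[which.min(tot)]]
  } else {
    match_idx <- integer(k)
    free <- seq_len(nrow(arc))
    for (i in order(apply(d, 1L, min))) {
      j <- free[which.min(d[i, free])]
      match_idx[i] <- j
      free <- setdiff(free, j)
      if (!length(free)) free <- seq_len(nrow(arc))
    }
  }
  new_names <- rownames(arc)[match_idx]
  old <- classification$labels
  classification$cells$label <- new_names[match(classification$cells$label, old)]
  rownames(classification$centres) <- new_names
  classification$labels <- new_names
  classification
}

## all k-permutations of v (k <= length(v))
.permutations <- function(v, k) {
  if (k == 0L) return(list(integer(0)))
  out <- list()
  for (i in seq_along(v)) {
    rest <- .permutations(v[-i], k - 1L)
    out <- c(out, lapply(rest, function(r) c(v[i], r)))
  }
  out
}

#' Interpolate structure labels to unlabelled cells with a random forest
#'
#' Fits a random forest (500 trees, `sqrt(p)` variables per split) on the
#' guild-count vectors of the clustered cells and predicts the structure of
#' every remaining cell.  Interpolated cells carry the forest's vote
#' fraction as their membership degree, by analogy with the fuzzy
#' memberships of the clustered cells, and `provenance = "interpolated"`.
#'
#' @param space A `trophic_space` or cell x guild count matrix covering all
#'   cells.
#' @param labelled A `structure_classification` of the training cells.
#' @param cells Cells to predict; default every row of `space` not in
#'   `labelled`.
#' @param ntree,seed Forest size and seed.
#' @return A `structure_classification` covering training and predicted
#'   cells, with out-of-bag accuracy in attribute `oob_accuracy`.
#' @export
interpolate_structures <- function(space, labelled, cells = NULL,
                                   ntree = 500L, seed = 1L) {
  counts <- if (inherits(space, "trophic_space")) space$counts else space
  counts <- as_sample_matrix(counts)
  stopifnot(inherits(labelled, "structure_classification"))
  train_id <- labelled$cells$cell
  if (is.null(cells)) cells <- setdiff(rownames(counts), train_id)
  y <- factor(labelled$cells$label)
  if (nlevels(y) < 2L) {
    warning("single-class training set; all predictions are that class")
    pred <- data.frame(cell = cells, label = as.character(y[1L]),
                       membership = 1, provenance = "interpolated",
                       stringsAsFactors = FALSE)
    out <- labelled
    out$cells <- rbind(labelled$cells, pred)
    attr(out, "oob_accuracy") <- 1
    return(out)
  }
  set.seed(seed)
  rf <- randomForest::randomForest(counts[train_id, , drop = FALSE], y,
                                   ntree = ntree)
  oob <- mean(rf$predicted == y)
  pred_lab <- as.character(predict(rf, counts[cells, , drop = FALSE]))
  votes <- predict(rf, counts[cells, , drop = FALSE], type = "vote")
  memb <- votes[cbind(seq_along(cells), match(pred_lab, colnames(votes)))]
  out <- labelled
  out$cells <- rbind(labelled$cells,
                     data.frame(cell = cells, label = pred_lab,
                                membership = memb,
                                provenance = "interpolated",
                                stringsAsFactors = FALSE))
  attr(out, "oob_accuracy") <- oob
  out$forest <- rf
  out
}

#' Principal-component decomposition of the trophic space
#'
#' PCA of the cell x guild count matrix (columns centred, unscaled by
#' default, so the first axis retains its species-richness interpretation),
#' reporting the per-axis share of total variance and the squared
#' correlation between the first-axis scores and per-cell species richness.
#'
#' @param space A `trophic_space` or cell x guild count matrix.
#' @param cells Optional subset of cells.
#' @param scale Scale columns to unit variance before decomposition.
#' @return List of class `richness_decomposition`: `variance_share` (per
#'   axis, summing to 1), `r2_richness` (axis 1 vs richness), `scores`,
#'   `loadings`.
#' @export
richness_decomposition <- function(space, cells = NULL, scale = FALSE) {
  counts <- if (inherits(space, "trophic_space")) space$counts else space
  counts <- as_sample_matrix(counts)
  if (!is.null(cells)) counts <- counts[cells, , drop = FALSE]
  if (nrow(counts) < 3L) stop("need at least 3 cells", call. = FALSE)
  if (all(apply(counts, 2L, function(v) max(v) == min(v))))
    stop("constant matrix: principal axes undefined", call. = FALSE)
  pc <- stats::prcomp(counts, center = TRUE, scale. = scale)
  share <- pc$sdev^2 / sum(pc$sdev^2)
  richness <- rowSums(counts)
  r2 <- if (stats::sd(richness) == 0) NA_real_
        else stats::cor(pc$x[, 1L], richness)^2
  structure(list(variance_share = share, r2_richness = r2,
                 scores = pc$x, loadings = pc$rotation),
            class = "richness_decomposition")
}

#' @export
print.richness_decomposition <- function(x, ...) {
  cat("variance share per axis:",
      paste(sprintf("%.1f%%", 100 * utils::head(x$variance_share, 4L)),
            collapse = ", "), "...\n")
  cat(sprintf("r2(axis 1, species richness) = %.3f\n", x$r2_richness))
  invisible(x)
}

#' Write a structure classification to CSV
#'
#' Columns: cell, label, membership, provenance, and lat/lon when a cell
#' table is supplied.
#'
#' @param classification A `structure_classification`.
#' @param path Output CSV path.
#' @param cell_table Optional data frame with `cell`, `lat`, `lon`.
#' @export
write_classification <- function(classification, path, cell_table = NULL) {
  stopifnot(inherits(classification, "structure_classification"))
  df <- classification$cells
  if (!is.null(cell_table)) {
    i <- match(df$cell, cell_table$cell)
    df$lat <- cell_table$lat[i]
    df$lon <- cell_table$lon[i]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
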