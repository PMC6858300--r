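## Trophic guild inference: fuzzy clustering of species in diet space and
## hard assignment of every species to its maximum-membership guild.

#' Read and validate a diet-composition matrix
#'
#' Diet matrices have species as rows and resource percentages as columns.
#' Literature-derived rows may be slightly off 100; rows within `band`
#' percentage points of 100 are renormalised exactly, rows outside the band
#' are reported and rejected.
#'
#' @param x CSV path (species id in the first column) or a matrix/data frame.
#' @param band Acceptable deviation of the raw row sum from 100.
#' @return Species x resource numeric matrix with rows summing to 100.
#' @export
read_diet_matrix <- function(x, band = 0.5) {
  m <- if (is.character(x) && length(x) == 1L) read_sample_matrix(x)
       else as_sample_matrix(x)
  if (any(m < 0) || any(m > 100))
    stop("diet percentages must lie in [0, 100]", call. = FALSE)
  dev <- abs(rowSums(m) - 100)
  bad <- which(dev > band)
  if (length(bad))
    stop("diet rows deviating from 100 by more than ", band, ": ",
         paste(sprintf("%s (%.2f)", rownames(m)[bad], rowSums(m)[bad]),
               collapse = ", "), call. = FALSE)
  m / rowSums(m) * 100
}

#' Infer trophic guilds from a diet matrix
#'
#' Clusters species in diet space with fuzzy c-means, using random restarts
#' and keeping the solution with the lowest objective.  Each species is then
#' hard-assigned to its maximum-membership guild.
#'
#' @param diet Diet matrix (see [read_diet_matrix()]).
#' @param n_guilds Number of guilds to fit (`>= 2`).
#' @param replicates Number of random restarts.
#' @param m Fuzzifier.
#' @param seed Integer seed.
#' @return Object of class `guild_assignment`: `guild` (integer index per
#'   species), `membership` (degree to the assigned guild), `centres`
#'   (guild x resource diet profiles), `names` (display names, initially
#'   `guild_1..guild_k`), and the full `partition`.
#' @export
infer_guilds <- function(diet, n_guilds = 11L, replicates = 50L, m = 2,
                         seed = 1L) {
  diet <- read_diet_matrix(diet)
  if (n_guilds < 2L || n_guilds > nrow(diet))
    stop("'n_guilds' must be in [2, number of species]", call. = FALSE)
  best <- NULL
  for (r in seq_len(replicates)) {
    p <- fit_cmeans(diet, n_guilds, m = m, seed = seed + r)
    if (is.null(best) || p$objective < best$objective) best <- p
  }
  lab <- hard_labels(best)
  res <- list(guild = stats::setNames(lab, rownames(diet)),
              membership = stats::setNames(
                best$membership[cbind(seq_along(lab), lab)], rownames(diet)),
              centres = best$centres,
              names = paste0("guild_", seq_len(n_guilds)),
              partition = best)
  class(res) <- "guild_assignment"
  res
}

#' @export
print.guild_assignment <- function(x, ...) {
  cat(sprintf("guild assignment: %d species in %d guilds\n",
              length(x$guild), nrow(x$centres)))
  print(table(factor(x$names[x$guild], levels = x$names)))
  invisible(x)
}

#' Species guild labels as display names
#'
#' @param assignment A `guild_assignment`.
#' @return Named character vector of guild display names per species.
#' @export
guild_labels <- function(assignment) {
  stopifnot(inherits(assignment, "guild_assignment"))
  stats::setNames(assignment$names[assignment$guild], names(assignment$guild))
}

#' Name guilds from their diet centres
#'
#' By default each fitted guild centre is matched to the nearest archetype
#' diet profile (Euclidean distance over the shared resource columns) and
#' takes its code; guild naming in the literature is ultimately expert
#' judgement, so an explicit `mapping` (one name per guild, in guild order)
#' overrides the heuristic entirely.  Heuristic names are made unique by
#' appending an index to duplicates; explicit duplicate names are an error.
#'
#' @param assignment A `guild_assignment`.
#' @param archetypes Reference diet table for the heuristic,
#'   [default_guild_archetypes()] by default.
#' @param mapping Optional character vector of explicit names, length equal
#'   to the number of guilds.
#' @return The assignment with its `names` field filled in.
#' @export
name_guilds <- function(assignment, archetypes = default_guild_archetypes(),
                        mapping = NULL) {
  stopifnot(inherits(assignment, "guild_assignment"))
  k <- nrow(assignment$centres)
  if (!is.null(mapping)) {
    if (length(mapping) != k)
      stop("explicit mapping must name all ", k, " guilds", call. = FALSE)
    if (anyDuplicated(mapping))
      stop("duplicate explicit guild names", call. = FALSE)
    assignment$names <- as.character(mapping)
    return(assignment)
  }
  shared <- intersect(colnames(assignment$centres), colnames(archetypes))
  if (!length(shared))
    stop("centres and archetypes share no resource columns", call. = FALSE)
  nm <- character(k)
  for (i in seq_len(k)) {
    d <- sqrt(colSums((t(archetypes[, shared, drop = FALSE]) -
                         assignment$centres[i, shared])^2))
    nm[i] <- rownames(archetypes)[which.min(d)]
  }
  dup <- duplicated(nm)
  nm[dup] <- paste0(nm[dup], "_", seq_len(sum(dup)) + 1L)
  assignment$names <- nm
  assignment
}

#' Scan the number of guilds with the AMD statistic
#'
#' Applies [amd_scan()] to the diet matrix: the selected cluster number is
#' the one whose best-of-replicates AMD is maximal.
#'
#' @inheritParams infer_guilds
#' @param c_min,c_max Scan range.
#' @return An `amd_scan` object.
#' @export
select_n_guilds <- function(diet, c_min = 2L, c_max = 15L, replicates = 50L,
                            m = 2, seed = 1L) {
  diet <- read_diet_matrix(diet)
  amd_scan(diet, c_min = c_min, c_max = c_max, replicates = replicates,
           m = m, seed = seed)
}

#' Write a guild assignment to CSV
#'
#' Columns: species, guild index, guild name, membership degree.
#'
#' @param assignment A `guild_assignment`.
#' @param path Output CSV path.
#' @export
write_guild_assignment <- function(assignment, path) {
  stopifnot(inherits(assignment, "guild_assignment"))
  df <- data.frame(species = names(assignment$guild),
                   guild = assignment$guild,
                   name = assignment$names[assignment$guild],
                   membership = assignment$membership)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
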