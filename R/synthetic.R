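## Synthetic inputs for every stage of the pipeline: artificial Gaussian
## cluster benchmarks for the AMD validity statistic, diet matrices drawn
## from guild archetypes, and a gridded world with climate, structure labels,
## land use, population and islands.

#' Canonical guild and resource codes
#'
#' Eleven consumer guilds (selective herbivores SH, plant-material feeders
#' PF, small carnivores SC, frugivores FR, folivores FL, mixed feeders MF,
#' omnivores OM, grazers Gz, piscivores PS, invertebrate feeders IF, large
#' carnivores LC) and twelve food resources (grass gr, leaves lv, fruits fr,
#' flowers fw, forbs fb, seeds sd, invertebrates inv, fish fs, small
#' vertebrates sv, mammals 1-10 kg sm, 10-100 kg mm, >100 kg lm).
#'
#' @rdname trophic_codes
#' @export
guild_codes <- function() c("SH", "PF", "SC", "FR", "FL", "MF", "OM", "Gz",
                            "PS", "IF", "LC")

#' @rdname trophic_codes
#' @export
resource_codes <- function() c("gr", "lv", "fr", "fw", "fb", "sd", "inv",
                               "fs", "sv", "sm", "mm", "lm")

#' Names of the six community trophic structures
#' @export
structure_names <- function() c("boreal", "temperate", "semiarid",
                                "seasonal_tropical", "humid_tropical",
                                "depauperate")

#' Artificial Gaussian cluster benchmark
#'
#' Generates `n` samples in `d` dimensions around `k` cluster centres drawn
#' i.i.d. uniform per dimension over `box`, each sample being its centre plus
#' isotropic Gaussian noise.  Samples are split into `k` equal groups (up to
#' remainder).  With the defaults (`n = 8000`, `d = 11`, `k = 6`,
#' `box = c(0, 10)`), fuzzy c-means with `m = 2` yields best-of-replicates
#' AMD peaks near 0.6 at `sd = 1` and near 0.39 at `sd = 1.7`, while
#' structureless uniform samples give AMD near 0.
#'
#' @param n Number of samples.
#' @param d Number of dimensions.
#' @param k Number of planted clusters.
#' @param sd Per-dimension Gaussian standard deviation (`>= 0`).
#' @param box Length-2 range from which centre coordinates are drawn.
#' @param seed Integer seed.
#' @return List of class `cluster_benchmark`: `samples` (n x d matrix),
#'   `true_labels` (integers 1..k), `centres` (k x d), `sd`, `box`, `seed`.
#' @export
generate_cluster_benchmark <- function(n = 8000L, d = 11L, k = 6L, sd = 1,
                                       box = c(0, 10), seed = 1L) {
  if (sd < 0) stop("'sd' must be >= 0", call. = FALSE)
  if (n < k || k < 1L) stop("need n >= k >= 1", call. = FALSE)
  set.seed(seed)
  centres <- matrix(stats::runif(k * d, box[1L], box[2L]), k, d)
  labels <- rep_len(seq_len(k), n)
  samples <- centres[labels, , drop = FALSE] +
    matrix(stats::rnorm(n * d, 0, sd), n, d)
  rownames(samples) <- paste0("s", seq_len(n))
  colnames(samples) <- paste0("dim", seq_len(d))
  structure(list(samples = samples, true_labels = labels, centres = centres,
                 sd = sd, box = box, seed = seed),
            class = "cluster_benchmark")
}

#' Structureless uniform samples
#'
#' i.i.d. uniform points over `[0, 10]^d`, the null case of the AMD
#' benchmark: fuzzy memberships approach `1/c` so AMD approaches 0.
#'
#' @inheritParams generate_cluster_benchmark
#' @return Sample matrix (n x d).
#' @export
generate_random_samples <- function(n = 8000L, d = 11L, seed = 1L) {
  if (n < 1L) stop("'n' must be >= 1", call. = FALSE)
  set.seed(seed)
  x <- matrix(stats::runif(n * d, 0, 10), n, d,
              dimnames = list(paste0("s", seq_len(n)), paste0("dim", seq_len(d))))
  x
}

#' Default diet archetypes of the eleven guilds
#'
#' One idealised diet-percentage vector per guild over the twelve resources;
#' rows sum to 100.  The profiles encode the conventional reading of each
#' guild: a piscivore eats only fish, a grazer almost only grass, an omnivore
#' spreads over many resources, large carnivores concentrate on large prey,
#' and so on.  Used as the means from which synthetic species diets are
#' drawn, and as the reference table for heuristic guild naming.
#'
#' @return A `g x r` matrix with guild codes as row names and resource codes
#'   as column names.
#' @export
default_guild_archetypes <- function() {
  r <- resource_codes()
  a <- matrix(0, length(guild_codes()), length(r),
              dimnames = list(guild_codes(), r))
  a["SH", c("fb", "fw", "sd", "lv")] <- c(40, 25, 20, 15)
  a["PF", c("gr", "lv", "fb", "sd", "fr")] <- c(25, 25, 20, 15, 15)
  a["SC", c("sv", "sm", "inv")] <- c(45, 35, 20)
  a["FR", c("fr", "lv", "sd", "inv")] <- c(75, 10, 10, 5)
  a["FL", c("lv", "fr", "fw")] <- c(85, 10, 5)
  a["MF", c("gr", "lv", "fb")] <- c(50, 40, 10)
  a["OM", c("fr", "inv", "lv", "sd", "sv", "gr", "fb", "sm")] <-
    c(20, 20, 15, 10, 10, 10, 10, 5)
  a["Gz", c("gr", "fb")] <- c(90, 10)
  a["PS", "fs"] <- 100
  a["IF", c("inv", "sv", "fr")] <- c(85, 10, 5)
  a["LC", c("mm", "lm", "sm", "sv")] <- c(40, 30, 20, 10)
  stopifnot(all(abs(rowSums(a) - 100) < 1e-9))
  a
}

#' Synthetic species diet matrix from guild archetypes
#'
#' Species are assigned to guilds round-robin; each species' diet is its
#' guild archetype plus Gaussian noise, clipped at zero and renormalised to
#' sum to 100.
#'
#' @param n_species Number of species (`>=` number of guilds).
#' @param archetypes Guild archetype matrix (rows sum to 100), default
#'   [default_guild_archetypes()].
#' @param noise_sd Standard deviation (percentage points) of the diet noise.
#' @param seed Integer seed.
#' @return List with `diet` (species x resource matrix, rows sum to 100) and
#'   `guild` (character vector of true guild codes per species).
#' @export
generate_diet_matrix <- function(n_species, archetypes = default_guild_archetypes(),
                                 noise_sd = 5, seed = 1L) {
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  g <- nrow(archetypes)
  if (n_species < g)
    stop("'n_species' must be at least the number of guilds", call. = FALSE)
  set.seed(seed)
  guild <- rownames(archetypes)[rep_len(seq_len(g), n_species)]
  diet <- archetypes[guild, , drop = FALSE] +
    matrix(stats::rnorm(n_species * ncol(archetypes), 0, noise_sd),
           n_species, ncol(archetypes))
  diet[diet < 0] <- 0
  diet <- diet / rowSums(diet) * 100
  rownames(diet) <- sprintf("sp%04d", seq_len(n_species))
  list(diet = diet, guild = stats::setNames(guild, rownames(diet)))
}

#' Default climatic threshold rules of the six trophic structures
#'
#' A fixed decision tree over bioclimatic variables encoding the threshold
#' logic that separates the six structures: mean annual temperature (bio1,
#' 17.6 degC) splits cold from warm regimes; within the cold branch maximum
#' temperature of the warmest month (bio5, 11.6 degC) and isothermality
#' (bio3, 21.3 and 46.8) separate depauperate, boreal and temperate; within
#' the warm branch annual precipitation (bio12, 144 / 588 / 1608 mm) and
#' temperature seasonality (bio4, 10.9) separate depauperate, semiarid,
#' seasonal tropical and humid tropical.  Used as the planted ground truth
#' of the synthetic world.
#'
#' @return A `tree_model` over the 19 `bio1..bio19` variables.
#' @export
default_climate_rules <- function() {
  vars <- paste0("bio", 1:19)
  rules <- list(var = "bio1", threshold = 17.6,
    left = list(var = "bio5", threshold = 11.6,
      left = list(var = "bio3", threshold = 21.3,
        left = "boreal", right = "depauperate"),
      right = list(var = "bio3", threshold = 46.8,
        left = "boreal", right = "temperate")),
    right = list(var = "bio12", threshold = 144,
      left = "depauperate",
      right = list(var = "bio12", threshold = 588,
        left = "semiarid",
        right = list(var = "bio12", threshold = 1608,
          left = "seasonal_tropical",
          right = list(var = "bio4", threshold = 10.9,
            left = "humid_tropical", right = "seasonal_tropical")))))
  rule_tree(rules, vars)
}

#' Default mean guild-count profiles of the six structures
#'
#' Mean number of species per guild for each structure, echoing the relative
#' guild composition of the six structures: boreal communities are
#' species-poor with omnivores and large carnivores relatively prominent;
#' temperate ones richer with plant-material and mixed feeders; semiarid
#' ones are the richest, dominated by omnivores, grazers and plant feeders;
#' seasonal tropical ones carry many small carnivores, plant and
#' invertebrate feeders; humid tropical ones many frugivores, small
#' carnivores and invertebrate feeders; depauperate ones very few species of
#' any guild.
#'
#' @return A 6 x 11 matrix (structures x guilds).
#' @export
default_structure_archetypes <- function() {
  g <- guild_codes()
  m <- rbind(
    boreal            = c(0.3, 5, 1.5, 0.3, 0.3, 2, 8, 0.3, 1.5, 1.5, 4.5),
    temperate         = c(1.5, 12, 4, 2, 1.5, 9, 7, 1.5, 1, 3, 4.5),
    semiarid          = c(7, 14, 8, 2.5, 1, 8, 20, 17, 0.5, 4, 6),
    seasonal_tropical = c(3, 11, 17, 7, 3, 4, 8, 6, 1, 13, 4),
    humid_tropical    = c(3, 5, 14, 20, 9, 1, 5, 0.5, 1.5, 13, 3.5),
    depauperate       = c(0.1, 0.4, 0.2, 0.1, 0.1, 0.1, 0.8, 0.1, 0.1, 0.2, 0.2))
  colnames(m) <- g
  m[structure_names(), ]
}

#' Default human-impact degradation parameters
#'
#' Thresholds at which the generator degrades a cell's observed structure:
#' cold-climate structures (boreal, temperate) collapse to depauperate where
#' urban cover is at least 5%, cropland at least 54%, or primary vegetation
#' below 1%; tropical structures (seasonal, humid) shift to semiarid where
#' population density exceeds 3.6 inhabitants per km2.  Islands are always
#' observed as depauperate.
#'
#' @return Named list of thresholds.
#' @export
default_impact_params <- function() {
  list(urban_min = 5, cropland_min = 54, primary_max = 1, pop_min = 3.6)
}

## per-leaf sampling boxes for the planted climate tree; constraints along
## the root-to-leaf path, other rule variables free within global ranges
.climate_ranges <- function() {
  list(bio1 = c(-15, 30), bio3 = c(5, 70), bio4 = c(1, 30),
       bio5 = c(-5, 40), bio12 = c(0, 3000))
}

.leaf_constraints <- function(rules) {
  out <- list()
  walk <- function(node, lo, hi) {
    if (node$leaf) {
      out[[length(out) + 1L]] <<- list(label = node$label, lo = lo, hi = hi)
      return(invisible())
    }
    v <- rules$var_names[node$var]
    hil <- hi; hil[v] <- min(hi[v], node$thr)
    lor <- lo; lor[v] <- max(lo[v], node$thr)
    walk(node$left, lo, hil)
    walk(node$right, lor, hi)
  }
  rng <- .climate_ranges()
  lo <- vapply(rng, `[`, numeric(1), 1L)
  hi <- vapply(rng, `[`, numeric(1), 2L)
  walk(rules$root, lo, hi)
  out
}

#' Synthetic gridded world
#'
#' Generates a 1-degree-style grid of cells with a 19-variable bioclim-like
#' climate vector, a true structure label given by the planted climate
#' rules, per-guild species counts drawn around the observed structure's
#' archetype profile, land-use and population indicators, and island flags.
#' Climate sampling is stratified over the leaves of the rule tree so every
#' structure is represented; leaf weights echo the relative prevalence of
#' structures at the global scale (boreal and temperate widespread, semiarid
#' rarest).  The observed label equals the true label except where the
#' degradation rules of `impact_params` fire or the cell is an island (see
#' [default_impact_params()]); guild counts are drawn around the *observed*
#' structure, since human impact degrades the community itself.
#'
#' @param n_cells Number of grid cells.
#' @param rules Planted climate rule tree ([default_climate_rules()]).
#' @param structure_archetypes Structure x guild matrix of mean counts.
#' @param impact_params Degradation thresholds ([default_impact_params()]).
#' @param island_fraction Fraction of cells flagged as islands.
#' @param overdispersion Size parameter of a negative-binomial alternative to
#'   Poisson counts; `Inf` (default) gives pure Poisson noise.
#' @param seed Integer seed.
#' @return Object of class `synthetic_world`: `cells` (data frame with cell
#'   id, lat, lon, bio1..bio19, land use, population, island, true and
#'   observed labels, and the degradation cause), `counts` (cells x guilds
#'   integer matrix), plus the generating `rules`, `archetypes`, parameters
#'   and `seed`.
#' @export
generate_world <- function(n_cells = 3000L, rules = default_climate_rules(),
                           structure_archetypes = default_structure_archetypes(),
                           impact_params = default_impact_params(),
                           island_fraction = 0.08,
                           overdispersion = Inf, seed = 1L) {
  leaves <- .leaf_constraints(rules)
  labels_avail <- unique(vapply(leaves, `[[`, character(1), "label"))
  missing_arch <- setdiff(labels_avail, rownames(structure_archetypes))
  if (length(missing_arch))
    stop("structure archetypes missing for rule outcome(s): ",
         paste(missing_arch, collapse = ", "), call. = FALSE)
  set.seed(seed)

  ## leaf weights: cold branch (depauperate, boreal x2, temperate) dominant,
  ## tropical leaves smaller, semiarid smallest - echoing global prevalence
  w <- rep_len(c(0.20, 0.12, 0.12, 0.26, 0.06, 0.06, 0.09, 0.06, 0.03),
               length(leaves))
  w <- w / sum(w)
  n_leaf <- floor(w * n_cells)
  rem <- n_cells - sum(n_leaf)
  if (rem > 0) n_leaf[seq_len(rem)] <- n_leaf[seq_len(rem)] + 1L
  leaf_of_cell <- rep(seq_along(leaves), n_leaf)

  rule_vars <- names(.climate_ranges())
  clim <- matrix(NA_real_, n_cells, 19L, dimnames = list(NULL, paste0("bio", 1:19)))
  for (i in seq_along(leaves)) {
    idx <- which(leaf_of_cell == i)
    for (v in rule_vars) {
      lo <- leaves[[i]]$lo[v]; hi <- leaves[[i]]$hi[v]
      clim[idx, v] <- stats::runif(length(idx), lo, hi)
    }
  }
  ## remaining 14 bioclim-style columns: correlated noise on the drivers
  noise_cols <- setdiff(colnames(clim), rule_vars)
  for (j in seq_along(noise_cols)) {
    a <- stats::runif(1, -1, 1); b <- stats::runif(1, -1, 1)
    clim[, noise_cols[j]] <- a * clim[, "bio1"] + b * clim[, "bio12"] / 100 +
      stats::rnorm(n_cells, 0, 3)
  }

  true_label <- predict(rules, as.data.frame(clim))

  ## human-impact indicators: a low-impact and a high-impact regime
  high <- stats::runif(n_cells) < 0.45
  primary <- ifelse(high, stats::runif(n_cells, 0, 40),
                    stats::runif(n_cells, 25, 95))
  urban <- ifelse(high, stats::rexp(n_cells, 1 / 4),
                  stats::runif(n_cells, 0, 0.002))
  cropland <- ifelse(high, stats::runif(n_cells, 0, 80),
                     stats::runif(n_cells, 0, 15))
  pop <- ifelse(high, stats::rexp(n_cells, 1 / 15),
                stats::rexp(n_cells, 1 / 1.5))
  pasture <- stats::runif(n_cells, 0, pmax(1, 100 - primary - cropland))
  secondary <- pmax(0, 100 - primary - cropland - pasture -
                      stats::runif(n_cells, 0, 10))
  urban <- pmin(urban, 100)
  island <- stats::runif(n_cells) < island_fraction

  cold <- c("boreal", "temperate")
  tropical <- c("seasonal_tropical", "humid_tropical")
  cause <- rep("none", n_cells)
  cause[true_label %in% cold &
          (urban >= impact_params$urban_min |
             cropland >= impact_params$cropland_min |
             primary < impact_params$primary_max)] <- "land_use"
  cause[true_label %in% tropical & pop > impact_params$pop_min] <- "population"
  cause[island] <- "island"
  observed <- true_label
  observed[cause == "land_use"] <- "depauperate"
  observed[cause == "population"] <- "semiarid"
  observed[cause == "island"] <- "depauperate"

  lam <- structure_archetypes[observed, , drop = FALSE]
  counts <- if (is.finite(overdispersion)) {
    matrix(stats::rnbinom(length(lam), size = overdispersion, mu = lam),
           nrow(lam), ncol(lam))
  } else {
    matrix(stats::rpois(length(lam), lam), nrow(lam), ncol(lam))
  }
  colnames(counts) <- colnames(structure_archetypes)
  cell_id <- sprintf("cell%05d", seq_len(n_cells))
  rownames(counts) <- cell_id

  cells <- data.frame(
    cell = cell_id,
    lat = pmin(80, pmax(-60, 62 - 2.4 * clim[, "bio1"] +
                          stats::rnorm(n_cells, 0, 6))),
    lon = stats::runif(n_cells, -180, 180),
    clim,
    cropland = cropland, pasture = pasture, primary = primary,
    secondary = secondary, urban = urban, pop_density = pop,
    island = island, true_label = true_label, observed_label = observed,
    degradation = cause, stringsAsFactors = FALSE)

  structure(list(cells = cells, counts = counts, rules = rules,
                 archetypes = structure_archetypes,
                 impact_params = impact_params,
                 island_fraction = island_fraction, seed = seed),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("synthetic world: %d cells, %d guilds (seed %d)\n",
              nrow(x$cells), ncol(x$counts), x$seed))
  print(table(observed = x$cells$observed_label))
  invisible(x)
}

#' Synthetic species presence grid consistent with a world's guild counts
#'
#' Given per-species guild labels (e.g. from [generate_diet_matrix()]),
#' draws for each cell and guild the required number of species at random
#' from that guild's species pool, producing a cell x species binary
#' presence matrix whose per-guild counts reproduce the world's count matrix
#' (capped at the pool size of each guild).
#'
#' @param world A `synthetic_world`.
#' @param species_guilds Named character vector: guild code per species id.
#' @param seed Integer seed.
#' @return Binary matrix, cells as rows, species as columns.
#' @export
generate_presence_grid <- function(world, species_guilds, seed = 1L) {
  stopifnot(inherits(world, "synthetic_world"))
  set.seed(seed)
  guilds <- colnames(world$counts)
  pools <- split(names(species_guilds), factor(species_guilds, levels = guilds))
  pres <- matrix(0L, nrow(world$counts), length(species_guilds),
                 dimnames = list(rownames(world$counts), names(species_guilds)))
  for (g in guilds) {
    pool <- pools[[g]]
    if (!length(pool)) next
    k <- pmin(world$counts[, g], length(pool))
    for (i in which(k > 0L))
      pres[i, sample(pool, k[i])] <- 1L
  }
  pres
}

#' Serialise a synthetic world to CSV plus a YAML manifest
#'
#' Writes the cell table and the guild-count table as CSV and the generation
#' parameters (seed, island fraction, impact thresholds) as a YAML manifest.
#'
#' @param world A `synthetic_world`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_world"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(cells = file.path(dir, "cells.csv"),
             counts = file.path(dir, "guild_counts.csv"),
             manifest = file.path(dir, "world.yml"))
  utils::write.csv(world$cells, paths["cells"], row.names = FALSE)
  utils::write.csv(data.frame(cell = rownames(world$counts), world$counts,
                              check.names = FALSE),
                   paths["counts"], row.names = FALSE)
  yaml::write_yaml(list(seed = world$seed,
                        island_fraction = world$island_fraction,
                        impact_params = world$impact_params,
                        n_cells = nrow(world$cells)),
                   paths["manifest"])
  invisible(paths)
}
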