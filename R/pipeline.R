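## One-command end-to-end run on synthetic data, plus the artificial-sample
## validation of the AMD cluster-count statistic.

#' Default pipeline configuration
#'
#' All stage parameters of the end-to-end synthetic run in one list.  A
#' single global seed fans out to fixed per-stage offsets so that every
#' stage is independently reproducible.
#'
#' @param seed Global integer seed.
#' @param n_cells Number of synthetic grid cells.
#' @param n_species Number of synthetic species.
#' @param diet_noise_sd Diet noise, percentage points.
#' @param n_guilds Number of guilds fitted (`"auto"` scans with AMD).
#' @param guild_replicates,structure_replicates Random restarts for the two
#'   clustering stages.
#' @param structure_c Number of structures (`"auto"` scans with AMD).
#' @param tree_config [evolution_config()] for the climate tree.
#' @param impact_tree_config [evolution_config()] for the impact trees.
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_cells = 3000L, n_species = 330L,
                            diet_noise_sd = 5, n_guilds = 11L,
                            guild_replicates = 50L,
                            structure_replicates = 50L,
                            structure_c = "auto",
                            tree_config = evolution_config(
                              population = 200L, generations = 300L,
                              patience = 60L, restarts = 2L,
                              seed = seed + 400L),
                            impact_tree_config = evolution_config(
                              population = 150L, generations = 200L,
                              patience = 50L, max_depth = 3L,
                              seed = seed + 500L),
                            out_dir = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full synthetic pipeline
#'
#' Executes, in order: world and diet simulation, guild inference and
#' naming, presence-grid synthesis and trophic-space construction,
#' low-impact filtering, structure classification (AMD scan) and naming,
#' random-forest interpolation, climate-tree fitting on mainland low-impact
#' cells, prediction of the climatic expectation for every cell, transition
#' mapping, kappa agreement, impact t tests and impact trees, and the
#' per-structure energy networks.  When `config$out_dir` is set, stage
#' outputs are written as CSV/JSON and a manifest with parameters, seeds,
#' timings and md5 checksums is saved.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result` with all stage outputs and the
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config"))
    stop("'config' must be a pipeline_config", call. = FALSE)
  t_start <- Sys.time()
  manifest <- list(seed = config$seed, stages = list())
  tick <- function(stage, t0, ...) {
    manifest$stages[[stage]] <<- c(
      list(seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 2)),
      list(...))
  }

  ## 1. simulate
  t0 <- Sys.time()
  world <- generate_world(n_cells = config$n_cells, seed = config$seed + 100L)
  diets <- generate_diet_matrix(config$n_species,
                                noise_sd = config$diet_noise_sd,
                                seed = config$seed + 200L)
  tick("simulate", t0, n_cells = config$n_cells,
       n_species = config$n_species)

  ## 2. guilds
  t0 <- Sys.time()
  if (identical(config$n_guilds, "auto")) {
    scan <- select_n_guilds(diets$diet, replicates = config$guild_replicates,
                            seed = config$seed + 300L)
    k <- scan$selected_c
  } else k <- config$n_guilds
  guilds <- infer_guilds(diets$diet, n_guilds = k,
                         replicates = config$guild_replicates,
                         seed = config$seed + 300L)
  guilds <- name_guilds(guilds)
  tick("guilds", t0, n_guilds = k)

  ## 3. trophic space from synthesised presences
  t0 <- Sys.time()
  presences <- generate_presence_grid(world, diets$guild,
                                      seed = config$seed + 350L)
  space <- build_trophic_space(presences, guilds)
  tick("trophic_space", t0)

  ## 4. classify low-impact cells, interpolate the rest
  t0 <- Sys.time()
  low <- filter_low_impact(world$cells, quiet = TRUE)
  classification <- classify_structures(space, cells = low,
                                        c = config$structure_c,
                                        replicates = config$structure_replicates,
                                        seed = config$seed + 360L)
  classification <- name_structures(classification)
  classification <- interpolate_structures(space, classification,
                                           seed = config$seed + 370L)
  tick("structures", t0,
       selected_c = length(classification$labels),
       oob_accuracy = attr(classification, "oob_accuracy"))

  ## 5. richness decomposition
  pca <- richness_decomposition(space, cells = low)

  ## 6. climate tree on mainland low-impact cells
  t0 <- Sys.time()
  mainland <- setdiff(low, world$cells$cell[world$cells$island])
  i <- match(mainland, classification$cells$cell)
  features <- world$cells[match(mainland, world$cells$cell),
                          paste0("bio", 1:19), drop = FALSE]
  climate_tree <- evolve_tree(features, classification$cells$label[i],
                              config$tree_config)
  predicted <- predict(climate_tree,
                       world$cells[, paste0("bio", 1:19), drop = FALSE])
  names(predicted) <- world$cells$cell
  tick("climate_tree", t0, misclass = climate_tree$misclass,
       n_leaves = climate_tree$n_leaves)

  ## 7. transitions
  t0 <- Sys.time()
  ord <- match(world$cells$cell, classification$cells$cell)
  observed <- classification$cells[ord, ]
  tmap <- compare_structures(observed, unname(predicted[observed$cell]),
                             island = world$cells$island)
  kappa <- kappa_agreement(tmap$observed, tmap$predicted)
  ## a small world may lack cells of a disagreement type; report NULL then
  safely <- function(expr) tryCatch(expr, error = function(e) {
    message("transition analysis skipped: ", conditionMessage(e))
    NULL
  })
  ttests <- list(typeI = safely(impact_ttests(tmap, world$cells, "typeI")),
                 typeII = safely(impact_ttests(tmap, world$cells, "typeII")))
  itrees <- list(
    typeI = safely(impact_tree(tmap, world$cells, "typeI",
                               config = config$impact_tree_config)),
    typeII = safely(impact_tree(tmap, world$cells, "typeII",
                                config = config$impact_tree_config)))
  tick("transitions", t0, kappa = kappa$kappa)

  ## 8. per-structure energy networks
  t0 <- Sys.time()
  networks <- lapply(stats::setNames(nm = classification$labels), function(s)
    tryCatch(structure_network(classification, s, presences, diets$diet,
                               guilds),
             error = function(e) NULL))
  tick("networks", t0)

  manifest$total_seconds <- round(as.numeric(Sys.time() - t_start,
                                             units = "secs"), 2)
  result <- list(world = world, diets = diets, guilds = guilds,
                 space = space, low_impact = low,
                 classification = classification, pca = pca,
                 climate_tree = climate_tree, predicted = predicted,
                 transitions = tmap, kappa = kappa, ttests = ttests,
                 impact_trees = itrees, networks = networks,
                 manifest = manifest, config = config)
  class(result) <- "pipeline_result"

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(
      write_world(world, file.path(config$out_dir, "world")),
      guilds = {
        p <- file.path(config$out_dir, "guild_assignment.csv")
        write_guild_assignment(guilds, p); p
      },
      classification = {
        p <- file.path(config$out_dir, "classification.csv")
        write_classification(classification, p, world$cells); p
      },
      tree = {
        p <- file.path(config$out_dir, "climate_tree.json")
        write_tree_model(climate_tree, p); p
      },
      transitions = {
        p <- file.path(config$out_dir, "transitions.csv")
        utils::write.csv(as.data.frame(unclass(tmap)), p, row.names = FALSE); p
      })
    manifest$checksums <- as.list(tools::md5sum(unname(paths)))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    result$manifest <- manifest
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline run (seed %d): %d cells, %d species\n",
              x$config$seed, nrow(x$world$cells), x$config$n_species))
  cat(sprintf("structures detected: %d; climate-tree misclassification %.3f; kappa %.3f\n",
              length(x$classification$labels), x$climate_tree$misclass,
              x$kappa$kappa))
  invisible(x)
}

#' Validate the AMD cluster-count statistic on artificial samples
#'
#' Reproduces the computer-generated benchmark of the AMD approach: (i)
#' uniform-random samples, where AMD stays near 0 at every candidate cluster
#' number; (ii) planted Gaussian clusters at two noise levels, where the AMD
#' curve peaks at the planted cluster number and the peak height falls as
#' the clusters blur.
#'
#' @param n,d,k Benchmark size: samples, dimensions, planted clusters.
#' @param sds Noise levels of the planted-cluster runs.
#' @param c_min,c_max Scan range.
#' @param replicates Random restarts per candidate cluster number.
#' @param seed Integer seed.
#' @return List of class `amd_benchmark_report`: `random_curve`, one
#'   `curve` per sd with its `peak_c` and `peak_amd`.
#' @export
validate_amd_benchmark <- function(n = 8000L, d = 11L, k = 6L,
                                   sds = c(1, 1.7), c_min = 2L, c_max = 10L,
                                   replicates = 200L, seed = 1L) {
  rnd <- generate_random_samples(n, d, seed = seed)
  random_scan <- amd_scan(rnd, c_min, c_max, replicates = replicates,
                          seed = seed)
  runs <- lapply(sds, function(s) {
    b <- generate_cluster_benchmark(n, d, k, sd = s, seed = seed)
    sc <- amd_scan(b$samples, c_min, c_max, replicates = replicates,
                   seed = seed)
    list(sd = s, curve = sc$curve, peak_c = sc$selected_c,
         peak_amd = max(sc$curve$best_amd))
  })
  names(runs) <- paste0("sd_", sds)
  structure(list(random_curve = random_scan$curve,
                 random_max_amd = max(random_scan$curve$best_amd),
                 planted = runs, k = k, n = n, d = d),
            class = "amd_benchmark_report")
}

#' @export
print.amd_benchmark_report <- function(x, ...) {
  cat(sprintf("AMD benchmark (n = %d, d = %d, %d planted clusters)\n",
              x$n, x$d, x$k))
  cat(sprintf("uniform-random max AMD over scan: %.4f\n", x$random_max_amd))
  for (r in x$planted)
    cat(sprintf("sd %.1f: peak at c = %d, AMD = %.3f\n", r$sd, r$peak_c,
                r$peak_amd))
  invisible(x)
}
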