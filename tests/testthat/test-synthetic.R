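test_that("cluster benchmark has the documented shape and balanced labels", {
  b <- generate_cluster_benchmark(n = 8000, d = 11, k = 6, sd = 1, seed = 1)
  expect_equal(dim(b$samples), c(8000, 11))
  expect_true(all(table(b$true_labels) %in% c(1333, 1334)))
  expect_error(generate_cluster_benchmark(sd = -1), "sd")
})

test_that("zero noise collapses samples onto their centres", {
  b <- generate_cluster_benchmark(n = 60, d = 3, k = 4, sd = 0, seed = 2)
  expect_equal(unname(b$samples), unname(b$centres[b$true_labels, ]))
})

test_that("per-cluster sample moments match the nominal sd", {
  b <- generate_cluster_benchmark(n = 6000, d = 4, k = 3, sd = 2, seed = 3)
  for (k in 1:3) {
    s <- apply(b$samples[b$true_labels == k, ], 2, sd)
    expect_true(all(abs(s - 2) / 2 < 0.05))
  }
})

test_that("random samples are uniform on [0,10]^d", {
  x <- generate_random_samples(8000, 11, seed = 4)
  expect_true(all(abs(colMeans(x) - 5) < 0.1))
  expect_equal(dim(generate_random_samples(1, 3, seed = 1)), c(1, 3))
})

test_that("diet matrices are archetypal at zero noise and always sum to 100", {
  arch <- default_guild_archetypes()
  g0 <- generate_diet_matrix(22, noise_sd = 0, seed = 1)
  expect_equal(unname(g0$diet), unname(arch[g0$guild, ]))
  # a piscivore eats only fish
  expect_equal(unname(g0$diet[g0$guild == "PS", "fs"]), rep(100, 2))
  g <- generate_diet_matrix(200, noise_sd = 8, seed = 2)
  expect_equal(unname(rowSums(g$diet)), rep(100, 200), tolerance = 1e-6)
  expect_true(all(g$diet >= 0))
})

test_that("planted guilds are recoverable from noisy diets", {
  g <- generate_diet_matrix(689, noise_sd = 5, seed = 5)
  ga <- infer_guilds(g$diet, n_guilds = 11, replicates = 10, seed = 1)
  expect_gte(adjusted_rand(ga$guild, g$guild), 0.9)
})

test_that("climate rules route canonical cells to the expected structures", {
  rules <- default_climate_rules()
  cells <- data.frame(matrix(0, 3, 19, dimnames = list(NULL, paste0("bio", 1:19))))
  # hot and wet with low seasonality -> humid tropical
  cells[1, c("bio1", "bio12", "bio4")] <- c(25, 2000, 5)
  # hot desert -> depauperate
  cells[2, c("bio1", "bio12")] <- c(25, 100)
  # near-arctic: cold, low max summer temperature, high isothermality
  cells[3, c("bio1", "bio5", "bio3")] <- c(-5, 5, 30)
  expect_equal(predict(rules, cells),
               c("humid_tropical", "depauperate", "depauperate"))
})

test_that("generated worlds are deterministic and internally consistent", {
  w1 <- generate_world(n_cells = 600, seed = 7)
  w2 <- generate_world(n_cells = 600, seed = 7)
  expect_identical(w1$cells, w2$cells)
  expect_identical(w1$counts, w2$counts)
  # true labels derive exactly from the planted rules
  expect_equal(w1$cells$true_label,
               predict(w1$rules, w1$cells[, paste0("bio", 1:19)]))
  # observed label differs from true only where a degradation cause fired
  agree <- w1$cells$observed_label == w1$cells$true_label
  fired <- w1$cells$degradation != "none"
  expect_true(all(agree[!fired]))
  # islands always observed depauperate
  expect_true(all(w1$cells$observed_label[w1$cells$island] == "depauperate"))
  # land-use percentages and counts in range
  for (v in c("cropland", "pasture", "primary", "secondary", "urban"))
    expect_true(all(w1$cells[[v]] >= 0 & w1$cells[[v]] <= 100))
  expect_true(all(w1$counts >= 0))
})

test_that("every climate-rule leaf is populated at moderate world sizes", {
  w <- generate_world(n_cells = 50 * 9, seed = 8)
  expect_setequal(unique(w$cells$true_label), structure_names())
})

test_that("degradation follows the planted impact thresholds", {
  w <- small_world()
  p <- w$impact_params
  cold <- w$cells$true_label %in% c("boreal", "temperate") & !w$cells$island
  hit <- w$cells$urban >= p$urban_min | w$cells$cropland >= p$cropland_min |
    w$cells$primary < p$primary_max
  expect_true(all(w$cells$observed_label[cold & hit] == "depauperate"))
  expect_true(all(w$cells$observed_label[cold & !hit] ==
                    w$cells$true_label[cold & !hit]))
  trop <- w$cells$true_label %in% c("seasonal_tropical", "humid_tropical") &
    !w$cells$island
  busy <- w$cells$pop_density > p$pop_min
  expect_true(all(w$cells$observed_label[trop & busy] == "semiarid"))
})

test_that("structure archetypes are separated well beyond Poisson noise", {
  a <- default_structure_archetypes()
  d <- as.matrix(dist(a))
  mean_between <- mean(d[upper.tri(d)])
  mean_within_sd <- mean(sqrt(a))
  expect_gt(mean_between, 3 * mean_within_sd)
})

test_that("presence grids reproduce the world's guild counts", {
  w <- generate_world(n_cells = 150, seed = 10)
  diets <- generate_diet_matrix(330, noise_sd = 0, seed = 1)
  pres <- generate_presence_grid(w, diets$guild, seed = 2)
  space <- build_trophic_space(pres, diets$guild)
  # counts match up to the per-guild pool size cap
  pool <- table(factor(diets$guild, colnames(w$counts)))
  capped <- pmin(w$counts, matrix(as.integer(pool), nrow(w$counts),
                                  ncol(w$counts), byrow = TRUE))
  expect_equal(unname(space$counts[, colnames(w$counts)]), unname(capped))
})

test_that("world serialisation writes cells, counts and manifest", {
  w <- generate_world(n_cells = 80, seed = 3)
  dir <- withr::local_tempdir()
  paths <- write_world(w, dir)
  expect_true(all(file.exists(paths)))
  back <- read.csv(paths["cells"])
  expect_equal(nrow(back), 80)
  man <- yaml::read_yaml(paths["manifest"])
  expect_equal(man$seed, 3)
})
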