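test_that("trophic space counts species per guild and conserves richness", {
  grid <- rbind(cell1 = c(A = 1, B = 1, C = 1), cell2 = c(0, 0, 0))
  labels <- c(A = "OM", B = "OM", C = "LC")
  sp <- build_trophic_space(grid, labels)
  expect_equal(sp$counts["cell1", c("OM", "LC")], c(OM = 2L, LC = 1L))
  expect_equal(unname(sp$counts["cell2", ]), c(0L, 0L))
  expect_equal(sp$richness, rowSums(sp$counts))
  # long format agrees with the matrix route
  long <- data.frame(cell = c("cell1", "cell1", "cell1"),
                     species = c("A", "B", "C"))
  sp2 <- build_trophic_space(long, labels)
  expect_equal(sp2$counts["cell1", ], sp$counts["cell1", ])
  expect_error(build_trophic_space(grid, c(A = "OM")), "without guild")
})

test_that("low-impact filter applies all three criteria and is idempotent", {
  imp <- data.frame(
    cell = paste0("c", 1:4),
    primary = c(20, 30, 30, 30),    # c1 fails primary
    urban = c(0.001, 0.01, 0.001, 0.001),  # c2 fails urban
    pop_density = c(10, 10, 30, 10))       # c3 fails population
  kept <- suppressMessages(filter_low_impact(imp))
  expect_equal(as.character(kept), "c4")
  expect_equal(attr(kept, "exclusions"),
               c(primary = 1L, urban = 1L, population = 1L))
  # idempotent and order-independent
  again <- suppressMessages(filter_low_impact(imp, cells = kept))
  expect_equal(as.character(again), as.character(kept))
  shuffled <- suppressMessages(filter_low_impact(imp[c(3, 1, 4, 2), ]))
  expect_setequal(as.character(shuffled), as.character(kept))
  expect_error(suppressMessages(filter_low_impact(imp, cells = "zz")),
               "no impact record")
  # boundary: the documented default retains primary 30 / urban 0.001 / pop 10
  expect_true("c4" %in% kept)
})

test_that("structure classification recovers the planted clusters", {
  w <- small_world()
  sp <- structure(list(counts = w$counts, richness = rowSums(w$counts),
                       guild_names = colnames(w$counts)),
                  class = "trophic_space")
  low <- suppressMessages(filter_low_impact(w$cells))
  cl <- classify_structures(sp, cells = low, c = "auto", replicates = 20,
                            seed = 1)
  expect_equal(length(cl$labels), 6)
  cl <- name_structures(cl)
  truth <- w$cells$observed_label[match(cl$cells$cell, w$cells$cell)]
  expect_gte(adjusted_rand(cl$cells$label, truth), 0.9)
  # named labels agree with the planted vocabulary
  expect_true(all(cl$cells$label %in% structure_names()))
  expect_true(all(cl$cells$membership > 0 & cl$cells$membership <= 1))
})

test_that("identical cells collapse to a single structure with membership 1", {
  counts <- matrix(3L, 10, 4, dimnames = list(paste0("c", 1:10), NULL))
  cl <- classify_structures(counts, c = 1, replicates = 2, seed = 1)
  expect_equal(unique(cl$cells$label), "S1")
  expect_equal(cl$cells$membership, rep(1, 10))
})

test_that("random-forest interpolation reproduces held-out labels", {
  w <- small_world()
  sp <- structure(list(counts = w$counts, richness = rowSums(w$counts),
                       guild_names = colnames(w$counts)),
                  class = "trophic_space")
  # train on a planted-label subset, predict a held-out subset
  set.seed(2)
  idx <- sample(nrow(w$cells))
  train <- idx[1:800]; test <- idx[801:1000]
  labelled <- structure(list(
    cells = data.frame(cell = w$cells$cell[train],
                       label = w$cells$observed_label[train],
                       membership = 1, provenance = "clustered",
                       stringsAsFactors = FALSE),
    centres = w$archetypes, labels = structure_names(), scan = NULL),
    class = "structure_classification")
  out <- interpolate_structures(sp, labelled, cells = w$cells$cell[test],
                                seed = 3)
  pred <- out$cells[out$cells$provenance == "interpolated", ]
  truth <- w$cells$observed_label[match(pred$cell, w$cells$cell)]
  expect_gte(mean(pred$label == truth), 0.95)
  expect_true(all(pred$membership > 0 & pred$membership <= 1))
  # a cell sitting exactly on an archetype profile gets that structure
  arch_cells <- round(w$archetypes)
  rownames(arch_cells) <- paste0("arch_", rownames(arch_cells))
  sp2 <- rbind(w$counts, arch_cells)
  out2 <- interpolate_structures(sp2, labelled, cells = rownames(arch_cells),
                                 seed = 3)
  pred2 <- out2$cells[match(rownames(arch_cells), out2$cells$cell), ]
  expect_equal(unname(pred2$label), rownames(w$archetypes))
})

test_that("single-class training predicts that class with a warning", {
  counts <- matrix(rpois(60, 4), 15, 4,
                   dimnames = list(paste0("c", 1:15), NULL))
  labelled <- structure(list(
    cells = data.frame(cell = paste0("c", 1:10), label = "boreal",
                       membership = 1, provenance = "clustered",
                       stringsAsFactors = FALSE)),
    class = "structure_classification")
  expect_warning(out <- interpolate_structures(counts, labelled), "single")
  pred <- out$cells[out$cells$provenance == "interpolated", ]
  expect_true(all(pred$label == "boreal"))
})

test_that("richness decomposition matches an eigendecomposition oracle", {
  set.seed(6)
  m <- matrix(rpois(1100, 6), 100, 11,
              dimnames = list(paste0("c", 1:100), NULL))
  rd <- richness_decomposition(m)
  expect_equal(sum(rd$variance_share), 1)
  ev <- eigen(cov(m))$values
  expect_equal(rd$variance_share, ev / sum(ev), tolerance = 1e-8)
  # rank-1 matrix: first axis carries everything, scores track richness
  base <- c(4, 2, 1, 0, 0)
  r1 <- outer(c(1, 2, 3, 5, 8), base)
  rownames(r1) <- paste0("c", 1:5)
  rd1 <- richness_decomposition(r1)
  expect_equal(rd1$variance_share[1], 1)
  expect_equal(rd1$r2_richness, 1, tolerance = 1e-10)
  expect_error(richness_decomposition(matrix(1, 5, 3)), "constant")
})
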