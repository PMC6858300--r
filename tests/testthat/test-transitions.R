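obs_df <- function(labels, cells = paste0("c", seq_along(labels)))
  data.frame(cell = cells, label = labels, stringsAsFactors = FALSE)

test_that("disagreements are typed by the I / II / island taxonomy", {
  obs <- obs_df(c("depauperate", "semiarid", "boreal", "depauperate",
                  "temperate", "humid_tropical"))
  pred <- c("temperate", "seasonal_tropical", "boreal", "boreal",
            "humid_tropical", "semiarid")
  island <- c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE)
  tm <- compare_structures(obs, pred, island)
  expect_equal(tm$type,
               c("typeI", "typeII", "none", "island", "other", "other"))
  # partition property: every cell has exactly one type
  expect_equal(sum(table(tm$type)), nrow(tm))
  expect_error(compare_structures(obs, rep("alpine", 6)), "vocabulary")
  expect_error(compare_structures(obs, pred[1:3]), "align")
})

test_that("kappa matches the closed-form oracle and its invariants", {
  # 2-class confusion (40, 10; 10, 40): p_o = .8, p_e = .5, kappa = .6
  a <- rep(c("x", "x", "y", "y"), c(40, 10, 10, 40))
  b <- rep(c("x", "y", "x", "y"), c(40, 10, 10, 40))
  rep_ <- kappa_agreement(a, b)
  expect_equal(rep_$p_o, 0.8)
  expect_equal(rep_$p_e, 0.5)
  expect_equal(rep_$kappa, 0.6)
  # identity and symmetry
  expect_equal(kappa_agreement(a, a)$kappa, 1)
  expect_equal(kappa_agreement(b, a)$kappa, rep_$kappa)
  # confusion margins reproduce label frequencies
  expect_equal(as.numeric(rowSums(rep_$confusion)), as.numeric(table(a)))
  expect_equal(as.numeric(colSums(rep_$confusion)), as.numeric(table(b)))
  # independent labels sit near zero
  set.seed(1)
  r1 <- sample(letters[1:4], 1e4, TRUE)
  r2 <- sample(letters[1:4], 1e4, TRUE)
  expect_lt(abs(kappa_agreement(r1, r2)$kappa), 0.03)
  expect_error(kappa_agreement(character(0), character(0)), "empty|equal")
})

test_that("kappa accepts a vocabulary alignment map", {
  a <- c("boreal", "temperate", "boreal")
  biome <- c("taiga", "deciduous", "taiga")
  align <- c(taiga = "boreal", deciduous = "temperate")
  expect_equal(kappa_agreement(a, biome, alignment = align)$kappa, 1)
})

make_tmap <- function(n_changed, n_unchanged, type = "typeI", seed = 1) {
  set.seed(seed)
  pred_ch <- if (type == "typeI") "temperate" else "seasonal_tropical"
  obs_ch <- if (type == "typeI") "depauperate" else "semiarid"
  cells <- paste0("c", seq_len(n_changed + n_unchanged))
  tm <- data.frame(
    cell = cells,
    observed = c(rep(obs_ch, n_changed), rep(pred_ch, n_unchanged)),
    predicted = pred_ch, island = FALSE,
    type = c(rep(type, n_changed), rep("none", n_unchanged)),
    stringsAsFactors = FALSE)
  class(tm) <- c("transition_map", "data.frame")
  tm
}

test_that("impact t tests match the closed-form two-sample formula", {
  tm <- make_tmap(4, 4)
  jit <- c(1e-6, -1e-6, 2e-6, -2e-6)
  imp <- data.frame(cell = tm$cell,
                    cropland = c(1 + jit, 0 + jit),
                    pasture = rep(5, 8), primary = rep(10, 8),
                    secondary = rep(1, 8), urban = rep(0.1, 8),
                    pop_density = rep(2, 8))
  res <- impact_ttests(tm, imp, "typeI")
  row <- res[res$indicator == "cropland", ]
  x <- imp$cropland[1:4]; y <- imp$cropland[5:8]
  sp <- sqrt(((3 * var(x) + 3 * var(y)) / 6) * (1 / 4 + 1 / 4))
  expect_equal(row$t, (mean(x) - mean(y)) / sp, tolerance = 1e-6)
  # identical groups: t = 0, p = 1
  row2 <- res[res$indicator == "pasture", ]
  expect_equal(row2$t, 0)
  expect_equal(row2$p, 1)
})

test_that("impact comparisons on the synthetic world point the expected way", {
  w <- small_world()
  pred <- w$cells$true_label
  names(pred) <- w$cells$cell
  obs <- data.frame(cell = w$cells$cell, label = w$cells$observed_label,
                    stringsAsFactors = FALSE)
  tm <- compare_structures(obs, pred, island = w$cells$island)
  resI <- impact_ttests(tm, w$cells, "typeI")
  urban <- resI[resI$indicator == "urban", ]
  expect_gt(urban$mean_changed, urban$mean_unchanged)
  expect_lt(urban$p, 1e-2)
  resII <- impact_ttests(tm, w$cells, "typeII")
  popr <- resII[resII$indicator == "pop_density", ]
  expect_gt(popr$mean_changed, popr$mean_unchanged)
  expect_lt(popr$p, 1e-2)
  # type I cells dominate the planted land-use violation set
  planted <- w$cells$degradation == "land_use"
  expect_gte(mean(tm$type[planted] == "typeI"), 0.95)
})

test_that("impact trees recover the planted degradation thresholds", {
  w <- small_world()
  pred <- w$cells$true_label
  names(pred) <- w$cells$cell
  obs <- data.frame(cell = w$cells$cell, label = w$cells$observed_label,
                    stringsAsFactors = FALSE)
  tm <- compare_structures(obs, pred, island = w$cells$island)
  cfg <- evolution_config(population = 120, generations = 200, patience = 50,
                          max_depth = 3, seed = 2)
  trI <- impact_tree(tm, w$cells, "typeI", config = cfg)
  thI <- extract_thresholds(trI)
  expect_true("urban" %in% thI$variable)
  expect_lt(abs(thI$threshold[thI$variable == "urban"][1] - 5), 1)
  trII <- impact_tree(tm, w$cells, "typeII", config = cfg)
  thII <- extract_thresholds(trII)
  expect_true("pop_density" %in% thII$variable)
  expect_lt(abs(thII$threshold[thII$variable == "pop_density"][1] - 3.6), 0.5)
})

test_that("a transition type with no changed cells yields a single-leaf model", {
  tm <- make_tmap(0, 30, type = "typeII")
  imp <- data.frame(cell = tm$cell, cropland = runif(30), pasture = 1,
                    primary = 50, secondary = 1, urban = 0,
                    pop_density = runif(30))
  m <- impact_tree(tm, imp, "typeII")
  expect_equal(m$n_leaves, 1)
  expect_equal(m$root$label, "unchanged")
})
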