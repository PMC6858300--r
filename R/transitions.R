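## Observed versus climate-predicted structures: disagreement typing,
## Cohen's kappa map agreement, and the human-impact analyses (t tests and
## globally optimised impact trees).

.cold_structures <- function() c("boreal", "temperate")
.tropical_structures <- function() c("seasonal_tropical", "humid_tropical")

#' Compare observed and climate-predicted structures
#'
#' Types every cell's disagreement: `none` where observed equals predicted
#' (mainland), `typeI` for observed depauperate cells whose climatic
#' prediction is boreal or temperate, `typeII` for observed semiarid cells
#' predicted seasonal or humid tropical, `island` for island cells
#' (overriding any other type), and `other` for remaining mismatches.
#'
#' @param observed A `structure_classification`, or a data frame with
#'   columns `cell` and `label`.
#' @param predicted Character vector of climate-predicted labels, aligned
#'   with the observed cells (or named by cell id).
#' @param island Logical vector of island flags, aligned the same way.
#' @return Object of class `transition_map`: data frame with `cell`,
#'   `observed`, `predicted`, `island`, `type`.
#' @export
compare_structures <- function(observed, predicted, island = NULL) {
  obs <- if (inherits(observed, "structure_classification")) observed$cells
         else observed
  stopifnot(all(c("cell", "label") %in% names(obs)))
  if (!is.null(names(predicted))) predicted <- predicted[obs$cell]
  if (length(predicted) != nrow(obs))
    stop("'predicted' must align with the observed cells", call. = FALSE)
  vocab <- structure_names()
  bad <- setdiff(unique(c(obs$label, predicted)), vocab)
  if (length(bad))
    stop("labels outside the structure vocabulary: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (is.null(island)) island <- rep(FALSE, nrow(obs))
  type <- ifelse(obs$label == predicted, "none", "other")
  type[obs$label == "depauperate" & predicted %in% .cold_structures()] <- "typeI"
  type[obs$label == "semiarid" & predicted %in% .tropical_structures()] <- "typeII"
  type[island] <- "island"
  res <- data.frame(cell = obs$cell, observed = obs$label,
                    predicted = predicted, island = island, type = type,
                    stringsAsFactors = FALSE)
  class(res) <- c("transition_map", "data.frame")
  res
}

#' @export
print.transition_map <- function(x, ...) {
  cat(sprintf("transition map: %d cells\n", nrow(x)))
  print(table(type = x$type))
  invisible(x)
}

#' Cohen's kappa agreement between two categorical labelings
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with `p_o`
#' the observed agreement and `p_e` the marginal-product chance agreement.
#' When the two maps use different vocabularies (e.g. trophic structures
#' versus vegetation biomes), supply `alignment` mapping labels of `b` onto
#' labels of `a` before comparison.
#'
#' @param a,b Equal-length label vectors.
#' @param alignment Optional named character vector translating `b` labels.
#' @return Object of class `agreement_report`: `kappa`, `p_o`, `p_e`,
#'   `confusion` (contingency table of a x b).
#' @export
kappa_agreement <- function(a, b, alignment = NULL) {
  if (!length(a) || length(a) != length(b))
    stop("'a' and 'b' must be non-empty and of equal length", call. = FALSE)
  a <- as.character(a); b <- as.character(b)
  if (!is.null(alignment)) b <- unname(alignment[b])
  lev <- sort(unique(c(a, b)))
  confusion <- table(factor(a, lev), factor(b, lev))
  n <- length(a)
  p_o <- sum(diag(confusion)) / n
  p_e <- sum(rowSums(confusion) * colSums(confusion)) / n^2
  kappa <- if (p_e == 1) 1 else (p_o - p_e) / (1 - p_e)
  structure(list(kappa = kappa, p_o = p_o, p_e = p_e, confusion = confusion,
                 n = n),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.3f (p_o = %.3f, p_e = %.3f, n = %d)\n",
              x$kappa, x$p_o, x$p_e, x$n))
  invisible(x)
}

## changed / unchanged cell sets for one disagreement type: the comparison
## group are the agreeing cells of the same climatic super-group
.transition_groups <- function(tmap, type = c("typeI", "typeII")) {
  type <- match.arg(type)
  supergroup <- if (type == "typeI") .cold_structures()
                else c("semiarid", .tropical_structures())
  changed <- tmap$cell[tmap$type == type]
  unchanged <- tmap$cell[tmap$type == "none" & tmap$predicted %in% supergroup]
  list(changed = changed, unchanged = unchanged)
}

#' Compare human-impact indicators in changed versus unchanged cells
#'
#' For one disagreement type, compares each impact indicator between changed
#' cells (cells of that type) and unchanged cells (matching cells of the
#' same climatic super-group: cold structures for type I, warm for type II)
#' with a two-sided two-sample t test.  The classical equal-variance
#' Student's t is the default; set `welch = TRUE` for the unequal-variance
#' variant.  P values are reported raw, without multiple-testing correction
#' across indicators.
#'
#' @param tmap A `transition_map`.
#' @param impacts Data frame with column `cell` and the indicator columns.
#' @param type `"typeI"` or `"typeII"`.
#' @param indicators Indicator columns to test.
#' @param welch Use Welch's unequal-variance t test.
#' @return Data frame of class `impact_comparison`: one row per indicator
#'   with group means, `t`, `p`, and group sizes.
#' @export
impact_ttests <- function(tmap, impacts,
                          type = c("typeI", "typeII"),
                          indicators = c("cropland", "pasture", "primary",
                                         "secondary", "urban", "pop_density"),
                          welch = FALSE) {
  stopifnot(inherits(tmap, "transition_map"))
  type <- match.arg(type)
  grp <- .transition_groups(tmap, type)
  if (length(grp$changed) < 2L || length(grp$unchanged) < 2L)
    stop("both changed and unchanged groups need at least 2 cells",
         call. = FALSE)
  ic <- impacts[match(grp$changed, impacts$cell), , drop = FALSE]
  iu <- impacts[match(grp$unchanged, impacts$cell), , drop = FALSE]
  rows <- lapply(indicators, function(v) {
    x <- ic[[v]]; y <- iu[[v]]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      # degenerate zero-variance case: identical groups are maximally
      # non-significant, distinct constant groups maximally significant
      tt <- list(statistic = if (mean(x) == mean(y)) 0 else
                   Inf * sign(mean(x) - mean(y)),
                 p.value = if (mean(x) == mean(y)) 1 else 0)
    } else {
      tt <- stats::t.test(x, y, var.equal = !welch)
    }
    data.frame(indicator = v, mean_changed = mean(x),
               mean_unchanged = mean(y), t = unname(tt$statistic),
               p = tt$p.value, n_changed = nrow(ic), n_unchanged = nrow(iu),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  attr(res, "type") <- type
  attr(res, "welch") <- welch
  class(res) <- c("impact_comparison", "data.frame")
  res
}

#' Explain one transition type with a globally optimised impact tree
#'
#' Fits [evolve_tree()] to the binary changed/unchanged outcome of one
#' disagreement type using the human-impact indicators as predictors, to
#' recover the impact thresholds at which structures degrade.
#'
#' @inheritParams impact_ttests
#' @param config An [evolution_config()].
#' @return A `tree_model` over the indicator variables with classes
#'   `changed` / `unchanged` (single-leaf `unchanged` model when no cell of
#'   the type exists).
#' @export
impact_tree <- function(tmap, impacts, type = c("typeI", "typeII"),
                        indicators = c("cropland", "pasture", "primary",
                                       "secondary", "urban", "pop_density"),
                        config = evolution_config()) {
  stopifnot(inherits(tmap, "transition_map"))
  type <- match.arg(type)
  grp <- .transition_groups(tmap, type)
  ids <- c(grp$changed, grp$unchanged)
  y <- rep(c("changed", "unchanged"), c(length(grp$changed),
                                        length(grp$unchanged)))
  X <- impacts[match(ids, impacts$cell), indicators, drop = FALSE]
  evolve_tree(X, y, config)
}
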