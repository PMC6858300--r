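## Bipartite energy-flow networks: resources feed guilds, edge fluxes are the
## summed diet percentages of the guild's species for that resource.

#' Build a bipartite resource-to-guild energy network
#'
#' The flux of edge resource r -> guild g is the sum of the diet percentage
#' of r over all species assigned to g.  Guild node weight is the number of
#' species in the guild; resource node weight is the total flux leaving the
#' resource.  With diets normalised to 100, total flux equals
#' `100 * n_species`.  Zero-flux edges are omitted.
#'
#' @param species Character vector of species ids to include.
#' @param diet Diet matrix (species x resources, rows summing to 100).
#' @param guilds A `guild_assignment` or a named character vector of guild
#'   labels per species.
#' @return Object of class `energy_network`: `guild_nodes` (id, species
#'   count), `resource_nodes` (id, total flux), `edges` (resource, guild,
#'   flux), `n_species`.
#' @export
build_energy_network <- function(species, diet, guilds) {
  labels <- if (inherits(guilds, "guild_assignment")) guild_labels(guilds)
            else guilds
  diet <- as_sample_matrix(diet)
  missing_diet <- setdiff(species, rownames(diet))
  if (length(missing_diet))
    stop("species without diet: ", paste(missing_diet, collapse = ", "),
         call. = FALSE)
  missing_guild <- setdiff(species, names(labels))
  if (length(missing_guild))
    stop("species without guild label: ",
         paste(missing_guild, collapse = ", "), call. = FALSE)
  d <- diet[species, , drop = FALSE]
  g <- factor(labels[species])
  ## flux matrix: resources x guilds
  flux <- t(rowsum(d, g))          # resources x guilds (rowsum over species)
  edges <- data.frame(
    resource = rownames(flux)[row(flux)[flux > 0]],
    guild = colnames(flux)[col(flux)[flux > 0]],
    flux = flux[flux > 0], stringsAsFactors = FALSE)
  net <- list(
    guild_nodes = data.frame(guild = levels(g),
                             n_species = as.integer(table(g)),
                             stringsAsFactors = FALSE),
    resource_nodes = data.frame(resource = rownames(flux),
                                flux = rowSums(flux),
                                stringsAsFactors = FALSE),
    edges = edges, n_species = length(species))
  class(net) <- "energy_network"
  net
}

#' @export
print.energy_network <- function(x, ...) {
  cat(sprintf("energy network: %d species, %d guilds, %d resources, %d edges\n",
              x$n_species, nrow(x$guild_nodes), nrow(x$resource_nodes),
              nrow(x$edges)))
  cat(sprintf("total flux %.1f (= 100 x species when diets are normalised)\n",
              sum(x$edges$flux)))
  invisible(x)
}

#' Energy network of one trophic structure
#'
#' Builds the network over the union of species present in the cells
#' classified into the given structure (each species counted once however
#' many cells it occupies).
#'
#' @param classification A `structure_classification`.
#' @param label Structure label.
#' @param grid Binary cell x species presence matrix.
#' @param diet,guilds As in [build_energy_network()].
#' @return An `energy_network`.
#' @export
structure_network <- function(classification, label, grid, diet, guilds) {
  stopifnot(inherits(classification, "structure_classification"))
  cells <- classification$cells$cell[classification$cells$label == label]
  if (!length(cells))
    stop("no cells carry structure label '", label, "'", call. = FALSE)
  cells <- intersect(cells, rownames(grid))
  sub <- grid[cells, , drop = FALSE]
  species <- colnames(sub)[colSums(sub) > 0]
  build_energy_network(species, diet, guilds)
}

#' Export an energy network
#'
#' Writes a GraphML (or GEXF-flavoured GraphML via igraph) file with node
#' weights and edge fluxes as attributes, and/or a plain edge-list CSV that
#' round-trips losslessly.
#'
#' @param net An `energy_network`.
#' @param path Output file path.
#' @param format `"graphml"` or `"csv"` (edge list with flux).
#' @return Invisibly, `path`.
#' @export
export_network <- function(net, path, format = c("graphml", "csv")) {
  stopifnot(inherits(net, "energy_network"))
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(net$edges, path, row.names = FALSE)
    return(invisible(path))
  }
  vertices <- data.frame(
    name = c(net$resource_nodes$resource, net$guild_nodes$guild),
    type = rep(c("resource", "guild"),
               c(nrow(net$resource_nodes), nrow(net$guild_nodes))),
    weight = c(net$resource_nodes$flux, net$guild_nodes$n_species),
    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = net$edges$resource, to = net$edges$guild,
               weight = net$edges$flux, stringsAsFactors = FALSE),
    directed = TRUE, vertices = vertices)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read an edge-list CSV back into an energy network
#'
#' Reconstructs edges and node weights from an exported edge list.  Guild
#' species counts are not stored in the edge list, so `guild_nodes` carries
#' `NA` counts unless `n_species` per guild is supplied.
#'
#' @param path CSV written by [export_network(format = "csv")].
#' @return An `energy_network` (without species counts).
#' @export
read_network_csv <- function(path) {
  edges <- utils::read.csv(path, stringsAsFactors = FALSE)
  net <- list(
    guild_nodes = data.frame(guild = sort(unique(edges$guild)),
                             n_species = NA_integer_),
    resource_nodes = data.frame(
      resource = sort(unique(edges$resource)),
      flux = as.numeric(tapply(edges$flux, edges$resource, sum))),
    edges = edges, n_species = NA_integer_)
  class(net) <- "energy_network"
  net
}
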