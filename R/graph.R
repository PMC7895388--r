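#' Region adjacency graph
#'
#' Two parameter regions are adjacent when they share a codimension-1
#' boundary: a point where exactly one attractor-condition inequality holds
#' with equality and whose neighbourhood meets both regions' interiors.
#' In the catalog these are the feasible one-flip walls between cells of
#' different configurations.
#'
#' @param catalog A [decompose_regions()] catalog.
#' @return An undirected [igraph::igraph] graph; vertices carry the region
#'   label, configuration bitmask and attractor counts.
#' @export
build_region_graph <- function(catalog) {
  stopifnot(inherits(catalog, "region_catalog"))
  reg <- catalog$regions
  g <- igraph::make_empty_graph(n = nrow(reg), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = reg$label)
  g <- igraph::set_vertex_attr(g, "config", value = reg$bitmask)
  g <- igraph::set_vertex_attr(g, "attractors", value = reg$attractors)
  g <- igraph::set_vertex_attr(g, "n_symmetric", value = reg$n_symmetric)
  g <- igraph::set_vertex_attr(g, "n_asymmetric", value = reg$n_asymmetric)
  g <- igraph::set_vertex_attr(g, "component", value = reg$component)
  dc <- catalog$walls[!catalog$walls$same_config, , drop = FALSE]
  if (nrow(dc)) {
    ra <- catalog$cells$region[match(dc$cell_a, catalog$cells$id)]
    rb <- catalog$cells$region[match(dc$cell_b, catalog$cells$id)]
    ep <- unique(t(apply(cbind(ra, rb), 1, sort)))
    g <- igraph::add_edges(g, rbind(match(ep[, 1], reg$label),
                                    match(ep[, 2], reg$label)))
  }
  igraph::simplify(g)
}

#' Are two regions adjacent?
#'
#' @param catalog A [decompose_regions()] catalog.
#' @param label_a,label_b Region labels from the catalog.
#' @return Logical. A region is never adjacent to itself.
#' @export
adjacent_regions <- function(catalog, label_a, label_b) {
  stopifnot(inherits(catalog, "region_catalog"))
  if (label_a == label_b) return(FALSE)
  g <- build_region_graph(catalog)
  igraph::are_adjacent(g, label_a, label_b)
}

#' Shortest-path distance statistics of a region graph
#'
#' All-pairs shortest paths (breadth-first search over unweighted edges;
#' adjacent regions are at distance 1), the distance histogram over
#' unordered pairs, the graph diameter, and the fraction of pairs at
#' distance at most 4.
#'
#' @param g A graph from [build_region_graph()] or [toy_region_graph()].
#' @return A list with `n_nodes`, `n_edges`, `diameter`, `frac_le4`,
#'   `n_pairs` and a `histogram` data frame (`distance`, `count`).
#' @export
distance_stats <- function(g) {
  d <- igraph::distances(g)
  du <- d[upper.tri(d)]
  fin <- du[is.finite(du)]
  hist <- as.data.frame(table(distance = fin))
  hist$distance <- as.integer(as.character(hist$distance))
  names(hist)[2] <- "count"
  list(n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g),
       diameter = max(fin), frac_le4 = mean(fin <= 4),
       n_pairs = length(du), connected = all(is.finite(du)),
       histogram = hist)
}

#' Toy-model region graph
#'
#' The path `D1 - D2 - D3`: `D1` and `D2` share the boundary
#' `b = gamma*theta`, `D2` and `D3` share `b + 1 = gamma*theta`, and `D1`,
#' `D3` are not adjacent (their closures meet only where both equalities
#' hold at once, which is impossible).
#'
#' @return An undirected igraph graph with 3 nodes and 2 edges.
#' @export
toy_region_graph <- function() {
  g <- igraph::make_graph(~ D1 - D2, D2 - D3)
  reg <- toy_regions()
  igraph::set_vertex_attr(g, "attractors",
                          value = reg$attractors[match(igraph::V(g)$name,
                                                       reg$label)])
}

#' Export a region graph
#'
#' Writes GraphML or DOT with the node attributes intact.
#'
#' @param g An igraph graph.
#' @param path Output file.
#' @param format `"graphml"` or `"dot"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(g, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  igraph::write_graph(g, path, format = format)
  invisible(path)
}
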