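# Bipartite herb-ingredient networks: construction restricted to active
# (hepatoprotective) ingredients, the hepatoprotective / undetermined split
# by herb status, degree analysis and the material-basis candidate filter.

#' Build the hepatoprotective and undetermined herb-ingredient networks
#'
#' Edges are restricted to ingredients in `active_ingredients`; herbs known
#' to be hepatoprotective go to the *hepatoprotective* network, all other
#' herbs to the *undetermined* network, so the two networks partition the
#' herbs. Duplicate pairs are collapsed; edges whose ingredient is not an
#' active ingredient are dropped (count logged).
#'
#' @param edges Edge tibble from [edge_table()] (columns `herb`,
#'   `ingredient`).
#' @param active_ingredients Character vector of active ingredient ids.
#' @param hepato_herbs Character vector of herb names with known
#'   hepatoprotective status.
#' @return A list with elements `hepatoprotective` and `undetermined`, each
#'   a `bipartite_network`: list(`kind`, `edges` tibble, `graph` igraph
#'   object with vertex attributes `role` (herb/ingredient) and `status`).
#' @export
build_networks <- function(edges, active_ingredients, hepato_herbs) {
  if (nrow(edges) == 0) hs_data_error("edge list is empty")
  active_ingredients <- normalize_ingredient(active_ingredients)
  edges <- dplyr::distinct(edges[, c("herb", "ingredient")])
  keep <- edges$ingredient %in% active_ingredients
  if (any(!keep)) {
    inform(sprintf("build_networks: dropped %d edge(s) with non-active ingredients",
                   sum(!keep)))
  }
  edges <- edges[keep, ]
  is_hep <- edges$herb %in% hepato_herbs
  list(
    hepatoprotective = bipartite_network(edges[is_hep, ], "hepatoprotective"),
    undetermined = bipartite_network(edges[!is_hep, ], "undetermined")
  )
}

#' @rdname build_networks
#' @param kind Network kind label.
#' @export
bipartite_network <- function(edges, kind = c("undetermined", "hepatoprotective")) {
  kind <- match.arg(kind)
  herbs <- unique(edges$herb)
  ingredients <- unique(edges$ingredient)
  g <- igraph::make_empty_graph(directed = FALSE) |>
    igraph::add_vertices(length(herbs), name = herbs, role = "herb",
                         type = FALSE) |>
    igraph::add_vertices(length(ingredients), name = ingredients,
                         role = "ingredient", type = TRUE)
  if (nrow(edges) > 0) {
    g <- igraph::add_edges(g, rbind(match(edges$herb, herbs),
                                    length(herbs) + match(edges$ingredient,
                                                          ingredients)))
  }
  igraph::V(g)$status <- ifelse(igraph::V(g)$role == "herb", kind, NA)
  structure(list(kind = kind, edges = edges, graph = g,
                 herbs = herbs, ingredients = ingredients),
            class = "bipartite_network")
}

#' Per-herb count of distinct active ingredients
#'
#' The degree of each herb node in the network, i.e. the number of distinct
#' hepatoprotective ingredients it is connected to (the herb's *material
#' basis*).
#'
#' @param net A `bipartite_network`.
#' @return A tibble `herb`, `n_active_ingredients`, sorted by count then
#'   name.
#' @export
ingredient_degree <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  if (nrow(net$edges) == 0) {
    return(tibble::tibble(herb = character(), n_active_ingredients = integer()))
  }
  net$edges |>
    dplyr::count(.data$herb, name = "n_active_ingredients") |>
    dplyr::arrange(dplyr::desc(.data$n_active_ingredients), .data$herb)
}

#' Material-basis candidate filter
#'
#' Herbs whose active-ingredient count reaches `min_count` (inclusive),
#' sorted by count descending then name.
#'
#' @param degrees Tibble from [ingredient_degree()] (columns `herb`,
#'   `n_active_ingredients`).
#' @param min_count Inclusive threshold (default 15).
#' @return The filtered, ordered tibble.
#' @export
filter_candidates <- function(degrees, min_count = 15) {
  if (min_count < 1) hs_config_error("min_count must be >= 1")
  degrees |>
    dplyr::filter(.data$n_active_ingredients >= min_count) |>
    dplyr::arrange(dplyr::desc(.data$n_active_ingredients), .data$herb)
}

#' Export a network to GraphML or GEXF
#'
#' Nodes carry a `role` attribute (`herb`/`ingredient`) and herbs a
#' `status` attribute; both formats load in standard graph tools.
#'
#' @param net A `bipartite_network`.
#' @param path Output file path.
#' @param format `"graphml"` (via igraph) or `"gexf"` (written directly).
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "gexf")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(net$graph, path, format = "graphml")
  } else {
    write_gexf(net, path)
  }
  invisible(path)
}

# Minimal GEXF 1.2 writer.
write_gexf <- function(net, path) {
  g <- net$graph
  doc <- xml2::xml_new_root("gexf", xmlns = "http://www.gexf.net/1.2draft",
                            version = "1.2")
  graph <- xml2::xml_add_child(doc, "graph", defaultedgetype = "undirected")
  attrs <- xml2::xml_add_child(graph, "attributes", class = "node")
  xml2::xml_add_child(attrs, "attribute", id = "0", title = "role",
                      type = "string")
  xml2::xml_add_child(attrs, "attribute", id = "1", title = "status",
                      type = "string")
  nodes <- xml2::xml_add_child(graph, "nodes")
  vs <- igraph::V(g)
  for (i in seq_along(vs)) {
    nd <- xml2::xml_add_child(nodes, "node", id = vs$name[i],
                              label = vs$name[i])
    av <- xml2::xml_add_child(nd, "attvalues")
    xml2::xml_add_child(av, "attvalue", `for` = "0", value = vs$role[i])
    if (!is.na(vs$status[i])) {
      xml2::xml_add_child(av, "attvalue", `for` = "1", value = vs$status[i])
    }
  }
  edges_el <- xml2::xml_add_child(graph, "edges")
  el <- igraph::as_edgelist(g)
  for (i in seq_len(nrow(el))) {
    xml2::xml_add_child(edges_el, "edge", id = as.character(i - 1),
                        source = el[i, 1], target = el[i, 2])
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a network back from GraphML (round-trip check helper)
#'
#' @param path GraphML file.
#' @return An igraph graph.
#' @export
import_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}
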