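# Graph export: GraphML via igraph, GEXF 1.2 written directly with xml2.

#' Convert a trait network to an igraph graph
#'
#' @param net A `trait_network`.
#' @param scores Optional pooled eigencentrality scores; attached as a node
#'   attribute when given.
#' @return An undirected igraph graph with node attributes `trait`,
#'   `category` (and `eigencentrality`) and edge attribute `weight`.
#' @export
as_igraph <- function(net, scores = NULL) {
  stopifnot(inherits(net, "trait_network"))
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = net$edges$modality_i, to = net$edges$modality_j,
                   weight = net$edges$weight),
    directed = FALSE,
    vertices = data.frame(name = net$nodes$modality, trait = net$nodes$trait,
                          category = net$nodes$category)
  )
  if (!is.null(scores)) {
    sub <- as_tibble(scores) %>%
      filter(.data$site == net$site, .data$treatment == net$treatment)
    sc <- setNames(sub$eigencentrality, sub$modality)
    igraph::V(g)$eigencentrality <- unname(sc[igraph::V(g)$name])
  }
  g
}

#' Export a trait network to GraphML or GEXF
#'
#' Writes the network with node category (and optional eigencentrality)
#' attributes and edge weights. Optionally embeds 2-D coordinates from a
#' seeded Fruchterman–Reingold force-directed layout, so repeated exports
#' with the same seed are identical.
#'
#' @param net A `trait_network`.
#' @param path Output file path.
#' @param format `"graphml"` or `"gexf"`.
#' @param scores Optional pooled eigencentrality scores.
#' @param layout_seed Integer seed; when given, Fruchterman–Reingold
#'   coordinates `x`, `y` are stored on the nodes.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "gexf"),
                           scores = NULL, layout_seed = NULL) {
  format <- match.arg(format)
  g <- as_igraph(net, scores)
  if (!is.null(layout_seed)) {
    coords <- withr::with_seed(layout_seed, igraph::layout_with_fr(g))
    if (igraph::vcount(g) > 0) {
      igraph::V(g)$x <- coords[, 1]
      igraph::V(g)$y <- coords[, 2]
    }
  }
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    write_gexf(g, path)
  }
  invisible(path)
}

# minimal GEXF 1.2 writer (igraph has no GEXF backend)
write_gexf <- function(g, path) {
  doc <- xml2::xml_new_root(
    "gexf",
    xmlns = "http://www.gexf.net/1.2draft",
    `xmlns:viz` = "http://www.gexf.net/1.2draft/viz", version = "1.2"
  )
  graph <- xml2::xml_add_child(doc, "graph", defaultedgetype = "undirected")
  v_attr <- setdiff(igraph::vertex_attr_names(g), c("name", "x", "y"))
  attrs <- xml2::xml_add_child(graph, "attributes", class = "node")
  for (i in seq_along(v_attr)) {
    type <- if (is.numeric(igraph::vertex_attr(g, v_attr[i]))) "double" else "string"
    xml2::xml_add_child(attrs, "attribute", id = as.character(i - 1),
                        title = v_attr[i], type = type)
  }
  nodes <- xml2::xml_add_child(graph, "nodes")
  vnames <- igraph::V(g)$name
  for (v in seq_along(vnames)) {
    node <- xml2::xml_add_child(nodes, "node", id = vnames[v], label = vnames[v])
    if (length(v_attr) > 0) {
      av <- xml2::xml_add_child(node, "attvalues")
      for (i in seq_along(v_attr)) {
        xml2::xml_add_child(av, "attvalue", `for` = as.character(i - 1),
                            value = as.character(igraph::vertex_attr(g, v_attr[i])[v]))
      }
    }
    if (all(c("x", "y") %in% igraph::vertex_attr_names(g))) {
      xml2::xml_add_child(node, "viz:position",
                          x = as.character(igraph::V(g)$x[v]),
                          y = as.character(igraph::V(g)$y[v]), z = "0")
    }
  }
  edges <- xml2::xml_add_child(graph, "edges")
  el <- igraph::as_edgelist(g)
  w <- igraph::E(g)$weight
  for (e in seq_len(nrow(el))) {
    xml2::xml_add_child(edges, "edge", id = as.character(e - 1),
                        source = el[e, 1], target = el[e, 2],
                        weight = as.character(w[e]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
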