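#' Convert a connectome or grouped matrix to an igraph graph
#'
#' Nodes carry `cell_type`, `side` and `role` attributes; directed edges
#' carry the synapse count (single-cell graphs) or the grouped weight —
#' averaged synapse number onto neuronal groups, summed synapses onto
#' effector groups.
#'
#' @param x A `connectome` or `grouped_matrix`.
#' @return An `igraph` directed graph.
#' @export
as_igraph <- function(x) {
  if (inherits(x, "connectome")) {
    verts <- x$neurons |>
      mutate(name = .data$id,
             role = ifelse(!is.na(.data$func_class) &
                             .data$func_class == "effector",
                           "effector", "neuronal")) |>
      select("name", "cell_type", "side", "role")
    edges <- x$links |> rename(from = "pre_id", to = "post_id",
                               weight = "count")
    igraph::graph_from_data_frame(edges, directed = TRUE, vertices = verts)
  } else if (inherits(x, "grouped_matrix")) {
    keys <- rownames(x)
    parts <- strsplit(keys, ".", fixed = TRUE)
    verts <- tibble(
      name = keys,
      cell_type = vapply(parts, function(p)
        paste(p[-length(p)], collapse = "."), ""),
      side = vapply(parts, function(p) p[length(p)], ""),
      role = unname(attr(x, "roles")[keys]) %||% rep("neuronal", length(keys))
    )
    edges <- as_tibble(x) |> rename(from = "pre", to = "post")
    igraph::graph_from_data_frame(edges, directed = TRUE, vertices = verts)
  } else {
    stop_config("export expects a connectome or grouped_matrix")
  }
}

#' Export a connectivity graph for network tools
#'
#' Writes a connectome or grouped matrix as GraphML or GEXF (both readable
#' by Gephi and other network-analysis tools). Node attributes `cell_type`,
#' `side` and `role` and the edge `weight` are preserved.
#'
#' @param x A `connectome` or `grouped_matrix`.
#' @param path Output file path.
#' @param format `"graphml"` (default) or `"gexf"`.
#' @return Invisibly, `path`.
#' @export
export_graph <- function(x, path, format = c("graphml", "gexf")) {
  format <- tryCatch(match.arg(format),
                     error = function(e)
                       stop_config(paste0("unsupported format: ",
                                          paste(format, collapse = "/"))))
  g <- as_igraph(x)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    write_gexf(g, path)
  }
  invisible(path)
}

# minimal GEXF 1.2 writer for a directed weighted graph with the three
# string node attributes used here
write_gexf <- function(g, path) {
  doc <- xml2::xml_new_root("gexf",
                            xmlns = "http://www.gexf.net/1.2draft",
                            version = "1.2")
  graph <- xml2::xml_add_child(doc, "graph", mode = "static",
                               defaultedgetype = "directed")
  attrs <- xml2::xml_add_child(graph, "attributes", class = "node")
  attr_names <- c("cell_type", "side", "role")
  for (i in seq_along(attr_names)) {
    xml2::xml_add_child(attrs, "attribute", id = as.character(i - 1),
                        title = attr_names[i], type = "string")
  }
  nodes <- xml2::xml_add_child(graph, "nodes")
  vnames <- igraph::V(g)$name
  for (i in seq_along(vnames)) {
    node <- xml2::xml_add_child(nodes, "node", id = vnames[i],
                                label = vnames[i])
    av <- xml2::xml_add_child(node, "attvalues")
    for (j in seq_along(attr_names)) {
      val <- igraph::vertex_attr(g, attr_names[j])[i]
      if (!is.null(val) && !is.na(val)) {
        xml2::xml_add_child(av, "attvalue", `for` = as.character(j - 1),
                            value = as.character(val))
      }
    }
  }
  edges <- xml2::xml_add_child(graph, "edges")
  el <- igraph::as_data_frame(g, what = "edges")
  if (nrow(el) > 0) {
    for (i in seq_len(nrow(el))) {
      xml2::xml_add_child(edges, "edge", id = as.character(i - 1),
                          source = el$from[i], target = el$to[i],
                          weight = as.character(el$weight[i]))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

# read a GEXF file written by write_gexf back into node/edge tibbles
read_gexf_tables <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(g = "http://www.gexf.net/1.2draft")
  node_xml <- xml2::xml_find_all(doc, ".//g:node", ns)
  edge_xml <- xml2::xml_find_all(doc, ".//g:edge", ns)
  list(
    nodes = tibble(id = xml2::xml_attr(node_xml, "id")),
    edges = tibble(from = xml2::xml_attr(edge_xml, "source"),
                   to = xml2::xml_attr(edge_xml, "target"),
                   weight = as.numeric(xml2::xml_attr(edge_xml, "weight")))
  )
}
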