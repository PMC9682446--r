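#' Export a redirection network for graph tooling
#'
#' Serializes the network with its node attributes (role and, when a metrics
#' table is supplied, in_degree / distinct_sources / pagerank, plus
#' legitimacy when profiles are supplied) and edge attributes (weight, apis).
#' Three interchange formats are supported: GraphML and GEXF (both readable
#' by Gephi) and a plain edge/node CSV pair. Every format round-trips through
#' [import_graph()].
#'
#' @param net Graph from [build_network()].
#' @param path Output file. For `edge_csv` this is the edge table; a node
#'   table is written alongside with suffix `_nodes.csv`.
#' @param format One of `"graphml"`, `"gexf"`, `"edge_csv"`.
#' @param metrics Optional [node_metrics()] tibble to attach per-node scores.
#' @param profiles Optional destination profiles to attach `legitimacy`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(net, path, format = c("graphml", "gexf", "edge_csv"),
                         metrics = NULL, profiles = NULL) {
  format <- match.arg(format)
  g <- net
  if (!is.null(metrics) && igraph::vcount(g) > 0) {
    idx <- match(igraph::V(g)$name, metrics$domain)
    igraph::V(g)$in_degree <- metrics$in_degree[idx]
    igraph::V(g)$distinct_sources <- metrics$distinct_sources[idx]
    igraph::V(g)$pagerank <- metrics$pagerank[idx]
  }
  if (!is.null(profiles) && igraph::vcount(g) > 0) {
    idx <- match(igraph::V(g)$name, profiles$domain)
    igraph::V(g)$legitimacy <- ifelse(is.na(idx), "not_in_database",
                                      profiles$legitimacy[idx])
  }
  switch(format,
    graphml = igraph::write_graph(g, path, format = "graphml"),
    gexf = write_gexf(g, path),
    edge_csv = {
      edges <- if (igraph::ecount(g) > 0) {
        el <- igraph::as_edgelist(g)
        tibble::tibble(source = el[, 1], destination = el[, 2],
                       weight = igraph::E(g)$weight, apis = igraph::E(g)$apis)
      } else {
        tibble::tibble(source = character(), destination = character(),
                       weight = numeric(), apis = character())
      }
      readr::write_csv(edges, path, progress = FALSE)
      nodes <- tibble::tibble(name = igraph::V(g)$name, role = igraph::V(g)$role)
      for (a in intersect(c("in_degree", "distinct_sources", "pagerank", "legitimacy"),
                          igraph::vertex_attr_names(g))) {
        nodes[[a]] <- igraph::vertex_attr(g, a)
      }
      readr::write_csv(nodes, edge_csv_nodes_path(path), progress = FALSE)
    }
  )
  invisible(path)
}

edge_csv_nodes_path <- function(path) sub("(\\.[^.]+)?$", "_nodes.csv", path)

#' Re-import an exported redirection network
#'
#' @param path File written by [export_graph()].
#' @param format The format it was written in.
#' @return An `igraph` directed graph.
#' @export
import_graph <- function(path, format = c("graphml", "gexf", "edge_csv")) {
  format <- match.arg(format)
  switch(format,
    graphml = igraph::read_graph(path, format = "graphml"),
    gexf = read_gexf(path),
    edge_csv = {
      edges <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
      nodes <- readr::read_csv(edge_csv_nodes_path(path), show_col_types = FALSE,
                               progress = FALSE)
      igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
    }
  )
}

# Minimal GEXF 1.2 writer/reader covering the attributes this package uses.
write_gexf <- function(g, path) {
  doc <- xml2::xml_new_root("gexf", xmlns = "http://www.gexf.net/1.2draft",
                            version = "1.2")
  graph <- xml2::xml_add_child(doc, "graph", defaultedgetype = "directed")
  natts <- xml2::xml_add_child(graph, "attributes", class = "node")
  node_attrs <- intersect(c("role", "in_degree", "distinct_sources",
                            "pagerank", "legitimacy"),
                          igraph::vertex_attr_names(g))
  for (i in seq_along(node_attrs)) {
    type <- if (is.numeric(igraph::vertex_attr(g, node_attrs[i]))) "double" else "string"
    xml2::xml_add_child(natts, "attribute", id = as.character(i - 1L),
                        title = node_attrs[i], type = type)
  }
  eatts <- xml2::xml_add_child(graph, "attributes", class = "edge")
  edge_attrs <- intersect("apis", igraph::edge_attr_names(g))
  for (i in seq_along(edge_attrs)) {
    xml2::xml_add_child(eatts, "attribute", id = as.character(i - 1L),
                        title = edge_attrs[i], type = "string")
  }
  nodes <- xml2::xml_add_child(graph, "nodes")
  vnames <- igraph::V(g)$name
  for (v in seq_len(igraph::vcount(g))) {
    node <- xml2::xml_add_child(nodes, "node", id = vnames[v], label = vnames[v])
    if (length(node_attrs) > 0) {
      av <- xml2::xml_add_child(node, "attvalues")
      for (i in seq_along(node_attrs)) {
        xml2::xml_add_child(av, "attvalue", `for` = as.character(i - 1L),
                            value = as.character(igraph::vertex_attr(g, node_attrs[i], v)))
      }
    }
  }
  edges <- xml2::xml_add_child(graph, "edges")
  if (igraph::ecount(g) > 0) {
    el <- igraph::as_edgelist(g)
    w <- igraph::E(g)$weight
    for (e in seq_len(nrow(el))) {
      edge <- xml2::xml_add_child(edges, "edge", id = as.character(e - 1L),
                                  source = el[e, 1], target = el[e, 2],
                                  weight = as.character(w[e]))
      if (length(edge_attrs) > 0) {
        av <- xml2::xml_add_child(edge, "attvalues")
        for (i in seq_along(edge_attrs)) {
          xml2::xml_add_child(av, "attvalue", `for` = as.character(i - 1L),
                              value = as.character(igraph::edge_attr(g, edge_attrs[i], e)))
        }
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

read_gexf <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  att_titles <- function(class) {
    nodes <- xml2::xml_find_all(doc, sprintf("./graph/attributes[@class='%s']/attribute", class))
    stats::setNames(xml2::xml_attr(nodes, "title"), xml2::xml_attr(nodes, "id"))
  }
  natt <- att_titles("node")
  eatt <- att_titles("edge")
  node_els <- xml2::xml_find_all(doc, "./graph/nodes/node")
  nodes <- tibble::tibble(name = xml2::xml_attr(node_els, "id"))
  for (id in names(natt)) {
    vals <- vapply(node_els, function(n) {
      v <- xml2::xml_attr(xml2::xml_find_first(n, sprintf("./attvalues/attvalue[@for='%s']", id)), "value")
      if (is.na(v)) NA_character_ else v
    }, character(1))
    num <- suppressWarnings(as.numeric(vals))
    nodes[[natt[[id]]]] <- if (!anyNA(num) || natt[[id]] %in%
                               c("in_degree", "distinct_sources", "pagerank")) num else vals
  }
  edge_els <- xml2::xml_find_all(doc, "./graph/edges/edge")
  edges <- tibble::tibble(
    source = xml2::xml_attr(edge_els, "source"),
    destination = xml2::xml_attr(edge_els, "target"),
    weight = as.numeric(xml2::xml_attr(edge_els, "weight"))
  )
  for (id in names(eatt)) {
    edges[[eatt[[id]]]] <- vapply(edge_els, function(e) {
      xml2::xml_attr(xml2::xml_find_first(e, sprintf("./attvalues/attvalue[@for='%s']", id)), "value")
    }, character(1))
  }
  if (nrow(nodes) == 0) return(igraph::make_empty_graph(0, directed = TRUE))
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
}
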