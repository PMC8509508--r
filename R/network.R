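#' Build the weighted drug co-reporting network
#'
#' Nodes are the distinct retained drugs; an undirected edge joins two drugs
#' whenever at least one report lists both, with weight equal to the number
#' of such reports (the pair count). Node attributes carry the marginal
#' report count, prevalence and ATC-1 main group (used as colour key in
#' external viewers); each edge additionally carries its O/E ratio as an
#' exploratory attribute. There are no self-loops.
#'
#' @param x an `icsr_set` (every report should already have >= 2 drugs).
#' @return an [igraph::igraph] object with vertex attributes `name`, `count`,
#'   `prevalence`, `atc1` and edge attributes `weight`, `oe`.
#' @export
build_graph <- function(x) {
  stopifnot(inherits(x, "icsr_set"))
  if (n_reports(x) == 0) stop("empty report set")
  marg <- drug_marginals(x)
  pairs <- combo_stats(x, 2)
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = pairs$drug1, to = pairs$drug2,
                   weight = pairs$n_obs, oe = pairs$oe),
    directed = FALSE,
    vertices = data.frame(name = marg$drug, count = marg$n,
                          prevalence = marg$prevalence,
                          atc1 = ifelse(is.na(marg$atc1), "", marg$atc1))
  )
  g
}

#' Prune a co-reporting network
#'
#' Removes edges below a weight threshold, then drops nodes left without any
#' edge (and optionally nodes below a report-count threshold). The input
#' graph is not modified. Thresholds of 1/0 give the identity.
#'
#' @param g graph from [build_graph()].
#' @param min_edge_weight keep edges with `weight >=` this.
#' @param min_node_count keep nodes with `count >=` this (applied before edge
#'   pruning); 0 keeps all.
#' @return the filtered igraph object.
#' @export
filter_graph <- function(g, min_edge_weight = 1, min_node_count = 0) {
  stopifnot(min_edge_weight >= 0, min_node_count >= 0)
  if (min_node_count > 0)
    g <- igraph::induced_subgraph(
      g, which(igraph::V(g)$count >= min_node_count))
  g <- igraph::delete_edges(
    g, which(igraph::E(g)$weight < min_edge_weight))
  igraph::delete_vertices(g, which(igraph::degree(g) == 0))
}

#' Export a co-reporting network
#'
#' Writes the graph with all node/edge attributes in a format that external
#' tools (e.g. Gephi) ingest directly. GraphML goes through igraph; GEXF 1.2
#' is written natively; `edgelist` is a CSV with columns
#' `source,target,weight,oe`.
#'
#' @param g graph from [build_graph()].
#' @param path output file path.
#' @param format `"graphml"`, `"gexf"` or `"edgelist"` (guessed from the file
#'   extension when omitted).
#' @return `path`, invisibly.
#' @export
export_graph <- function(g, path, format = c("auto", "graphml", "gexf",
                                             "edgelist")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, graphml = "graphml", gexf = "gexf",
                     csv = "edgelist",
                     stop("cannot guess graph format from extension: ", ext))
  }
  switch(format,
    graphml = igraph::write_graph(g, path, format = "graphml"),
    gexf = write_gexf(g, path),
    edgelist = {
      el <- igraph::as_data_frame(g, what = "edges")
      names(el)[1:2] <- c("source", "target")
      utils::write.csv(el, path, row.names = FALSE, quote = FALSE)
    }
  )
  invisible(path)
}

#' Re-import an exported network
#'
#' Round-trip counterpart of [export_graph()] for the GraphML and edge-list
#' formats (GEXF export is write-only; validate it with an XML parser).
#'
#' @param path file written by [export_graph()].
#' @param format `"graphml"` or `"edgelist"` (guessed from extension).
#' @return an igraph object.
#' @export
import_graph <- function(path, format = c("auto", "graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, graphml = "graphml", csv = "edgelist",
                     stop("cannot guess graph format from extension: ", ext))
  }
  if (format == "graphml") return(igraph::read_graph(path, format = "graphml"))
  el <- utils::read.csv(path, colClasses = c(source = "character",
                                             target = "character"))
  igraph::graph_from_data_frame(el, directed = FALSE)
}

# Minimal GEXF 1.2 writer: undirected graph, node attribute atc1/count/
# prevalence, edge weight (+ oe attribute).
write_gexf <- function(g, path) {
  doc <- xml2::xml_new_root(
    "gexf", xmlns = "http://www.gexf.net/1.2draft", version = "1.2")
  graph <- xml2::xml_add_child(doc, "graph", defaultedgetype = "undirected")
  attrs <- xml2::xml_add_child(graph, "attributes", class = "node")
  nodedefs <- list(c("0", "atc1", "string"), c("1", "count", "integer"),
                   c("2", "prevalence", "double"))
  for (a in nodedefs)
    xml2::xml_add_child(attrs, "attribute", id = a[1], title = a[2],
                        type = a[3])
  eattrs <- xml2::xml_add_child(graph, "attributes", class = "edge")
  xml2::xml_add_child(eattrs, "attribute", id = "0", title = "oe",
                      type = "double")
  nodes <- xml2::xml_add_child(graph, "nodes")
  vdf <- igraph::as_data_frame(g, what = "vertices")
  for (i in seq_len(nrow(vdf))) {
    node <- xml2::xml_add_child(nodes, "node", id = vdf$name[i],
                                label = vdf$name[i])
    av <- xml2::xml_add_child(node, "attvalues")
    xml2::xml_add_child(av, "attvalue", `for` = "0", value = vdf$atc1[i])
    xml2::xml_add_child(av, "attvalue", `for` = "1",
                        value = as.character(vdf$count[i]))
    xml2::xml_add_child(av, "attvalue", `for` = "2",
                        value = format(vdf$prevalence[i], digits = 10))
  }
  edges <- xml2::xml_add_child(graph, "edges")
  edf <- igraph::as_data_frame(g, what = "edges")
  for (i in seq_len(nrow(edf))) {
    edge <- xml2::xml_add_child(
      edges, "edge", id = as.character(i - 1), source = edf$from[i],
      target = edf$to[i], weight = as.character(edf$weight[i]))
    av <- xml2::xml_add_child(edge, "attvalues")
    xml2::xml_add_child(av, "attvalue", `for` = "0",
                        value = format(edf$oe[i], digits = 10))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
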