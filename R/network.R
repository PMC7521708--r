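# PPI network handling: edge-list loading, cleaning (self-loops, duplicate
# edges, small disconnected components) and the four classical centrality
# baselines.

#' Read a two-column edge list
#'
#' @param path TSV file with two columns of gene identifiers, no header.
#' @return Data frame with columns `from`, `to`.
#' @export
read_edge_list <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("from", "to"))
  if (!nrow(df)) stopf("edge list %s is empty", path)
  df
}

#' Build and filter a PPI network
#'
#' Drops self-interactions, collapses duplicate and reversed-duplicate
#' edges, and keeps only the largest connected component (closeness is
#' undefined across components). Identifiers are trimmed of surrounding
#' whitespace.
#'
#' @param edges Data frame / matrix with two identifier columns, or a path
#'   accepted by [read_edge_list()].
#' @param verbose Report node/edge counts before and after filtering.
#' @return An undirected simple connected [igraph::graph] object.
#' @examples
#' g <- ppi_network(data.frame(from = c("a", "a", "b"), to = c("a", "b", "a")))
#' igraph::ecount(g)  # 1: loop removed, reverse duplicate collapsed
#' @export
ppi_network <- function(edges, verbose = FALSE) {
  if (is.character(edges) && length(edges) == 1) edges <- read_edge_list(edges)
  edges <- as.data.frame(edges)[, 1:2]
  edges[] <- lapply(edges, function(x) trimws(as.character(x)))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  n0 <- igraph::vcount(g); e0 <- igraph::ecount(g)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  comp <- igraph::components(g)
  if (comp$no > 0) {
    keep <- which(comp$membership == which.max(comp$csize))
    g <- igraph::induced_subgraph(g, keep)
  }
  if (igraph::vcount(g) == 0 || igraph::ecount(g) == 0)
    stopf("network empty after filtering")
  if (verbose)
    message(sprintf("network: %d nodes / %d edges -> %d nodes / %d edges after filtering",
                    n0, e0, igraph::vcount(g), igraph::ecount(g)))
  g
}

#' Centrality baselines
#'
#' Degree (DC), shortest-path betweenness (BC, unnormalized, each unordered
#' pair counted once), eigenvector centrality (EC, principal eigenvector
#' scaled to unit Euclidean norm) and closeness (CC, normalized so values
#' lie in (0, 1] on a connected graph) for every node.
#'
#' @param g A connected [igraph::graph], e.g. from [ppi_network()].
#' @return Data frame with columns `gene_id`, `DC`, `BC`, `EC`, `CC`.
#' @export
centralities <- function(g) {
  if (!igraph::is_connected(g)) stopf("centralities need a connected graph")
  ev <- igraph::eigen_centrality(g)$vector
  ev <- ev / sqrt(sum(ev^2))
  data.frame(
    gene_id = igraph::V(g)$name,
    DC = as.numeric(igraph::degree(g)),
    BC = as.numeric(igraph::betweenness(g)),
    EC = as.numeric(ev),
    CC = as.numeric(igraph::closeness(g, normalized = TRUE)),
    stringsAsFactors = FALSE
  )
}
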