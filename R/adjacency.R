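#' OGU adjacency graph
#'
#' Undirected graph of neighbouring OGUs, used to enforce geographic
#' contiguity of regions and to drive the spatially autocorrelated null
#' model of the biotic element analysis.
#'
#' @param nodes character vector of OGU ids
#' @param edges two-column matrix or data.frame of OGU-id pairs
#' @return an object of class `adjacency_graph` (wraps an igraph)
#' @export
adjacency_graph <- function(nodes, edges) {
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop("edges must have two columns")
  mode(edges) <- "character"
  unknown <- setdiff(c(edges), nodes)
  if (length(unknown))
    stop(sprintf("edge endpoint(s) not registered as OGUs: %s",
                 paste(unique(unknown), collapse = ", ")))
  if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2]),
    directed = FALSE,
    vertices = data.frame(name = nodes))
  g <- igraph::simplify(g)
  structure(list(graph = g, nodes = nodes), class = "adjacency_graph")
}

#' Read an adjacency edge list from CSV
#'
#' Expects two columns (`ogu_a`, `ogu_b`).  Node set defaults to the union
#' of the endpoints unless `nodes` is supplied.
#'
#' @param path CSV/TSV path
#' @param nodes optional full OGU id vector (isolated OGUs allowed)
#' @return an [adjacency_graph()]
#' @export
read_adjacency <- function(path, nodes = NULL) {
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  if (is.null(nodes)) nodes <- sort(unique(c(df[[1]], df[[2]])))
  adjacency_graph(nodes, df[, 1:2])
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat(sprintf("<adjacency_graph> %d OGUs, %d edges\n",
              length(x$nodes), igraph::ecount(x$graph)))
  invisible(x)
}

#' Neighbours of an OGU
#' @param g an `adjacency_graph`
#' @param ogu OGU id
#' @return character vector of adjacent OGU ids
#' @export
ogu_neighbors <- function(g, ogu) {
  if (!ogu %in% x_nodes(g)) stop(sprintf("unknown OGU '%s'", ogu))
  names(igraph::neighbors(g$graph, ogu))
}

x_nodes <- function(g) igraph::V(g$graph)$name

#' Connected components of a node subset
#'
#' Splits `members` into the connected components they induce on the graph.
#'
#' @param g an `adjacency_graph`
#' @param members character vector of OGU ids
#' @return list of character vectors, one per component
#' @export
induced_components <- function(g, members) {
  miss <- setdiff(members, x_nodes(g))
  if (length(miss))
    stop(sprintf("OGU(s) missing from adjacency graph: %s",
                 paste(miss, collapse = ", ")))
  sub <- igraph::induced_subgraph(g$graph, members)
  comp <- igraph::components(sub)
  split(names(comp$membership), comp$membership)
}

#' Graph (hop) distances between OGUs
#' @param g an `adjacency_graph`
#' @param from,to OGU id vectors
#' @return numeric matrix of hop counts
#' @export
hop_distances <- function(g, from, to) {
  igraph::distances(g$graph, v = from, to = to)
}

#' Cap the neighbourhood size of every OGU
#'
#' Keeps, for each OGU, at most `k` incident edges (smallest neighbour ids
#' first, for determinism), mirroring sensitivity runs that restrict each
#' unit to its four nearest neighbours.  An edge survives if either endpoint
#' retains it.
#'
#' @param g an `adjacency_graph`
#' @param k maximum neighbours per OGU
#' @return a new `adjacency_graph`
#' @export
cap_neighbors <- function(g, k) {
  stopifnot(k >= 1)
  el <- igraph::as_edgelist(g$graph)
  keep <- rep(FALSE, nrow(el))
  for (v in x_nodes(g)) {
    inc <- which(el[, 1] == v | el[, 2] == v)
    if (!length(inc)) next
    other <- ifelse(el[inc, 1] == v, el[inc, 2], el[inc, 1])
    keep[inc[order(other)][seq_len(min(k, length(inc)))]] <- TRUE
  }
  adjacency_graph(x_nodes(g), el[keep, , drop = FALSE])
}
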