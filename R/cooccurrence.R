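#' Build the domain co-occurrence network
#'
#' Nodes are domain types with their total occurrence count across the
#' analyzed proteins; edges count adjacency (consecutive positions in an
#' architecture), including self-loops for identical neighbours.  Each
#' architecture contributes once per member protein.
#'
#' @param architectures Character vector of architecture strings (one per
#'   assembly or per protein).
#' @param weights Integer member counts parallel to `architectures`
#'   (default all 1, i.e. one protein each).
#' @return A `cooccurrence_network`: list with `nodes` (data frame `name`,
#'   `occurrence`) and `edges` (data frame `from`, `to`, `frequency`;
#'   unordered pairs with `from <= to`).
#' @examples
#' build_network("A + B + A")
#' @export
build_network <- function(architectures, weights = NULL) {
  weights <- weights %||% rep(1L, length(architectures))
  stopifnot(length(weights) == length(architectures))
  keep <- nzchar(architectures)
  architectures <- architectures[keep]
  weights <- weights[keep]
  node_counts <- list()
  edge_counts <- list()
  for (k in seq_along(architectures)) {
    names_k <- strsplit(architectures[k], " + ", fixed = TRUE)[[1]]
    w <- weights[k]
    for (nm in names_k)
      node_counts[[nm]] <- (node_counts[[nm]] %||% 0L) + w
    if (length(names_k) >= 2) {
      for (i in seq_len(length(names_k) - 1)) {
        pair <- sort(c(names_k[i], names_k[i + 1]))
        key <- paste(pair, collapse = "\r")
        edge_counts[[key]] <- (edge_counts[[key]] %||% 0L) + w
      }
    }
  }
  nodes <- data.frame(name = names(node_counts),
                      occurrence = as.integer(unlist(node_counts)),
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(-nodes$occurrence, nodes$name), , drop = FALSE]
  rownames(nodes) <- NULL
  if (length(edge_counts)) {
    pairs <- do.call(rbind, strsplit(names(edge_counts), "\r", fixed = TRUE))
    edges <- data.frame(from = pairs[, 1], to = pairs[, 2],
                        frequency = as.integer(unlist(edge_counts)),
                        stringsAsFactors = FALSE)
    edges <- edges[order(-edges$frequency, edges$from, edges$to), ,
                   drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = character(), to = character(),
                        frequency = integer(), stringsAsFactors = FALSE)
  }
  net <- structure(list(nodes = nodes, edges = edges),
                   class = "cooccurrence_network")
  validate_network(net)
  net
}

# Conservation laws: every edge endpoint is a node; counts positive.
validate_network <- function(net) {
  stopifnot(all(c(net$edges$from, net$edges$to) %in% net$nodes$name),
            all(net$nodes$occurrence >= 1),
            all(net$edges$frequency >= 1))
  invisible(net)
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat("Domain co-occurrence network:", nrow(x$nodes), "domain types,",
      nrow(x$edges), "edges\n")
  cat("Total domain instances:", sum(x$nodes$occurrence), "\n")
  invisible(x)
}

#' Convert a co-occurrence network to igraph
#'
#' Vertex attribute `occurrence`, edge attribute `frequency`; self-loops
#' preserved.
#'
#' @param net A `cooccurrence_network`.
#' @return An [igraph::graph] object.
#' @export
as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes)
  g
}

#' Export the co-occurrence network
#'
#' `graphml` writes a Cytoscape-importable GraphML file (node attribute
#' `occurrence`, edge attribute `frequency`); `edge-tsv` writes a flat
#' `source target frequency` table.
#'
#' @param net A `cooccurrence_network`.
#' @param path Output file.
#' @param format `"graphml"` or `"edge-tsv"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(net, path, format = c("graphml", "edge-tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  } else {
    out <- data.frame(source = net$edges$from, target = net$edges$to,
                      frequency = net$edges$frequency)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a GraphML export back into a co-occurrence network
#'
#' Round-trip companion of [export_graph()] (used to verify lossless
#' export).
#'
#' @param path GraphML file written by [export_graph()].
#' @return A `cooccurrence_network`.
#' @export
read_graphml_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- data.frame(name = igraph::V(g)$name,
                      occurrence = as.integer(igraph::V(g)$occurrence),
                      stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(g)
  if (nrow(el)) {
    from <- pmin(el[, 1], el[, 2])
    to <- pmax(el[, 1], el[, 2])
    edges <- data.frame(from = from, to = to,
                        frequency = as.integer(igraph::E(g)$frequency),
                        stringsAsFactors = FALSE)
    edges <- edges[order(-edges$frequency, edges$from, edges$to), ,
                   drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = character(), to = character(),
                        frequency = integer(), stringsAsFactors = FALSE)
  }
  nodes <- nodes[order(-nodes$occurrence, nodes$name), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges),
            class = "cooccurrence_network")
}
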