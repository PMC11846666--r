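#' Construct a contextualized subnetwork
#'
#' The common output container of every contextualization method: a subgraph
#' of the parent PKN, optional node scores, and full provenance (method name,
#' parameter map, seed). Construction verifies that every subgraph edge
#' (source, target, sign) exists in the parent PKN.
#'
#' @param subgraph a `pkn_graph`
#' @param pkn the parent `pkn_graph`; containment of `subgraph` is asserted
#' @param node_scores optional named numeric vector over subgraph nodes
#' @param method method name recorded in provenance
#' @param parameters named list of method parameters
#' @param seed integer seed or `NULL`
#' @param notes optional character vector of provenance notes (for example
#'   unreachable source/target pairs)
#' @return an object of class `contextualized_network`
#' @export
contextualized_network <- function(subgraph, pkn, node_scores = NULL,
                                   method = "unknown", parameters = list(),
                                   seed = NULL, notes = character()) {
  stopifnot(inherits(subgraph, "pkn_graph"), inherits(pkn, "pkn_graph"))
  extra <- setdiff(edge_keys(subgraph), edge_keys(pkn))
  if (length(extra)) {
    stop("subgraph contains edges absent from the parent PKN: ",
         paste(gsub("\r", "->", extra), collapse = ", "))
  }
  if (!is.null(node_scores)) {
    node_scores <- node_scores[names(node_scores) %in% subgraph$nodes]
  }
  structure(list(subgraph = subgraph,
                 node_scores = node_scores,
                 provenance = list(method = method,
                                   parameters = parameters,
                                   seed = seed,
                                   notes = notes)),
            class = "contextualized_network")
}

#' @export
print.contextualized_network <- function(x, ...) {
  cat(sprintf("<contextualized_network> method=%s: %d nodes, %d edges\n",
              x$provenance$method, n_nodes(x$subgraph), n_edges(x$subgraph)))
  if (length(x$provenance$notes)) {
    cat("notes:", paste(x$provenance$notes, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Nodes of a contextualized network
#' @param network a `contextualized_network`
#' @return character vector of node identifiers
#' @export
network_nodes <- function(network) network$subgraph$nodes

#' Edges of a contextualized network
#' @param network a `contextualized_network`
#' @return data.frame with columns source, target, sign, weight
#' @export
network_edges <- function(network) network$subgraph$edges
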