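#' Construct a signed directed prior-knowledge network
#'
#' A PKN is a directed graph whose edges carry a sign (+1 activation, -1
#' inhibition) and an optional nonzero finite weight (default 1). Parallel
#' edges between the same ordered node pair are allowed when their signs
#' differ (a kinase may activate a substrate in one context and inhibit it in
#' another); duplicate (source, target, sign) triples are collapsed.
#'
#' @param edges data.frame with columns `source`, `target`, `sign` and
#'   optionally `weight`. `sign` must be -1 or +1; missing `weight` defaults
#'   to 1.
#' @param nodes optional character vector of additional (possibly isolated)
#'   node identifiers; endpoints of `edges` are always included.
#' @return An object of class `pkn_graph` with elements `nodes` (sorted
#'   character vector), `edges` (data.frame `source`, `target`, `sign`,
#'   `weight`, sorted by source/target/sign) and `directed` (always `TRUE`).
#' @examples
#' g <- pkn_graph(data.frame(source = "A", target = "B", sign = 1))
#' n_edges(g)
#' @export
pkn_graph <- function(edges = NULL, nodes = character()) {
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    edges <- data.frame(source = character(), target = character(),
                        sign = integer(), weight = numeric(),
                        stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (!all(c("source", "target", "sign") %in% names(edges))) {
      stop("edges must have columns 'source', 'target', 'sign'")
    }
    if (is.null(edges$weight)) edges$weight <- 1
    edges <- edges[, c("source", "target", "sign", "weight")]
    edges$source <- as.character(edges$source)
    edges$target <- as.character(edges$target)
    edges$sign <- as.integer(edges$sign)
    edges$weight <- as.numeric(edges$weight)
  }
  g <- structure(list(nodes = character(), edges = edges, directed = TRUE),
                 class = "pkn_graph")
  g$nodes <- sort(unique(c(as.character(nodes), edges$source, edges$target)))
  validate_pkn(canonicalize_pkn(g))
}

canonicalize_pkn <- function(g) {
  e <- g$edges
  if (nrow(e)) {
    key <- paste(e$source, e$target, e$sign, sep = "\r")
    dup <- duplicated(key)
    if (any(dup)) {
      first_w <- e$weight[match(key[dup], key)]
      if (any(abs(first_w - e$weight[dup]) > 0)) {
        warning("duplicate (source, target, sign) edges with differing weights; keeping the first weight")
      }
      e <- e[!dup, , drop = FALSE]
    }
    e <- e[order(e$source, e$target, e$sign), , drop = FALSE]
    rownames(e) <- NULL
  }
  g$edges <- e
  g
}

validate_pkn <- function(g) {
  stopifnot(inherits(g, "pkn_graph"))
  e <- g$edges
  if (any(!nzchar(g$nodes))) stop("node identifiers must be non-empty")
  if (any(grepl("[ \t]", g$nodes))) {
    stop("node identifiers may not contain whitespace or tab characters")
  }
  if (nrow(e)) {
    if (!all(e$sign %in% c(-1L, 1L))) stop("edge sign must be -1 or +1")
    if (any(!is.finite(e$weight))) stop("edge weights must be finite")
    miss <- setdiff(unique(c(e$source, e$target)), g$nodes)
    if (length(miss)) stop("edge endpoints missing from node set: ",
                           paste(miss, collapse = ", "))
  }
  g
}

#' @export
print.pkn_graph <- function(x, ...) {
  cat(sprintf("<pkn_graph> %d nodes, %d signed directed edges\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges)) {
    show <- utils::head(x$edges, 6L)
    print(show, row.names = FALSE)
    if (nrow(x$edges) > 6L) cat(sprintf("... and %d more edges\n", nrow(x$edges) - 6L))
  }
  invisible(x)
}

#' Number of edges / nodes in a PKN
#' @param g a `pkn_graph`
#' @return integer count
#' @export
n_edges <- function(g) nrow(g$edges)

#' @rdname n_edges
#' @export
n_nodes <- function(g) length(g$nodes)

edge_keys <- function(g) {
  if (!n_edges(g)) return(character())
  paste(g$edges$source, g$edges$target, g$edges$sign, sep = "\r")
}

#' Structural equality of two PKNs
#'
#' Graphs are equal when they have the same node set and the same
#' (source, target, sign, weight) edge multiset, irrespective of order.
#' @param a,b `pkn_graph` objects
#' @param tol numeric tolerance on weights
#' @return logical
#' @export
pkn_equal <- function(a, b, tol = 1e-12) {
  if (!identical(a$nodes, b$nodes)) return(FALSE)
  if (n_edges(a) != n_edges(b)) return(FALSE)
  if (!identical(edge_keys(a), edge_keys(b))) return(FALSE)
  all(abs(a$edges$weight - b$edges$weight) <= tol)
}

#' Restrict a PKN to a node set
#'
#' Keeps the nodes in `keep` that are present in the graph and every edge
#' whose two endpoints are both retained. `keep` may contain unknown node
#' identifiers; they are ignored.
#'
#' @param g a `pkn_graph`
#' @param keep character vector of node identifiers to retain
#' @return a `pkn_graph`
#' @export
induced_subgraph <- function(g, keep) {
  keep <- intersect(g$nodes, as.character(keep))
  e <- g$edges[g$edges$source %in% keep & g$edges$target %in% keep, , drop = FALSE]
  pkn_graph(e, nodes = keep)
}

relation_to_sign <- function(tok) {
  out <- c("1" = 1L, "+1" = 1L, "+" = 1L, "activate" = 1L,
           "-1" = -1L, "-" = -1L, "inhibit" = -1L)[tolower(tok)]
  unname(out)
}

#' Read a PKN from a SIF file
#'
#' Each non-empty line must hold at least three whitespace- or tab-separated
#' tokens: `source relation target [weight]`. Accepted relation tokens are
#' `1`, `-1`, `+`, `-`, `activate`, `inhibit` (case-insensitive). Duplicate
#' (source, target, sign) lines are collapsed.
#'
#' @param path file path
#' @return a `pkn_graph`
#' @export
read_sif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (!length(keep)) return(pkn_graph())
  rows <- lapply(keep, function(i) {
    toks <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(toks) < 3L) {
      stop(sprintf("line %d: expected at least 3 tokens, got %d", i, length(toks)))
    }
    sgn <- relation_to_sign(toks[2L])
    if (is.na(sgn)) {
      stop(sprintf("line %d: unmappable relation token '%s'", i, toks[2L]))
    }
    if (!nzchar(toks[1L]) || !nzchar(toks[3L])) {
      stop(sprintf("line %d: empty endpoint identifier", i))
    }
    w <- if (length(toks) >= 4L) suppressWarnings(as.numeric(toks[4L])) else 1
    if (is.na(w)) stop(sprintf("line %d: non-numeric weight '%s'", i, toks[4L]))
    data.frame(source = toks[1L], target = toks[3L], sign = sgn, weight = w,
               stringsAsFactors = FALSE)
  })
  pkn_graph(do.call(rbind, rows))
}

#' Write a PKN to a SIF file
#'
#' Writes `source<TAB>sign<TAB>target` lines, appending a fourth weight column
#' only when some weight differs from 1, so that `read_sif(write_sif(g))`
#' reproduces `g` exactly.
#'
#' @param g a `pkn_graph`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_sif <- function(g, path) {
  e <- g$edges
  if (!nrow(e)) {
    lines <- character()
  } else if (all(e$weight == 1)) {
    lines <- sprintf("%s\t%d\t%s", e$source, e$sign, e$target)
  } else {
    lines <- sprintf("%s\t%d\t%s\t%.15g", e$source, e$sign, e$target, e$weight)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a PKN from an edge-list TSV
#'
#' Alternate reader dialect: a TSV with header
#' `source<TAB>sign<TAB>target<TAB>weight` (weight column optional). Missing,
#' empty or zero signs default to +1 with a warning.
#'
#' @param path file path
#' @return a `pkn_graph`
#' @export
read_edgelist_tsv <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("source", "sign", "target") %in% names(d))) {
    stop("edge-list TSV must have header columns source, sign, target")
  }
  if (!nrow(d)) return(pkn_graph())
  sgn <- suppressWarnings(as.integer(d$sign))
  unsigned <- is.na(sgn) | sgn == 0L
  if (any(unsigned)) {
    warning(sprintf("%d unsigned edge(s) defaulted to sign +1", sum(unsigned)))
    sgn[unsigned] <- 1L
  }
  w <- if ("weight" %in% names(d)) suppressWarnings(as.numeric(d$weight)) else rep(1, nrow(d))
  w[is.na(w)] <- 1
  pkn_graph(data.frame(source = d$source, target = d$target, sign = sgn,
                       weight = w, stringsAsFactors = FALSE))
}

#' Convert a PKN to an igraph object
#'
#' Edge attributes `sign` and `weight` are carried over; parallel signed
#' edges become parallel igraph edges.
#' @param g a `pkn_graph`
#' @param node_scores optional named numeric vector attached as a `score`
#'   vertex attribute
#' @return an `igraph` graph
#' @export
as_igraph <- function(g, node_scores = NULL) {
  ig <- igraph::make_empty_graph(n = 0, directed = TRUE)
  ig <- igraph::add_vertices(ig, length(g$nodes), name = g$nodes)
  if (n_edges(g)) {
    idx <- rbind(match(g$edges$source, g$nodes), match(g$edges$target, g$nodes))
    ig <- igraph::add_edges(ig, as.vector(idx),
                            sign = g$edges$sign, weight = g$edges$weight)
  }
  if (!is.null(node_scores)) {
    sc <- rep(NA_real_, length(g$nodes))
    hit <- match(names(node_scores), g$nodes)
    sc[hit[!is.na(hit)]] <- node_scores[!is.na(hit)]
    ig <- igraph::set_vertex_attr(ig, "score", value = sc)
  }
  ig
}

#' Export a contextualized network (or bare PKN) to GraphML
#'
#' Writes a GraphML document carrying `sign` and `weight` edge attributes and,
#' when node scores are present, a `score` node attribute. The file is
#' parseable by any standard GraphML reader.
#'
#' @param network a `contextualized_network` or `pkn_graph`
#' @param path output file path
#' @return `path`, invisibly
#' @export
export_graphml <- function(network, path) {
  if (inherits(network, "contextualized_network")) {
    ig <- as_igraph(network$subgraph, node_scores = network$node_scores)
  } else {
    ig <- as_igraph(network)
  }
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}
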