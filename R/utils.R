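# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards. seed = NULL leaves the RNG untouched.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(code)
}

# Adjacency list over edge row indices: for each node, the indices of edges
# leaving it (or entering it when reverse = TRUE). Self-loops optionally
# dropped because they never lie on a simple source->target path.
edge_adjacency <- function(g, reverse = FALSE, drop_self_loops = TRUE) {
  e <- g$edges
  idx <- seq_len(nrow(e))
  if (drop_self_loops && nrow(e)) idx <- idx[e$source != e$target]
  by <- if (reverse) e$target[idx] else e$source[idx]
  adj <- split(idx, factor(by, levels = g$nodes))
  names(adj) <- g$nodes
  adj
}

# Hop distances from the node set `from` over unique (u, v) arcs.
# Returns a named integer vector; unreachable nodes get NA.
bfs_hops <- function(g, from, reverse = FALSE) {
  dist <- stats::setNames(rep(NA_integer_, length(g$nodes)), g$nodes)
  from <- intersect(from, g$nodes)
  if (!length(from)) return(dist)
  e <- g$edges[g$edges$source != g$edges$target, , drop = FALSE]
  succ <- if (reverse) split(e$source, factor(e$target, levels = g$nodes))
          else split(e$target, factor(e$source, levels = g$nodes))
  dist[from] <- 0L
  frontier <- from
  d <- 0L
  while (length(frontier)) {
    nxt <- unique(unlist(succ[frontier], use.names = FALSE))
    nxt <- nxt[is.na(dist[nxt])]
    d <- d + 1L
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

# Row-normalized transition matrix over |weight| (diffusion is sign-blind).
# Parallel edges accumulate. reverse = TRUE builds the matrix of the
# edge-reversed graph. Dangling rows are left as zero; callers decide the
# dangling dialect.
transition_matrix <- function(g, reverse = FALSE) {
  n <- length(g$nodes)
  P <- matrix(0, n, n, dimnames = list(g$nodes, g$nodes))
  e <- g$edges
  if (nrow(e)) {
    i <- match(if (reverse) e$target else e$source, g$nodes)
    j <- match(if (reverse) e$source else e$target, g$nodes)
    for (k in seq_along(i)) P[i[k], j[k]] <- P[i[k], j[k]] + abs(e$weight[k])
    rs <- rowSums(P)
    nz <- rs > 0
    P[nz, ] <- P[nz, , drop = FALSE] / rs[nz]
  }
  P
}

# Positive restart/seed distribution over graph nodes from a named
# nonnegative weight vector; errors when nothing usable remains.
seed_distribution <- function(g, seeds) {
  w <- stats::setNames(rep(0, length(g$nodes)), g$nodes)
  seeds <- seeds[names(seeds) %in% g$nodes]
  if (any(seeds < 0)) stop("seed weights must be nonnegative")
  w[names(seeds)] <- w[names(seeds)] + seeds
  if (sum(w) <= 0) stop("no positive seed weight on any PKN node")
  w / sum(w)
}
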