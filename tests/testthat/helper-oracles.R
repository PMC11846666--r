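# Independent oracles used to cross-check the package implementations.
# They deliberately take different routes: igraph path enumeration for the
# topology methods, dense linear algebra for diffusion, literal-invariant
# state enumeration for causal selection, exact combinatorics for ORA.

# Random signed directed multigraph, independent of the fixtures module.
random_pkn <- function(n_nodes, n_edges, seed, p_neg = 0.4,
                       weights = FALSE) {
  withr::with_seed(seed, {
    nodes <- paste0("v", seq_len(n_nodes))
    src <- sample(nodes, n_edges, replace = TRUE)
    tgt <- sample(nodes, n_edges, replace = TRUE)
    keep <- src != tgt
    e <- data.frame(source = src[keep], target = tgt[keep],
                    sign = ifelse(stats::runif(sum(keep)) < p_neg, -1L, 1L),
                    weight = if (weights) stats::runif(sum(keep), 0.2, 2) else 1,
                    stringsAsFactors = FALSE)
    pkn_graph(e, nodes = nodes)
  })
}

# All simple directed node paths from -> to with at most max_len edges,
# via igraph. Returns a list of character vectors of node names.
oracle_node_paths <- function(pkn, from, to, max_len) {
  ig <- as_igraph(pkn)
  if (!(from %in% pkn$nodes) || !(to %in% pkn$nodes) || from == to) return(list())
  ps <- igraph::all_simple_paths(ig, from, to, mode = "out", cutoff = max_len)
  lapply(ps, function(p) names(p))
}

# Edge rows of pkn$edges lying between consecutive nodes of a node path
# (all parallel signed variants).
path_edge_rows <- function(pkn, nodes) {
  out <- integer()
  for (i in seq_len(length(nodes) - 1L)) {
    out <- c(out, which(pkn$edges$source == nodes[i] &
                          pkn$edges$target == nodes[i + 1L]))
  }
  out
}

# Edge-index union of all simple paths <= max_len between the seed sets.
oracle_all_paths_edges <- function(pkn, sources, targets, max_len) {
  keep <- integer()
  for (s in sources) for (t in targets) {
    for (np in oracle_node_paths(pkn, s, t, max_len)) {
      keep <- c(keep, path_edge_rows(pkn, np))
    }
  }
  sort(unique(keep))
}

# Edge-index union of all minimum-hop paths between the seed sets.
oracle_shortest_edges <- function(pkn, sources, targets) {
  keep <- integer()
  for (s in sources) for (t in targets) {
    nps <- oracle_node_paths(pkn, s, t, length(pkn$nodes) - 1L)
    if (!length(nps)) next
    lens <- vapply(nps, length, integer(1)) - 1L
    for (np in nps[lens == min(lens)]) keep <- c(keep, path_edge_rows(pkn, np))
  }
  sort(unique(keep))
}

# Edge-index union of sign-consistent paths: expands each node path into all
# parallel-edge combinations and keeps combos whose sign product matches
# source sign x target sign.
oracle_sign_consistent_edges <- function(pkn, source_signs, target_signs,
                                         max_len, shortest_only = FALSE) {
  keep <- integer()
  for (s in names(source_signs)) for (t in names(target_signs)) {
    nps <- oracle_node_paths(pkn, s, t, max_len)
    if (shortest_only && length(nps)) {
      lens <- vapply(nps, length, integer(1)) - 1L
      nps <- nps[lens == min(lens)]
    }
    want <- source_signs[[s]] * target_signs[[t]]
    for (np in nps) {
      steps <- lapply(seq_len(length(np) - 1L), function(i) {
        which(pkn$edges$source == np[i] & pkn$edges$target == np[i + 1L])
      })
      combos <- expand.grid(steps)
      for (r in seq_len(nrow(combos))) {
        idx <- as.integer(combos[r, ])
        if (prod(pkn$edges$sign[idx]) == want) keep <- c(keep, idx)
      }
    }
  }
  sort(unique(keep))
}

# Dense transition matrix built from scratch (independent of the package's
# transition_matrix): row-normalized |weight| adjacency.
oracle_transition <- function(pkn, reverse = FALSE) {
  n <- length(pkn$nodes)
  P <- matrix(0, n, n, dimnames = list(pkn$nodes, pkn$nodes))
  e <- pkn$edges
  for (k in seq_len(nrow(e))) {
    i <- if (reverse) e$target[k] else e$source[k]
    j <- if (reverse) e$source[k] else e$target[k]
    P[i, j] <- P[i, j] + abs(e$weight[k])
  }
  for (i in seq_len(n)) if (sum(P[i, ]) > 0) P[i, ] <- P[i, ] / sum(P[i, ])
  P
}

# Exact PPR by dense linear solve, with dangling rows replaced by the restart
# distribution: x = (1 - a) (I - a t(Ptilde))^-1 r.
oracle_ppr <- function(pkn, seeds, damping, reverse = FALSE) {
  P <- oracle_transition(pkn, reverse)
  r <- stats::setNames(rep(0, length(pkn$nodes)), pkn$nodes)
  r[names(seeds)] <- seeds
  r <- r / sum(r)
  dang <- rowSums(P) == 0
  P[dang, ] <- matrix(r, sum(dang), length(r), byrow = TRUE)
  x <- solve(diag(length(r)) - damping * t(P), (1 - damping) * r)
  stats::setNames(as.vector(x), pkn$nodes)
}

# Exact heat kernel by dense matrix exponential of the random-walk Laplacian,
# in the mass-transport orientation (adjoint applied to the seed distribution).
oracle_heat <- function(pkn, seeds, t) {
  P <- oracle_transition(pkn)
  s <- stats::setNames(rep(0, length(pkn$nodes)), pkn$nodes)
  s[names(seeds)] <- seeds
  s <- s / sum(s)
  L <- diag(length(s)) - P
  x <- as.vector(t(as.matrix(Matrix::expm(-t * L))) %*% s)
  x <- pmax(x, 0)
  stats::setNames(x / sum(x), pkn$nodes)
}

# Exact one-sided hypergeometric tail by direct combinatorial sum (all values
# are exactly representable in doubles for N <= 30).
oracle_hyper_tail <- function(N, K, n, k) {
  i <- k:min(K, n)
  if (k > min(K, n)) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Naive layer-by-layer re-implementation of recursive propagation that
# materializes each layer explicitly (lists of frontier nodes), used as an
# oracle for the package's vectorized version. Zero-score nodes are scored
# but excluded as parents; pruning keeps only strictly sign-compatible edges.
oracle_recursive <- function(pkn, target_signs, n_layers) {
  e <- pkn$edges[pkn$edges$source != pkn$edges$target, , drop = FALSE]
  targets <- intersect(names(target_signs), pkn$nodes)
  scores <- as.list(stats::setNames(as.numeric(target_signs[targets]), targets))
  for (layer in seq_len(n_layers)) {
    frontier <- list()
    for (u in setdiff(pkn$nodes, names(scores))) {
      vals <- c()
      for (r in which(e$source == u)) {
        v <- e$target[r]
        if (v %in% names(scores) && scores[[v]] != 0) {
          vals <- c(vals, e$sign[r] * scores[[v]])
        }
      }
      if (length(vals)) frontier[[u]] <- mean(vals)
    }
    if (!length(frontier)) break
    scores <- c(scores, frontier)
  }
  unlist(scores)
}

# Tie-break comparator shared by the causal oracle: higher objective, then
# fewer edges, then lexicographically smaller sorted edge index vector.
oracle_beats <- function(obj, idx, best_obj, best_idx, eps = 1e-12) {
  if (obj > best_obj + eps) return(TRUE)
  if (obj < best_obj - eps) return(FALSE)
  if (length(idx) != length(best_idx)) return(length(idx) < length(best_idx))
  d <- which(idx != best_idx)
  length(d) > 0 && idx[d[1L]] < best_idx[d[1L]]
}

# Brute-force causal-selection oracle: enumerates every edge subset and every
# {-1,+1} state assignment over the touched non-source nodes, checks the
# causal-assignment invariants literally, and keeps the best objective under
# the deterministic tie-break.
oracle_causal <- function(pkn, source_signs, target_signs, lambda) {
  eidx <- which(pkn$edges$source != pkn$edges$target)
  e <- pkn$edges[eidx, , drop = FALSE]
  m <- nrow(e)
  nodes <- pkn$nodes
  src_names <- names(source_signs)
  best <- list(objective = 0, idx = integer())
  bits <- if (m) 2^(seq_len(m) - 1L) else numeric()
  for (mask in 0:(2^m - 1)) {
    sel <- if (mask == 0) integer() else which(bitwAnd(mask, bits) > 0)
    sub <- e[sel, , drop = FALSE]
    idx <- sort(eidx[sel])
    touched <- unique(c(sub$source, sub$target))
    free <- setdiff(touched, src_names)
    # structural invariants that do not depend on the state values:
    # every touched non-source node (necessarily nonzero) needs an active
    # incoming edge, and every active edge must start on a path from a source
    if (!all(free %in% sub$target)) next
    reach <- src_names
    repeat {
      add <- setdiff(unique(sub$target[sub$source %in% reach]), reach)
      if (!length(add)) break
      reach <- c(reach, add)
    }
    if (nrow(sub) && !all(sub$source %in% reach)) next
    # enumerate +-1 states over free touched nodes, vectorized across states
    n_free <- length(free)
    combos <- if (n_free) {
      as.matrix(expand.grid(rep(list(c(-1L, 1L)), n_free)))
    } else matrix(integer(), 1L, 0L)
    S <- matrix(0L, nrow(combos), length(nodes), dimnames = list(NULL, nodes))
    S[, src_names] <- matrix(source_signs, nrow(combos), length(src_names),
                             byrow = TRUE)
    if (n_free) S[, free] <- combos
    ok <- rep(TRUE, nrow(combos))
    for (r in seq_len(nrow(sub))) {
      ok <- ok & (S[, sub$source[r]] * sub$sign[r] == S[, sub$target[r]])
    }
    if (!any(ok)) next
    tm <- S[ok, names(target_signs), drop = FALSE]
    expl <- rowSums(tm == matrix(target_signs, nrow(tm), length(target_signs),
                                 byrow = TRUE))
    best_expl <- max(expl)
    obj <- best_expl - lambda * length(idx)
    if (oracle_beats(obj, idx, best$objective, best$idx)) {
      best <- list(objective = obj, idx = idx)
    }
  }
  best
}
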