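# Recursive upstream propagation and causal sign-consistency selection.
# The selector optimizes explained targets minus an edge penalty over all
# feasible causal assignments; at desk scale it is solved exactly by edge
# subset enumeration (node states are uniquely forced by propagation from the
# fixed source signs), with a path-greedy fallback for larger graphs.

#' Recursive upstream score propagation
#'
#' Layer 0 assigns each target its measured sign. Each subsequent layer scores
#' every still-unscored node with at least one scored successor as the mean,
#' over its out-edges into scored successors, of edge sign x successor score.
#' Zero-score nodes propagate no further: they are excluded as propagation
#' parents and their incident edges are pruned. After scoring, every edge
#' whose endpoint scores are sign-incompatible (edge sign x downstream score
#' disagreeing in sign with the upstream score) is pruned, and the pruned
#' graph restricted to scored nodes is returned.
#'
#' @param pkn a `pkn_graph`
#' @param target_signs named integer vector with values in \{-1, +1\}; at
#'   least one name must be a PKN node
#' @param n_layers number of upstream layers to score (>= 1)
#' @return list with `scores` (named numeric in [-1, 1]) and `network`
#'   (the pruned `contextualized_network`)
#' @export
recursive_propagation <- function(pkn, target_signs, n_layers = 5L) {
  stopifnot(all(target_signs %in% c(-1L, 1L)), n_layers >= 1L)
  targets <- intersect(names(target_signs), pkn$nodes)
  if (!length(targets)) stop("no target present in the PKN")
  e <- pkn$edges[pkn$edges$source != pkn$edges$target, , drop = FALSE]
  scores <- stats::setNames(as.numeric(target_signs[targets]), targets)
  for (layer in seq_len(n_layers)) {
    scored <- names(scores)
    usable <- scored[scores[scored] != 0]   # zero scores propagate no further
    cand <- e[!(e$source %in% scored) & e$target %in% usable, , drop = FALSE]
    if (!nrow(cand)) break
    contrib <- cand$sign * scores[cand$target]
    new_scores <- tapply(contrib, cand$source, mean)
    scores <- c(scores, stats::setNames(as.numeric(new_scores), names(new_scores)))
  }
  scored <- names(scores)
  keep_e <- pkn$edges$source %in% scored & pkn$edges$target %in% scored &
    pkn$edges$source != pkn$edges$target
  su <- scores[pkn$edges$source]
  sv <- pkn$edges$sign * scores[pkn$edges$target]
  compatible <- !is.na(su) & !is.na(sv) & su != 0 & sv != 0 & sign(su) == sign(sv)
  keep_e <- keep_e & compatible
  sub <- pkn_graph(pkn$edges[keep_e, , drop = FALSE],
                   nodes = scored)
  net <- contextualized_network(sub, pkn, node_scores = scores,
                                method = "recursive_propagation",
                                parameters = list(n_layers = n_layers))
  list(scores = scores, network = net)
}

# --- causal selection --------------------------------------------------------

new_causal_assignment <- function(node_state, active_edges, objective,
                                  explained_targets) {
  structure(list(node_state = node_state, active_edges = active_edges,
                 objective = objective, explained_targets = explained_targets),
            class = "causal_assignment")
}

#' @export
print.causal_assignment <- function(x, ...) {
  cat(sprintf("<causal_assignment> objective=%.4g, %d active edge(s), %d explained target(s)\n",
              x$objective, nrow(x$active_edges), length(x$explained_targets)))
  invisible(x)
}

# Node states forced by propagating fixed source signs over an active edge
# subset. Returns NULL when the subset admits no valid causal assignment:
# a state conflict, or an active edge whose tail never becomes nonzero
# (i.e. the edge is not on a directed path from a nonzero source).
propagate_states <- function(nodes, src, tgt, sgn, edge_idx, source_signs) {
  state <- stats::setNames(rep(0L, length(nodes)), nodes)
  state[names(source_signs)] <- as.integer(source_signs)
  repeat {
    changed <- FALSE
    for (ei in edge_idx) {
      u <- src[ei]; v <- tgt[ei]
      if (state[[u]] != 0L) {
        want <- state[[u]] * sgn[ei]
        if (state[[v]] == 0L) {
          if (v %in% names(source_signs)) return(NULL)  # would override a fixed source
          state[[v]] <- want
          changed <- TRUE
        } else if (state[[v]] != want) {
          return(NULL)
        }
      }
    }
    if (!changed) break
  }
  for (ei in edge_idx) if (state[[src[ei]]] == 0L) return(NULL)
  state
}

causal_objective <- function(state, target_signs, lambda, n_edges) {
  explained <- names(target_signs)[state[names(target_signs)] == target_signs]
  list(objective = length(explained) - lambda * n_edges, explained = explained)
}

# TRUE when candidate (obj, edge index set) beats the incumbent under the
# deterministic tie-break: higher objective, then fewer edges, then
# lexicographically smaller sorted edge index vector.
beats <- function(obj, idx, best_obj, best_idx, eps = 1e-12) {
  if (obj > best_obj + eps) return(TRUE)
  if (obj < best_obj - eps) return(FALSE)
  if (length(idx) != length(best_idx)) return(length(idx) < length(best_idx))
  d <- which(idx != best_idx)
  length(d) > 0 && idx[d[1L]] < best_idx[d[1L]]
}

#' Causal sign-assignment selection
#'
#' Selects the set of active edges (and the node states they force) that
#' maximizes `(number of targets whose state matches its measured sign) -
#' lambda x (number of active edges)` over all valid causal assignments:
#' active edges connect nonzero nodes with `state(u) x sign == state(v)`,
#' every nonzero non-source node has an active incoming edge, and every
#' active edge lies on a directed path from a nonzero source. Node states on
#' sources are fixed to `source_signs`. The exhaustive solver enumerates all
#' edge subsets and is exact, with deterministic tie-breaking toward fewer
#' active edges and then the lexicographically smallest edge set; the greedy
#' solver adds sign-consistent source-to-target paths while the objective
#' improves.
#'
#' @param pkn a `pkn_graph`
#' @param source_signs,target_signs named integer vectors with values in
#'   \{-1, +1\}
#' @param lambda edge penalty, > 0; default 0.1
#' @param solver `"exhaustive"` (exact, requires at most
#'   `max_edges_exhaustive` non-self-loop edges) or `"greedy"`
#' @param max_edges_exhaustive edge cap for the exhaustive solver; default 15
#' @param max_len,cap path bounds used by the greedy solver
#' @return a `causal_assignment`; when no path can explain any target the
#'   assignment has zero explained targets and an empty edge set (objective 0)
#' @export
causal_selection <- function(pkn, source_signs, target_signs, lambda = 0.1,
                             solver = c("exhaustive", "greedy"),
                             max_edges_exhaustive = 15L,
                             max_len = NULL, cap = 1e5) {
  solver <- match.arg(solver)
  stopifnot(lambda > 0,
            all(source_signs %in% c(-1L, 1L)), all(target_signs %in% c(-1L, 1L)))
  seeds <- check_seed_nodes(pkn, names(source_signs), names(target_signs))
  source_signs <- source_signs[seeds$sources]
  target_signs <- target_signs[seeds$targets]
  e <- pkn$edges
  usable <- which(e$source != e$target)
  src <- e$source; tgt <- e$target; sgn <- e$sign
  nodes <- pkn$nodes

  score_subset <- function(idx) {
    state <- propagate_states(nodes, src, tgt, sgn, idx, source_signs)
    if (is.null(state)) return(NULL)
    c(list(state = state),
      causal_objective(state, target_signs, lambda, length(idx)))
  }

  base <- score_subset(integer())
  best <- list(idx = integer(), state = base$state,
               objective = base$objective, explained = base$explained)

  if (solver == "exhaustive") {
    m <- length(usable)
    if (m > max_edges_exhaustive) {
      stop(sprintf("%d edges exceeds the exhaustive cap of %d; use solver = 'greedy'",
                   m, max_edges_exhaustive))
    }
    if (m > 0L) {
      bits <- 2^(seq_len(m) - 1L)
      for (mask in seq_len(2^m - 1L)) {
        idx <- usable[bitwAnd(mask, bits) > 0]
        res <- score_subset(idx)
        if (is.null(res)) next
        if (beats(res$objective, idx, best$objective, best$idx)) {
          best <- list(idx = idx, state = res$state,
                       objective = res$objective, explained = res$explained)
        }
      }
    }
  } else {
    if (is.null(max_len)) max_len <- length(nodes) - 1L
    counter <- new.env(parent = emptyenv()); counter$n <- 0L
    cand <- list()
    for (s in seeds$sources) {
      for (t in seeds$targets) {
        paths <- enumerate_simple_paths(pkn, s, t, max_len, counter, cap)
        want <- source_signs[[s]] * target_signs[[t]]
        for (p in paths) if (path_sign(pkn, p) == want) cand[[length(cand) + 1L]] <- sort(p)
      }
    }
    repeat {
      improved <- FALSE
      step <- best
      for (p in cand) {
        idx <- sort(union(best$idx, p))
        if (identical(idx, best$idx)) next
        res <- score_subset(idx)
        if (is.null(res)) next
        if (beats(res$objective, idx, step$objective, step$idx)) {
          step <- list(idx = idx, state = res$state,
                       objective = res$objective, explained = res$explained)
          improved <- step$objective > best$objective + 1e-12
        }
      }
      if (!improved) break
      best <- step
    }
  }
  new_causal_assignment(best$state, e[best$idx, , drop = FALSE],
                        best$objective, best$explained)
}

#' Two-phase composite contextualization
#'
#' Phase 1 restricts the PKN to the union of sign-consistent simple paths of
#' at most `max_len` edges (a topology prefilter); phase 2 runs
#' [causal_selection()] on the phase-1 graph, exhaustively when it is small
#' enough and greedily otherwise. The output carries a node-to-layer map
#' (minimum hop distance from any source within the selected network) as node
#' scores, giving a hierarchical signaling model.
#'
#' @inheritParams causal_selection
#' @param max_len phase-1 maximum path length in edges
#' @return a `contextualized_network`; node scores hold the layer indices
#' @export
two_phase_composite <- function(pkn, source_signs, target_signs, max_len = 5L,
                                lambda = 0.1, max_edges_exhaustive = 15L,
                                cap = 1e5) {
  phase1 <- sign_consistent_paths_network(pkn, source_signs, target_signs,
                                          mode = max_len, cap = cap)
  g1 <- phase1$subgraph
  if (!n_edges(g1)) {
    return(contextualized_network(pkn_graph(), pkn, method = "two_phase_composite",
                                  parameters = list(max_len = max_len, lambda = lambda),
                                  notes = "phase 1 empty: no sign-consistent path"))
  }
  n_usable <- sum(g1$edges$source != g1$edges$target)
  solver <- if (n_usable <= max_edges_exhaustive) "exhaustive" else "greedy"
  ss <- source_signs[names(source_signs) %in% g1$nodes]
  ts <- target_signs[names(target_signs) %in% g1$nodes]
  sel <- causal_selection(g1, ss, ts, lambda = lambda, solver = solver,
                          max_edges_exhaustive = max_edges_exhaustive,
                          max_len = max_len, cap = cap)
  sub <- pkn_graph(sel$active_edges)
  layers <- bfs_hops(sub, intersect(names(ss), sub$nodes))
  layers <- layers[!is.na(layers)]
  contextualized_network(sub, pkn, node_scores = as.numeric(layers) |>
                           stats::setNames(names(layers)),
                         method = "two_phase_composite",
                         parameters = list(max_len = max_len, lambda = lambda,
                                           solver = solver),
                         notes = sprintf("objective=%.6g", sel$objective))
}
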