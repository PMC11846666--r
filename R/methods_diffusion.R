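# Diffusion-based contextualization. Diffusion is sign-blind: edge weights
# enter as nonnegative transition propensities via |weight|; signed reasoning
# is the business of the topology and causal families.

new_diffusion_scores <- function(scores, converged, iterations, parameters) {
  structure(list(scores = scores, converged = converged,
                 iterations = iterations, parameters = parameters),
            class = "diffusion_scores")
}

#' @export
print.diffusion_scores <- function(x, ...) {
  cat(sprintf("<diffusion_scores> %d nodes, converged=%s (%d iterations)\n",
              length(x$scores), x$converged, x$iterations))
  invisible(x)
}

#' Personalized PageRank
#'
#' Power iteration on the row-normalized |weight| adjacency matrix (the
#' edge-reversed adjacency when `direction = "reverse"`), with restart
#' distribution proportional to the seed weights. Dangling nodes redirect
#' their mass to the restart distribution. Iteration stops when the L1 change
#' falls below `tol`; if `max_iter` is reached first, a warning is raised and
#' the non-converged scores are still returned with `converged = FALSE`.
#'
#' @param pkn a `pkn_graph`
#' @param seeds named nonnegative numeric vector; at least one positive weight
#'   must fall on a PKN node
#' @param damping restart-complement alpha in (0, 1); default 0.85
#' @param tol L1 convergence tolerance; default 1e-8
#' @param max_iter maximum power iterations; default 1000
#' @param direction `"forward"` or `"reverse"`
#' @param init optional starting probability vector (named over PKN nodes);
#'   the converged scores do not depend on it (default: the restart
#'   distribution)
#' @return a `diffusion_scores` object; scores are nonnegative and sum to 1
#' @export
personalized_pagerank <- function(pkn, seeds, damping = 0.85, tol = 1e-8,
                                  max_iter = 1000L, direction = c("forward", "reverse"),
                                  init = NULL) {
  direction <- match.arg(direction)
  if (damping <= 0 || damping >= 1) stop("damping must be in (0, 1)")
  r <- seed_distribution(pkn, seeds)
  P <- transition_matrix(pkn, reverse = direction == "reverse")
  dangling <- rowSums(P) == 0
  x <- if (is.null(init)) r else {
    stopifnot(length(init) == length(r), all(init >= 0), sum(init) > 0)
    init <- init[pkn$nodes]
    init / sum(init)
  }
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    x_new <- damping * (as.vector(crossprod(P, x)) + sum(x[dangling]) * r) +
      (1 - damping) * r
    if (sum(abs(x_new - x)) < tol) {
      x <- x_new
      converged <- TRUE
      break
    }
    x <- x_new
  }
  if (!converged) warning("personalized PageRank did not converge within max_iter")
  new_diffusion_scores(stats::setNames(x, pkn$nodes), converged, iter,
                       list(damping = damping, tol = tol,
                            max_iter = max_iter, direction = direction))
}

#' Diffusion subnetwork by percentile threshold
#'
#' Shared extraction used by the PPR and heat-diffusion contextualization
#' methods: nodes whose combined score reaches the given percentile (and is
#' strictly positive) are kept, and the induced subgraph is returned with the
#' combined scores attached.
#' @noRd
diffusion_subnetwork <- function(pkn, combined, percentile, method, parameters,
                                 notes = character()) {
  if (percentile < 0 || percentile > 100) stop("percentile must be in [0, 100]")
  thr <- stats::quantile(combined, percentile / 100, names = FALSE, type = 7)
  keep <- names(combined)[combined >= thr & combined > 0]
  sub <- induced_subgraph(pkn, keep)
  contextualized_network(sub, pkn, node_scores = combined[sub$nodes],
                         method = method, parameters = parameters,
                         notes = notes)
}

#' Two-sided personalized-PageRank subnetwork
#'
#' Computes forward PPR seeded by the absolute source scores and reverse PPR
#' seeded by the absolute target scores; the combined node score is the
#' geometric mean of the two (scale-comparable to each component). Nodes at or
#' above `percentile` of the combined scores are kept and the induced
#' subgraph returned with scores attached.
#'
#' @param pkn a `pkn_graph`
#' @param source_scores,target_scores `measurement_set`s; both must intersect
#'   the PKN nodes
#' @param damping restart-complement alpha; default 0.85
#' @param percentile node-retention percentile in [0, 100]; default 90
#' @param tol,max_iter convergence controls passed to
#'   [personalized_pagerank()]
#' @return a `contextualized_network` with combined scores as node scores
#' @export
ppr_subnetwork <- function(pkn, source_scores, target_scores, damping = 0.85,
                           percentile = 90, tol = 1e-8, max_iter = 1000L) {
  s_seed <- abs(source_scores$scores)
  t_seed <- abs(target_scores$scores)
  fwd <- personalized_pagerank(pkn, s_seed, damping, tol, max_iter, "forward")
  rev <- personalized_pagerank(pkn, t_seed, damping, tol, max_iter, "reverse")
  combined <- sqrt(fwd$scores * rev$scores)
  diffusion_subnetwork(pkn, combined, percentile, "ppr",
                       list(damping = damping, percentile = percentile,
                            tol = tol, max_iter = max_iter),
                       notes = sprintf("ppr converged: forward=%s reverse=%s",
                                       fwd$converged, rev$converged))
}

#' Truncated heat diffusion
#'
#' Node scores are the truncated series
#' `sum_{k=0..K} (-t)^k L^k s / k!` with `L = I - P` the out-degree
#' random-walk Laplacian applied in the mass-transport orientation (the
#' adjoint acts on the seed distribution, so heat flows along edge direction
#' and total mass is conserved on dangling-free graphs), `s` the normalized
#' seed vector; the result is renormalized to sum 1 (tiny negative truncation
#' residues are clamped at zero first). At `t = 0` the normalized seed vector
#' is returned exactly.
#'
#' @param pkn a `pkn_graph`
#' @param seeds named nonnegative numeric vector with at least one positive
#'   weight on a PKN node
#' @param t diffusion time, >= 0
#' @param K truncation order, >= 1; default 20
#' @param direction `"forward"` or `"reverse"` (heat on the edge-reversed
#'   graph)
#' @return a `diffusion_scores` object
#' @export
heat_diffusion <- function(pkn, seeds, t = 1, K = 20L,
                           direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  if (t < 0) stop("t must be >= 0")
  if (K < 1) stop("K must be >= 1")
  s <- seed_distribution(pkn, seeds)
  if (t == 0) {
    return(new_diffusion_scores(stats::setNames(s, pkn$nodes), TRUE, 0L,
                                list(t = t, K = K, direction = direction)))
  }
  P <- transition_matrix(pkn, reverse = direction == "reverse")
  L <- diag(length(s)) - P
  term <- s
  acc <- s
  for (k in seq_len(K)) {
    term <- as.vector(crossprod(L, term)) * (-t / k)
    acc <- acc + term
  }
  acc[acc < 0 & acc > -1e-9] <- 0
  if (any(acc < 0)) {
    warning("truncation order too low for this t: negative scores clamped")
    acc[acc < 0] <- 0
  }
  acc <- acc / sum(acc)
  new_diffusion_scores(stats::setNames(acc, pkn$nodes), TRUE, K,
                       list(t = t, K = K, direction = direction))
}

#' Two-sided heat-diffusion subnetwork
#'
#' Mirrors [ppr_subnetwork()]: forward heat from the absolute source scores,
#' reverse heat from the absolute target scores, geometric-mean combination,
#' percentile threshold, induced subgraph.
#'
#' @inheritParams ppr_subnetwork
#' @param t diffusion time
#' @param K truncation order
#' @return a `contextualized_network`
#' @export
heat_subnetwork <- function(pkn, source_scores, target_scores, t = 1, K = 20L,
                            percentile = 90) {
  fwd <- heat_diffusion(pkn, abs(source_scores$scores), t, K, "forward")
  rev <- heat_diffusion(pkn, abs(target_scores$scores), t, K, "reverse")
  combined <- sqrt(fwd$scores * rev$scores)
  diffusion_subnetwork(pkn, combined, percentile, "heat_diffusion",
                       list(t = t, K = K, percentile = percentile))
}
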