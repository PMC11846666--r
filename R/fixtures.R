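#' Specify a synthetic PKN fixture
#'
#' Parameters of the synthetic generator: an Erdos-Renyi-style signed directed
#' background graph plus one planted simple path per (source, target) pair
#' whose edge signs make the path sign-consistent with the drawn source and
#' target perturbation signs. Defaults describe a sparse signaling-scale toy
#' network: 50 nodes, 5% background edge density, 30% inhibitory edges, two
#' perturbed sources, two downstream readouts, planted paths of three edges,
#' and Gaussian readout noise of sd 0.1 around the unit activity scores.
#'
#' @param n_nodes number of nodes (positive integer)
#' @param edge_prob background edge probability in (0, 1]; may be 0 for a
#'   pure planted-path graph
#' @param neg_sign_frac probability that a background edge is inhibitory
#' @param n_sources,n_targets number of perturbed source nodes and downstream
#'   target nodes
#' @param planted_path_len number of edges in each planted path (>= 1)
#' @param noise_sd standard deviation of Gaussian noise added to target scores
#' @param seed integer RNG seed
#' @return an object of class `fixture_spec`
#' @export
fixture_spec <- function(n_nodes = 50, edge_prob = 0.05, neg_sign_frac = 0.3,
                         n_sources = 2, n_targets = 2, planted_path_len = 3,
                         noise_sd = 0.1, seed = 1L) {
  sp <- structure(list(n_nodes = as.integer(n_nodes),
                       edge_prob = edge_prob,
                       neg_sign_frac = neg_sign_frac,
                       n_sources = as.integer(n_sources),
                       n_targets = as.integer(n_targets),
                       planted_path_len = as.integer(planted_path_len),
                       noise_sd = noise_sd,
                       seed = as.integer(seed)),
                  class = "fixture_spec")
  validate_fixture_spec(sp)
}

validate_fixture_spec <- function(sp) {
  with(sp, {
    if (n_nodes < 1L) stop("n_nodes must be positive")
    if (edge_prob < 0 || edge_prob > 1) stop("edge_prob must be in [0, 1]")
    if (neg_sign_frac < 0 || neg_sign_frac > 1) stop("neg_sign_frac must be in [0, 1]")
    if (n_sources < 1L || n_targets < 1L) stop("n_sources and n_targets must be positive")
    if (n_sources + n_targets > n_nodes) stop("n_sources + n_targets must not exceed n_nodes")
    if (planted_path_len < 1L) stop("planted_path_len must be >= 1")
    if (planted_path_len > n_nodes - 1L) stop("planted_path_len must be <= n_nodes - 1")
    if (noise_sd < 0) stop("noise_sd must be >= 0")
  })
  sp
}

#' Generate a synthetic PKN with planted sign-consistent paths
#'
#' Builds a random signed directed graph and plants, for every
#' (source, target) pair, a simple directed path of `planted_path_len` edges
#' whose sign product satisfies
#' `source sign x product of edge signs == target sign`. Planted paths are
#' node-disjoint from each other whenever the node budget allows (overlap is
#' permitted otherwise, with a message). To keep recovery identifiable,
#' background edges never point into planted intermediate or target nodes, so
#' each planted path is the unique directed route from its source to its
#' target. Fully deterministic given `spec$seed`.
#'
#' @param spec a `fixture_spec`
#' @return list with elements `pkn` (a `pkn_graph`) and `truth` (a
#'   `planted_truth`: `true_edges` data.frame, `paths` list, `source_signs`,
#'   `target_signs`, `offtarget_nodes`)
#' @export
generate_pkn <- function(spec) {
  spec <- validate_fixture_spec(spec)
  with_seed(spec$seed, {
    width <- max(3L, nchar(as.character(spec$n_nodes)))
    nodes <- sprintf(paste0("N%0", width, "d"), seq_len(spec$n_nodes))
    perm <- sample(nodes)
    sources <- sort(perm[seq_len(spec$n_sources)])
    targets <- sort(perm[spec$n_sources + seq_len(spec$n_targets)])
    pool <- setdiff(perm, c(sources, targets))

    source_signs <- stats::setNames(sample(c(-1L, 1L), spec$n_sources, TRUE), sources)
    target_signs <- stats::setNames(sample(c(-1L, 1L), spec$n_targets, TRUE), targets)

    L <- spec$planted_path_len
    n_mid <- L - 1L
    paths <- list()
    planted <- list()
    overlapped <- FALSE
    for (s in sources) {
      for (t in targets) {
        if (n_mid > 0L) {
          if (length(pool) >= n_mid) {
            mid <- pool[seq_len(n_mid)]
            pool <- pool[-seq_len(n_mid)]
          } else {
            overlapped <- TRUE
            mid <- sample(setdiff(nodes, c(sources, targets)), n_mid,
                          replace = FALSE)
          }
        } else {
          mid <- character()
        }
        pnodes <- c(s, mid, t)
        sgn <- sample(c(-1L, 1L), L, replace = TRUE)
        # force overall sign consistency: s_sign * prod(sgn) == t_sign
        sgn[L] <- source_signs[[s]] * target_signs[[t]] * prod(sgn[-L])
        pedges <- data.frame(source = pnodes[-length(pnodes)],
                             target = pnodes[-1L],
                             sign = sgn, weight = 1,
                             stringsAsFactors = FALSE)
        planted[[length(planted) + 1L]] <- pedges
        paths[[length(paths) + 1L]] <- list(source = s, target = t,
                                            nodes = pnodes, edges = pedges)
      }
    }
    if (overlapped) message("node budget exhausted: planted paths share intermediate nodes")
    planted <- do.call(rbind, planted)
    protected <- unique(c(planted$target))  # intermediates and targets

    bg <- NULL
    if (spec$edge_prob > 0) {
      cand <- expand.grid(source = nodes,
                          target = setdiff(nodes, protected),
                          stringsAsFactors = FALSE)
      cand <- cand[cand$source != cand$target, , drop = FALSE]
      keep <- stats::runif(nrow(cand)) < spec$edge_prob
      cand <- cand[keep, , drop = FALSE]
      if (nrow(cand)) {
        cand$sign <- ifelse(stats::runif(nrow(cand)) < spec$neg_sign_frac, -1L, 1L)
        cand$weight <- 1
        bg <- cand
      }
    }
    pkn <- pkn_graph(rbind(planted, bg), nodes = nodes)

    # candidate off-targets: within two hops downstream of a source
    off <- character()
    for (s in sources) {
      d <- bfs_hops(pkn, s)
      near <- setdiff(names(d)[!is.na(d) & d <= 2L & d > 0L], sources)
      if (length(near)) off <- c(off, sample(near, min(2L, length(near))))
    }
    truth <- structure(list(true_edges = pkn_graph(planted)$edges,
                            paths = paths,
                            source_signs = source_signs,
                            target_signs = target_signs,
                            offtarget_nodes = sort(unique(off))),
                       class = "planted_truth")
    validate_planted_truth(truth)
    list(pkn = pkn, truth = truth)
  })
}

validate_planted_truth <- function(truth) {
  for (p in truth$paths) {
    prod_sign <- prod(p$edges$sign)
    if (truth$source_signs[[p$source]] * prod_sign != truth$target_signs[[p$target]]) {
      stop("planted path violates sign consistency (internal error)")
    }
    if (!all(p$edges$source == p$nodes[-length(p$nodes)]) ||
        !all(p$edges$target == p$nodes[-1L])) {
      stop("planted path edges do not form the stated node sequence")
    }
  }
  invisible(truth)
}

#' Generate perturbation-style measurements from a planted truth
#'
#' Source scores are the source perturbation signs (exactly +-1); target
#' scores are the target signs plus Gaussian noise of sd `noise_sd`.
#' Deterministic given `seed`.
#'
#' @param truth a `planted_truth`
#' @param noise_sd Gaussian noise sd on target scores
#' @param seed integer RNG seed
#' @param condition condition label attached to both sets
#' @return list with `sources` and `targets`, both `measurement_set`s
#' @export
generate_measurements <- function(truth, noise_sd = 0.1, seed = 1L,
                                  condition = "") {
  with_seed(seed, {
    src <- measurement_set(truth$source_signs * 1.0, "source", condition)
    tgt_scores <- truth$target_signs * 1.0 +
      stats::rnorm(length(truth$target_signs), 0, noise_sd)
    tgt <- measurement_set(stats::setNames(tgt_scores, names(truth$target_signs)),
                           "target", condition)
    list(sources = src, targets = tgt)
  })
}

#' Generate a drug x cell-line perturbation benchmark fixture
#'
#' Emulates the shape of a single-dose kinase-inhibitor screen: a manifest of
#' `n_drugs` x `n_cell_lines` conditions over one shared PKN. Each drug's
#' primary target is one perturbed source node; a hidden off-target set is
#' drawn from nodes within two hops downstream of that primary target, so
#' off-target recovery is achievable by contextualization rather than pure
#' chance. Defaults follow a 32-inhibitor, 11-cell-line design.
#'
#' @param n_drugs,n_cell_lines positive counts
#' @param spec optional `fixture_spec`; `n_sources` is set to `n_drugs`. The
#'   default uses 250 nodes and background edge probability 0.02.
#' @return list with `manifest` (data.frame drug, cell_line, condition_id),
#'   `pkn`, `truth`, `drugs` (data.frame drug, primary_target) and
#'   `conditions` (per condition: `sources`, `targets` measurement sets and
#'   the hidden `offtargets` node set)
#' @export
generate_panacea_like <- function(n_drugs = 32L, n_cell_lines = 11L,
                                  spec = NULL) {
  n_drugs <- as.integer(n_drugs); n_cell_lines <- as.integer(n_cell_lines)
  if (n_drugs < 1L || n_cell_lines < 1L) stop("counts must be positive")
  if (is.null(spec)) {
    spec <- fixture_spec(n_nodes = max(250L, 8L * n_drugs), edge_prob = 0.02,
                         n_sources = n_drugs, n_targets = 2L,
                         planted_path_len = 3L, noise_sd = 0.1, seed = 7L)
  } else {
    spec$n_sources <- n_drugs
    spec <- validate_fixture_spec(spec)
  }
  gen <- generate_pkn(spec)
  sources <- names(gen$truth$source_signs)
  drugs <- data.frame(drug = sprintf("D%02d", seq_len(n_drugs)),
                      primary_target = sources,
                      stringsAsFactors = FALSE)
  cells <- sprintf("CL%02d", seq_len(n_cell_lines))
  manifest <- expand.grid(drug = drugs$drug, cell_line = cells,
                          stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$drug, manifest$cell_line), , drop = FALSE]
  manifest$condition_id <- paste(manifest$drug, manifest$cell_line, sep = "_")
  rownames(manifest) <- NULL

  # hidden off-target sets, one per drug, fixed across cell lines
  off_by_drug <- with_seed(spec$seed + 1L, {
    out <- list()
    for (i in seq_len(n_drugs)) {
      d <- bfs_hops(gen$pkn, sources[i])
      near <- setdiff(names(d)[!is.na(d) & d > 0L & d <= 2L], sources)
      out[[drugs$drug[i]]] <- if (length(near)) sort(sample(near, min(3L, length(near)))) else character()
    }
    out
  })

  conditions <- list()
  for (k in seq_len(nrow(manifest))) {
    drug <- manifest$drug[k]
    primary <- drugs$primary_target[drugs$drug == drug]
    cond_truth <- gen$truth
    cond_truth$source_signs <- gen$truth$source_signs[primary]
    ms <- generate_measurements(cond_truth, noise_sd = spec$noise_sd,
                                seed = spec$seed + 100L + k,
                                condition = manifest$condition_id[k])
    conditions[[manifest$condition_id[k]]] <-
      list(sources = ms$sources, targets = ms$targets,
           offtargets = off_by_drug[[drug]])
  }
  list(manifest = manifest, pkn = gen$pkn, truth = gen$truth,
       drugs = drugs, conditions = conditions)
}

#' Write a complete fixture directory
#'
#' Generates a PKN with planted truth plus measurements and writes them as
#' plain-text files: `pkn.sif`, `sources.tsv`, `targets.tsv`,
#' `truth_edges.sif`, `offtargets.txt`.
#'
#' @param dir output directory (created if missing)
#' @param spec a `fixture_spec`
#' @return the generated list from [generate_pkn()], with measurements,
#'   invisibly
#' @export
write_fixture_dir <- function(dir, spec = fixture_spec()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_pkn(spec)
  ms <- generate_measurements(gen$truth, spec$noise_sd, seed = spec$seed + 1L)
  write_sif(gen$pkn, file.path(dir, "pkn.sif"))
  write_sif(pkn_graph(gen$truth$true_edges), file.path(dir, "truth_edges.sif"))
  write_measurements(ms$sources, file.path(dir, "sources.tsv"))
  write_measurements(ms$targets, file.path(dir, "targets.tsv"))
  writeLines(gen$truth$offtarget_nodes, file.path(dir, "offtargets.txt"))
  invisible(c(gen, list(measurements = ms)))
}
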