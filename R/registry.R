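# Method catalog and configuration-driven dispatch: the high-level surface
# that ties the PKN model, measurements, methods and exports together.

method_catalog <- function() {
  data.frame(
    name = c("shortest_path", "sign_consistent", "all_paths",
             "ppr", "heat_diffusion",
             "recursive_propagation",
             "causal_selection", "two_phase_composite"),
    family = c("topology", "topology", "topology",
               "diffusion", "diffusion",
               "recursive propagation",
               "causal propagation", "causal propagation"),
    description = c(
      "union of all minimum-hop source-to-target simple paths",
      "edge union of sign-consistent source-to-target paths",
      "union of all simple source-to-target paths up to max_len edges",
      "two-sided personalized PageRank with percentile node retention",
      "two-sided truncated heat diffusion with percentile node retention",
      "iterative upstream mean-sign scoring from targets with inconsistency pruning",
      "exact (or greedy) causal sign-assignment maximizing explained targets minus an edge penalty",
      "sign-consistent path prefilter followed by causal selection, with hierarchy layers"),
    parameters = c(
      "", "mode=shortest", "max_len=5",
      "damping=0.85,percentile=90,tol=1e-8,max_iter=1000",
      "t=1,K=20,percentile=90",
      "n_layers=5",
      "lambda=0.1,solver=exhaustive,max_edges_exhaustive=15",
      "max_len=5,lambda=0.1,max_edges_exhaustive=15"),
    stringsAsFactors = FALSE)
}

#' List the registered contextualization methods
#'
#' The default build registers eight methods across the four families
#' (topology, diffusion, recursive propagation, causal propagation).
#'
#' @return data.frame with columns `name`, `family`, `description`,
#'   `parameters` (comma-separated `key=default` pairs)
#' @export
list_methods <- function() method_catalog()

#' Run a contextualization method by name
#'
#' Uniform dispatch: every method takes the PKN plus source and target
#' measurement sets and returns a `contextualized_network`. Methods that
#' reason over signs derive them from the arithmetic sign of the measurement
#' scores (zero scores are unsigned and dropped with a warning).
#'
#' @param method a method name from [list_methods()]
#' @param pkn a `pkn_graph`
#' @param sources,targets `measurement_set`s with roles source and target
#' @param params named list of method parameters overriding the defaults
#' @param seed integer seed recorded in provenance (the built-in methods are
#'   deterministic; the seed matters for user-supplied stochastic extensions)
#' @return a `contextualized_network`
#' @export
run_method <- function(method, pkn, sources, targets, params = list(),
                       seed = NULL) {
  stopifnot(inherits(pkn, "pkn_graph"),
            inherits(sources, "measurement_set"),
            inherits(targets, "measurement_set"))
  if (!method %in% method_catalog()$name) {
    stop(sprintf("unknown method '%s'; available: %s", method,
                 paste(method_catalog()$name, collapse = ", ")))
  }
  p <- params
  net <- switch(method,
    shortest_path = shortest_paths_network(pkn, names(sources$scores),
                                           names(targets$scores)),
    sign_consistent = sign_consistent_paths_network(
      pkn, measurement_signs(sources), measurement_signs(targets),
      mode = p$mode %||% "shortest", cap = p$cap %||% 1e5),
    all_paths = all_paths_network(pkn, names(sources$scores),
                                  names(targets$scores),
                                  max_len = p$max_len %||% 5L,
                                  cap = p$cap %||% 1e5),
    ppr = ppr_subnetwork(pkn, sources, targets,
                         damping = p$damping %||% 0.85,
                         percentile = p$percentile %||% 90,
                         tol = p$tol %||% 1e-8,
                         max_iter = p$max_iter %||% 1000L),
    heat_diffusion = heat_subnetwork(pkn, sources, targets,
                                     t = p$t %||% 1, K = p$K %||% 20L,
                                     percentile = p$percentile %||% 90),
    recursive_propagation = recursive_propagation(
      pkn, measurement_signs(targets), n_layers = p$n_layers %||% 5L)$network,
    causal_selection = {
      sel <- causal_selection(pkn, measurement_signs(sources),
                              measurement_signs(targets),
                              lambda = p$lambda %||% 0.1,
                              solver = p$solver %||% "exhaustive",
                              max_edges_exhaustive = p$max_edges_exhaustive %||% 15L,
                              max_len = p$max_len, cap = p$cap %||% 1e5)
      sub <- pkn_graph(sel$active_edges)
      st <- sel$node_state[sel$node_state != 0]
      contextualized_network(sub, pkn, node_scores = as.numeric(st) |>
                               stats::setNames(names(st)),
                             method = "causal_selection",
                             parameters = list(lambda = p$lambda %||% 0.1),
                             notes = sprintf("objective=%.6g", sel$objective))
    },
    two_phase_composite = two_phase_composite(
      pkn, measurement_signs(sources), measurement_signs(targets),
      max_len = p$max_len %||% 5L, lambda = p$lambda %||% 0.1,
      max_edges_exhaustive = p$max_edges_exhaustive %||% 15L,
      cap = p$cap %||% 1e5))
  net$provenance$method <- method
  net$provenance$parameters <- utils::modifyList(
    as.list(net$provenance$parameters), params)
  net$provenance$seed <- seed
  net
}

#' Run a contextualization method from a configuration
#'
#' The configuration is a named list (or path to a JSON file) with fields
#' `pkn` (SIF path), `sources` and `targets` (measurement TSV paths),
#' `method`, optional `params`, optional integer `seed`, and `outdir`. The
#' run writes `network.sif`, `network.graphml` and `provenance.json`
#' (method, parameters, seed and MD5 digests of the input files) into
#' `outdir`, so every run is reproducible from its provenance alone.
#'
#' @param config named list or JSON file path
#' @return the `contextualized_network`, invisibly
#' @export
run_from_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  for (f in c("pkn", "sources", "targets", "method", "outdir")) {
    if (is.null(config[[f]])) stop(sprintf("config field '%s' is required", f))
  }
  pkn <- read_sif(config$pkn)
  src <- read_measurements(config$sources, "source")
  tgt <- read_measurements(config$targets, "target")
  seed <- if (!is.null(config$seed)) as.integer(config$seed) else NULL
  net <- run_method(config$method, pkn, src, tgt,
                    params = as.list(config$params), seed = seed)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  write_sif(net$subgraph, file.path(config$outdir, "network.sif"))
  export_graphml(net, file.path(config$outdir, "network.graphml"))
  prov <- list(method = net$provenance$method,
               parameters = net$provenance$parameters,
               seed = seed,
               notes = net$provenance$notes,
               inputs = list(
                 pkn = list(path = config$pkn,
                            md5 = unname(tools::md5sum(config$pkn))),
                 sources = list(path = config$sources,
                                md5 = unname(tools::md5sum(config$sources))),
                 targets = list(path = config$targets,
                                md5 = unname(tools::md5sum(config$targets)))))
  jsonlite::write_json(prov, file.path(config$outdir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  invisible(net)
}
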