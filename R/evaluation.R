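# Benchmarking strategies for contextualized subnetworks. Each strategy
# returns one or more evaluation records with a size-matched permutation null
# (network size preserved, degree sequence not -- stated simplification) and
# an add-one empirical p-value, so p is never exactly zero.

new_eval_record <- function(strategy, metric, observed, null_mean = NA_real_,
                            null_sd = NA_real_, empirical_p = NA_real_,
                            n_permutations = NA_integer_, seed = NA_integer_) {
  structure(list(strategy = strategy, metric = metric, observed = observed,
                 null_mean = null_mean, null_sd = null_sd,
                 empirical_p = empirical_p,
                 n_permutations = n_permutations, seed = seed),
            class = "eval_record")
}

#' @export
print.eval_record <- function(x, ...) {
  cat(sprintf("<eval_record> %s/%s: observed=%.4g, null=%.4g+-%.4g, p=%.4g\n",
              x$strategy, x$metric, x$observed, x$null_mean, x$null_sd,
              x$empirical_p))
  invisible(x)
}

eval_records_to_df <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    data.frame(strategy = r$strategy, metric = r$metric, observed = r$observed,
               null_mean = r$null_mean, null_sd = r$null_sd,
               empirical_p = r$empirical_p, n_permutations = r$n_permutations,
               seed = r$seed, stringsAsFactors = FALSE)
  }))
}

# Shared kernel: recovery of a labelled node set by a network, against a null
# of uniformly drawn node sets of the same size from the PKN universe.
node_set_recovery <- function(strategy, network, labels, pkn, n_perm = 1000L,
                              seed = 1L) {
  net_nodes <- network_nodes(network)
  if (!length(net_nodes)) stop("empty network")
  labels <- as.character(labels)
  outside <- setdiff(labels, pkn$nodes)
  if (length(outside)) {
    warning(sprintf("%d label(s) absent from the PKN dropped: %s",
                    length(outside), paste(outside, collapse = ",")))
    labels <- intersect(labels, pkn$nodes)
  }
  observed <- length(intersect(net_nodes, labels))
  frac <- if (length(labels)) observed / length(labels) else NA_real_
  k <- length(intersect(net_nodes, pkn$nodes))
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      length(intersect(sample(pkn$nodes, k), labels))
    }, numeric(1))
  })
  p <- (1 + sum(null >= observed)) / (1 + n_perm)
  list(
    new_eval_record(strategy, "recovered_count", observed,
                    mean(null), stats::sd(null), p, as.integer(n_perm),
                    as.integer(seed)),
    new_eval_record(strategy, "recovered_fraction", frac,
                    mean(null) / max(length(labels), 1L),
                    stats::sd(null) / max(length(labels), 1L), p,
                    as.integer(n_perm), as.integer(seed)))
}

#' Off-target recovery benchmark
#'
#' Scores a contextualized network by the number (and fraction) of known
#' drug off-target proteins among its nodes, against a permutation null of
#' uniformly drawn node sets of the same size from the PKN.
#'
#' @param network a `contextualized_network` (non-empty)
#' @param offtargets character vector of off-target node identifiers; labels
#'   absent from the PKN are dropped with a warning
#' @param pkn the parent `pkn_graph` (the sampling universe)
#' @param n_perm number of null permutations; default 1000
#' @param seed RNG seed for the null
#' @return list of two `eval_record`s (count and fraction)
#' @export
offtarget_recovery <- function(network, offtargets, pkn, n_perm = 1000L,
                               seed = 1L) {
  node_set_recovery("offtarget_recovery", network, offtargets, pkn, n_perm, seed)
}

#' Binary responsive-label recovery benchmark
#'
#' Identical machinery to [offtarget_recovery()] with responsive-node labels
#' (e.g. phosphosites/proteins responsive to a drug perturbation, binarized).
#'
#' @param network a `contextualized_network`
#' @param responsive character vector of responsive node identifiers
#' @inheritParams offtarget_recovery
#' @return list of two `eval_record`s
#' @export
binary_recovery <- function(network, responsive, pkn, n_perm = 1000L,
                            seed = 1L) {
  node_set_recovery("binary_recovery", network, responsive, pkn, n_perm, seed)
}

#' Over-representation analysis of a gene set in a network
#'
#' One-sided hypergeometric tail probability of observing at least the actual
#' overlap between the network's nodes and an a priori expected gene set,
#' within a finite background universe:
#' `p = sum_{i=k}^{min(K,n)} C(K,i) C(N-K,n-i) / C(N,n)` with `N` the
#' background size, `K` the gene-set size, `n` the network size and `k` the
#' observed overlap.
#'
#' @param network_nodes character vector of network node identifiers
#' @param gene_set character vector; members outside `background` are dropped
#'   with a warning (likewise network nodes)
#' @param background character vector, the finite node universe
#' @return list with `overlap` (integer) and `p_value`
#' @export
ora_enrichment <- function(network_nodes, gene_set, background) {
  background <- unique(as.character(background))
  if (!length(background)) stop("empty background")
  drop_out <- function(x, what) {
    x <- unique(as.character(x))
    out <- setdiff(x, background)
    if (length(out)) {
      warning(sprintf("%d %s node(s) outside the background dropped", length(out), what))
    }
    intersect(x, background)
  }
  network_nodes <- drop_out(network_nodes, "network")
  gene_set <- drop_out(gene_set, "gene-set")
  N <- length(background)
  K <- length(gene_set)
  n <- length(network_nodes)
  k <- length(intersect(network_nodes, gene_set))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(overlap = k, p_value = min(1, p))
}

#' Rank-based activity enrichment of a network
#'
#' Tests whether molecular activity scores (e.g. kinase activities inferred
#' from phosphoproteomics) are higher inside the network than outside it.
#' The observed statistic is the difference in mean midrank between scored
#' in-network and out-of-network nodes; the null permutes the in/out labels
#' `n_perm` times, and the one-sided p is for "in-network scores higher".
#'
#' @param network_nodes character vector of network node identifiers
#' @param activity_scores named numeric vector over the scored universe; at
#'   least one scored node must fall inside and one outside the network
#' @param n_perm number of label permutations; default 1000
#' @param seed RNG seed
#' @return an `eval_record` (metric `mean_rank_difference`)
#' @export
activity_rank_test <- function(network_nodes, activity_scores, n_perm = 1000L,
                               seed = 1L) {
  network_nodes <- as.character(network_nodes)
  ids <- names(activity_scores)
  inside <- ids %in% network_nodes
  if (!any(inside) || all(inside)) {
    stop("need at least one scored node inside and one outside the network")
  }
  rk <- rank(activity_scores)  # midranks for ties
  stat <- function(inside) mean(rk[inside]) - mean(rk[!inside])
  observed <- stat(inside)
  n_in <- sum(inside)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      stat(seq_along(ids) %in% sample(seq_along(ids), n_in))
    }, numeric(1))
  })
  p <- (1 + sum(null >= observed)) / (1 + n_perm)
  new_eval_record("activity_rank_test", "mean_rank_difference", observed,
                  mean(null), stats::sd(null), p, as.integer(n_perm),
                  as.integer(seed))
}

#' List the registered evaluation strategies
#' @return data.frame with columns `name` and `description`
#' @export
list_strategies <- function() {
  data.frame(
    name = c("offtarget_recovery", "binary_recovery", "ora_enrichment",
             "activity_rank_test"),
    description = c(
      "number/fraction of known drug off-targets recovered, size-matched permutation null",
      "recovery of binary responsive-node labels, size-matched permutation null",
      "one-sided hypergeometric over-representation of an expected gene set",
      "mean-rank difference of activity scores inside vs outside the network, label-permutation null"),
    stringsAsFactors = FALSE)
}

#' Evaluate a set of networks under configured strategies
#'
#' Runs each configured strategy on each network and returns the cross-product
#' metric table, ordered by network name and then strategy name; re-running
#' with the same seeds reproduces the table exactly.
#'
#' @param networks named list of `contextualized_network`s
#' @param strategies named list of strategy configurations; each is a list
#'   with `strategy` (one of [list_strategies()] names) and its arguments:
#'   `labels` + `pkn` (+ `n_perm`, `seed`) for the recovery strategies,
#'   `gene_set` + `background` for `ora_enrichment`, `activity_scores`
#'   (+ `n_perm`, `seed`) for `activity_rank_test`
#' @param out optional TSV path; when given the table is also written there
#' @return data.frame with one row per (network, strategy, metric)
#' @export
evaluate_all <- function(networks, strategies, out = NULL) {
  stopifnot(length(networks) >= 1L, length(strategies) >= 1L)
  if (is.null(names(networks)) || any(!nzchar(names(networks)))) {
    stop("networks must be a named list")
  }
  rows <- list()
  for (nw in sort(names(networks))) {
    net <- networks[[nw]]
    for (st in sort(names(strategies))) {
      cfg <- strategies[[st]]
      recs <- switch(cfg$strategy,
        offtarget_recovery = offtarget_recovery(net, cfg$labels, cfg$pkn,
                                                cfg$n_perm %||% 1000L,
                                                cfg$seed %||% 1L),
        binary_recovery = binary_recovery(net, cfg$labels, cfg$pkn,
                                          cfg$n_perm %||% 1000L,
                                          cfg$seed %||% 1L),
        ora_enrichment = {
          res <- ora_enrichment(network_nodes(net), cfg$gene_set, cfg$background)
          list(new_eval_record("ora_enrichment", "overlap", res$overlap),
               new_eval_record("ora_enrichment", "p_value", res$p_value))
        },
        activity_rank_test = list(activity_rank_test(network_nodes(net),
                                                     cfg$activity_scores,
                                                     cfg$n_perm %||% 1000L,
                                                     cfg$seed %||% 1L)),
        stop(sprintf("unknown strategy '%s'", cfg$strategy)))
      df <- eval_records_to_df(recs)
      df <- cbind(network = nw, config = st, df, stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- df
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (!is.null(out)) {
    fmt <- tab
    for (cl in c("observed", "null_mean", "null_sd", "empirical_p")) {
      fmt[[cl]] <- sprintf("%.10g", tab[[cl]])
    }
    utils::write.table(fmt, out, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a
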