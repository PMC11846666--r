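test_that("recursive propagation scores simple cases by hand", {
  g <- pkn_graph(data.frame(source = "A", target = "B", sign = -1L))
  res <- recursive_propagation(g, c(B = 1L), n_layers = 1)
  expect_equal(res$scores[["A"]], -1)

  # cancellation: two successors contribute +1 and -1, node scores 0 and all
  # incident edges are pruned; zero-score nodes propagate no further
  g2 <- pkn_graph(data.frame(source = c("U", "U", "W"),
                             target = c("V1", "V2", "U"),
                             sign = c(1L, 1L, 1L)))
  res2 <- recursive_propagation(g2, c(V1 = 1L, V2 = -1L), n_layers = 3)
  expect_equal(res2$scores[["U"]], 0)
  expect_false("W" %in% names(res2$scores))
  expect_equal(n_edges(res2$network$subgraph), 0L)
})

test_that("recursive propagation matches the naive layer oracle on random DAGs", {
  for (seed in 1:15) {
    # random DAG: edges only from lower to higher topological rank
    g <- withr::with_seed(seed, {
      nodes <- paste0("n", 1:8)
      m <- sample(6:14, 1)
      src_i <- sample(1:7, m, replace = TRUE)
      tgt_i <- vapply(src_i, function(i) sample((i + 1):8, 1), integer(1))
      pkn_graph(data.frame(source = nodes[src_i], target = nodes[tgt_i],
                           sign = sample(c(-1L, 1L), m, TRUE)))
    })
    sinks <- setdiff(g$nodes, unique(g$edges$source))
    if (!length(sinks)) sinks <- g$nodes[8]
    tsigns <- withr::with_seed(seed, stats::setNames(
      sample(c(-1L, 1L), length(sinks), TRUE), sinks))
    mine <- recursive_propagation(g, tsigns, n_layers = 8)
    oracle <- oracle_recursive(g, tsigns, 8)
    expect_equal(sort(names(mine$scores)), sort(names(oracle)),
                 info = paste("seed", seed))
    expect_equal(mine$scores[sort(names(mine$scores))],
                 oracle[sort(names(oracle))], tolerance = 1e-12,
                 info = paste("seed", seed))
    expect_true(all(abs(mine$scores) <= 1 + 1e-12))
  }
})

test_that("causal selection solves the hand-worked chains", {
  chain <- pkn_graph(data.frame(source = c("A", "B"), target = c("B", "C"),
                                sign = 1L))
  sel <- causal_selection(chain, c(A = 1L), c(C = 1L), lambda = 0.1)
  expect_equal(nrow(sel$active_edges), 2L)
  expect_equal(sel$objective, 0.8)
  expect_equal(sel$explained_targets, "C")
  expect_equal(sel$node_state[["B"]], 1L)

  wrong <- causal_selection(chain, c(A = 1L), c(C = -1L), lambda = 0.1)
  expect_equal(nrow(wrong$active_edges), 0L)
  expect_equal(wrong$objective, 0)
  expect_length(wrong$explained_targets, 0L)
})

test_that("ties break toward the shorter of two parallel consistent paths", {
  g <- pkn_graph(data.frame(
    source = c("S", "M", "S", "P", "Q"),
    target = c("M", "T", "P", "Q", "T"),
    sign = 1L))
  sel <- causal_selection(g, c(S = 1L), c(T = 1L), lambda = 0.1)
  expect_equal(nrow(sel$active_edges), 2L)
  expect_setequal(sel$active_edges$source, c("S", "M"))
  oracle <- oracle_causal(g, c(S = 1L), c(T = 1L), 0.1)
  expect_equal(sel$objective, oracle$objective)
})

test_that("exhaustive selection matches the literal-invariant oracle", {
  for (seed in 1:20) {
    g <- random_pkn(6, sample(5:9, 1), seed)
    nodes <- g$nodes
    ss <- withr::with_seed(seed, stats::setNames(sample(c(-1L, 1L), 1), nodes[1]))
    ts <- withr::with_seed(seed + 50, stats::setNames(
      sample(c(-1L, 1L), 2, TRUE), nodes[5:6]))
    sel <- causal_selection(g, ss, ts, lambda = 0.1)
    oracle <- oracle_causal(g, ss, ts, 0.1)
    expect_equal(sel$objective, oracle$objective, info = paste("seed", seed))
    mine_idx <- sort(match(paste(sel$active_edges$source, sel$active_edges$target,
                                 sel$active_edges$sign),
                           paste(g$edges$source, g$edges$target, g$edges$sign)))
    expect_identical(mine_idx, as.integer(oracle$idx), info = paste("seed", seed))
  }
})

test_that("negating all signs maps optima to optima with the same objective", {
  for (seed in 1:8) {
    g <- random_pkn(6, 8, seed)
    ss <- stats::setNames(1L, g$nodes[1])
    ts <- stats::setNames(c(-1L, 1L), g$nodes[5:6])
    a <- causal_selection(g, ss, ts, lambda = 0.1)
    b <- causal_selection(g, -ss, -ts, lambda = 0.1)
    expect_equal(a$objective, b$objective, info = paste("seed", seed))
    expect_identical(-a$node_state, b$node_state, info = paste("seed", seed))
  }
})

test_that("greedy never beats exhaustive and matches it on planted paths", {
  for (seed in 1:8) {
    g <- random_pkn(6, 8, seed)
    ss <- stats::setNames(1L, g$nodes[1])
    ts <- stats::setNames(c(-1L, 1L), g$nodes[5:6])
    ex <- causal_selection(g, ss, ts, lambda = 0.1, solver = "exhaustive")
    gr <- causal_selection(g, ss, ts, lambda = 0.1, solver = "greedy")
    expect_lte(gr$objective, ex$objective + 1e-12)
  }
  sp <- fixture_spec(n_nodes = 8, edge_prob = 0, n_sources = 1, n_targets = 1,
                     planted_path_len = 3, seed = 4)
  gen <- generate_pkn(sp)
  ex <- causal_selection(gen$pkn, gen$truth$source_signs,
                         gen$truth$target_signs, solver = "exhaustive")
  gr <- causal_selection(gen$pkn, gen$truth$source_signs,
                         gen$truth$target_signs, solver = "greedy")
  expect_equal(gr$objective, ex$objective)
  expect_equal(nrow(gr$active_edges), 3L)
})

test_that("the exhaustive cap triggers a redirect to the greedy solver", {
  g <- random_pkn(10, 25, 3)
  expect_error(causal_selection(g, stats::setNames(1L, g$nodes[1]),
                                stats::setNames(1L, g$nodes[10]),
                                max_edges_exhaustive = 5L),
               "greedy")
})

test_that("two-phase composite recovers a planted path with layer indices", {
  sp <- fixture_spec(n_nodes = 8, edge_prob = 0, n_sources = 1, n_targets = 1,
                     planted_path_len = 3, seed = 12)
  gen <- generate_pkn(sp)
  net <- two_phase_composite(gen$pkn, gen$truth$source_signs,
                             gen$truth$target_signs, max_len = 4)
  expect_true(pkn_equal(net$subgraph, pkn_graph(gen$truth$true_edges)))
  layers <- net$node_scores[gen$truth$paths[[1]]$nodes]
  expect_equal(unname(layers), 0:3)
})

test_that("two-phase composite output is contained in phase 1 and the PKN", {
  for (seed in 1:6) {
    sp <- fixture_spec(n_nodes = 12, edge_prob = 0.1, n_sources = 1,
                       n_targets = 1, planted_path_len = 2, seed = seed)
    gen <- generate_pkn(sp)
    phase1 <- sign_consistent_paths_network(gen$pkn, gen$truth$source_signs,
                                            gen$truth$target_signs, mode = 4)
    net <- two_phase_composite(gen$pkn, gen$truth$source_signs,
                               gen$truth$target_signs, max_len = 4,
                               max_edges_exhaustive = 12L)
    k_out <- netcontext:::edge_keys(net$subgraph)
    expect_true(all(k_out %in% netcontext:::edge_keys(phase1$subgraph)),
                info = paste("seed", seed))
    expect_true(all(k_out %in% netcontext:::edge_keys(gen$pkn)))
  }
})

test_that("an empty phase 1 yields an empty composite network", {
  g <- pkn_graph(data.frame(source = "A", target = "B", sign = 1L))
  net <- two_phase_composite(g, c(A = 1L), c(B = -1L))
  expect_equal(n_edges(net$subgraph), 0L)
  expect_match(net$provenance$notes, "phase 1 empty")
})
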