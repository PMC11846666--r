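toy_network <- function(nodes, pkn) {
  contextualized_network(induced_subgraph(pkn, nodes), pkn, method = "toy")
}

line_pkn <- function(n) {
  nodes <- paste0("g", seq_len(n))
  pkn_graph(data.frame(source = nodes[-n], target = nodes[-1], sign = 1L))
}

test_that("off-target recovery counts and fractions are as expected", {
  pkn <- line_pkn(10)
  net <- toy_network(paste0("g", 1:3), pkn)
  recs <- suppressWarnings(offtarget_recovery(net, c("g2", "g9"), pkn,
                                              n_perm = 200, seed = 1))
  cnt <- recs[[1]]; frac <- recs[[2]]
  expect_equal(cnt$observed, 1)
  expect_equal(frac$observed, 0.5)
  full <- offtarget_recovery(toy_network(paste0("g", 1:5), pkn),
                             c("g2", "g3"), pkn, n_perm = 100, seed = 1)
  expect_equal(full[[2]]$observed, 1.0)
  expect_error(offtarget_recovery(toy_network(character(), pkn), "g1", pkn),
               "empty network")
})

test_that("the null mean matches the hypergeometric expectation", {
  pkn <- line_pkn(10)
  net <- toy_network(paste0("g", 1:5), pkn)
  recs <- offtarget_recovery(net, c("g1", "g7"), pkn, n_perm = 10000, seed = 3)
  cnt <- recs[[1]]
  hyper_mean <- 2 * 5 / 10
  mc_se <- cnt$null_sd / sqrt(cnt$n_permutations)
  expect_lt(abs(cnt$null_mean - hyper_mean), 3 * mc_se)
  expect_gte(cnt$empirical_p, 1 / (cnt$n_permutations + 1))
  expect_lte(cnt$empirical_p, 1)
})

test_that("binary recovery shares the kernel with off-target recovery", {
  pkn <- line_pkn(8)
  net <- toy_network(paste0("g", 2:4), pkn)
  labels <- c("g3", "g7")
  a <- offtarget_recovery(net, labels, pkn, n_perm = 500, seed = 9)
  b <- binary_recovery(net, labels, pkn, n_perm = 500, seed = 9)
  expect_equal(a[[1]]$observed, b[[1]]$observed)
  expect_equal(a[[1]]$null_mean, b[[1]]$null_mean)
  expect_equal(a[[1]]$empirical_p, b[[1]]$empirical_p)
  none <- binary_recovery(net, c("g7", "g8"), pkn, n_perm = 100, seed = 1)
  expect_equal(none[[1]]$observed, 0)
  again <- binary_recovery(net, labels, pkn, n_perm = 500, seed = 9)
  expect_identical(b[[1]]$empirical_p, again[[1]]$empirical_p)
})

test_that("ORA reproduces the worked hypergeometric example and edge cases", {
  bg <- paste0("g", 1:10)
  res <- ora_enrichment(bg[1:4], bg[1:5], bg)
  expect_equal(res$overlap, 4L)
  expect_equal(res$p_value, 5 / 210, tolerance = 1e-12)

  none <- ora_enrichment(bg[6:9], bg[1:5], bg)
  expect_equal(none$overlap, 0L)
  expect_equal(none$p_value, 1.0)

  forced <- ora_enrichment(bg[1:4], bg, bg)
  expect_equal(forced$p_value, 1.0)
  expect_error(ora_enrichment("a", "a", character()), "empty background")
  expect_warning(ora_enrichment(c(bg[1:3], "alien"), bg[1:5], bg), "dropped")
})

test_that("ORA equals the exact combinatorial tail on a parameter sweep", {
  for (N in c(5, 9, 17, 26)) {
    bg <- paste0("x", seq_len(N))
    for (K in c(0, 2, N %/% 2, N)) {
      for (n in c(1, N %/% 3 + 1, N)) {
        gene_set <- utils::head(bg, K)
        net <- utils::tail(bg, n)
        k <- length(intersect(net, gene_set))
        res <- ora_enrichment(net, gene_set, bg)
        expect_equal(res$p_value, min(1, oracle_hyper_tail(N, K, n, k)),
                     tolerance = 1e-12, info = sprintf("N=%d K=%d n=%d", N, K, n))
      }
    }
  }
})

test_that("rank test statistic is exact on hand-computable inputs", {
  scores <- c(a = 1, b = 2, c = 3, d = 4)
  rec <- activity_rank_test(c("c", "d"), scores, n_perm = 100, seed = 1)
  expect_equal(rec$observed, 2.0)

  sym <- c(a = 1, b = 2, c = 1, d = 2)
  rec2 <- activity_rank_test(c("a", "b"), sym, n_perm = 100, seed = 1)
  expect_equal(rec2$observed, 0)

  expect_error(activity_rank_test(names(scores), scores), "inside and one outside")
  expect_error(activity_rank_test("zz", scores), "inside and one outside")
})

test_that("the permutation p converges to the exact enumeration p", {
  scores <- c(a = 3, b = 1, c = 4, d = 1, e = 5, f = 2)
  inside <- c("c", "e", "a")
  rk <- rank(scores)
  obs <- mean(rk[names(scores) %in% inside]) - mean(rk[!names(scores) %in% inside])
  combos <- utils::combn(6, 3)
  exact_stats <- apply(combos, 2, function(ix) {
    mean(rk[ix]) - mean(rk[-ix])
  })
  exact_p <- mean(exact_stats >= obs - 1e-12)
  rec <- activity_rank_test(inside, scores, n_perm = 20000, seed = 2)
  expect_lt(abs(rec$empirical_p - exact_p), 0.02)
})

test_that("evaluate_all builds the deterministic cross-product table", {
  pkn <- line_pkn(12)
  nets <- list(big = toy_network(paste0("g", 1:6), pkn),
               small = toy_network(paste0("g", 2:4), pkn))
  strategies <- list(
    off = list(strategy = "offtarget_recovery", labels = c("g2", "g5"),
               pkn = pkn, n_perm = 200, seed = 4),
    ora = list(strategy = "ora_enrichment", gene_set = paste0("g", 1:4),
               background = pkn$nodes))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  tab1 <- evaluate_all(nets, strategies, out = f1)
  tab2 <- evaluate_all(nets, strategies, out = f2)
  # 2 networks x (2 recovery metrics + 2 ORA metrics) = 8 rows
  expect_equal(nrow(tab1), 8L)
  expect_identical(tab1$network, rep(c("big", "small"), each = 4))
  expect_identical(readLines(f1), readLines(f2))
  expect_error(evaluate_all(nets, list(x = list(strategy = "bogus"))), "bogus")
  expect_error(evaluate_all(list(toy_network("g1", pkn)), strategies), "named")
})

test_that("recovery strategies are invariant to input node order", {
  pkn <- line_pkn(10)
  net <- toy_network(paste0("g", c(5, 1, 3)), pkn)
  a <- offtarget_recovery(net, c("g3", "g9"), pkn, n_perm = 300, seed = 2)
  b <- offtarget_recovery(net, c("g9", "g3"), pkn, n_perm = 300, seed = 2)
  expect_identical(a[[1]]$observed, b[[1]]$observed)
  expect_identical(a[[1]]$empirical_p, b[[1]]$empirical_p)
})
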