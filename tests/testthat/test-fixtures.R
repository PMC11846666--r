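test_that("zero-background spec yields exactly the planted path", {
  sp <- fixture_spec(n_nodes = 5, edge_prob = 0, n_sources = 1, n_targets = 1,
                     planted_path_len = 2, noise_sd = 0, seed = 3)
  gen <- generate_pkn(sp)
  expect_equal(n_edges(gen$pkn), 2L)
  expect_true(pkn_equal(induced_subgraph(gen$pkn, unique(c(gen$truth$true_edges$source,
                                                           gen$truth$true_edges$target))),
                        pkn_graph(gen$truth$true_edges, nodes = unique(c(gen$truth$true_edges$source,
                                                                         gen$truth$true_edges$target)))))
})

test_that("generation is deterministic under a fixed seed", {
  sp <- fixture_spec(n_nodes = 30, edge_prob = 0.1, seed = 11)
  g1 <- generate_pkn(sp)
  g2 <- generate_pkn(sp)
  expect_true(pkn_equal(g1$pkn, g2$pkn))
  expect_identical(g1$truth$source_signs, g2$truth$source_signs)
  expect_identical(g1$truth$true_edges, g2$truth$true_edges)
  m1 <- generate_measurements(g1$truth, 0.2, seed = 5)
  m2 <- generate_measurements(g2$truth, 0.2, seed = 5)
  expect_identical(m1$targets$scores, m2$targets$scores)
})

test_that("planted paths are sign-consistent for every pair and seed", {
  for (seed in 1:20) {
    sp <- fixture_spec(n_nodes = 25, edge_prob = 0.08, n_sources = 2,
                       n_targets = 2, planted_path_len = 3, seed = seed)
    truth <- generate_pkn(sp)$truth
    for (p in truth$paths) {
      expect_equal(truth$source_signs[[p$source]] * prod(p$edges$sign),
                   truth$target_signs[[p$target]],
                   info = sprintf("seed %d pair %s->%s", seed, p$source, p$target))
    }
  }
})

test_that("planted paths stay the unique source-to-target route", {
  # background edges never enter planted intermediates or targets, so each
  # planted path is the only directed route for its pair
  for (seed in 1:5) {
    sp <- fixture_spec(n_nodes = 40, edge_prob = 0.08, n_sources = 2,
                       n_targets = 2, planted_path_len = 3, seed = seed)
    gen <- generate_pkn(sp)
    protected <- unique(gen$truth$true_edges$target)
    bg <- gen$pkn$edges[!paste(gen$pkn$edges$source, gen$pkn$edges$target,
                               gen$pkn$edges$sign) %in%
                          paste(gen$truth$true_edges$source,
                                gen$truth$true_edges$target,
                                gen$truth$true_edges$sign), ]
    expect_false(any(bg$target %in% protected), info = paste("seed", seed))
  }
})

test_that("measurements reflect signs exactly at zero noise", {
  sp <- fixture_spec(n_nodes = 10, edge_prob = 0, n_sources = 2, n_targets = 2,
                     planted_path_len = 2, seed = 9)
  truth <- generate_pkn(sp)$truth
  ms <- generate_measurements(truth, noise_sd = 0, seed = 1)
  expect_equal(unname(ms$sources$scores), unname(truth$source_signs * 1.0))
  expect_equal(unname(ms$targets$scores), unname(truth$target_signs * 1.0))
  expect_equal(sign(ms$targets$scores), as.numeric(truth$target_signs),
               ignore_attr = TRUE)
})

test_that("target noise has the requested standard deviation", {
  # 10,000 noise draws: 100 seeds x 100 planted targets
  sp <- fixture_spec(n_nodes = 102, edge_prob = 0, n_sources = 1,
                     n_targets = 100, planted_path_len = 1, seed = 2)
  truth <- generate_pkn(sp)$truth
  resid <- unlist(lapply(1:100, function(s) {
    ms <- generate_measurements(truth, noise_sd = 0.5, seed = s)
    ms$targets$scores - truth$target_signs
  }))
  expect_length(resid, 10000L)
  expect_lt(abs(sd(resid) - 0.5) / 0.5, 0.05)
})

test_that("drug x cell-line fixture has the expected manifest shape", {
  fx <- generate_panacea_like(n_drugs = 4, n_cell_lines = 3,
                              spec = fixture_spec(n_nodes = 60, edge_prob = 0.03,
                                                  n_sources = 4, n_targets = 2,
                                                  planted_path_len = 2, seed = 21))
  expect_equal(nrow(fx$manifest), 12L)
  expect_equal(length(unique(fx$manifest$drug)), 4L)
  expect_equal(length(fx$conditions), 12L)
  for (cond in fx$conditions) {
    expect_true(all(cond$offtargets %in% fx$pkn$nodes))
    expect_equal(cond$sources$role, "source")
    expect_length(cond$sources$scores, 1L)  # one primary target per drug
  }
  tiny <- generate_panacea_like(1, 1, fixture_spec(n_nodes = 20, n_sources = 1,
                                                   seed = 5))
  expect_equal(nrow(tiny$manifest), 1L)
})

test_that("fixture directories round-trip through the file readers", {
  dir <- withr::local_tempdir()
  sp <- fixture_spec(n_nodes = 20, edge_prob = 0.05, seed = 13)
  gen <- write_fixture_dir(dir, sp)
  pkn <- read_sif(file.path(dir, "pkn.sif"))
  expect_true(pkn_equal(induced_subgraph(pkn, pkn$nodes), pkn))
  expect_equal(sort(unique(c(pkn$edges$source, pkn$edges$target))),
               sort(unique(c(gen$pkn$edges$source, gen$pkn$edges$target))))
  src <- read_measurements(file.path(dir, "sources.tsv"), "source")
  expect_equal(sort(names(src$scores)), sort(names(gen$truth$source_signs)))
  truth_g <- read_sif(file.path(dir, "truth_edges.sif"))
  expect_true(pkn_equal(truth_g, pkn_graph(gen$truth$true_edges)))
})

test_that("fixture specs reject invariant violations", {
  expect_error(fixture_spec(n_nodes = 3, n_sources = 2, n_targets = 2), "exceed")
  expect_error(fixture_spec(n_nodes = 4, planted_path_len = 4), "n_nodes - 1")
  expect_error(fixture_spec(edge_prob = 1.5), "edge_prob")
  expect_error(fixture_spec(noise_sd = -1), "noise_sd")
})
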