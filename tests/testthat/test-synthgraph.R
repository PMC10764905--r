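test_that("pair link probability follows the membership agreement rule", {
  expect_equal(predict_link_prob(c(1, 0), c(1, 0), rates = 1), 1)
  expect_equal(predict_link_prob(c(1, 0), c(0, 1), rates = 1), 0)
  expect_equal(predict_link_prob(c(0.5, 0.5), c(0.5, 0.5), rates = c(1, 1)), 0.5)
  expect_equal(predict_link_prob(c(0.3, 0.7), c(0.6, 0.4), rates = c(0.9, 0.8)),
               0.3 * 0.6 * 0.9 + 0.7 * 0.4 * 0.8)
})

test_that("sampled mixed-membership graphs match the closed-form link probability", {
  # aggregate Monte-Carlo check: over all pairs of a sampled graph, the
  # realized link count must sit within 3 binomial SEs of the closed form
  g <- sample_mmsb_graph(200, mmsb_hyper(2, alpha = 5), seed = 7)
  pairs <- which(upper.tri(g$graph$adjacency), arr.ind = TRUE)
  p_pair <- rowSums(g$truth[pairs[, 1], ] * g$truth[pairs[, 2], ])
  expected <- sum(p_pair)
  se <- sqrt(sum(p_pair * (1 - p_pair)))
  observed <- g$graph$n_edges
  expect_lt(abs(observed - expected), 3 * se)

  # concentrated memberships: near-one-hot pairs behave deterministically
  g2 <- sample_mmsb_graph(150, mmsb_hyper(3, alpha = 0.02), seed = 3)
  pairs2 <- which(upper.tri(g2$graph$adjacency), arr.ind = TRUE)
  p2 <- rowSums(g2$truth[pairs2[, 1], ] * g2$truth[pairs2[, 2], ])
  linked <- g2$graph$adjacency[pairs2] == 1
  expect_gt(mean(linked[p2 > 0.99]), 0.97)
  expect_lt(mean(linked[p2 < 0.01]), 0.03)
})

test_that("beta scales the per-community link rates", {
  g1 <- sample_mmsb_graph(120, mmsb_hyper(2, alpha = 0.05, beta = 1), seed = 5)
  g5 <- sample_mmsb_graph(120, mmsb_hyper(2, alpha = 0.05, beta = 0.5), seed = 5)
  expect_lt(g5$graph$n_edges, g1$graph$n_edges)
  expect_error(mmsb_hyper(2, beta = 1.5), "beta")
  expect_error(mmsb_hyper(1), "k")
  expect_error(mmsb_hyper(2, alpha = -1), "alpha")
})

test_that("disjoint benchmarks have exactly one membership per node", {
  g <- generate_lfr_graph(lfr_params(n_nodes = 60, avg_degree = 8, c_min = 10,
                                     c_max = 30, on = 0), seed = 1)
  expect_true(all(rowSums(g$truth) == 1))
  adj <- g$graph$adjacency
  expect_true(all(adj == t(adj)))
  expect_true(all(diag(adj) == 0))
  expect_true(all(adj %in% 0:1))
})

test_that("overlapping-node count and memberships-per-node are exact", {
  for (om in 2:3) {
    g <- generate_lfr_graph(lfr_params(n_nodes = 60, avg_degree = 8, c_min = 10,
                                       c_max = 30, on = 12, om = om), seed = om)
    mem <- rowSums(g$truth)
    expect_identical(sum(mem > 1), 12L)
    expect_true(all(mem %in% c(1L, om)))
    expect_true(all(mem[mem > 1] == om))
  }
})

test_that("the benchmark sweep spans 20 overlap configurations", {
  on_fracs <- seq(0, 0.9, by = 0.1)
  grid <- expand.grid(on_frac = on_fracs, om = 2:3)
  expect_identical(nrow(grid), 20L)
  params <- lapply(seq_len(nrow(grid)), function(i)
    lfr_params(n_nodes = 60, avg_degree = 8, c_min = 10, c_max = 30,
               on = round(grid$on_frac[i] * 60), om = grid$om[i]))
  expect_length(params, 20)
  # spot-generate the two extremes
  g0 <- generate_lfr_graph(params[[1]], seed = 2)
  g9 <- generate_lfr_graph(params[[10]], seed = 2)
  expect_identical(sum(rowSums(g0$truth) > 1), 0L)
  expect_identical(sum(rowSums(g9$truth) > 1), as.integer(round(0.9 * 60)))
})

test_that("low mixing keeps links inside communities", {
  g <- generate_lfr_graph(lfr_params(n_nodes = 60, avg_degree = 8, mu_topo = 0.05,
                                     c_min = 10, c_max = 30, on = 0), seed = 4)
  # count internal vs external edges against the generator's own truth
  same <- tcrossprod(g$truth) > 0
  internal <- sum(g$graph$adjacency * same) / sum(g$graph$adjacency)
  expect_gte(internal, 0.9)
  expect_equal(internal, 1 - g$bookkeeping$realized_mu)
})

test_that("degree and mixing hit their targets within tolerance at scale", {
  g <- generate_lfr_graph(lfr_params(), seed = 1)
  b <- g$bookkeeping
  expect_lt(abs(b$realized_avg_degree - b$requested_avg_degree) /
              b$requested_avg_degree, 0.1)
  expect_lt(abs(b$realized_mu - b$requested_mu), 0.05)
  expect_true(all(b$sizes >= 27 & b$sizes <= 190))
  expect_lt(abs(g$graph$density - 0.15), 0.015)
})

test_that("unrealizable parameter combinations fail loudly", {
  expect_error(generate_lfr_graph(lfr_params(n_nodes = 50, avg_degree = 45,
                                             mu_topo = 0.05, c_min = 5,
                                             c_max = 12)),
               "unrealizable")
})

test_that("generators are deterministic given a seed", {
  expect_identical(generate_lfr_graph(lfr_params(n_nodes = 60, avg_degree = 8,
                                                 c_min = 10, c_max = 30), seed = 9),
                   generate_lfr_graph(lfr_params(n_nodes = 60, avg_degree = 8,
                                                 c_min = 10, c_max = 30), seed = 9))
  expect_identical(sample_mmsb_graph(50, mmsb_hyper(3), seed = 2),
                   sample_mmsb_graph(50, mmsb_hyper(3), seed = 2))
  truth <- planted_membership(10, 2)
  expect_identical(
    generate_hierarchical_dataset(truth, n_animals = 2, n_sessions = 1,
                                  n_runs = 2, n_timepoints = 100, seed = 3),
    generate_hierarchical_dataset(truth, n_animals = 2, n_sessions = 1,
                                  n_runs = 2, n_timepoints = 100, seed = 3))
})

test_that("noise-free runs reproduce the planted mixing exactly", {
  truth <- planted_membership(10, 2)
  ds <- generate_hierarchical_dataset(truth, n_animals = 1, n_sessions = 1,
                                      n_runs = 1, n_timepoints = 200,
                                      noise_sd = 0, animal_sd = 0, run_sd = 0,
                                      seed = 5)
  x <- ds$runs[[1]]$signal
  # ROIs 1 and 3 share a membership row, so their traces are identical
  expect_equal(cor(x[1, ], x[3, ]), 1, tolerance = 1e-12)
})

test_that("a planted two-block dataset yields two components at 15% density", {
  truth <- planted_membership(30, 2)
  ds <- generate_hierarchical_dataset(truth, n_animals = 1, n_sessions = 1,
                                      n_runs = 1, n_timepoints = 400,
                                      noise_sd = 0.1, animal_sd = 0,
                                      run_sd = 0, seed = 6)
  g <- threshold_density(correlation_matrix(ds$runs[[1]]), d = 0.15)
  comp <- igraph::components(igraph::graph_from_adjacency_matrix(
    g$adjacency, mode = "undirected"))
  blocks <- rep(1:2, length.out = 30)
  # every connected component stays inside one planted block
  expect_true(all(tapply(blocks, comp$membership, function(b) length(unique(b))) == 1))
})

test_that("the dataset hierarchy is yoked and carries motion traces", {
  truth <- planted_membership(10, 2)
  ds <- generate_hierarchical_dataset(truth, n_animals = 2, n_sessions = 2,
                                      n_runs = 3, n_timepoints = 50, seed = 1)
  idx <- dataset_index(ds)
  expect_identical(nrow(idx), 2L * 2L * 3L)
  expect_identical(sort(unique(idx$animal)), c("a01", "a02"))
  for (r in ds$runs) expect_length(r$motion, ncol(r$signal))
  expect_error(run_record(matrix(0, 3, 10), fs = 1, motion = rep(0, 5)), "motion")
  expect_error(fc_dataset(list(run_record(matrix(0, 3, 5), fs = 1),
                               run_record(matrix(0, 4, 5), fs = 1))),
               "ROI count")
})
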