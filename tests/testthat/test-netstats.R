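test_that("membership entropy matches its closed forms", {
  expect_equal(node_entropy(c(1, 0, 0)), 0)
  expect_equal(node_entropy(rep(1 / 7, 7)), 1)
  expect_equal(node_entropy(c(0.5, 0.5, 0, 0, 0, 0, 0)), log(2) / log(7),
               tolerance = 1e-12)
  expect_equal(round(node_entropy(c(0.5, 0.5, 0, 0, 0, 0, 0)), 2), 0.36)
})

test_that("entropy bounds and extremes hold over random simplices", {
  set.seed(4)
  for (k in c(2, 5, 7)) {
    p <- random_simplex(200, k)
    h <- node_entropy(p, k)
    expect_true(all(h >= 0 & h <= 1))
    one_hot <- diag(k)[sample(k, 50, replace = TRUE), ]
    expect_equal(node_entropy(one_hot, k), rep(0, 50))
  }
  # matrix and vector forms agree
  p <- random_simplex(10, 3)
  expect_equal(node_entropy(p), vapply(seq_len(10), function(i)
    node_entropy(p[i, ]), numeric(1)))
})

test_that("membership thresholding matches a direct t-test/BH oracle", {
  runs <- list(
    rbind(c(0.5, 0.5, 0.0), c(0.52, 0.48, 0.0), c(1, 0, 0)),
    rbind(c(0.5, 0.5, 0.0), c(0.55, 0.45, 0.0), c(1, 0, 0)),
    rbind(c(0.5, 0.5, 0.0), c(0.49, 0.51, 0.0), c(1, 0, 0)),
    rbind(c(0.5, 0.5, 0.0), c(0.51, 0.47, 0.02), c(1, 0, 0)))
  got <- threshold_memberships(runs, fdr_q = 0.05)
  # brute-force oracle on the flattened entries
  arr <- simplify2array(runs)
  p_manual <- apply(arr, c(1, 2), function(v) {
    if (sd(v) == 0) return(if (mean(v) > 0) 0 else 1)
    t.test(v, mu = 0)$p.value
  })
  keep <- matrix(p.adjust(p_manual, "BH") <= 0.05, 3)
  m <- apply(arr, c(1, 2), mean) * keep
  expected <- m / rowSums(m)
  expect_equal(unclass(got), expected, tolerance = 1e-10, ignore_attr = TRUE)
  # constant 0.5 retained, constant 0 zeroed
  expect_gt(got[1, 1], 0)
  expect_identical(got[3, 2], 0)
  expect_identical(got[3, 3], 0)
})

test_that("belonging counts and overlap score follow the t-threshold rule", {
  pi <- rbind(c(1, 0), c(0.6, 0.4), c(0.5, 0.5))
  se_tiny <- matrix(1e-6, 3, 2)
  bel <- belonging_matrix(pi, se_tiny, belonging_config(mu0 = 0.5))
  # entries strictly above 0.5 with tiny SE belong; others do not
  expect_identical(bel$belonging, rbind(c(1L, 0L), c(1L, 0L), c(0L, 0L)))
  expect_identical(bel$counts, c(1, 1, 0))
  expect_equal(bel$overlap_score, 0)

  bel2 <- belonging_matrix(pi, se_tiny, belonging_config(mu0 = 0.1))
  expect_true(all(bel2$counts[2:3] == 2))
  expect_equal(bel2$overlap_score, 2 / 3)

  # hand-computed t thresholds with a moderate SE: t = (pi - mu0)/se,
  # one-sided normal p, BH over 6 entries
  se <- matrix(0.05, 3, 2)
  cfg <- belonging_config(mu0 = 0.3, correction = "none")
  bel3 <- belonging_matrix(pi, se, cfg)
  p_manual <- pnorm((pi - 0.3) / 0.05, lower.tail = FALSE)
  expect_identical(bel3$belonging, (p_manual <= 0.05) * 1L)
})

test_that("membership tiers assign the highest significant multiplier", {
  k <- 7
  pi <- rbind(rep(1 / k, k),                 # uniform: no tier above 1/k
              c(0.9, rep(0.1 / 6, 6)),       # strong: top tier in community 1
              c(0.35, 0.35, rep(0.3 / 5, 5)))
  se <- matrix(0.01, 3, k)
  tiers <- membership_tiers(pi, se, tier_multipliers = c(0.05, 1, 2, 3.5),
                            correction = "none")
  expect_identical(tiers[2, 1], 4L)            # 0.9 > 3.5/7
  expect_identical(tiers[3, 1], 3L)            # 0.35 > 2/7 but < 3.5/7
  expect_true(all(tiers[1, ] == 1L))           # 1/7 > 0.05/7 only
})

test_that("membership distributions bin above the 0.2 floor", {
  # fully disjoint input: all mass in the top bin
  pi <- diag(3)[rep(1:3, each = 4), ]
  d <- membership_distribution(pi)
  expect_true(all(d["(0.8,1]", ] >= 80 * (4 / 12)))
  considered <- colSums(d)
  expect_equal(as.numeric(d["(0.8,1]", ] / considered), rep(1, 3))

  # uniform 1/7 memberships: everything below the floor
  u <- matrix(1 / 7, 10, 7)
  du <- membership_distribution(u)
  expect_true(all(du == 0))
  expect_equal(as.numeric(attr(du, "excluded_pct")), rep(100, 7))

  # hand-built 10-node case, community 1
  v <- c(0.25, 0.45, 0.65, 0.85, 0.95, 0.15, 0.35, 0.55, 0.75, 0.05)
  pi10 <- cbind(v, 1 - v)
  d10 <- membership_distribution(pi10)
  # 0.25/0.35, 0.45/0.55, 0.65/0.75, 0.85/0.95 -> 2 nodes per bin;
  # 0.05 and 0.15 fall below the floor
  expect_equal(as.numeric(d10[, 1]), rep(20, 4))  # % of 10 nodes
})

test_that("degree statistics equal adjacency row sums", {
  n <- 5
  full <- matrix(1L, n, n); diag(full) <- 0L
  ds <- degree_stats(full)
  expect_equal(ds$degree, rep(n - 1, n))
  expect_equal(ds$normalized_degree, rep((n - 1) / n, n))
  expect_equal(degree_stats(matrix(0L, 4, 4))$degree, rep(0, 4))

  set.seed(6)
  w <- matrix(rnorm(25), 5); w <- (w + t(w)) / 2; diag(w) <- 1
  g <- threshold_density(w, d = 0.4)
  ds2 <- degree_stats(g, weights = w)
  expect_equal(ds2$degree, rowSums(g$adjacency))
  expect_equal(ds2$weighted_degree, rowSums(g$adjacency * w))
})

test_that("percentile maps rank t-statistics across runs", {
  vals <- cbind(c(1, 2, 3), c(1.1, 2.1, 3.3), c(0.9, 1.9, 2.9))
  pm <- percentile_map(vals)
  expect_equal(order(pm), order(rowMeans(vals) / apply(vals, 1, sd)))
  expect_true(all(pm > 0 & pm <= 100))
})

test_that("participation coefficient matches brute-force edge counting", {
  # all links within own module
  adj <- two_cliques_adj(5)
  labels <- rep(1:2, each = 5)
  expect_equal(as.numeric(participation_coefficient(adj, labels)), rep(0, 10))

  # equal links to each of K modules
  k <- 4
  star <- matrix(0L, k + 1, k + 1)
  star[1, 2:(k + 1)] <- star[2:(k + 1), 1] <- 1L
  pc <- participation_coefficient(star, c(99, 1:k))
  expect_equal(as.numeric(pc[1]), 1 - 1 / k)

  # random graphs up to 30 nodes against the brute-force oracle
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(5:30, 1)
    adj <- matrix(0L, n, n); up <- upper.tri(adj)
    adj[up] <- rbinom(sum(up), 1, 0.3); adj <- adj + t(adj)
    labels <- sample(1:3, n, replace = TRUE)
    expect_equal(as.numeric(participation_coefficient(adj, labels)),
                 participation_brute(adj, labels), tolerance = 1e-12)
  }
})

test_that("network similarity anchors at 1, 0.5, and 0", {
  set.seed(2)
  u <- runif(20)
  expect_equal(as.numeric(network_cosine_similarity(u, u)), 1)
  uc <- u - mean(u)
  expect_equal(as.numeric(network_cosine_similarity(u, -uc + mean(u))), 0,
               tolerance = 1e-12)
  v <- rnorm(20)
  v_orth <- v - mean(v)
  u_c <- u - mean(u)
  v_orth <- v_orth - sum(v_orth * u_c) / sum(u_c^2) * u_c  # centered-orthogonal
  expect_equal(as.numeric(network_cosine_similarity(u, v_orth + mean(v))), 0.5,
               tolerance = 1e-12)
  prof <- network_similarity_profile(cbind(u, v), cbind(u, v))
  expect_equal(prof$per_network, c(1, 1))
  expect_equal(prof$overall, 1)
})

test_that("disjointification takes the argmax with lowest-index ties", {
  pi <- rbind(c(0.6, 0.4), c(0.5, 0.5), c(0.1, 0.9))
  lab <- disjointify(pi)
  expect_identical(as.integer(lab), c(1L, 1L, 2L))
  expect_identical(attr(lab, "n_ties"), 1L)
})
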