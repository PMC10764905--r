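test_that("degenerate bootstrap inputs give zero-width intervals", {
  d <- expand.grid(animal = 1:3, session = 1:2, run = 1:2)
  d$value <- 2.5
  b <- hierarchical_bootstrap(d, n_iter = 200, seed = 1)
  expect_equal(b$se, 0)
  expect_equal(b$ci_low, 2.5)
  expect_equal(b$ci_high, 2.5)
  expect_equal(b$estimate, 2.5)
})

test_that("every resampled path exists in the original hierarchy (yoking)", {
  # animal a has sessions 1-2, animal b only session 3; values encode the
  # (animal, session) pair so the statistic can verify yoking on every draw
  d <- rbind(data.frame(animal = "a", session = 1, value = 101),
             data.frame(animal = "a", session = 1, value = 101),
             data.frame(animal = "a", session = 2, value = 102),
             data.frame(animal = "b", session = 3, value = 203),
             data.frame(animal = "b", session = 3, value = 203))
  valid <- c(101, 102, 203)
  checker <- function(v) { stopifnot(all(v %in% valid)); mean(v) }
  expect_no_error(hierarchical_bootstrap(d, statistic = checker,
                                         n_iter = 500, seed = 2))
})

test_that("tiny-hierarchy bootstrap matches exhaustive enumeration", {
  # 2 animals x 1 session x 2 runs: animal draws (2^2 equally likely ordered
  # pairs) x per-animal run draws (2^2 each) are fully enumerable
  d <- data.frame(animal = rep(c("a", "b"), each = 2),
                  session = 1, value = c(1, 2, 10, 20))
  enumerate_means <- function() {
    runs <- list(a = c(1, 2), b = c(10, 20))
    out <- c()
    for (a1 in c("a", "b")) for (a2 in c("a", "b")) {
      r1 <- expand.grid(runs[[a1]], runs[[a1]])
      r2 <- expand.grid(runs[[a2]], runs[[a2]])
      for (i in seq_len(nrow(r1))) for (j in seq_len(nrow(r2))) {
        out <- c(out, mean(c(as.numeric(r1[i, ]), as.numeric(r2[j, ]))))
      }
    }
    out
  }
  exact <- enumerate_means()
  b <- hierarchical_bootstrap(d, n_iter = 4000, seed = 3)
  expect_true(all(b$replicates %in% exact))
  mc_se <- sd(exact) / sqrt(4000)
  expect_lt(abs(mean(b$replicates) - mean(exact)), 3 * mc_se)
})

test_that("single-animal data falls back to a percentile interval", {
  d <- data.frame(animal = "a", session = rep(1:2, each = 3),
                  value = c(1, 2, 3, 4, 5, 6))
  expect_warning(b <- hierarchical_bootstrap(d, n_iter = 300, seed = 1),
                 "single animal")
  expect_identical(b$method, "percentile")
})

test_that("nominal 95% BCa intervals cover at close to the nominal rate", {
  set.seed(99)
  reps <- 300
  hits <- 0
  for (r in seq_len(reps)) {
    d <- expand.grid(animal = 1:10, session = 1:3, run = 1:2)
    a_eff <- rnorm(10, 0, 0.5)[d$animal]
    s_eff <- rnorm(30, 0, 0.3)[(d$animal - 1) * 3 + d$session]
    d$value <- 1 + a_eff + s_eff + rnorm(nrow(d), 0, 0.5)
    b <- suppressWarnings(hierarchical_bootstrap(d, n_iter = 300, seed = r))
    hits <- hits + (b$ci_low <= 1 && 1 <= b$ci_high)
  }
  coverage <- hits / reps
  mc_se <- sqrt(0.95 * 0.05 / reps)
  expect_lt(abs(coverage - 0.95), 3 * mc_se + 0.01)
})

test_that("paired permutation test handles its analytic cases", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(paired_permutation_test(x, x)$p_value, 1)

  # all differences of one sign, n = 10, exact enumeration: only the two
  # all-plus/all-minus flips reach |mean(d)|
  set.seed(1)
  x10 <- rnorm(10) + 5
  y10 <- x10 - runif(10, 0.5, 1)
  r <- paired_permutation_test(x10, y10, n_resamples = 2000)
  expect_identical(r$method, "exact")
  expect_equal(r$p_value, 2 / 2^10, tolerance = 1e-12)
})

test_that("Monte-Carlo p-values agree with exhaustive enumeration", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(5:11, 1)
    x <- rnorm(n); y <- rnorm(n)
    exact <- exact_signflip_p(x - y)
    mc <- paired_permutation_test(x, y, n_resamples = 4000, seed = rep)
    if (mc$method == "exact") {
      expect_equal(mc$p_value, exact, tolerance = 1e-12)
    } else {
      se <- sqrt(exact * (1 - exact) / 4000)
      expect_lt(abs(mc$p_value - exact), 3 * se + 2 / 4000)
    }
  }
})

test_that("permutation p-values are symmetric in the pair order", {
  set.seed(33)
  x <- rnorm(9); y <- rnorm(9)
  p_xy <- paired_permutation_test(x, y, n_resamples = 600, seed = 5)$p_value
  p_yx <- paired_permutation_test(y, x, n_resamples = 600, seed = 5)$p_value
  expect_equal(p_xy, p_yx)
  ord <- sample(9)
  p_perm <- paired_permutation_test(x[ord], y[ord], n_resamples = 600,
                                    seed = 5)$p_value
  expect_equal(p_perm, p_xy)
})

test_that("the permutation test holds its type-I error at the 5% level", {
  set.seed(77)
  reps <- 2000
  rejections <- 0
  for (r in seq_len(reps)) {
    x <- rnorm(8); y <- rnorm(8)
    p <- paired_permutation_test(x, y, n_resamples = 300)$p_value
    rejections <- rejections + (p <= 0.05)
  }
  rate <- rejections / reps
  expect_gte(rate, 0.035)
  expect_lte(rate, 0.065)
})

test_that("Holm and BH decisions equal literal textbook procedures", {
  expect_false(any(holm_bonferroni(rep(1, 6))$reject))
  expect_false(any(benjamini_hochberg(rep(1, 6))$reject))
  expect_equal(holm_bonferroni(0.03)$p_adjusted, 0.03)
  expect_equal(benjamini_hochberg(0.03)$p_adjusted, 0.03)
  set.seed(13)
  for (rep in 1:40) {
    n <- sample(1:12, 1)
    p <- runif(n)^sample(1:3, 1)
    expect_identical(holm_bonferroni(p)$reject, holm_textbook(p))
    expect_identical(benjamini_hochberg(p)$reject, bh_textbook(p))
  }
})

test_that("matrix-valued bootstrap reproduces mean and yields finite SEs", {
  set.seed(3)
  idx <- expand.grid(animal = c("a1", "a2", "a3"), session = c("s1", "s2"))
  idx <- idx[rep(seq_len(nrow(idx)), each = 2), ]
  mats <- lapply(seq_len(nrow(idx)), function(i) random_simplex(6, 2))
  bs <- hierarchical_bootstrap_matrix(mats, idx, n_iter = 400, seed = 1)
  grand <- Reduce(`+`, mats) / length(mats)
  expect_equal(dim(bs$se), dim(grand))
  expect_true(all(bs$se >= 0))
  expect_lt(max(abs(bs$mean - grand)), 0.15)
})
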