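#' Hyperparameters of the mixed-membership graph sampler
#'
#' @param k Number of communities (>= 2).
#' @param alpha Dirichlet concentration for node memberships; scalar or
#'   length-`k` vector of positive reals. Small values produce concentrated
#'   (near-disjoint) memberships.
#' @param beta Per-community link rate in `[0, 1]`; scalar or length-`k`.
#'   The default 1 reproduces the deterministic link-on-agreement rule: a pair
#'   is connected whenever its community indicators agree.
#' @return An object of class `"mmsb_hyper"`.
#' @export
mmsb_hyper <- function(k, alpha = 1 / k, beta = 1) {
  if (!is.numeric(k) || length(k) != 1L || k < 2) {
    stop("k must be an integer >= 2", call. = FALSE)
  }
  k <- as.integer(k)
  alpha <- rep_len(alpha, k)
  beta <- rep_len(beta, k)
  if (any(alpha <= 0)) stop("alpha must be positive", call. = FALSE)
  if (any(beta < 0 | beta > 1)) stop("beta must lie in [0, 1]", call. = FALSE)
  structure(list(k = k, alpha = alpha, beta = beta), class = "mmsb_hyper")
}

#' Sample a graph from the mixed-membership stochastic blockmodel
#'
#' Generative process: each node draws a membership vector `pi_i` from a
#' Dirichlet; for each unordered pair, each endpoint draws a community
#' indicator from its own membership vector, and a link is placed with
#' probability `beta_k` when the indicators agree on community `k` (never when
#' they disagree). The marginal pair link probability is therefore
#' `sum_k pi_ik * pi_jk * beta_k`.
#'
#' @param n_nodes Number of nodes (>= 2).
#' @param hyper An [mmsb_hyper()] object.
#' @param seed Integer seed; the draw is reproducible bit-for-bit.
#' @return An object of class `"benchmark_graph"`: list with the sampled
#'   `graph` (an [fc_graph()]), the true membership matrix `truth`
#'   (rows on the simplex), `params`, and `seed`.
#' @examples
#' g <- sample_mmsb_graph(30, mmsb_hyper(2, alpha = 0.1), seed = 1)
#' g$graph
#' @export
sample_mmsb_graph <- function(n_nodes, hyper, seed = 1L) {
  if (!inherits(hyper, "mmsb_hyper")) stop("hyper must be an mmsb_hyper object", call. = FALSE)
  if (n_nodes < 2) stop("n_nodes must be >= 2", call. = FALSE)
  set.seed(seed)
  k <- hyper$k
  g <- matrix(stats::rgamma(n_nodes * k, shape = rep(hyper$alpha, each = n_nodes)),
              n_nodes, k)
  pi <- g / rowSums(g)

  pairs <- .upper_pairs(n_nodes)
  z1 <- .sample_categories(pi[pairs[, 1], , drop = FALSE])
  z2 <- .sample_categories(pi[pairs[, 2], , drop = FALSE])
  agree <- z1 == z2
  linked <- agree & stats::runif(nrow(pairs)) < hyper$beta[z1]
  adj <- matrix(0L, n_nodes, n_nodes)
  adj[pairs[linked, , drop = FALSE]] <- 1L
  adj <- adj + t(adj)

  structure(list(graph = fc_graph(adj), truth = pi, params = hyper, seed = seed),
            class = "benchmark_graph")
}

#' @export
print.benchmark_graph <- function(x, ...) {
  n_over <- if (is.matrix(x$truth)) sum(rowSums(x$truth > 0) > 1) else NA
  cat(sprintf("<benchmark_graph> %d nodes, %d edges, %s overlapping nodes\n",
              nrow(x$graph$adjacency), x$graph$n_edges,
              ifelse(is.na(n_over), "?", n_over)))
  invisible(x)
}
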