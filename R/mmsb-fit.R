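#' Control parameters for the mixed-membership fit
#'
#' Tuning knobs of the stochastic variational fit. The step size at iteration
#' `t` is `(tau + t)^(-kappa)`; `kappa` must lie in `(0.5, 1]` for valid
#' stochastic-approximation convergence. Every iteration uses all observed
#' links together with a fresh uniform sample of non-links (non-link
#' mini-batching), whose contribution is reweighted to be unbiased for the
#' full-data natural gradient.
#'
#' @param max_iters Maximum number of stochastic updates.
#' @param tau Step-size offset (down-weights early iterations).
#' @param kappa Step-size forgetting exponent, in `(0.5, 1]`.
#' @param local_iters Coupled local updates of the per-pair indicator
#'   distributions per global step.
#' @param nonlink_factor Non-link mini-batch size as a multiple of the link
#'   count.
#' @param tol,tol_checks,check_every Convergence: the fit stops when the
#'   relative change of the full-data objective is below `tol` for
#'   `tol_checks` consecutive checks, evaluated every `check_every` iterations.
#' @param init Initialization: `"spectral"` (k-means on leading adjacency
#'   eigenvectors; recommended), `"labels"` (random hard labels propagated one
#'   step over the graph), or `"uniform"` (small random perturbation of
#'   uniform memberships).
#' @param init_nstart k-means restarts of the spectral initialization; more
#'   restarts make independent seeds converge to the same optimum, which
#'   sharpens the seed consensus.
#' @param eps Background link rate for non-agreeing community indicators
#'   (regularizes the deterministic agreement rule).
#' @param alpha Dirichlet prior concentration; default `1/k`, filled in by
#'   [fit_mmsb()].
#' @param init_gamma Optional explicit initial Dirichlet parameter matrix
#'   (node-by-k), overriding `init`; permuting its columns permutes the
#'   fitted communities identically.
#' @return A list of class `"mmsb_control"`.
#' @export
mmsb_control <- function(max_iters = 200L, tau = 1, kappa = 0.9,
                         local_iters = 2L, nonlink_factor = 1,
                         tol = 1e-6, tol_checks = 10L, check_every = 10L,
                         init = c("spectral", "labels", "uniform"),
                         init_nstart = 30L,
                         eps = 1e-5, alpha = NULL, init_gamma = NULL) {
  if (kappa <= 0.5 || kappa > 1) stop("kappa must lie in (0.5, 1]", call. = FALSE)
  if (max_iters < 1) stop("max_iters must be >= 1", call. = FALSE)
  structure(list(max_iters = as.integer(max_iters), tau = tau, kappa = kappa,
                 local_iters = as.integer(local_iters),
                 nonlink_factor = nonlink_factor, tol = tol,
                 tol_checks = as.integer(tol_checks),
                 check_every = as.integer(check_every),
                 init = match.arg(init), init_nstart = as.integer(init_nstart),
                 eps = eps, alpha = alpha, init_gamma = init_gamma),
            class = "mmsb_control")
}

#' Fit an assortative mixed-membership stochastic blockmodel
#'
#' Models a binary graph by giving every node a membership vector `pi_i` on
#' the K-simplex; a pair of nodes connects when per-pair community indicators,
#' drawn from the two membership vectors, agree (community `k` agreement links
#' with rate `beta_k`), so the marginal link probability is
#' `sum_k pi_ik pi_jk beta_k`. Inference is stochastic variational: Dirichlet
#' variational factors per node, Beta factors per community rate, multinomial
#' factors per sampled pair, updated by natural-gradient steps of size
#' `(tau + t)^(-kappa)` over mini-batches (all links plus resampled
#' non-links).
#'
#' The returned memberships are the variational posterior means; rows lie on
#' the simplex. The fit is deterministic given `seed`. Isolated nodes carry no
#' link information and end near the uniform membership (with a warning).
#'
#' @param graph An [fc_graph()], a `"benchmark_graph"`, or a binary symmetric
#'   adjacency matrix.
#' @param k Number of communities (>= 2).
#' @param seed Integer seed controlling initialization and mini-batch
#'   sampling.
#' @param control An [mmsb_control()] list.
#' @param verbose Print objective snapshots.
#' @return An object of class `"mmsb"` with elements `pi` (node-by-k
#'   membership matrix), `rates` (posterior mean community link rates),
#'   `gamma` (Dirichlet variational parameters), `elbo` (objective trace at
#'   check points), `converged`, `iters`, `k`, `seed`, and `call`.
#' @seealso [consensus_over_seeds()] to combine fits across seeds,
#'   [predict.mmsb()] for link probabilities, [simulate.mmsb()] to draw
#'   graphs from the fitted model.
#' @examples
#' adj <- matrix(0, 12, 12)
#' adj[1:6, 1:6] <- 1; adj[7:12, 7:12] <- 1; diag(adj) <- 0
#' fit <- fit_mmsb(adj, k = 2, seed = 1)
#' round(coef(fit), 2)
#' @export
fit_mmsb <- function(graph, k, seed = 1L, control = mmsb_control(),
                     verbose = FALSE) {
  adj <- .as_adjacency(graph)
  n <- nrow(adj)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (sum(adj) == 0) stop("graph has no edges; nothing to fit", call. = FALSE)
  set.seed(seed)
  alpha <- control$alpha %||% (1 / k)
  eps <- control$eps

  deg <- rowSums(adj)
  if (any(deg == 0)) {
    warning(sum(deg == 0), " isolated node(s); their memberships stay near-uniform")
  }

  ed <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  n_links <- nrow(ed)
  n_pairs <- n * (n - 1) / 2
  n_non <- n_pairs - n_links
  m0 <- min(n_non, max(1L, as.integer(round(n_links * control$nonlink_factor))))

  gamma <- control$init_gamma %||%
    .mmsb_init(adj, k, alpha, control$init, control$init_nstart)
  if (!all(dim(gamma) == c(n, k))) stop("init_gamma has the wrong shape", call. = FALSE)
  lam0 <- rep(9, k); lam1 <- rep(1, k)

  log_eps1 <- log(eps); log_eps0 <- log1p(-eps)
  w0 <- n_non / m0
  elbo <- numeric(0)
  stable <- 0L
  converged <- FALSE
  t_done <- control$max_iters

  for (t in seq_len(control$max_iters)) {
    rho <- (control$tau + t)^(-control$kappa)
    Elogpi <- digamma(gamma) - digamma(rowSums(gamma))
    Eb1 <- digamma(lam0) - digamma(lam0 + lam1)
    Eb0 <- digamma(lam1) - digamma(lam0 + lam1)

    ni <- cbind(sample.int(n, m0, TRUE), sample.int(n, m0, TRUE))
    bad <- ni[, 1] == ni[, 2] | adj[ni] == 1
    while (any(bad)) {
      nb <- sum(bad)
      ni[bad, ] <- cbind(sample.int(n, nb, TRUE), sample.int(n, nb, TRUE))
      bad <- ni[, 1] == ni[, 2] | adj[ni] == 1
    }
    pairs <- rbind(ed, ni)
    y <- rep(c(1, 0), c(n_links, m0))

    diagterm <- rbind(matrix(Eb1, n_links, k, byrow = TRUE),
                      matrix(Eb0, m0, k, byrow = TRUE))
    off <- rep(c(log_eps1, log_eps0), c(n_links, m0))
    lp_i <- Elogpi[pairs[, 1], , drop = FALSE]
    lp_j <- Elogpi[pairs[, 2], , drop = FALSE]
    phi2 <- .softmax_rows(lp_j)
    for (it in seq_len(control$local_iters)) {
      phi1 <- .softmax_rows(lp_i + phi2 * (diagterm - off) + off)
      phi2 <- .softmax_rows(lp_j + phi1 * (diagterm - off) + off)
    }

    wts <- rep(c(1, w0), c(n_links, m0))
    contrib <- rbind(phi1 * wts, phi2 * wts)
    ghat <- matrix(alpha, n, k)
    agg <- rowsum(contrib, c(pairs[, 1], pairs[, 2]), reorder = FALSE)
    ghat[as.integer(rownames(agg)), ] <- ghat[as.integer(rownames(agg)), ] + agg
    gamma <- (1 - rho) * gamma + rho * ghat

    agree <- phi1 * phi2
    lam0 <- (1 - rho) * lam0 + rho * (1 + colSums(agree[y == 1, , drop = FALSE]))
    lam1 <- (1 - rho) * lam1 + rho * (1 + w0 * colSums(agree[y == 0, , drop = FALSE]))

    if (t %% control$check_every == 0L || t == control$max_iters) {
      ll <- .mmsb_objective(adj, gamma / rowSums(gamma), lam0 / (lam0 + lam1), eps)
      if (verbose) message(sprintf("iter %4d  objective %.4f  step %.4g", t, ll, rho))
      if (length(elbo) > 0) {
        rel <- abs(ll - elbo[length(elbo)]) / (abs(elbo[length(elbo)]) + 1e-12)
        stable <- if (rel < control$tol) stable + 1L else 0L
      }
      elbo <- c(elbo, ll)
      if (stable >= control$tol_checks) { converged <- TRUE; t_done <- t; break }
    }
  }

  pi <- gamma / rowSums(gamma)
  structure(list(pi = pi, rates = lam0 / (lam0 + lam1), gamma = gamma,
                 elbo = elbo, converged = converged, iters = t_done,
                 k = as.integer(k), seed = seed, n_nodes = n,
                 density = n_links / n_pairs, control = control,
                 call = match.call()),
            class = "mmsb")
}

# Full-data Bernoulli pseudo log-likelihood of the posterior-mean memberships.
.mmsb_objective <- function(adj, pi, rates, eps) {
  p <- pi %*% (rates * t(pi))
  p <- pmin(pmax(p + eps, eps), 1 - 1e-12)
  up <- upper.tri(adj)
  y <- adj[up]
  sum(y * log(p[up]) + (1 - y) * log1p(-p[up]))
}

.mmsb_init <- function(adj, k, alpha, init, nstart = 10L) {
  n <- nrow(adj)
  if (init == "uniform") {
    return(matrix(alpha + stats::runif(n * k, 0, 0.01), n, k))
  }
  if (init == "spectral") {
    ev <- eigen(adj, symmetric = TRUE)
    v <- ev$vectors[, seq_len(min(k, n)), drop = FALSE]
    cl <- stats::kmeans(v, centers = min(k, n), nstart = nstart)$cluster
  } else {
    cl <- sample.int(k, n, TRUE)
  }
  s <- matrix(0, n, k)
  s[cbind(seq_len(n), cl)] <- 1
  if (init == "labels") s <- s + adj %*% s
  g <- alpha + 10 * .normalize_rows(s + 1e-9) + matrix(stats::runif(n * k), n, k)
  g[rowSums(adj) == 0, ] <- alpha  # isolated nodes start (and stay) uniform
  g
}

.as_adjacency <- function(graph) {
  if (inherits(graph, "benchmark_graph")) graph <- graph$graph
  if (inherits(graph, "fc_graph")) return(graph$adjacency)
  if (is.matrix(graph)) return(fc_graph(graph)$adjacency)
  stop("graph must be an fc_graph, benchmark_graph, or adjacency matrix", call. = FALSE)
}
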