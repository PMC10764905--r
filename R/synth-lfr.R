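#' Parameters of the overlapping LFR-style benchmark generator
#'
#' Benchmark graphs with a truncated power-law degree sequence, power-law
#' community sizes, a tunable fraction of each node's links placed outside its
#' own communities (topological mixing), and a configurable number of
#' overlapping nodes that hold several memberships.
#'
#' Defaults mirror a 542-region cortical parcellation thresholded at 15% edge
#' density: `avg_degree = round(0.15 * (n_nodes - 1))`, community sizes
#' between 5% and 35% of the node count, and a community-size exponent of 0.1
#' (nearly flat across the allowed range).
#'
#' @param n_nodes Number of nodes.
#' @param avg_degree Target mean degree; default matches a 15% edge density.
#' @param mu_topo Topological mixing parameter in `[0, 1)`: target fraction of
#'   each node's links that are external to all of its communities.
#' @param t1 Minus exponent of the degree distribution (> 0).
#' @param t2 Minus exponent of the community-size distribution (> 0).
#' @param c_min,c_max Community-size bounds.
#' @param on Number of overlapping nodes.
#' @param om Memberships per overlapping node (>= 1).
#' @return An object of class `"lfr_params"`.
#' @export
lfr_params <- function(n_nodes = 542L, avg_degree = round(0.15 * (n_nodes - 1)),
                       mu_topo = 0.1, t1 = 2, t2 = 0.1,
                       c_min = round(0.05 * n_nodes),
                       c_max = round(0.35 * n_nodes),
                       on = 0L, om = 2L) {
  if (c_min > c_max || c_max > n_nodes) {
    stop("community-size bounds must satisfy c_min <= c_max <= n_nodes", call. = FALSE)
  }
  if (on < 0 || on > n_nodes) stop("on must lie in [0, n_nodes]", call. = FALSE)
  if (om < 1) stop("om must be >= 1", call. = FALSE)
  if (t1 <= 0 || t2 <= 0) stop("exponents t1, t2 must be positive", call. = FALSE)
  if (mu_topo < 0 || mu_topo >= 1) stop("mu_topo must lie in [0, 1)", call. = FALSE)
  structure(list(n_nodes = as.integer(n_nodes), avg_degree = avg_degree,
                 mu_topo = mu_topo, t1 = t1, t2 = t2,
                 c_min = as.integer(c_min), c_max = as.integer(c_max),
                 on = as.integer(on), om = as.integer(om)),
            class = "lfr_params")
}

# Truncated power-law draw with density proportional to x^(-t) on [a, b].
.rpowerlaw <- function(n, t, a, b) {
  u <- stats::runif(n)
  if (abs(t - 1) < 1e-12) {
    exp(u * (log(b) - log(a)) + log(a))
  } else {
    e <- 1 - t
    (u * (b^e - a^e) + a^e)^(1 / e)
  }
}

# Mean of the continuous truncated power law x^(-t) on [a, b].
.powerlaw_mean <- function(t, a, b) {
  if (abs(t - 1) < 1e-9) return((b - a) / log(b / a))
  if (abs(t - 2) < 1e-9) return(a * b * log(b / a) / (b - a))
  ((b^(2 - t) - a^(2 - t)) / (2 - t)) / ((b^(1 - t) - a^(1 - t)) / (1 - t))
}

# Lower cutoff a such that the truncated power law on [a, k_max] with
# exponent t1 has the requested mean degree; the mean is increasing in a.
.powerlaw_kmin <- function(t1, avg, k_max) {
  lo <- .powerlaw_mean(t1, 1, k_max)
  if (avg < lo || avg > k_max) {
    stop("unrealizable degree sequence: mean degree ", avg,
         " not attainable with exponent ", t1, " and maximum degree ", k_max,
         call. = FALSE)
  }
  stats::uniroot(function(a) .powerlaw_mean(t1, a, k_max) - avg,
                 lower = 1, upper = k_max - 1e-6, tol = 1e-8)$root
}

#' Generate an overlapping LFR-style benchmark graph
#'
#' Builds a binary, symmetric, loop-free graph with planted (possibly
#' overlapping) communities: power-law degrees rescaled to the target mean,
#' power-law community sizes truncated to `[c_min, c_max]`, exactly `on`
#' overlapping nodes carrying `om` memberships each, and a fraction `mu_topo`
#' of each node's links placed outside its communities. Edges are realized by
#' stub matching within and between communities; degree and mixing are matched
#' up to the unavoidable rounding/rejection slack (realized values are
#' reported in the `bookkeeping` element), while the overlapping-node count
#' and memberships-per-node are exact by construction.
#'
#' @param params An [lfr_params()] object.
#' @param seed Integer seed.
#' @param max_retries Retry cap for the rejection-resampling of community
#'   sizes and the capacity-constrained membership assignment (default 100).
#' @return A `"benchmark_graph"` whose `truth` is a binary node-by-community
#'   matrix; `bookkeeping` records realized degree, mixing, and sizes.
#' @export
generate_lfr_graph <- function(params, seed = 1L, max_retries = 100L) {
  stopifnot(inherits(params, "lfr_params"))
  set.seed(seed)
  n <- params$n_nodes
  mu <- params$mu_topo

  # --- degree sequence: power law rescaled to the requested mean, capped so
  # every node's internal degree fits inside the largest community
  k_max <- min(n - 1L, floor((params$c_max - 1) / (1 - mu)))
  if (k_max < 1 || params$avg_degree > k_max) {
    stop("unrealizable degree sequence: target mean degree ", params$avg_degree,
         " exceeds the cap ", k_max, " imposed by c_max and mu_topo", call. = FALSE)
  }
  # Degrees, community sizes, and the capacity-constrained membership
  # assignment are jointly rejection-resampled: a draw that leaves some
  # high-degree node without a large-enough community is discarded whole.
  slots <- n + params$on * (params$om - 1L)
  deg <- sizes <- membership <- NULL
  failure <- "degree/size draw"
  k_min <- .powerlaw_kmin(params$t1, params$avg_degree, k_max)
  for (try in seq_len(max_retries)) {
    d <- .rpowerlaw(n, params$t1, k_min, k_max)
    d <- pmax(1L, pmin(k_max, as.integer(round(d))))

    # community sizes: power-law draws accumulated to the total membership
    # count (overlapping nodes consume om slots each), remainder folded back
    s <- integer(0)
    while (sum(s) < slots) {
      s <- c(s, as.integer(round(.rpowerlaw(1, params$t2, params$c_min, params$c_max))))
    }
    s[length(s)] <- s[length(s)] - (sum(s) - slots)
    if (s[length(s)] < params$c_min) {
      s <- s[-length(s)]
      deficit <- slots - sum(s)
      room <- params$c_max - s
      if (length(s) == 0 || sum(room) < deficit) { failure <- "community sizes"; next }
      add <- pmin(room, pmax(deficit - c(0, cumsum(room))[seq_along(room)], 0))
      s <- s + add
      if (sum(s) != slots) { failure <- "community sizes"; next }
    }

    # membership assignment under capacity and internal-degree constraints
    d_int <- as.integer(round((1 - mu) * d))
    n_mem <- rep(1L, n)
    if (params$on > 0) n_mem[sample.int(n, params$on)] <- params$om
    req <- ceiling(d_int / n_mem)  # internal degree demanded per membership
    cap <- s
    mem <- vector("list", n)
    ok <- TRUE
    for (i in order(req, decreasing = TRUE)) {
      eligible <- which(cap > 0 & s - 1L >= req[i])
      if (length(eligible) < n_mem[i]) { ok <- FALSE; break }
      pick <- if (length(eligible) == 1L) eligible else {
        sample(eligible, n_mem[i], prob = cap[eligible])
      }
      mem[[i]] <- pick
      cap[pick] <- cap[pick] - 1L
    }
    if (!ok) { failure <- "membership capacities"; next }
    deg <- d; sizes <- s; membership <- mem
    break
  }
  if (is.null(membership)) {
    stop("unrealizable benchmark after ", max_retries, " retries (", failure,
         "): node degrees, mixing, and community-size bounds are incompatible",
         call. = FALSE)
  }
  q <- length(sizes)
  d_int <- as.integer(round((1 - mu) * deg))

  # --- internal stubs: split each node's internal degree across its communities
  int_deg <- matrix(0L, n, q)
  for (i in seq_len(n)) {
    cs <- membership[[i]]
    base <- d_int[i] %/% length(cs)
    extra <- d_int[i] %% length(cs)
    dd <- rep(base, length(cs))
    if (extra > 0) dd[sample.int(length(cs), extra)] <- base + 1L
    int_deg[i, cs] <- dd
  }

  # Edge realization by the expected-degree (Chung-Lu) construction: within
  # each community a pair of members links with probability proportional to
  # the product of their internal target degrees, and externally with
  # probability proportional to the product of external target degrees
  # (restricted to pairs sharing no community). Degrees and mixing are thus
  # matched in expectation, without the rejection losses of stub matching in
  # dense communities; realized values are reported in bookkeeping.
  adj <- matrix(0L, n, n)
  for (c_id in seq_len(q)) {
    mem_c <- which(int_deg[, c_id] > 0)
    if (length(mem_c) < 2) next
    kd <- pmin(int_deg[mem_c, c_id], length(mem_c) - 1L)
    if (sum(kd) %% 2L == 1L) kd[which.max(kd)] <- kd[which.max(kd)] - 1L
    gc_ <- suppressWarnings(
      tryCatch(igraph::sample_degseq(kd, method = "vl"),
               error = function(e) tryCatch(
                 igraph::sample_degseq(kd, method = "fast.heur.simple"),
                 error = function(e) NULL)))
    if (!is.null(gc_)) {
      el <- igraph::as_edgelist(gc_, names = FALSE)
      ij <- cbind(mem_c[el[, 1]], mem_c[el[, 2]])
    } else {
      # expected-degree fallback for non-graphical sequences
      p <- pmin(outer(kd, kd) / sum(kd), 1)
      pr <- .upper_pairs(length(mem_c))
      hit <- stats::runif(nrow(pr)) < p[pr]
      ij <- cbind(mem_c[pr[hit, 1]], mem_c[pr[hit, 2]])
    }
    if (nrow(ij)) {
      adj[ij] <- 1L
      adj[ij[, c(2, 1), drop = FALSE]] <- 1L
    }
  }

  # --- external links: pairs that share no community. The exclusion of
  # same-community pairs removes probability mass, so the expected-degree
  # weights are recalibrated by a few proportional-fitting rounds before
  # sampling.
  d_ext <- pmax(0, deg - rowSums(int_deg))
  if (sum(d_ext) > 0) {
    truth_mat <- matrix(0L, n, q)
    for (i in seq_len(n)) truth_mat[i, membership[[i]]] <- 1L
    allowed <- (tcrossprod(truth_mat) == 0) * 1
    w <- d_ext
    for (it in 1:4) {
      expected <- w * as.vector(allowed %*% w) / max(sum(w), 1)
      ratio <- ifelse(expected > 0, d_ext / expected, 1)
      w <- w * pmin(ratio, 10)
    }
    p_ext <- pmin(outer(w, w) / max(sum(w), 1), 1) * allowed
    pr <- .upper_pairs(n)
    hit <- stats::runif(nrow(pr)) < p_ext[pr]
    if (any(hit)) {
      ij <- pr[hit, , drop = FALSE]
      adj[ij] <- 1L
      adj[ij[, c(2, 1), drop = FALSE]] <- 1L
    }
  }

  truth <- matrix(0L, n, q)
  for (i in seq_len(n)) truth[i, membership[[i]]] <- 1L

  realized_deg <- rowSums(adj)
  # realized mixing: fraction of each node's links outside all its communities
  same_comm <- tcrossprod(truth) > 0
  ext_links <- rowSums(adj * !same_comm)
  realized_mu <- sum(ext_links) / max(1, sum(realized_deg))

  structure(list(graph = fc_graph(adj), truth = truth, params = params, seed = seed,
                 bookkeeping = list(sizes = sizes,
                                    requested_avg_degree = params$avg_degree,
                                    realized_avg_degree = mean(realized_deg),
                                    requested_mu = mu, realized_mu = realized_mu)),
            class = "benchmark_graph")
}
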