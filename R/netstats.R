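#' Membership diversity (normalized Shannon entropy)
#'
#' Base-K Shannon entropy of a node's membership vector, with the
#' `0 * log 0 = 0` convention. 0 means the node belongs to a single network
#' (disjoint); 1 means it belongs to all K networks with equal strength. A
#' node split evenly between exactly two of K networks scores `log_K(2)`
#' (about 0.356 for K = 7).
#'
#' @param pi Membership vector, or node-by-k matrix (one value per row).
#' @param k Number of communities; defaults to the vector length/column
#'   count.
#' @return Entropy value(s) in `[0, 1]`.
#' @examples
#' node_entropy(c(0.5, 0.5, 0, 0, 0, 0, 0))  # log_7(2)
#' @export
node_entropy <- function(pi, k = NULL) {
  if (is.matrix(pi)) {
    k <- k %||% ncol(pi)
    return(.entropy_rows(pi, k))
  }
  k <- k %||% length(pi)
  .entropy_rows(matrix(pi, nrow = 1), k)[1]
}

#' Threshold an animal's memberships by a one-sample t-test
#'
#' For every node-community entry, tests across the animal's runs whether the
#' membership differs from zero (one-sample t-test); p-values are corrected by
#' Benjamini-Hochberg FDR across all entries of the animal, non-significant
#' entries are zeroed, and the surviving values of each row are rescaled to
#' sum to 1. Zero-variance entries are decided by their mean (a constant
#' positive membership is kept, a constant zero is dropped). Rows losing all
#' entries are left at zero with a warning.
#'
#' @param per_run_pis List of node-by-k membership matrices, one per run of
#'   one animal.
#' @param fdr_q FDR level (default 0.05).
#' @return The thresholded, renormalized animal-level mean membership matrix,
#'   with attribute `"p_values"`.
#' @export
threshold_memberships <- function(per_run_pis, fdr_q = 0.05) {
  if (length(per_run_pis) < 2L) {
    stop("need at least two runs for the one-sample t-test", call. = FALSE)
  }
  arr <- simplify2array(per_run_pis)        # N x k x runs
  m <- apply(arr, c(1, 2), mean)
  s <- apply(arr, c(1, 2), stats::sd)
  n <- length(per_run_pis)
  tt <- m / (s / sqrt(n))
  p <- 2 * stats::pt(abs(tt), df = n - 1, lower.tail = FALSE)
  p[s == 0 & m > 0] <- 0
  p[s == 0 & m == 0] <- 1
  keep <- matrix(stats::p.adjust(p, "BH") <= fdr_q, nrow(m))
  out <- m * keep
  dead <- rowSums(out) == 0
  if (any(dead)) warning(sum(dead), " node(s) lost all memberships at q = ", fdr_q)
  out <- .normalize_rows(out)
  attr(out, "p_values") <- p
  out
}

#' Belonging configuration
#'
#' @param mu0 Null membership level a value must exceed to count as belonging
#'   (default `1/k`, supplied by the caller).
#' @param alpha_level Significance level (default 0.05).
#' @param correction Multiplicity correction, `"BH"` or `"none"`.
#' @param df Degrees of freedom of the t reference distribution; `Inf` (the
#'   default) uses the normal approximation appropriate for bootstrap SEs.
#' @return A list of class `"belonging_config"`.
#' @export
belonging_config <- function(mu0, alpha_level = 0.05,
                             correction = c("BH", "none"), df = Inf) {
  if (mu0 <= 0 || mu0 >= 1) stop("mu0 must lie in (0, 1)", call. = FALSE)
  structure(list(mu0 = mu0, alpha_level = alpha_level,
                 correction = match.arg(correction), df = df),
            class = "belonging_config")
}

#' Belonging matrix, belonging counts, and overlap score
#'
#' A node "belongs to" a network when its group-average membership is
#' statistically greater than the null level `mu0`: the one-sided t-statistic
#' `(pi_bar - mu0) / SE` is converted to a p-value, corrected across all
#' node-community entries, and thresholded at the configured level. The
#' overlap score is the fraction of nodes belonging to more than one network.
#'
#' @param group_pi Group-level node-by-k membership matrix.
#' @param se Matrix of standard errors (same shape), typically from
#'   [hierarchical_bootstrap()].
#' @param cfg A [belonging_config()].
#' @return List with `belonging` (binary matrix), `counts` (per-node number
#'   of networks), and `overlap_score`.
#' @export
belonging_matrix <- function(group_pi, se, cfg) {
  stopifnot(inherits(cfg, "belonging_config"))
  if (!all(dim(group_pi) == dim(se))) stop("se must match group_pi in shape", call. = FALSE)
  tt <- (group_pi - cfg$mu0) / pmax(se, 1e-300)
  p <- stats::pt(tt, df = cfg$df, lower.tail = FALSE)
  if (cfg$correction == "BH") p <- matrix(stats::p.adjust(p, "BH"), nrow(p))
  belonging <- (p <= cfg$alpha_level) * 1L
  counts <- rowSums(belonging)
  list(belonging = belonging, counts = counts,
       overlap_score = mean(counts > 1))
}

#' Membership tiers by statistical thresholding
#'
#' Bins each significant membership into tiers: a node-community entry is
#' assigned the highest multiplier `m` such that the one-sided test of
#' `pi_bar > m / k` is significant (after correction). Entries significant at
#' no tier get 0. Default multipliers follow bins incremented by `1/k` with a
#' permissive lowest tier.
#'
#' @param group_pi Group-level membership matrix.
#' @param se Standard-error matrix.
#' @param tier_multipliers Increasing multipliers of `1/k` (default
#'   `c(0.05, 1, 2, 3.5)`; an alternative reading of the lowest tier is 0.5).
#' @param alpha_level,correction,df As in [belonging_config()].
#' @return Integer matrix of tier indices (0 = none, `length(tier_multipliers)`
#'   = highest).
#' @export
membership_tiers <- function(group_pi, se, tier_multipliers = c(0.05, 1, 2, 3.5),
                             alpha_level = 0.05, correction = "BH", df = Inf) {
  k <- ncol(group_pi)
  tiers <- matrix(0L, nrow(group_pi), k)
  for (ti in seq_along(tier_multipliers)) {
    if (tier_multipliers[ti] / k >= 1) next  # unattainable above full membership
    cfg <- belonging_config(mu0 = tier_multipliers[ti] / k,
                            alpha_level = alpha_level,
                            correction = correction, df = df)
    sig <- belonging_matrix(group_pi, se, cfg)$belonging
    tiers[sig == 1L] <- ti
  }
  tiers
}

#' Binned membership distribution above a robustness floor
#'
#' Histograms the membership values of each community into bins covering
#' `(floor, 1]`, expressed as the percentage of all nodes; values at or below
#' the floor (where a fully disjoint benchmark still spreads its residual
#' strength) are excluded and reported in the `"excluded_pct"` attribute.
#'
#' @param pi Node-by-k membership matrix (one run, or an average).
#' @param bin_width Bin width (default 0.2, giving 4 bins over (0.2, 1]).
#' @param floor Lowest considered membership value (default 0.2).
#' @return Bins-by-community matrix of percentages.
#' @export
membership_distribution <- function(pi, bin_width = 0.2, floor = 0.2) {
  breaks <- seq(floor, 1, by = bin_width)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  n <- nrow(pi)
  out <- sapply(seq_len(ncol(pi)), function(k) {
    v <- pi[, k]
    v <- v[v > floor]
    100 * as.vector(table(cut(v, breaks = breaks, include.lowest = FALSE))) / n
  })
  rownames(out) <- paste0("(", utils::head(breaks, -1), ",", breaks[-1], "]")
  attr(out, "excluded_pct") <- 100 * colMeans(pi <= floor)
  out
}

#' Per-node degree statistics of a binary graph
#'
#' @param graph An [fc_graph()] or adjacency matrix.
#' @param weights Optional symmetric weight (correlation) matrix; the weighted
#'   degree sums the weights of retained edges.
#' @return Data frame with `degree`, `normalized_degree` (fraction of the
#'   region count), and (when weights are given) `weighted_degree`.
#' @export
degree_stats <- function(graph, weights = NULL) {
  adj <- .as_adjacency(graph)
  n <- nrow(adj)
  deg <- rowSums(adj)
  out <- data.frame(degree = deg, normalized_degree = deg / n)
  if (!is.null(weights)) {
    .check_square_symmetric(weights, "weights")
    out$weighted_degree <- rowSums(adj * weights)
  }
  out
}

#' Percentile map from run-level values
#'
#' Computes a one-sample t-statistic per node across runs and rank-orders the
#' statistics into percentiles, discounting magnitude differences between
#' conditions.
#'
#' @param values_per_run Node-by-run matrix of a statistic.
#' @return Vector of percentiles in (0, 100].
#' @export
percentile_map <- function(values_per_run) {
  n <- ncol(values_per_run)
  m <- rowMeans(values_per_run)
  s <- apply(values_per_run, 1, stats::sd)
  tt <- m / (s / sqrt(n))
  tt[s == 0] <- sign(m[s == 0]) * Inf
  100 * rank(tt, ties.method = "average") / length(tt)
}

#' Participation coefficient over hard modules
#'
#' `1 - sum_s (k_is / k_i)^2`, where `k_is` counts node i's links into module
#' s. 0 for nodes whose links stay within one module; `1 - 1/K` for links
#' spread evenly over K modules. Isolated nodes are set to 0 by convention;
#' their count is reported in the `"n_isolated"` attribute.
#'
#' @param graph An [fc_graph()] or adjacency matrix.
#' @param labels Integer module label per node (e.g. from [disjointify()]).
#' @return Numeric vector of participation coefficients.
#' @export
participation_coefficient <- function(graph, labels) {
  adj <- .as_adjacency(graph)
  n <- nrow(adj)
  if (length(labels) != n) stop("labels must have one entry per node", call. = FALSE)
  mods <- sort(unique(labels))
  s <- matrix(0, n, length(mods))
  s[cbind(seq_len(n), match(labels, mods))] <- 1
  k_is <- adj %*% s
  k_i <- rowSums(adj)
  pc <- 1 - rowSums((k_is / pmax(k_i, 1))^2)
  pc[k_i == 0] <- 0
  attr(pc, "n_isolated") <- sum(k_i == 0)
  pc
}

#' Similarity between two network maps on a 0-1 scale
#'
#' Cosine similarity between two community membership columns, mapped
#' affinely from `[-1, 1]` to `[0, 1]` so that 1 means identical, 0.5
#' orthogonal/unrelated, and 0 perfectly inversely related. Columns are
#' mean-centered before the cosine (so "inversely correlated" is attainable
#' for nonnegative memberships); the raw uncentered cosine is kept in the
#' `"raw_cosine"` attribute.
#'
#' @param u,v Numeric vectors (membership columns of one network each).
#' @param center Mean-center before the cosine (default TRUE).
#' @return Scalar similarity in `[0, 1]`.
#' @export
network_cosine_similarity <- function(u, v, center = TRUE) {
  if (length(u) != length(v)) stop("u and v must have equal length", call. = FALSE)
  raw <- sum(u * v) / max(sqrt(sum(u^2)) * sqrt(sum(v^2)), 1e-300)
  if (center) { u <- u - mean(u); v <- v - mean(v) }
  cc <- sum(u * v) / max(sqrt(sum(u^2)) * sqrt(sum(v^2)), 1e-300)
  out <- (cc + 1) / 2
  attr(out, "raw_cosine") <- raw
  out
}

#' Per-network and collapsed similarity between two membership matrices
#'
#' Applies [network_cosine_similarity()] to each aligned community pair and
#' collapses across networks by the mean.
#'
#' @param a,b Node-by-k membership matrices with corresponding columns.
#' @param center Mean-center columns before the cosine.
#' @return List with `per_network` (length-k vector) and `overall`.
#' @export
network_similarity_profile <- function(a, b, center = TRUE) {
  if (!all(dim(a) == dim(b))) stop("a and b must have identical dimensions", call. = FALSE)
  per <- vapply(seq_len(ncol(a)), function(k)
    as.numeric(network_cosine_similarity(a[, k], b[, k], center = center)),
    numeric(1))
  list(per_network = per, overall = mean(per))
}

#' Disjoint labels from a membership matrix
#'
#' Collapses memberships to hard labels by each node's maximum membership.
#' Ties are broken by the lowest community index; the number of tied nodes is
#' reported in the `"n_ties"` attribute.
#'
#' @param pi Node-by-k membership matrix.
#' @return Integer label vector.
#' @export
disjointify <- function(pi) {
  lab <- max.col(pi, ties.method = "first")
  mx <- pi[cbind(seq_len(nrow(pi)), lab)]
  n_ties <- sum(rowSums(pi == mx) > 1)
  attr(lab, "n_ties") <- n_ties
  lab
}
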