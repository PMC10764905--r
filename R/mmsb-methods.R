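#' Pairwise link probability under the mixed-membership model
#'
#' The marginal probability that two nodes connect given their membership
#' vectors and the per-community link rates: `sum_k pi_ik pi_jk beta_k`,
#' clipped to `[0, 1]`.
#'
#' @param pi_i,pi_j Membership vectors (nonnegative, summing to 1).
#' @param rates Per-community link rates; scalar or length-K.
#' @return A single probability.
#' @examples
#' predict_link_prob(c(0.5, 0.5), c(0.5, 0.5), rates = 1)  # 0.5
#' @export
predict_link_prob <- function(pi_i, pi_j, rates = 1) {
  if (length(pi_i) != length(pi_j)) stop("membership vectors differ in length", call. = FALSE)
  rates <- rep_len(rates, length(pi_i))
  min(max(sum(pi_i * pi_j * rates), 0), 1)
}

#' @export
print.mmsb <- function(x, ...) {
  cat(sprintf("Mixed-membership blockmodel fit: %d nodes, k = %d (seed %d)\n",
              x$n_nodes, x$k, x$seed))
  cat(sprintf("  graph density %.3f | %s after %d iterations\n",
              x$density, if (x$converged) "converged" else "iteration cap reached",
              x$iters))
  cat(sprintf("  median max membership %.3f | community rates %s\n",
              stats::median(apply(x$pi, 1, max)),
              paste(sprintf("%.2f", x$rates), collapse = " ")))
  invisible(x)
}

#' @export
summary.mmsb <- function(object, ...) {
  mx <- apply(object$pi, 1, max)
  h <- .entropy_rows(object$pi, object$k)
  out <- list(k = object$k, n_nodes = object$n_nodes, seed = object$seed,
              converged = object$converged, iters = object$iters,
              rates = object$rates,
              max_membership = stats::quantile(mx, c(0.05, 0.25, 0.5, 0.75, 0.95)),
              entropy = stats::quantile(h, c(0.05, 0.5, 0.95)),
              community_sizes = table(disjointify(object$pi)),
              objective = utils::tail(object$elbo, 1))
  class(out) <- "summary.mmsb"
  out
}

#' @export
print.summary.mmsb <- function(x, ...) {
  cat(sprintf("Mixed-membership blockmodel (k = %d, %d nodes, seed %d)\n",
              x$k, x$n_nodes, x$seed))
  cat(sprintf("%s after %d iterations; objective %.2f\n",
              if (x$converged) "Converged" else "Stopped", x$iters, x$objective))
  cat("Max membership quantiles:\n"); print(round(x$max_membership, 3))
  cat("Membership entropy quantiles:\n"); print(round(x$entropy, 3))
  cat("Disjoint community sizes:\n"); print(x$community_sizes)
  invisible(x)
}

#' @export
coef.mmsb <- function(object, ...) object$pi

#' Predicted link probabilities of a fitted blockmodel
#'
#' @param object An `"mmsb"` fit.
#' @param pairs Optional 2-column matrix of node indices; when omitted the
#'   full N x N probability matrix is returned (zero diagonal).
#' @param ... Unused.
#' @return A probability matrix or, with `pairs`, a vector.
#' @export
predict.mmsb <- function(object, pairs = NULL, ...) {
  p <- object$pi %*% (object$rates * t(object$pi))
  p <- pmin(pmax(p, 0), 1)
  diag(p) <- 0
  if (is.null(pairs)) p else p[pairs]
}

#' @export
residuals.mmsb <- function(object, graph, ...) {
  adj <- .as_adjacency(graph)
  if (nrow(adj) != object$n_nodes) stop("graph size does not match the fit", call. = FALSE)
  adj - predict(object)
}

#' Simulate graphs from a fitted mixed-membership blockmodel
#'
#' Draws new graphs through the model's own generative process (per-pair
#' community indicators from the fitted memberships, link on agreement with
#' the fitted rates).
#'
#' @param object An `"mmsb"` fit.
#' @param nsim Number of graphs.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A list of `"benchmark_graph"` objects.
#' @export
simulate.mmsb <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$n_nodes
  pairs <- .upper_pairs(n)
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    z1 <- .sample_categories(object$pi[pairs[, 1], , drop = FALSE])
    z2 <- .sample_categories(object$pi[pairs[, 2], , drop = FALSE])
    linked <- z1 == z2 & stats::runif(nrow(pairs)) < object$rates[z1]
    adj <- matrix(0L, n, n)
    adj[pairs[linked, , drop = FALSE]] <- 1L
    adj <- adj + t(adj)
    out[[s]] <- structure(list(graph = fc_graph(adj), truth = object$pi,
                               params = object$rates, seed = seed),
                          class = "benchmark_graph")
  }
  out
}

#' Membership heat map of a fitted blockmodel
#'
#' @param x An `"mmsb"` fit.
#' @param order_nodes Sort nodes by disjoint label and membership strength.
#' @param ... Passed to [graphics::image()].
#' @export
plot.mmsb <- function(x, order_nodes = TRUE, ...) {
  pi <- x$pi
  if (order_nodes) {
    lab <- disjointify(pi)
    pi <- pi[order(lab, -apply(pi, 1, max)), , drop = FALSE]
  }
  graphics::image(t(pi)[, rev(seq_len(nrow(pi))), drop = FALSE],
                  axes = FALSE, xlab = "community", ylab = "node",
                  main = sprintf("memberships (k = %d)", x$k), ...)
  graphics::axis(1, at = seq(0, 1, length.out = x$k), labels = seq_len(x$k))
  invisible(x)
}
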