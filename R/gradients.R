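#' Diffusion-map connectivity gradients
#'
#' Decomposes a group-averaged functional-connectivity matrix into continuous
#' axes of variation (gradients) via diffusion-map embedding: each row is
#' sparsified to its strongest connections, a cosine-affinity kernel is built
#' between the sparsified connectivity profiles, the kernel receives the
#' anisotropic normalization `W / (d_i^alpha d_j^alpha)`, and the resulting
#' Markov operator is eigendecomposed. Components are ordered by eigenvalue
#' magnitude and z-scored (gradient units are arbitrary); the variance
#' fraction of component m is `lambda_m / sum(lambda)` over the non-trivial
#' spectrum.
#'
#' @param group_fc Symmetric group-average correlation matrix.
#' @param n_components Number of gradients to return (< N).
#' @param sparsify_top Fraction of each row's strongest entries kept
#'   (default 0.1).
#' @param diffusion_alpha Anisotropic-normalization exponent in `[0, 1]`
#'   (default 0.5).
#' @return An object of class `"gradient_set"`: `components` (N x M,
#'   z-scored, sign fixed so the largest-magnitude loading is positive),
#'   `eigenvalues`, and `variance_fraction` (non-increasing, summing to <= 1).
#' @examples
#' fc <- matrix(0.2, 20, 20); fc[1:10, 1:10] <- fc[11:20, 11:20] <- 0.8
#' diag(fc) <- 1
#' # small matrices need a generous row-sparsification to stay connected
#' g <- compute_gradients(fc, n_components = 2, sparsify_top = 0.5)
#' g$variance_fraction
#' @export
compute_gradients <- function(group_fc, n_components = 4L,
                              sparsify_top = 0.1, diffusion_alpha = 0.5) {
  .check_square_symmetric(group_fc, "group_fc")
  n <- nrow(group_fc)
  if (n_components >= n) stop("n_components must be smaller than the node count", call. = FALSE)

  # row sparsification: keep each row's strongest off-diagonal entries
  a <- group_fc
  diag(a) <- 0
  m_keep <- max(1L, ceiling(sparsify_top * (n - 1)))
  for (i in seq_len(n)) {
    thr <- sort(a[i, ], decreasing = TRUE)[m_keep]
    a[i, a[i, ] < thr] <- 0
  }

  # cosine affinity between sparsified connectivity profiles; negative
  # affinities are clipped so the kernel stays admissible
  norms <- sqrt(rowSums(a^2))
  w <- tcrossprod(a) / outer(pmax(norms, 1e-300), pmax(norms, 1e-300))
  w <- pmax(w, 0)
  diag(w) <- 1

  comp <- igraph::components(igraph::graph_from_adjacency_matrix(
    (w > 0) * 1, mode = "undirected", diag = FALSE))
  if (comp$no > 1) {
    stop("affinity graph is disconnected (", comp$no,
         " components); gradients are undefined", call. = FALSE)
  }

  # anisotropic normalization and symmetrized Markov operator
  d <- rowSums(w)
  w1 <- w / outer(d^diffusion_alpha, d^diffusion_alpha)
  d1 <- rowSums(w1)
  s <- w1 / outer(sqrt(d1), sqrt(d1))
  es <- eigen(s, symmetric = TRUE)

  ord <- order(abs(es$values), decreasing = TRUE)
  vals <- es$values[ord]
  vecs <- es$vectors[, ord, drop = FALSE]
  # drop the trivial stationary component (eigenvalue 1)
  vals_nt <- vals[-1]
  vecs_nt <- vecs[, -1, drop = FALSE] / sqrt(d1)
  pos <- pmax(vals_nt, 0)
  varfrac <- pos / sum(pos)

  take <- seq_len(n_components)
  comps <- vecs_nt[, take, drop = FALSE]
  comps <- apply(comps, 2, function(v) {
    v <- v * sign(v[which.max(abs(v))])
    as.numeric(scale(v))
  })
  structure(list(components = comps, eigenvalues = vals_nt[take],
                 variance_fraction = varfrac[take]),
            class = "gradient_set")
}

#' @export
print.gradient_set <- function(x, ...) {
  cat(sprintf("<gradient_set> %d gradients over %d nodes; variance fractions: %s\n",
              ncol(x$components), nrow(x$components),
              paste(sprintf("%.3f", x$variance_fraction), collapse = " ")))
  invisible(x)
}

#' Match gradients between two conditions
#'
#' Pearson-correlates all pairs of gradients from two gradient sets and finds
#' the pairing that maximizes total absolute correlation (eigenvector signs
#' are arbitrary, so matching ignores sign while the raw signed correlations
#' are returned).
#'
#' @param a,b `"gradient_set"` objects over the same nodes.
#' @return List with `correlation` (M x M signed Pearson matrix, rows = `a`),
#'   `pairing` (for each gradient of `a`, the matched column of `b`), and
#'   `matched_correlation` (signed correlation of each matched pair).
#' @export
match_gradients <- function(a, b) {
  stopifnot(inherits(a, "gradient_set"), inherits(b, "gradient_set"))
  cc <- stats::cor(a$components, b$components)
  row_to_col <- .lsap_min(-abs(cc))
  list(correlation = cc, pairing = row_to_col,
       matched_correlation = cc[cbind(seq_along(row_to_col), row_to_col)])
}
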