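# Internal helpers shared across modules.

# Renormalize rows to the unit simplex; rows summing to zero are left at zero.
.normalize_rows <- function(x) {
  rs <- rowSums(x)
  ok <- rs > 0
  x[ok, ] <- x[ok, , drop = FALSE] / rs[ok]
  x
}

.check_membership <- function(pi, tol = 1e-9) {
  if (!is.matrix(pi) || !is.numeric(pi)) {
    stop("membership matrix must be a numeric matrix", call. = FALSE)
  }
  if (any(pi < -tol) || any(pi > 1 + tol)) {
    stop("membership values must lie in [0, 1]", call. = FALSE)
  }
  rs <- rowSums(pi)
  if (any(abs(rs - 1) > 1e-6 & rs > 0)) {
    stop("membership rows must sum to 1 (or be all zero)", call. = FALSE)
  }
  invisible(pi)
}

.check_square_symmetric <- function(m, name = "matrix", tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop(name, " must be a square matrix", call. = FALSE)
  }
  if (max(abs(m - t(m))) > tol) {
    stop(name, " must be symmetric", call. = FALSE)
  }
  invisible(m)
}

# All unordered node pairs (i < j) of an N-node graph, as a 2-column matrix.
.upper_pairs <- function(n) {
  which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
}

# Row-wise softmax with overflow guard. Row maxima via iterated pmax over
# the (few) columns, much faster than apply() on tall matrices.
.softmax_rows <- function(x) {
  m <- x[, 1]
  for (j in seq_len(ncol(x))[-1]) m <- pmax(m, x[, j])
  x <- exp(x - m)
  x / rowSums(x)
}

# Vectorized categorical draw: one index per row of the probability matrix.
.sample_categories <- function(prob) {
  cs <- t(apply(prob, 1, cumsum))
  u <- stats::runif(nrow(prob)) * cs[, ncol(cs)]
  as.integer(rowSums(u > cs) + 1L)
}

# Base-K entropy of probability rows with the 0 * log 0 = 0 convention.
.entropy_rows <- function(p, k) {
  lp <- ifelse(p > 0, log(p), 0)
  h <- -rowSums(p * lp) / log(k)
  pmin(pmax(h, 0), 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
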