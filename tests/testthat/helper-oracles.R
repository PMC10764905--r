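# Independent oracles and small fixture builders used across test files.

# Two disjoint cliques of size m each.
two_cliques_adj <- function(m = 20) {
  n <- 2 * m
  adj <- matrix(0L, n, n)
  adj[seq_len(m), seq_len(m)] <- 1L
  adj[m + seq_len(m), m + seq_len(m)] <- 1L
  diag(adj) <- 0L
  adj
}

# All permutations of 1..k (k small).
all_perms <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in all_perms(k - 1)) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
    }
  }
  out
}

# Brute-force assignment: permutation maximizing sum(sim[perm[j], j]).
brute_assignment <- function(sim) {
  k <- ncol(sim)
  best <- NULL; best_val <- -Inf
  for (p in all_perms(k)) {
    val <- sum(sim[cbind(p, seq_len(k))])
    if (val > best_val) { best_val <- val; best <- p }
  }
  list(perm = best, value = best_val)
}

# Textbook step-down Holm procedure, applied literally.
holm_textbook <- function(p, alpha = 0.05) {
  m <- length(p)
  ord <- order(p)
  reject <- logical(m)
  for (i in seq_len(m)) {
    if (p[ord[i]] <= alpha / (m - i + 1)) reject[ord[i]] <- TRUE else break
  }
  reject
}

# Textbook step-up Benjamini-Hochberg procedure, applied literally.
bh_textbook <- function(p, q = 0.05) {
  m <- length(p)
  ord <- order(p)
  k_star <- 0L
  for (i in seq_len(m)) if (p[ord[i]] <= i / m * q) k_star <- i
  reject <- logical(m)
  if (k_star > 0) reject[ord[seq_len(k_star)]] <- TRUE
  reject
}

# Exact sign-flip distribution of the mean paired difference.
exact_signflip_p <- function(d) {
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  stat <- as.vector(signs %*% d) / n
  obs <- mean(d)
  mean(abs(stat) >= abs(obs) - 1e-12)
}

# Brute-force participation coefficient by per-module edge counting.
participation_brute <- function(adj, labels) {
  n <- nrow(adj)
  vapply(seq_len(n), function(i) {
    ki <- sum(adj[i, ])
    if (ki == 0) return(0)
    1 - sum(vapply(unique(labels), function(s)
      (sum(adj[i, labels == s]) / ki)^2, numeric(1)))
  }, numeric(1))
}

random_simplex <- function(n, k) {
  g <- matrix(rexp(n * k), n, k)
  g / rowSums(g)
}
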