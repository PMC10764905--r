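# Alignment of community solutions across seeds, runs, and animals.

# Shortest-augmenting-path solver for the square linear assignment problem
# (minimization). Returns perm with perm[row] = assigned column. O(n^3);
# deterministic, so ties at equal cost resolve to the lowest column index.
.lsap_min <- function(cost) {
  n <- nrow(cost)
  if (ncol(cost) != n) stop("cost matrix must be square", call. = FALSE)
  u <- numeric(n); v <- numeric(n + 1)
  p <- integer(n + 1)          # p[j] = row matched to column j (0 = free)
  way <- integer(n)
  for (i in seq_len(n)) {
    p[n + 1] <- i
    j0 <- n + 1
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(n + 1)) {
        if (used[j]) {
          if (p[j] > 0) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1) break
    }
  }
  perm <- integer(n)
  for (j in seq_len(n)) perm[p[j]] <- j
  perm
}

#' Optimal assignment maximizing total similarity
#'
#' Hungarian (shortest augmenting path) solution of the linear assignment
#' problem on a similarity matrix: returns the permutation `perm` such that
#' `sum_k sim[perm[k], k]` is maximal, i.e. `perm[k]` is the row matched to
#' column `k`.
#'
#' @param sim Square similarity matrix (rows = sources, columns = targets).
#' @return Integer permutation of `seq_len(ncol(sim))`.
#' @examples
#' max_assignment(diag(3)[, c(2, 1, 3)])  # recovers the swap
#' @export
max_assignment <- function(sim) {
  row_to_col <- .lsap_min(-sim)
  perm <- integer(length(row_to_col))
  perm[row_to_col] <- seq_along(row_to_col)  # perm[col] = row
  perm
}

# Cosine similarity between all column pairs of two matrices; zero columns
# yield similarity 0.
.column_cosine <- function(a, b) {
  na <- sqrt(colSums(a^2)); nb <- sqrt(colSums(b^2))
  s <- crossprod(a, b) / outer(pmax(na, 1e-300), pmax(nb, 1e-300))
  s[na == 0, ] <- 0
  s[, nb == 0] <- 0
  s
}

#' Align a membership solution to target centroids
#'
#' Computes the pairwise cosine similarity between the source's community
#' columns and the centroid columns, and finds the column permutation that
#' maximizes the total diagonal similarity (Hungarian assignment). The
#' aligned matrix is the source with its columns permuted accordingly.
#'
#' @param source Node-by-k membership matrix to align.
#' @param centroids Node-by-k target matrix (e.g. k-means centroids).
#' @return A list of class `"alignment"`: `permutation` (`aligned[, j] ==
#'   source[, permutation[j]]`), `similarity` (k x k cosine matrix,
#'   source columns by target columns), and `aligned`.
#' @export
align_to_centroids <- function(source, centroids) {
  if (!is.matrix(source) || !is.matrix(centroids) ||
      !all(dim(source) == dim(centroids))) {
    stop("source and centroids must be matrices of identical dimensions", call. = FALSE)
  }
  sim <- .column_cosine(source, centroids)
  perm <- max_assignment(sim)
  structure(list(permutation = perm, similarity = sim,
                 aligned = source[, perm, drop = FALSE]),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat("<alignment> permutation:", paste(x$permutation, collapse = " "),
      sprintf("| mean diagonal similarity %.3f\n",
              mean(x$similarity[cbind(x$permutation, seq_along(x$permutation))])))
  invisible(x)
}

#' Consensus membership matrix over random seeds
#'
#' Pools the community membership columns from all per-seed fits, clusters the
#' distinct column profiles into `k` centroids with k-means, aligns every
#' seed's solution to the centroids (cosine similarity + Hungarian
#' assignment), averages the aligned matrices, and renormalizes rows to the
#' simplex. The result is invariant to arbitrary column permutations of the
#' individual seed solutions; its column order is anchored to the first
#' seed's solution (permuting that seed permutes the output columns
#' correspondingly, nothing else changes).
#'
#' @param fits List of node-by-k membership matrices (or `"mmsb"` fits).
#' @param k Number of communities.
#' @param seed Seed controlling the k-means restarts.
#' @param nstart k-means restarts (the lowest within-cluster inertia solution
#'   is kept).
#' @return A node-by-k consensus membership matrix.
#' @export
consensus_over_seeds <- function(fits, k, seed = 1L, nstart = 50L) {
  fits <- lapply(fits, function(f) if (inherits(f, "mmsb")) f$pi else f)
  if (length(fits) == 0L) stop("no fits supplied", call. = FALSE)
  if (any(vapply(fits, ncol, integer(1)) != k)) {
    stop("all fits must have k = ", k, " communities", call. = FALSE)
  }
  cols <- t(do.call(cbind, fits))           # (n_seeds * k) x N
  uniq <- unique(cols)
  set.seed(seed)
  centroids <- if (nrow(uniq) == k) {
    t(uniq)
  } else if (nrow(uniq) < k) {
    stop("fewer than k distinct community profiles across seeds", call. = FALSE)
  } else {
    t(stats::kmeans(uniq, centers = k, nstart = nstart)$centers)
  }
  # anchor the (arbitrary) centroid order to the first seed's solution so
  # the consensus column order is stable and identical seeds round-trip
  centroids <- align_to_centroids(centroids, fits[[1]])$aligned
  aligned <- lapply(fits, function(f) align_to_centroids(f, centroids)$aligned)
  .normalize_rows(Reduce(`+`, aligned) / length(aligned))
}

# Align a list of matrices to a running centroid and average; order fixed by
# the list's (sorted) position to keep results independent of input order.
.aligned_average <- function(mats) {
  ref <- mats[[1]]
  acc <- ref
  n <- 1
  for (m in mats[-1]) {
    acc <- acc + align_to_centroids(m, acc / n)$aligned
    n <- n + 1
  }
  .normalize_rows(acc / n)
}

#' Aggregate run-level memberships up the experimental hierarchy
#'
#' Runs are averaged within session, sessions within animal, and animals into
#' a group result. At every stage each matrix is aligned (cosine + Hungarian)
#' to the running centroid of its level before averaging, and rows are
#' renormalized to the simplex after each average.
#'
#' @param pis List of node-by-k run-level membership matrices.
#' @param index Data frame with one row per element of `pis`, columns
#'   `animal` and `session` (e.g. from [dataset_index()]).
#' @return A list with `session` (named list, `animal/session` keys),
#'   `animal` (named list), and `group` (matrix).
#' @export
aggregate_hierarchy <- function(pis, index) {
  if (length(pis) != nrow(index)) {
    stop("index must have one row per membership matrix", call. = FALSE)
  }
  skey <- paste(index$animal, index$session, sep = "/")
  session <- lapply(split(seq_along(pis), skey), function(ii) .aligned_average(pis[ii]))
  animal_of <- vapply(strsplit(names(session), "/"), `[`, "", 1)
  animal <- lapply(split(seq_along(session), animal_of),
                   function(ii) .aligned_average(session[ii]))
  group <- .aligned_average(animal[order(names(animal))])
  list(session = session, animal = animal, group = group)
}
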