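#' Zero-phase Butterworth band-pass filter for a run
#'
#' Applies a forward-backward (zero-phase) Butterworth filter to every ROI
#' trace and trims edge frames distorted by the filter. The forward-backward
#' pass doubles the effective filter order; the `order` argument refers to the
#' order of the underlying one-pass design.
#'
#' @param run A [run_record()].
#' @param low_hz,high_hz Pass-band edges in Hz; `0 <= low_hz < high_hz <= fs/2`.
#'   A `low_hz` of 0 yields a pure low-pass design.
#' @param order Butterworth order of the one-pass design (default 3).
#' @param trim Number of frames discarded from both the beginning and the end
#'   after filtering (default 15), to suppress edge artifacts.
#' @return The filtered, trimmed [run_record()] (motion trace trimmed in step).
#' @examples
#' r <- run_record(matrix(rnorm(2 * 600), 2, 600), fs = 1)
#' filtered <- bandpass_filter(r, 0.01, 0.4)
#' ncol(filtered$signal)  # 600 - 2 * 15
#' @export
bandpass_filter <- function(run, low_hz, high_hz, order = 3L, trim = 15L) {
  stopifnot(inherits(run, "run_record"))
  nyq <- run$fs / 2
  if (low_hz < 0 || high_hz <= low_hz || high_hz > nyq) {
    stop(sprintf("band [%g, %g] Hz outside [0, Nyquist = %g] Hz", low_hz, high_hz, nyq),
         call. = FALSE)
  }
  if (ncol(run$signal) <= 2 * trim) {
    stop("run too short for the requested edge trim", call. = FALSE)
  }
  filt <- if (low_hz == 0) {
    signal::butter(order, high_hz / nyq, type = "low")
  } else {
    signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  }
  filtered <- t(apply(run$signal, 1, function(x) signal::filtfilt(filt, x)))
  keep <- (trim + 1L):(ncol(filtered) - trim)
  run$signal <- filtered[, keep, drop = FALSE]
  if (!is.null(run$motion)) run$motion <- run$motion[keep]
  run
}

#' Censor high-motion frames and flag unusable runs
#'
#' Frames whose framewise displacement exceeds `threshold_mm` are removed from
#' the signal (and motion trace). When the censored fraction reaches
#' `drop_fraction` the run is flagged for removal from the data pool; the
#' censored run is still returned so callers can inspect it.
#'
#' @param run A [run_record()] carrying a motion trace.
#' @param threshold_mm Displacement threshold in mm (default 0.1).
#' @param drop_fraction Censored-fraction at or above which the run is flagged
#'   for removal (default 0.5, i.e. half of the frames).
#' @return The censored [run_record()] with attributes `"flagged"` (logical)
#'   and `"n_censored"` (integer).
#' @export
censor_frames <- function(run, threshold_mm = 0.1, drop_fraction = 0.5) {
  stopifnot(inherits(run, "run_record"))
  if (is.null(run$motion)) {
    stop("run has no motion trace; cannot censor frames", call. = FALSE)
  }
  bad <- run$motion > threshold_mm
  frac <- mean(bad)
  run$signal <- run$signal[, !bad, drop = FALSE]
  run$motion <- run$motion[!bad]
  attr(run, "n_censored") <- sum(bad)
  attr(run, "flagged") <- frac >= drop_fraction
  run
}

#' Pearson correlation matrix of a run
#'
#' Pairwise Pearson correlation between ROI traces. Constant traces have an
#' undefined correlation; their entries are set to 0 with a warning and the
#' diagonal is forced to 1.
#'
#' @param run A [run_record()].
#' @return A symmetric N x N correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(run) {
  stopifnot(inherits(run, "run_record"))
  x <- t(run$signal)
  sds <- apply(x, 2, stats::sd)
  const <- sds == 0
  r <- suppressWarnings(stats::cor(x))
  if (any(const)) {
    warning(sum(const), " constant ROI trace(s); correlations set to 0")
    r[const, ] <- 0
    r[, const] <- 0
  }
  r[is.na(r)] <- 0
  diag(r) <- 1
  r
}

#' Binarize a correlation matrix at a fixed edge density
#'
#' Rank-orders the off-diagonal weights and keeps the strongest fraction `d`,
#' so graphs from different runs and animals have identical edge counts. Ties
#' at the cutoff are broken deterministically in lexicographic (i, j) order.
#' By default edges compete by signed correlation value; set
#' `absolute = TRUE` to rank by magnitude instead.
#'
#' @param corr Symmetric correlation (or weight) matrix.
#' @param d Target edge density in (0, 1]; the retained edge count is
#'   `round(d * N * (N - 1) / 2)`.
#' @param absolute Rank edges by `|weight|` rather than signed weight.
#' @return An object of class `"fc_graph"`: list with elements `adjacency`
#'   (0/1 symmetric, zero diagonal), `density` (requested d) and `n_edges`.
#' @examples
#' r <- run_record(matrix(rnorm(5 * 100), 5, 100), fs = 1)
#' g <- threshold_density(correlation_matrix(r), d = 0.4)
#' g$n_edges
#' @export
threshold_density <- function(corr, d = 0.15, absolute = FALSE) {
  .check_square_symmetric(corr, "correlation matrix")
  if (d <= 0 || d > 1) stop("density d must lie in (0, 1]", call. = FALSE)
  n <- nrow(corr)
  pairs <- .upper_pairs(n)
  w <- corr[pairs]
  if (absolute) w <- abs(w)
  m <- as.integer(round(d * n * (n - 1) / 2))
  # order by decreasing weight, ties by (i, j)
  ord <- order(-w, pairs[, 1], pairs[, 2])
  keep <- ord[seq_len(m)]
  adj <- matrix(0L, n, n)
  adj[pairs[keep, , drop = FALSE]] <- 1L
  adj <- adj + t(adj)
  structure(list(adjacency = adj, density = d, n_edges = m),
            class = "fc_graph")
}

#' Construct a binary graph from an adjacency matrix
#'
#' @param adjacency Symmetric 0/1 matrix with zero diagonal.
#' @return An `"fc_graph"` object; density is computed from the edge count.
#' @export
fc_graph <- function(adjacency) {
  .check_square_symmetric(adjacency, "adjacency")
  if (any(adjacency != 0 & adjacency != 1)) {
    stop("adjacency must be binary", call. = FALSE)
  }
  if (any(diag(adjacency) != 0)) stop("adjacency must have zero diagonal", call. = FALSE)
  n <- nrow(adjacency)
  m <- sum(adjacency) / 2
  structure(list(adjacency = adjacency, density = m / (n * (n - 1) / 2),
                 n_edges = as.integer(m)),
            class = "fc_graph")
}

#' @export
print.fc_graph <- function(x, ...) {
  cat(sprintf("<fc_graph> %d nodes, %d edges (density %.3f)\n",
              nrow(x$adjacency), x$n_edges, x$density))
  invisible(x)
}

#' Fisher r-to-z group average of correlation matrices
#'
#' Element-wise `atanh`, arithmetic mean across matrices, and `tanh` back-
#' transform; the diagonal is forced to 1. Entries at exactly +/-1 are nudged
#' inside the open interval before the transform.
#'
#' @param mats List of symmetric correlation matrices of equal size.
#' @return The group-average correlation matrix.
#' @export
fisher_group_average <- function(mats) {
  if (!is.list(mats) || length(mats) == 0L) {
    stop("mats must be a non-empty list of correlation matrices", call. = FALSE)
  }
  z <- lapply(mats, function(m) {
    .check_square_symmetric(m, "correlation matrix")
    atanh(pmin(pmax(m, -1 + 1e-12), 1 - 1e-12))
  })
  avg <- tanh(Reduce(`+`, z) / length(z))
  diag(avg) <- 1
  avg
}
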