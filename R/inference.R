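#' Hierarchical bootstrap with BCa intervals
#'
#' Resamples the nested structure of a longitudinal design: animals are drawn
#' with replacement, then sessions within each sampled animal, then runs
#' within each sampled session, so every resampled run path exists in the
#' original data (sessions and runs stay yoked to their parents). The
#' statistic is evaluated on each resample's run-level values; the standard
#' error is the bootstrap standard deviation and the confidence interval uses
#' the bias-corrected and accelerated (BCa) method with a jackknife over
#' animals for the acceleration term.
#'
#' @param data Data frame with columns `animal`, `session`, and `value` (one
#'   row per run), or an [fc_dataset()] together with `statistic_run` to
#'   reduce each run to a value.
#' @param statistic Function collapsing a vector of resampled run values to a
#'   scalar (default [mean()]).
#' @param n_iter Bootstrap iterations (default 10000; large studies use more,
#'   the estimate simply tightens).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @param statistic_run Optional function mapping a [run_record()] to a
#'   value, required when `data` is an `fc_dataset`.
#' @return An object of class `"bootstrap_result"`: `estimate`, `se`,
#'   `ci_low`, `ci_high`, `n_iter`, `seed`, `method` ("bca" or
#'   "percentile"), and `replicates`. With a single animal the acceleration
#'   is undefined and a percentile interval is returned with a warning. If
#'   the point estimate falls outside the BCa interval (pathological
#'   distributions) the result is flagged via attribute
#'   `"estimate_outside_ci"` rather than silently clipped.
#' @examples
#' d <- expand.grid(animal = 1:4, session = 1:2, run = 1:2)
#' d$value <- rnorm(nrow(d), mean = 1)
#' hierarchical_bootstrap(d, n_iter = 500, seed = 1)
#' @export
hierarchical_bootstrap <- function(data, statistic = mean, n_iter = 10000L,
                                   seed = 1L, conf = 0.95,
                                   statistic_run = NULL) {
  if (inherits(data, "fc_dataset")) {
    if (is.null(statistic_run)) {
      stop("statistic_run is required to reduce runs of an fc_dataset", call. = FALSE)
    }
    idx <- dataset_index(data)
    data <- data.frame(animal = idx$animal, session = idx$session,
                       value = vapply(data$runs, statistic_run, numeric(1)))
  }
  if (!all(c("animal", "session", "value") %in% names(data))) {
    stop("data needs columns animal, session, value", call. = FALSE)
  }
  if (nrow(data) == 0L) stop("empty dataset", call. = FALSE)
  set.seed(seed)

  animals <- unique(data$animal)
  n_a <- length(animals)
  # pre-split for speed: values per (animal, session)
  by_animal <- split(data, data$animal)
  sess_of <- lapply(by_animal, function(d) split(d$value, d$session))

  resample_once <- function() {
    a_draw <- sample(animals, n_a, replace = TRUE)
    vals <- unlist(lapply(a_draw, function(a) {
      sess <- sess_of[[as.character(a)]]
      s_draw <- sample(names(sess), length(sess), replace = TRUE)
      unlist(lapply(s_draw, function(s) {
        runs <- sess[[s]]
        runs[sample.int(length(runs), length(runs), replace = TRUE)]
      }), use.names = FALSE)
    }), use.names = FALSE)
    statistic(vals)
  }

  est <- statistic(data$value)
  boot <- vapply(seq_len(n_iter), function(i) resample_once(), numeric(1))
  se <- stats::sd(boot)
  alpha <- (1 - conf) / 2

  if (n_a < 2L || se == 0) {
    if (n_a < 2L) warning("single animal: acceleration undefined, using percentile interval")
    ci <- stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE, type = 6)
    method <- "percentile"
  } else {
    # bias correction from the bootstrap distribution
    prop <- mean(boot < est) + 0.5 * mean(boot == est)
    z0 <- stats::qnorm(min(max(prop, 1 / (n_iter + 1)), n_iter / (n_iter + 1)))
    # acceleration from a jackknife over animals (the exchangeable unit)
    jack <- vapply(animals, function(a) {
      statistic(data$value[data$animal != a])
    }, numeric(1))
    jm <- mean(jack)
    num <- sum((jm - jack)^3)
    den <- 6 * (sum((jm - jack)^2))^1.5
    acc <- if (den == 0) 0 else num / den
    zlo <- stats::qnorm(alpha); zhi <- stats::qnorm(1 - alpha)
    a1 <- stats::pnorm(z0 + (z0 + zlo) / (1 - acc * (z0 + zlo)))
    a2 <- stats::pnorm(z0 + (z0 + zhi) / (1 - acc * (z0 + zhi)))
    ci <- stats::quantile(boot, c(a1, a2), names = FALSE, type = 6)
    method <- "bca"
  }

  out <- structure(list(estimate = est, se = se, ci_low = ci[1], ci_high = ci[2],
                        n_iter = as.integer(n_iter), seed = seed,
                        method = method, conf = conf, replicates = boot),
                   class = "bootstrap_result")
  if (est < ci[1] || est > ci[2]) {
    attr(out, "estimate_outside_ci") <- TRUE
    warning("point estimate falls outside the BCa interval (pathological bootstrap distribution)")
  }
  out
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("estimate %.4g (SE %.4g), %g%% %s CI [%.4g, %.4g], %d iterations\n",
              x$estimate, x$se, 100 * x$conf, toupper(x$method),
              x$ci_low, x$ci_high, x$n_iter))
  invisible(x)
}

#' Paired two-sided permutation test
#'
#' Sign-flip test on paired differences: under the null the sign of each
#' pair's difference is exchangeable, so the mean difference is compared to
#' its distribution over sign flips. All `2^n` flips are enumerated when that
#' is within `n_resamples`; otherwise Monte-Carlo flips are drawn and the
#' p-value uses the add-one correction `(b + 1) / (B + 1)`.
#'
#' @param x,y Paired per-animal values.
#' @param n_resamples Resampling budget (default 10000).
#' @param seed Seed for Monte-Carlo mode.
#' @return List with `p_value`, `statistic` (observed mean difference),
#'   `method` ("exact" or "monte_carlo"), and `n_resamples` used.
#' @export
paired_permutation_test <- function(x, y, n_resamples = 10000L, seed = 1L) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  d <- x - y
  n <- length(d)
  obs <- mean(d)
  tol <- 1e-12 * max(1, abs(obs))
  if (2^n <= n_resamples) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    stat <- as.vector(signs %*% d) / n
    p <- mean(abs(stat) >= abs(obs) - tol)
    list(p_value = p, statistic = obs, method = "exact",
         n_resamples = as.integer(2^n))
  } else {
    set.seed(seed)
    signs <- matrix(sample(c(-1, 1), n * n_resamples, replace = TRUE), ncol = n)
    stat <- as.vector(signs %*% d) / n
    b <- sum(abs(stat) >= abs(obs) - tol)
    list(p_value = (b + 1) / (n_resamples + 1), statistic = obs,
         method = "monte_carlo", n_resamples = as.integer(n_resamples))
  }
}

#' Holm-Bonferroni step-down correction
#'
#' @param pvals Vector of p-values.
#' @param alpha Family-wise error level for the decisions.
#' @return List with `p_adjusted` and logical `reject`.
#' @export
holm_bonferroni <- function(pvals, alpha = 0.05) {
  adj <- stats::p.adjust(pvals, method = "holm")
  list(p_adjusted = adj, reject = adj <= alpha)
}

#' Benjamini-Hochberg step-up FDR correction
#'
#' @param pvals Vector of p-values.
#' @param q FDR level for the decisions.
#' @return List with `p_adjusted` and logical `reject`.
#' @export
benjamini_hochberg <- function(pvals, q = 0.05) {
  adj <- stats::p.adjust(pvals, method = "BH")
  list(p_adjusted = adj, reject = adj <= q)
}

#' Hierarchical bootstrap mean and SE of a membership matrix
#'
#' Entry-wise version of [hierarchical_bootstrap()] for run-level membership
#' matrices: each iteration resamples animals, then sessions within animals,
#' then runs within sessions (yoked), averages the selected matrices, and
#' accumulates the element-wise bootstrap mean and standard deviation. The SE
#' matrix feeds the belonging t-statistics.
#'
#' @param mats List of node-by-k run-level membership matrices.
#' @param index Data frame with columns `animal` and `session`, one row per
#'   matrix.
#' @param n_iter Bootstrap iterations.
#' @param seed Integer seed.
#' @return List with `mean` and `se` matrices.
#' @export
hierarchical_bootstrap_matrix <- function(mats, index, n_iter = 1000L, seed = 1L) {
  if (length(mats) != nrow(index)) stop("index must match mats", call. = FALSE)
  set.seed(seed)
  animals <- unique(index$animal)
  by_a <- split(seq_along(mats), index$animal)
  sess_of <- lapply(by_a, function(ii) split(ii, index$session[ii]))
  s1 <- s2 <- matrix(0, nrow(mats[[1]]), ncol(mats[[1]]))
  for (b in seq_len(n_iter)) {
    a_draw <- sample(animals, length(animals), replace = TRUE)
    picked <- unlist(lapply(a_draw, function(a) {
      sess <- sess_of[[as.character(a)]]
      s_draw <- sample(names(sess), length(sess), replace = TRUE)
      unlist(lapply(s_draw, function(s) {
        runs <- sess[[s]]
        runs[sample.int(length(runs), length(runs), replace = TRUE)]
      }), use.names = FALSE)
    }), use.names = FALSE)
    m <- Reduce(`+`, mats[picked]) / length(picked)
    s1 <- s1 + m
    s2 <- s2 + m^2
  }
  mu <- s1 / n_iter
  list(mean = mu, se = sqrt(pmax(s2 / n_iter - mu^2, 0) * n_iter / (n_iter - 1)))
}
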