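#' Simulate a hierarchical multi-animal imaging dataset
#'
#' Emulates the nested design of a longitudinal multimodal study: animals
#' scanned across several sessions with several runs per session. Each
#' community is given an independent latent time course (low-pass-smoothed
#' white noise, so band-limited analyses are meaningful), and each ROI's
#' signal is the membership-weighted mixture of the community time courses
#' plus Gaussian noise:
#' `x_i(t) = sum_k pi_ik s_k(t) + e_i(t)`.
#' Animal-level variability is induced by perturbing the planted membership
#' matrix per animal (and, more weakly, per run) before mixing. Each run also
#' carries a synthetic framewise-displacement trace with occasional spikes so
#' that censoring rules can be exercised.
#'
#' The default design (10 animals x 3 sessions x 4 runs of 10 minutes at
#' 1 Hz) reproduces a 1200-minute acquisition.
#'
#' @param truth Planted node-by-community membership matrix (rows on the
#'   simplex); its row count fixes the ROI count.
#' @param n_animals,n_sessions,n_runs Hierarchy dimensions.
#' @param n_timepoints Frames per run (default 600 = 10 min at 1 Hz).
#' @param noise_sd Standard deviation of additive ROI noise.
#' @param fs Sampling rate in Hz.
#' @param animal_sd Magnitude of the per-animal membership perturbation
#'   (Gaussian on the logits of `truth`, renormalized); 0 removes all
#'   between-animal variance.
#' @param run_sd Magnitude of the additional per-run perturbation.
#' @param lowpass_cutoff Cutoff (Hz) of the smoothing applied to the latent
#'   community time courses; defaults to `0.2 * fs`.
#' @param motion_spike_prob Per-frame probability of a >0.1 mm motion spike.
#' @param condition Condition label stamped on every run.
#' @param seed Integer seed; identical seeds give bit-identical datasets.
#' @return An [fc_dataset()] whose `truth` is the planted membership matrix.
#' @examples
#' truth <- rbind(diag(2)[rep(1, 5), ], diag(2)[rep(2, 5), ])
#' ds <- generate_hierarchical_dataset(truth, n_animals = 2, n_sessions = 1,
#'                                     n_runs = 2, n_timepoints = 120, seed = 1)
#' ds
#' @export
generate_hierarchical_dataset <- function(truth,
                                          n_animals = 10L, n_sessions = 3L,
                                          n_runs = 4L, n_timepoints = 600L,
                                          noise_sd = 0.5, fs = 1,
                                          animal_sd = 0.1, run_sd = 0.02,
                                          lowpass_cutoff = 0.2 * fs,
                                          motion_spike_prob = 0.01,
                                          condition = "bold", seed = 1L) {
  .check_membership(truth)
  set.seed(seed)
  n_rois <- nrow(truth)
  k <- ncol(truth)
  lp <- signal::butter(2, min(lowpass_cutoff / (fs / 2), 0.99), type = "low")

  perturb <- function(pi, sd) {
    if (sd <= 0) return(pi)
    lg <- log(pmax(pi, 1e-6)) + matrix(stats::rnorm(length(pi), 0, sd), nrow(pi))
    .normalize_rows(exp(lg))
  }

  runs <- list()
  for (a in seq_len(n_animals)) {
    pi_a <- perturb(truth, animal_sd)
    for (s in seq_len(n_sessions)) {
      for (r in seq_len(n_runs)) {
        pi_r <- perturb(pi_a, run_sd)
        latent <- vapply(seq_len(k), function(.)
          signal::filtfilt(lp, stats::rnorm(n_timepoints)), numeric(n_timepoints))
        x <- pi_r %*% t(latent) +
          matrix(stats::rnorm(n_rois * n_timepoints, 0, noise_sd), n_rois)
        motion <- abs(stats::rnorm(n_timepoints, 0, 0.02))
        spikes <- stats::runif(n_timepoints) < motion_spike_prob
        motion[spikes] <- motion[spikes] + stats::runif(sum(spikes), 0.1, 0.5)
        runs[[length(runs) + 1L]] <- run_record(
          x, fs = fs,
          animal_id = sprintf("a%02d", a), session_id = sprintf("s%02d", s),
          run_id = sprintf("r%02d", r), condition = condition, motion = motion)
      }
    }
  }
  fc_dataset(runs, truth = truth, seed = seed)
}

#' Planted membership matrix with a controlled overlap fraction
#'
#' Utility truth generator: nodes are split evenly into `k` blocks; a
#' fraction of nodes is made overlapping by mixing their membership between
#' their own block and the next one.
#'
#' @param n_nodes Number of nodes.
#' @param k Number of communities.
#' @param overlap Fraction of nodes given two memberships (default 0,
#'   fully disjoint).
#' @param mix Membership weight moved to the second community for
#'   overlapping nodes (default 0.5, an even split).
#' @param seed Integer seed (which nodes overlap is random).
#' @return A node-by-k membership matrix with rows on the simplex.
#' @export
planted_membership <- function(n_nodes, k, overlap = 0, mix = 0.5, seed = 1L) {
  set.seed(seed)
  block <- rep(seq_len(k), length.out = n_nodes)
  pi <- matrix(0, n_nodes, k)
  pi[cbind(seq_len(n_nodes), block)] <- 1
  n_over <- round(overlap * n_nodes)
  if (n_over > 0) {
    ov <- sample.int(n_nodes, n_over)
    second <- block[ov] %% k + 1L
    pi[cbind(ov, block[ov])] <- 1 - mix
    pi[cbind(ov, second)] <- mix
  }
  pi
}
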